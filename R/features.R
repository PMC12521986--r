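#' Class-average trial prototypes
#'
#' The per-class arithmetic mean over the training trials,
#' `P = (1/m) * sum_i X_i`, one channels x samples matrix per condition.
#' Prototypes are computed from the designated training subset only, so
#' test trials can never leak into them.
#'
#' @param epochs A `nirs_epochs`.
#' @param train_idx Integer indices of the training trials.
#' @return A list of class `nirs_prototypes` with elements `IMAGERY`,
#'   `NO_IMAGERY` (matrices) and `m` (trial counts).
#' @export
compute_prototypes <- function(epochs, train_idx = seq_len(dim(epochs$data)[1])) {
  stopifnot(inherits(epochs, "nirs_epochs"))
  labs <- epochs$labels[train_idx]
  out <- list()
  m <- integer(0)
  for (cl in levels(epochs$labels)) {
    idx <- train_idx[labs == cl]
    if (length(idx) == 0) stopf("class '%s' absent from training subset", cl)
    sub <- epochs$data[idx, , , drop = FALSE]
    out[[cl]] <- apply(sub, c(2, 3), mean)
    m[cl] <- length(idx)
  }
  structure(c(out, list(m = m)), class = "nirs_prototypes")
}

#' Fit xDAWN spatial filters
#'
#' Per class, the `f` leading generalized eigenvectors maximising the
#' ratio of evoked-response power (power of the class-average response)
#' to total signal power across the training trials.  Projecting trials
#' through these filters concentrates the task-evoked response into a
#' few virtual channels.
#'
#' @param epochs A `nirs_epochs`.
#' @param train_idx Training trial indices.
#' @param f Filters per class (2, 4 or 6 in the model grid).
#' @return A list of class `nirs_xdawn`: per-class `f x channels` filter
#'   matrices, their generalized eigenvalues, and `f`.
#' @export
fit_xdawn <- function(epochs, train_idx = seq_len(dim(epochs$data)[1]), f = 4) {
  stopifnot(inherits(epochs, "nirs_epochs"))
  n_ch <- dim(epochs$data)[2]
  ns <- dim(epochs$data)[3]
  if (f > n_ch) stopf("cannot fit %d filters on %d channels", f, n_ch)
  labs <- epochs$labels[train_idx]
  if (any(table(labs) < 2)) stopf("need at least 2 training trials per class")
  # total covariance: average over training trials of X X' / ns
  Cx <- matrix(0, n_ch, n_ch)
  for (i in train_idx) {
    X <- matrix(epochs$data[i, , ], n_ch, ns)
    Cx <- Cx + tcrossprod(X) / ns
  }
  Cx <- Cx / length(train_idx)
  protos <- compute_prototypes(epochs, train_idx)
  filters <- list()
  values <- list()
  regularized <- FALSE
  for (cl in levels(epochs$labels)) {
    Cs <- tcrossprod(protos[[cl]]) / ns
    fit <- xdawn_fit_cpp(Cs, Cx, as.integer(f))
    filters[[cl]] <- fit$filters
    values[[cl]] <- as.numeric(fit$values)
    regularized <- regularized || fit$regularized
  }
  if (regularized)
    warnf("rank-deficient total covariance; xDAWN solve was regularized")
  structure(list(filters = filters, values = values, f = as.integer(f)),
            class = "nirs_xdawn")
}

#' Prototype-augmented, filtered, OAS-shrunk trial covariances
#'
#' Each class prototype is reduced by its own class's `f` filters; every
#' trial is reduced by all `2f` filters; the three blocks are stacked
#' into the augmented matrix `X~_i = [P_IMAGERY; P_NO_IMAGERY; X_i]`
#' (`4f` rows) whose OAS-shrunk covariance represents the trial as a
#' point on the SPD manifold.  Covariances of a trial with the class
#' templates thereby encode trial-to-template similarity.
#'
#' @param epochs A `nirs_epochs` (all trials are transformed).
#' @param prototypes A `nirs_prototypes` fitted on the training subset.
#' @param filters A `nirs_xdawn` fitted on the training subset.
#' @return An object of class `nirs_spdset`: array `matrices`
#'   (`4f x 4f x trials`), per-trial shrinkage `rho`, and `labels`.
#' @export
augment_and_covary <- function(epochs, prototypes, filters) {
  stopifnot(inherits(epochs, "nirs_epochs"),
            inherits(prototypes, "nirs_prototypes"),
            inherits(filters, "nirs_xdawn"))
  cls <- levels(epochs$labels)
  Wa <- filters$filters[[cls[1]]]
  Wb <- filters$filters[[cls[2]]]
  PA <- Wa %*% prototypes[[cls[1]]]
  PB <- Wb %*% prototypes[[cls[2]]]
  W <- rbind(Wa, Wb)
  X <- aperm(epochs$data, c(2, 3, 1))      # channels x samples x trials
  res <- augment_cov_cpp(X, PA, PB, W)
  structure(list(matrices = res$covs, rho = as.numeric(res$rho),
                 labels = epochs$labels, f = filters$f),
            class = "nirs_spdset")
}

#' OAS-shrunk covariance of a single multichannel matrix
#'
#' Oracle approximating shrinkage of the biased sample covariance
#' towards the scaled identity `mu * I`, `mu = tr(S)/p`; the closed-form
#' intensity `rho` lies in `[0, 1]` and the trace is preserved.
#'
#' @param x Numeric matrix, variables x observations.
#' @return List with `sigma` (shrunk covariance) and `rho`.
#' @export
oas_cov <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 1, ncol(x) >= 2)
  res <- oas_cov_cpp(x)
  list(sigma = res$sigma, rho = as.numeric(res$rho))
}
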