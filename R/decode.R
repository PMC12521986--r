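#' Stratified k-fold assignment
#'
#' Trials of each class are shuffled with the given seed and dealt
#' round-robin into folds, so every fold preserves the class balance.
#'
#' @param labels Factor of trial labels.
#' @param k Number of folds.
#' @param seed Integer seed for the within-class shuffle.
#' @return Integer fold id per trial.
#' @export
make_folds <- function(labels, k = 5, seed = 1L) {
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  folds
}

# Accuracy matrix (folds x C values) for one filter count f.  Per fold,
# the fused compiled pipeline fits prototypes, xDAWN filters, augmented
# OAS covariances and the Fréchet reference on the training folds only
# and maps every trial into that fold's tangent space; the per-fold
# features are then shared across all C values.
crossval_core <- function(epochs, labels, folds, f, C_values, cube = NULL) {
  cube <- cube %||% aperm(epochs$data, c(2, 3, 1))
  k <- max(folds)
  y01 <- as.integer(labels == levels(labels)[1])
  acc <- matrix(NA_real_, k, length(C_values))
  for (fold in seq_len(k)) {
    train <- which(folds != fold)
    test <- which(folds == fold)
    pf <- pipeline_features_cpp(cube, train, y01, as.integer(f),
                                tol = 1e-6)
    Xtr <- pf$features[train, , drop = FALSE]
    Xte <- pf$features[test, , drop = FALSE]
    for (j in seq_along(C_values)) {
      fit <- ridge_logistic_cpp(Xtr, y01[train], C_values[j])
      eta <- as.numeric(Xte %*% fit$coef) + fit$intercept
      acc[fold, j] <- mean((eta > 0) == (y01[test] == 1))
    }
  }
  acc
}

#' Cross-validated decoding accuracy for one model configuration
#'
#' Stratified five-fold cross-validation of the complete pipeline:
#' per fold, class prototypes, xDAWN filters, prototype-augmented OAS
#' covariances, the Fréchet reference point and an L2-regularised
#' logistic regression are fitted on the training folds only, and the
#' held-out fold is scored.
#'
#' @param epochs A `nirs_epochs` with at least 5 trials per class.
#' @param f xDAWN filters per class.
#' @param C Inverse regularisation strength of the logistic regression.
#' @param seed Seed for the fold assignment.
#' @param k Number of folds.
#' @param folds Optional explicit fold assignment (overrides `seed`).
#' @param labels Optional label override (used by the permutation test).
#' @return An object of class `nirs_cv`: `fold_accuracies`,
#'   `mean_accuracy`, `f`, `C`, `seed`.
#' @export
crossval_accuracy <- function(epochs, f = 4, C = 10, seed = 1L, k = 5,
                              folds = NULL, labels = NULL) {
  stopifnot(inherits(epochs, "nirs_epochs"))
  labels <- labels %||% epochs$labels
  if (any(table(labels) < k))
    stopf("each class needs at least %d trials for %d-fold CV", k, k)
  folds <- folds %||% make_folds(labels, k, seed)
  acc <- crossval_core(epochs, labels, folds, f, C)
  structure(list(fold_accuracies = as.numeric(acc),
                 mean_accuracy = mean(acc),
                 f = f, C = C, seed = seed),
            class = "nirs_cv")
}

#' @export
print.nirs_cv <- function(x, ...) {
  cat(sprintf("<nirs_cv> f=%d C=%g: mean accuracy %.3f (folds %s)\n",
              x$f, x$C, x$mean_accuracy,
              paste(sprintf("%.2f", x$fold_accuracies), collapse = " ")))
  invisible(x)
}

#' Hyperparameter grid search over the decoding model
#'
#' Evaluates all combinations of xDAWN filter counts and logistic
#' regularisation strengths (12 configurations by default) with one
#' shared stratified fold assignment, and selects the configuration with
#' the highest mean cross-validated accuracy.  Exact ties resolve to the
#' smallest `f`, then the smallest `C`.
#'
#' @param epochs A `nirs_epochs`.
#' @param seed Seed for the shared fold assignment.
#' @param f_grid,C_grid Hyperparameter grids.
#' @param k Number of folds.
#' @param labels Optional label override.
#' @return An object of class `nirs_search`: tibble `results` (one row
#'   per configuration), `best` (list with `f`, `C`), `best_accuracy`,
#'   `folds`, `seed`.
#' @export
grid_search <- function(epochs, seed = 1L, f_grid = c(2, 4, 6),
                        C_grid = c(1, 10, 100, 1000), k = 5,
                        labels = NULL) {
  stopifnot(inherits(epochs, "nirs_epochs"))
  labels <- labels %||% epochs$labels
  folds <- make_folds(labels, k, seed)
  cube <- aperm(epochs$data, c(2, 3, 1))
  rows <- list()
  for (f in f_grid) {
    acc <- crossval_core(epochs, labels, folds, f, C_grid, cube)
    for (j in seq_along(C_grid))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        f = f, C = C_grid[j],
        mean_accuracy = mean(acc[, j]),
        fold_accuracies = list(as.numeric(acc[, j])))
  }
  results <- do.call(rbind, rows)
  best_i <- which.max(results$mean_accuracy)  # grids ascending => tie-break
  structure(list(results = results,
                 best = list(f = results$f[best_i], C = results$C[best_i]),
                 best_accuracy = results$mean_accuracy[best_i],
                 folds = folds, seed = seed),
            class = "nirs_search")
}

#' @export
print.nirs_search <- function(x, ...) {
  cat(sprintf("<nirs_search> best f=%d C=%g, accuracy %.3f over %d configs\n",
              x$best$f, x$best$C, x$best_accuracy, nrow(x$results)))
  invisible(x)
}
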