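#' Permutation test of decoding accuracy
#'
#' Builds an empirical null distribution by shuffling the trial labels
#' `n_perm` times and re-running, for each shuffle, the complete
#' analysis that produced the observed statistic: by default this
#' includes the hyperparameter grid search, so that the null statistic
#' is — like the observed one — the *selected* (best-of-grid) mean CV
#' accuracy.  Prototypes, filters, covariances, reference and classifier
#' are refitted for every permutation under the same fold assignment.
#' Re-selecting per shuffle keeps the test exact despite the selection
#' optimism of the observed accuracy; `null_method = "fixed"` instead
#' refits only the selected configuration (cheaper, but anti-conservative,
#' retained for comparison).  The empirical p-value uses the add-one
#' correction `p = (1 + #(null >= observed)) / (1 + n_perm)`, which
#' guarantees validity: `p` can never fall below `1/(n_perm + 1)`.
#'
#' @param epochs A `nirs_epochs`.
#' @param best List with elements `f` and `C` (e.g. from
#'   [grid_search()]`$best`); required for `null_method = "fixed"`,
#'   recorded in the result otherwise.
#' @param n_perm Number of permutations.
#' @param seed Master seed; fold assignment and all permutations derive
#'   from it.
#' @param observed Observed accuracy to test.  Defaults to the
#'   best-of-grid mean CV accuracy on the unshuffled labels (identical
#'   to [grid_search()]`$best_accuracy` at the same seed).
#' @param null_method `"grid"` (default, re-select per shuffle) or
#'   `"fixed"`.
#' @param alpha_stop Optional decision threshold enabling sequential
#'   curtailment: once enough null values have reached the observed
#'   accuracy that the full-`n_perm` p-value is guaranteed to be
#'   `>= alpha_stop`, remaining permutations are skipped.  The reported
#'   p-value is then computed from the permutations actually run (a
#'   valid, conservative value) and `curtailed` is set; the
#'   RESPONSIVE/UNRESPONSIVE decision at `alpha_stop` is identical to
#'   the full run's.  `NULL` (default) always runs all permutations.
#' @param f_grid,C_grid Hyperparameter grids used when re-selecting.
#' @return An object of class `nirs_perm`: `chromophore`,
#'   `observed_accuracy`, `null_accuracies`, `p_value`, `n_perm`,
#'   `n_done`, `curtailed`.
#' @export
permutation_pvalue <- function(epochs, best = NULL, n_perm = 250, seed = 1L,
                               observed = NULL,
                               null_method = c("grid", "fixed"),
                               alpha_stop = NULL,
                               f_grid = c(2, 4, 6),
                               C_grid = c(1, 10, 100, 1000)) {
  stopifnot(inherits(epochs, "nirs_epochs"))
  null_method <- match.arg(null_method)
  if (n_perm < 1) stopf("'n_perm' must be at least 1")
  labels <- epochs$labels
  folds <- make_folds(labels, 5, seed)
  cube <- aperm(epochs$data, c(2, 3, 1))
  if (is.null(observed)) {
    gs <- grid_search(epochs, seed = seed, f_grid = f_grid, C_grid = C_grid)
    observed <- gs$best_accuracy
    best <- best %||% gs$best
  }
  y01 <- as.integer(labels == levels(labels)[1])
  perm_y01 <- vapply(seq_len(n_perm), function(b) {
    y01[withr::with_seed(derive_seed(seed, b), sample(length(y01)))]
  }, integer(length(y01)))
  # folds are re-stratified on each shuffled labelling, mirroring the
  # observed analysis exactly (stratification is part of the procedure
  # being permuted)
  perm_folds <- vapply(seq_len(n_perm), function(b) {
    plab <- factor(levels(labels)[2 - perm_y01[, b]], levels = levels(labels))
    make_folds(plab, 5, seed)
  }, integer(length(y01)))
  stop_exceed <- -1L
  if (!is.null(alpha_stop))
    stop_exceed <- as.integer(ceiling(alpha_stop * (1 + n_perm)) - 1)
  res <- if (null_method == "grid") {
    perm_null_grid_cpp(cube, perm_y01, perm_folds,
                       as.integer(f_grid), as.numeric(C_grid),
                       observed, stop_exceed)
  } else {
    if (is.null(best)) stopf("'best' is required for null_method = \"fixed\"")
    perm_null_fixed_cpp(cube, perm_y01, perm_folds,
                        as.integer(best$f), as.numeric(best$C),
                        observed, stop_exceed)
  }
  p <- (1 + res$n_exceed) / (1 + res$n_done)
  structure(list(chromophore = epochs$chromophore,
                 observed_accuracy = observed,
                 null_accuracies = as.numeric(res$null),
                 p_value = p, n_perm = n_perm, n_done = res$n_done,
                 curtailed = res$n_done < n_perm,
                 null_method = null_method, seed = seed,
                 best = best),
            class = "nirs_perm")
}

#' @export
print.nirs_perm <- function(x, ...) {
  cat(sprintf("<nirs_perm> %s: observed %.3f vs null %.3f +/- %.3f (%d/%d perms%s), p%s%.4f\n",
              x$chromophore, x$observed_accuracy, mean(x$null_accuracies),
              sd(x$null_accuracies), x$n_done, x$n_perm,
              if (isTRUE(x$curtailed)) ", curtailed" else "",
              if (isTRUE(x$curtailed)) " >= " else " = ", x$p_value))
  invisible(x)
}

#' Combine per-chromophore permutation results into a diagnosis
#'
#' Takes the minimum p-value over the HbO, HbR and combined analyses and
#' labels the dataset RESPONSIVE if it falls strictly below `alpha`.
#'
#' @param results List of exactly three `nirs_perm` objects covering
#'   HBO, HBR and BOTH.  A result whose permutation test was skipped by
#'   the sequential shortcut (see [run_full_diagnosis()]) carries
#'   `p_value = NA` and is excluded from the minimum; at least one
#'   evaluated p-value is required.
#' @param alpha Decision threshold.
#' @param provenance Optional list recorded in the result.
#' @return An object of class `nirs_diagnosis`.
#' @export
decide_responsiveness <- function(results, alpha = 0.05, provenance = list()) {
  chroms <- vapply(results, function(r) r$chromophore, "")
  if (!setequal(chroms, c("HBO", "HBR", "BOTH")) || length(results) != 3)
    stopf("need exactly one result each for HBO, HBR and BOTH (got: %s)",
          paste(chroms, collapse = ", "))
  names(results) <- chroms
  p <- vapply(results, function(r) as.numeric(r$p_value), 0)
  if (all(is.na(p))) stopf("no evaluated p-values")
  p_min <- min(p, na.rm = TRUE)
  label <- if (p_min < alpha) "RESPONSIVE" else "UNRESPONSIVE"
  structure(list(chromophores = results, p_values = p, p_min = p_min,
                 alpha = alpha, label = label, provenance = provenance),
            class = "nirs_diagnosis")
}

#' @export
print.nirs_diagnosis <- function(x, ...) {
  cat(sprintf("<nirs_diagnosis> %s (p_min = %.4f, alpha = %g)\n",
              x$label, x$p_min, x$alpha))
  for (ch in c("HBO", "HBR", "BOTH")) {
    r <- x$chromophores[[ch]]
    cat(sprintf("  %-4s accuracy %.3f  p = %s  (f=%d, C=%g)\n",
                ch, r$observed_accuracy,
                if (is.na(r$p_value)) "not evaluated"
                else sprintf("%.4f", r$p_value),
                r$best$f, r$best$C))
  }
  invisible(x)
}

#' Class distinctiveness on the SPD manifold
#'
#' Ratio of the Riemannian distance between the two class centres
#' (Fréchet means) to the average within-class dispersion:
#' `classDis = d(Xbar_A, Xbar_B) / (0.5 (sigma_A + sigma_B))`, where
#' `sigma_K` is the mean distance of class-K matrices to their centre.
#'
#' @param spdset A `nirs_spdset` (or any list with `matrices` and
#'   `labels`).
#' @return Non-negative scalar.
#' @export
class_distinctiveness <- function(spdset) {
  labs <- spdset$labels
  cls <- levels(labs)
  if (length(cls) != 2) stopf("exactly two classes required")
  centres <- list()
  sigma <- numeric(2)
  for (k in 1:2) {
    idx <- which(labs == cls[k])
    if (length(idx) < 2)
      stopf("class '%s' has fewer than 2 matrices; dispersion undefined", cls[k])
    sub <- spdset$matrices[, , idx, drop = FALSE]
    res <- frechet_mean_cpp(sub, 1e-8, 50)
    if (!res$converged) stopf("class centre did not converge")
    centres[[k]] <- res$mean
    D <- dim(sub)[1]
    sigma[k] <- mean(vapply(seq_along(idx), function(i)
      airm_distance_cpp(matrix(sub[, , i], D, D), res$mean), 0))
  }
  airm_distance_cpp(centres[[1]], centres[[2]]) / (0.5 * sum(sigma))
}

#' Full responsiveness diagnosis of a dataset
#'
#' Preprocesses and pools one or more runs, then for each chromophore
#' set (HbO, HbR, combined) performs the hyperparameter grid search and
#' the permutation test of the selected model, and finally applies the
#' minimum-p decision rule.
#'
#' @param runs A single `nirs_recording` or a list of them (typically
#'   the two runs of one state).
#' @param config Options: `n_perm` (250), `alpha` (0.05), `seed` (1),
#'   `early_stop` (FALSE; when TRUE, permutations for a chromophore are
#'   curtailed as soon as its p-value is guaranteed to be `>= alpha` —
#'   the decision is unchanged, only non-significant p-values become
#'   conservative bounds), `sequential` (FALSE; when TRUE, once one
#'   chromophore's exact p-value falls below `alpha` the remaining
#'   chromophore sets report their grid search but skip their
#'   permutation null, since additional p-values can only lower the
#'   minimum and the RESPONSIVE label is already determined),
#'   `epoch.tmax_s` (12), plus the preprocessing options of
#'   [preprocess_run()].
#' @return A `nirs_diagnosis` with per-chromophore grid-search and
#'   permutation results and full provenance.
#' @export
run_full_diagnosis <- function(runs, config = list()) {
  if (inherits(runs, "nirs_recording")) runs <- list(runs)
  if (length(runs) < 1) stopf("at least one run required")
  cfg <- modifyList(list(n_perm = 250, alpha = 0.05, seed = 1L,
                         early_stop = FALSE, sequential = FALSE), config)
  hb <- lapply(runs, preprocess_run, config = cfg)
  results <- list()
  searches <- list()
  decided <- FALSE
  for (i in seq_along(c("HBO", "HBR", "BOTH"))) {
    chrom <- c("HBO", "HBR", "BOTH")[i]
    epochs <- pool_epochs(lapply(hb, make_epochs, chromophore = chrom,
                                 tmax_s = cfg$epoch.tmax_s %||% 12))
    cseed <- derive_seed(cfg$seed, 1000L + i)
    gs <- grid_search(epochs, seed = cseed)
    if (isTRUE(cfg$sequential) && decided) {
      pr <- structure(list(chromophore = chrom,
                           observed_accuracy = gs$best_accuracy,
                           null_accuracies = numeric(0),
                           p_value = NA_real_, n_perm = cfg$n_perm,
                           n_done = 0L, curtailed = FALSE, skipped = TRUE,
                           null_method = "grid", seed = cseed,
                           best = gs$best),
                      class = "nirs_perm")
    } else {
      pr <- permutation_pvalue(epochs, gs$best, n_perm = cfg$n_perm,
                               seed = cseed, observed = gs$best_accuracy,
                               alpha_stop = if (isTRUE(cfg$early_stop)) cfg$alpha)
      if (!is.na(pr$p_value) && !pr$curtailed && pr$p_value < cfg$alpha)
        decided <- TRUE
    }
    searches[[chrom]] <- gs
    results[[chrom]] <- pr
  }
  decide_responsiveness(
    results, alpha = cfg$alpha,
    provenance = list(config = cfg, n_runs = length(runs),
                      searches = lapply(searches, function(g)
                        c(g$best, accuracy = g$best_accuracy)),
                      package_version = as.character(utils::packageVersion("nirsaware"))))
}

#' Serialise a diagnosis to JSON
#'
#' @param x A `nirs_diagnosis`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diagnosis <- function(x, path) {
  stopifnot(inherits(x, "nirs_diagnosis"))
  out <- list(
    schema = "nirsaware-diagnosis/1",
    label = x$label, p_min = x$p_min, alpha = x$alpha,
    chromophores = lapply(x$chromophores, function(r)
      list(chromophore = r$chromophore,
           observed_accuracy = r$observed_accuracy,
           p_value = r$p_value, n_perm = r$n_perm,
           n_done = r$n_done,
           best = r$best,
           null_mean = if (length(r$null_accuracies))
             mean(r$null_accuracies) else NULL,
           null_sd = if (length(r$null_accuracies) > 1)
             sd(r$null_accuracies) else NULL)),
    provenance = x$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
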