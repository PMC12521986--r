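# Tidy summaries and plots of fitted result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a grid-search result
#'
#' @param x A `nirs_search`.
#' @param ... Unused.
#' @return One row per configuration: `f`, `C`, `mean_accuracy`.
#' @export
tidy.nirs_search <- function(x, ...) {
  tibble::tibble(f = x$results$f, C = x$results$C,
                 mean_accuracy = x$results$mean_accuracy)
}

#' @rdname tidy.nirs_search
#' @export
glance.nirs_search <- function(x, ...) {
  tibble::tibble(best_f = x$best$f, best_C = x$best$C,
                 best_accuracy = x$best_accuracy,
                 n_configs = nrow(x$results))
}

#' Tidy a diagnosis
#'
#' @param x A `nirs_diagnosis`.
#' @param ... Unused.
#' @return One row per chromophore set with observed accuracy, null
#'   summary and p-value.
#' @export
tidy.nirs_diagnosis <- function(x, ...) {
  do.call(rbind, lapply(x$chromophores, function(r)
    tibble::tibble(chromophore = r$chromophore,
                   observed_accuracy = r$observed_accuracy,
                   null_mean = if (length(r$null_accuracies))
                     mean(r$null_accuracies) else NA_real_,
                   null_sd = if (length(r$null_accuracies) > 1)
                     sd(r$null_accuracies) else NA_real_,
                   p_value = r$p_value,
                   n_perm = r$n_perm)))
}

#' @rdname tidy.nirs_diagnosis
#' @export
glance.nirs_diagnosis <- function(x, ...) {
  tibble::tibble(label = x$label, p_min = x$p_min, alpha = x$alpha)
}

#' Plot the permutation null against the observed accuracy
#'
#' Histogram of the null accuracies of each chromophore set with the
#' observed cross-validated accuracy marked.
#'
#' @param object A `nirs_diagnosis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.nirs_diagnosis <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("ggplot2 is required for plotting")
  nulls <- do.call(rbind, lapply(object$chromophores, function(r)
    data.frame(chromophore = r$chromophore, accuracy = r$null_accuracies)))
  obs <- do.call(rbind, lapply(object$chromophores, function(r)
    data.frame(chromophore = r$chromophore, accuracy = r$observed_accuracy,
               p = r$p_value)))
  ggplot2::ggplot(nulls, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 25, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$accuracy),
                        colour = "red", linewidth = 0.8) +
    ggplot2::facet_wrap(~chromophore) +
    ggplot2::labs(x = "cross-validated accuracy", y = "permutations",
                  title = sprintf("%s (p_min = %.3f)",
                                  object$label, object$p_min)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
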