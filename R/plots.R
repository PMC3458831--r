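#' Plot the permutation null distributions of an MRM fit
#'
#' Histograms of the permuted |coefficient| per predictor with the observed
#' value marked; requires a fit run with `keep_perms = TRUE`.
#'
#' @param object An [mrm()] result.
#' @param statistic `"beta"` (permuted absolute coefficients) or `"ss"`
#'   (permuted sequential sums of squares).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mrm
#' @export
autoplot.mrm <- function(object, statistic = c("beta", "ss"), ...) {
  statistic <- match.arg(statistic)
  if (is.null(object$perm_stats)) {
    stop("fit was run with keep_perms = FALSE; nothing to plot", call. = FALSE)
  }
  mat <- if (statistic == "beta") object$perm_stats$abs_beta else object$perm_stats$seq_ss
  obs <- if (statistic == "beta") abs(object$coefficients) else object$seq_ss
  long <- as_tibble(mat) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "term", values_to = "value")
  obs_df <- tibble(term = names(obs), observed = unname(obs))
  lab <- if (statistic == "beta") "permuted |beta|" else "permuted sequential SS"
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(
      data = obs_df, ggplot2::aes(xintercept = .data$observed),
      colour = "firebrick", linewidth = 0.8
    ) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = lab, y = "count") +
    ggplot2::theme_minimal()
}

#' Plot posterior topology-test frequencies
#'
#' Bar chart of the posterior percentage of trees consistent with each
#' hypothesis.
#'
#' @param object A [posterior_frequency()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pp_result
#' @export
autoplot.pp_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$hypothesis, y = .data$pp)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f%% (N=%d)", .data$pp_display, .data$n_consistent)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(x = NULL, y = "posterior frequency (% of trees)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
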