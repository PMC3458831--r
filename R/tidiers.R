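#' Tidy a distance-matrix regression fit
#'
#' One row per predictor with the coefficient, partial correlation,
#' sequential sum of squares and (when the fit carries permutation tests)
#' the permutation p-values.
#'
#' @param x An [mrm_fit()] or [mrm()] object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `partial_corr`,
#'   `seq_ss`, and for permutation fits `p_beta`, `p_ss`.
#' @method tidy mrm_fit
#' @export
tidy.mrm_fit <- function(x, ...) {
  out <- tibble(
    term = x$terms,
    estimate = unname(x$coefficients),
    partial_corr = unname(x$partial_corr),
    seq_ss = unname(x$seq_ss)
  )
  if (!is.null(x$p_beta)) {
    out$p_beta <- unname(x$p_beta)
    out$p_ss <- unname(x$p_ss)
  }
  out
}

#' One-row model summary of a distance-matrix regression
#'
#' @inheritParams tidy.mrm_fit
#' @return A tibble with `n_taxa`, `n_pairs`, `sst`, `sse`,
#'   `percent_variance`, `intercept`, and for permutation fits
#'   `permutations`.
#' @method glance mrm_fit
#' @export
glance.mrm_fit <- function(x, ...) {
  out <- tibble(
    n_taxa = x$n_taxa,
    n_pairs = x$n_pairs,
    sst = x$sst,
    sse = x$sse,
    percent_variance = x$percent_variance,
    intercept = x$intercept
  )
  if (!is.null(x$permutations)) out$permutations <- x$permutations
  out
}
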