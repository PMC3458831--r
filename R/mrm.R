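#' Vectorize the lower triangle of a symmetric distance matrix
#'
#' Returns the n(n-1)/2 off-diagonal entries (i, j) with i > j in the
#' matrix's label order, row-major — the pairwise observations that distance
#' matrix regression is fitted on.
#'
#' @param m A symmetric numeric matrix, n >= 3.
#' @param tol Asymmetry tolerance: `max |m - t(m)|` above this errors.
#' @return Numeric vector of length n(n-1)/2; names are `"i|j"` pair labels
#'   when the matrix is labeled.
#' @export
vectorize_lower <- function(m, tol = 1e-9) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), nrow(m) >= 3)
  if (max(abs(m - t(m))) > tol) {
    stop("matrix is asymmetric beyond tolerance ", tol, call. = FALSE)
  }
  v <- t(m)[upper.tri(m)]
  if (!is.null(rownames(m))) {
    n <- nrow(m)
    ii <- rep(2:n, times = 1:(n - 1))
    jj <- unlist(lapply(2:n, function(i) 1:(i - 1)))
    names(v) <- paste(rownames(m)[ii], rownames(m)[jj], sep = "|")
  }
  v
}

# Align predictor matrices to the response's taxon order; error if the label
# sets differ.
align_matrices <- function(Y, Xs) {
  if (is.null(rownames(Y))) stop("response matrix must be labeled", call. = FALSE)
  if (is.matrix(Xs)) Xs <- list(X = Xs)
  if (is.null(names(Xs)) || any(!nzchar(names(Xs)))) {
    names(Xs) <- paste0("X", seq_along(Xs))
  }
  labs <- rownames(Y)
  Xs <- lapply(Xs, function(x) {
    if (is.null(rownames(x))) stop("all predictor matrices must be labeled", call. = FALSE)
    reorder_matrix(x, labs)
  })
  Xs
}

#' Ordinary least squares on vectorized distance matrices
#'
#' Regresses the lower triangle of `Y` on the lower triangles of the
#' predictor matrices (plus an intercept) and reports, per predictor: the
#' coefficient, the partial correlation (correlation of the residuals of `Y`
#' and of that predictor on all other predictors), and the sequential
#' (type-I) sum of squares in the supplied predictor order. The sequential
#' sums of squares and the error sum of squares add up exactly to the total
#' sum of squares, and the percent variance explained is
#' `100 * (SST - SSE) / SST`.
#'
#' @param Y Labeled symmetric response matrix (e.g. node distance).
#' @param Xs Named list of labeled symmetric predictor matrices, in the
#'   order in which sequential sums of squares are wanted.
#' @return An object of class `mrm_fit`; see [tidy.mrm_fit()] and
#'   [glance.mrm_fit()].
#' @seealso [mrm()] for permutation significance tests.
#' @export
mrm_fit <- function(Y, Xs) {
  Xs <- align_matrices(Y, Xs)
  y <- vectorize_lower(Y)
  if (stats::var(y) == 0) stop("response matrix has zero variance", call. = FALSE)
  design <- cbind(`(Intercept)` = 1, vapply(Xs, vectorize_lower, numeric(length(y))))
  p <- ncol(design)
  qd <- qr(design)
  if (qd$rank < p) {
    dropped <- colnames(design)[qd$pivot[(qd$rank + 1):p]]
    stop(
      "rank-deficient design; collinear or constant predictor(s): ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
  }
  if (!identical(qd$pivot, seq_len(p))) { # refit preserving column order
    qd <- qr(design, tol = 1e-12)
    if (!identical(qd$pivot, seq_len(p))) {
      stop("design columns are too ill-conditioned to keep in order; rescale predictors", call. = FALSE)
    }
  }
  qty <- qr.qty(qd, y)[seq_len(p)]
  coefs <- qr.coef(qd, y)
  seq_ss <- qty[-1]^2
  names(seq_ss) <- names(Xs)
  sst <- sum((y - mean(y))^2)
  sse <- sum(y^2) - sum(qty^2)
  partial <- vapply(seq_along(Xs), function(k) {
    other <- design[, -(k + 1), drop = FALSE]
    qo <- qr(other)
    cor(qr.resid(qo, y), qr.resid(qo, design[, k + 1]))
  }, numeric(1))
  names(partial) <- names(Xs)
  structure(
    list(
      terms = names(Xs),
      intercept = unname(coefs[1]),
      coefficients = setNames(unname(coefs[-1]), names(Xs)),
      partial_corr = partial,
      seq_ss = seq_ss,
      sst = sst,
      sse = sse,
      percent_variance = 100 * (sst - sse) / sst,
      n_taxa = nrow(Y),
      n_pairs = length(y),
      qr = qd,
      y = y
    ),
    class = "mrm_fit"
  )
}

#' Multiple regression on distance matrices with permutation tests
#'
#' Fits [mrm_fit()] and assesses significance by matrix permutation: for
#' each resample a uniform random permutation of the n taxa (the identity is
#' never used) is applied simultaneously to the rows and columns of the
#' response matrix only, and the model is refitted. Reported p-values use
#' the add-one convention `p = (b + 1) / (R + 1)`, two-sided for
#' coefficients (absolute value) and upper-tailed for sequential sums of
#' squares, so the smallest attainable p is `1 / (R + 1)`.
#'
#' `permutations = "exhaustive"` enumerates all n! simultaneous row/column
#' permutations (n <= 8) and returns exact permutation p-values
#' `p = #\{permutations with statistic >= observed\} / n!` (the identity
#' permutation always counts, so the two conventions agree).
#'
#' @inheritParams mrm_fit
#' @param permutations Number of random permutations R (e.g. 9999), or
#'   `"exhaustive"`.
#' @param seed Integer seed driving the permutation stream (one generator,
#'   Fisher-Yates draws); `NULL` uses the current RNG state.
#' @param permute `"response"` (default; Manly's scheme for symmetric
#'   matrices) or `"predictors"`, a sensitivity variant that permutes all
#'   predictor matrices jointly while holding the response fixed.
#' @param keep_perms Keep the permutation null distributions (matrices of
#'   permuted |beta| and sequential SS) in the result, for plotting.
#' @return An object of class `mrm` (inherits `mrm_fit`) adding `p_beta`,
#'   `p_ss`, `permutations`, `seed`, `permute` and (optionally) `perm_stats`.
#' @examples
#' set.seed(1)
#' sim <- simulate_mrm_dataset(n = 12, seed = 7)
#' fit <- mrm(sim$Y, sim$X, permutations = 199, seed = 42)
#' tidy(fit)
#' @export
mrm <- function(Y, Xs, permutations = 9999, seed = NULL, permute = c("response", "predictors"),
                keep_perms = TRUE) {
  permute <- match.arg(permute)
  fit <- mrm_fit(Y, Xs)
  n <- fit$n_taxa
  exhaustive <- identical(permutations, "exhaustive")
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration supported for n <= 8 taxa", call. = FALSE)
    perms <- all_permutations(n)
  } else {
    stopifnot(is.numeric(permutations), length(permutations) == 1L, permutations >= 1)
    R <- as.integer(permutations)
    perms <- with_seed(seed, draw_permutations(n, R))
  }
  if (permute == "predictors") {
    # Permuting every predictor by P equals permuting the response by P^-1
    # up to relabeling, which leaves all fitted statistics unchanged.
    perms <- t(apply(perms, 1, order))
  }
  stats <- perm_stats(fit, perms)
  np <- nrow(perms)
  obs_beta <- abs(fit$coefficients)
  obs_ss <- fit$seq_ss
  eps <- 1e-9
  b_ge <- colSums(stats$abs_beta >= rep(obs_beta * (1 - eps), each = np))
  s_ge <- colSums(stats$seq_ss >= rep(obs_ss * (1 - eps), each = np))
  if (exhaustive) {
    p_beta <- b_ge / np
    p_ss <- s_ge / np
  } else {
    p_beta <- (b_ge + 1) / (np + 1)
    p_ss <- (s_ge + 1) / (np + 1)
  }
  fit$p_beta <- setNames(p_beta, fit$terms)
  fit$p_ss <- setNames(p_ss, fit$terms)
  fit$permutations <- np
  fit$exhaustive <- exhaustive
  fit$seed <- seed
  fit$permute <- permute
  if (keep_perms) fit$perm_stats <- stats
  class(fit) <- c("mrm", "mrm_fit")
  fit
}

# Draw R uniform random non-identity permutations of 1..n (rows).
draw_permutations <- function(n, R) {
  perms <- matrix(0L, R, n)
  id <- seq_len(n)
  for (r in seq_len(R)) {
    repeat {
      p <- sample.int(n)
      if (!identical(p, id)) break
    }
    perms[r, ] <- p
  }
  perms
}

# Refit statistics for every permutation (rows of `perms`). Only the
# response vector changes, so the design's QR is reused: permuted
# coefficients are backsolve(R, Q'y*) and the sequential SS of predictor k
# is the squared k-th component of Q'y* past the intercept. Chunked so the
# gathered response matrix stays small.
perm_stats <- function(fit, perms, chunk = 512L) {
  n <- fit$n_taxa
  p <- length(fit$terms)
  pim <- pair_index_matrix(n)
  ii <- rep(2:n, times = 1:(n - 1))
  jj <- unlist(lapply(2:n, function(i) 1:(i - 1)))
  y <- unname(fit$y)
  qd <- fit$qr
  Rmat <- qr.R(qd)
  np <- nrow(perms)
  abs_beta <- matrix(0, np, p)
  seq_ss <- matrix(0, np, p)
  for (start in seq(1L, np, by = chunk)) {
    rows <- start:min(start + chunk - 1L, np)
    Ym <- vapply(rows, function(r) {
      pr <- perms[r, ]
      y[pim[cbind(pr[ii], pr[jj])]]
    }, numeric(length(y)))
    qty <- qr.qty(qd, Ym)[seq_len(p + 1), , drop = FALSE]
    betas <- backsolve(Rmat, qty)
    abs_beta[rows, ] <- t(abs(betas[-1, , drop = FALSE]))
    seq_ss[rows, ] <- t(qty[-1, , drop = FALSE]^2)
  }
  colnames(abs_beta) <- colnames(seq_ss) <- fit$terms
  list(abs_beta = abs_beta, seq_ss = seq_ss)
}

#' Variance decomposition identities of a sequential-SS regression
#'
#' Given a total sum of squares and the per-predictor sequential sums of
#' squares, returns the error sum of squares `SSE = SST - sum(SS)` and the
#' percent variance explained `100 * (SST - SSE) / SST` — the footer
#' quantities of an MRM table.
#'
#' @param sst Total sum of squares.
#' @param seq_ss Numeric vector of sequential sums of squares.
#' @return A tibble with columns `model_ss`, `sse`, `percent_variance`.
#' @export
variance_decomposition <- function(sst, seq_ss) {
  stopifnot(sst > 0, all(seq_ss >= 0), sum(seq_ss) <= sst + 1e-8 * sst)
  model_ss <- sum(seq_ss)
  sse <- sst - model_ss
  tibble(
    model_ss = model_ss,
    sse = sse,
    percent_variance = 100 * model_ss / sst
  )
}

#' @export
print.mrm_fit <- function(x, digits = 4, ...) {
  cat("Multiple regression on distance matrices (", x$n_taxa, " taxa, ",
    x$n_pairs, " pairs)\n",
    sep = ""
  )
  cat("Total sum of squares:", format(x$sst, nsmall = digits), "\n")
  tab <- data.frame(
    `Partial Corr.` = round(x$partial_corr, 6),
    Beta = round(x$coefficients, 6),
    SS = round(x$seq_ss, digits),
    check.names = FALSE
  )
  if (!is.null(x$p_beta)) {
    tab$`P(Beta)` <- round(x$p_beta, digits)
    tab$`P(SS)` <- round(x$p_ss, digits)
  }
  print(tab)
  cat("Error sum of squares:", format(x$sse, nsmall = digits), "\n")
  cat(
    "Percent of the variance explained by the model:",
    format(round(x$percent_variance, 2), nsmall = 2), "\n"
  )
  if (!is.null(x$permutations)) {
    cat(
      "Permutations:", x$permutations,
      if (isTRUE(x$exhaustive)) "(exhaustive)" else "",
      "scheme:", x$permute, "\n"
    )
  }
  invisible(x)
}
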