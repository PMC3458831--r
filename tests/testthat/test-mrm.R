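test_that("lower-triangle vectorization is row-major with exact pair bookkeeping", {
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  v <- vectorize_lower(m)
  expect_length(v, 3)
  expect_equal(unname(v), c(1, 2, 3)) # (B,A), (C,A), (C,B)

  expect_equal(unname(vectorize_lower(matrix(0, 4, 4))), rep(0, 6))

  asym <- m
  asym[1, 2] <- 5
  expect_error(vectorize_lower(asym), "asymmetric")

  # permuting rows/cols then vectorizing equals applying the induced pair
  # permutation to the vector (indices computed by explicit loops)
  set.seed(5)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    m <- random_dist_matrix(n)
    perm <- sample(n)
    v1 <- unname(vectorize_lower(permute_matrix(m, perm)))
    pos <- function(i, j) {
      a <- max(i, j)
      b <- min(i, j)
      (a - 1) * (a - 2) / 2 + b
    }
    v <- unname(vectorize_lower(m))
    v2 <- numeric(length(v))
    t <- 1
    for (a in 2:n) {
      for (b in 1:(a - 1)) {
        v2[t] <- v[pos(perm[a], perm[b])]
        t <- t + 1
      }
    }
    expect_equal(v1, v2)
  }
})

test_that("a response identical to its predictor is fitted perfectly", {
  set.seed(11)
  X <- random_dist_matrix(8)
  fit <- mrm_fit(X, list(x = X))
  expect_equal(unname(fit$coefficients), 1, tolerance = 1e-10)
  expect_equal(fit$sse, 0, tolerance = 1e-8)
  expect_equal(fit$percent_variance, 100, tolerance = 1e-8)
})

test_that("coefficients and sequential SS match the normal-equations oracle", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    Y <- random_dist_matrix(n)
    Xs <- list(a = random_dist_matrix(n), b = random_dist_matrix(n), c = random_dist_matrix(n))
    fit <- mrm_fit(Y, Xs)
    o <- oracle_seq_ols(
      unname(vectorize_lower(Y)),
      lapply(Xs, function(x) unname(vectorize_lower(x)))
    )
    expect_equal(unname(fit$coefficients), unname(o$coef), tolerance = 1e-8)
    expect_equal(fit$intercept, o$intercept, tolerance = 1e-8)
    expect_equal(unname(fit$seq_ss), o$seq_ss, tolerance = 1e-6)
    expect_equal(fit$sse, o$sse, tolerance = 1e-6)
    expect_equal(fit$sst, o$sst, tolerance = 1e-8)
    # additivity: SST = sum(seq SS) + SSE
    expect_equal(fit$sst, sum(fit$seq_ss) + fit$sse, tolerance = 1e-8 * fit$sst)
  }
})

test_that("an independent predictor at n = 50 explains almost nothing", {
  set.seed(17)
  Y <- random_dist_matrix(50)
  X <- random_dist_matrix(50)
  fit <- mrm_fit(Y, list(x = X))
  expect_lt(fit$percent_variance, 2)
  expect_lt(abs(unname(fit$coefficients)), 0.1)
})

test_that("betas are positive when larger response co-occurs with predictor one", {
  n <- 10
  labels <- paste0("t", 1:n)
  grp <- rep(c("u", "v"), each = n / 2)
  X <- 1 * outer(grp, grp, `!=`)
  dimnames(X) <- list(labels, labels)
  set.seed(19)
  Y <- X * 4 + random_dist_matrix(n) * 0.2
  Y <- (Y + t(Y)) / 2
  diag(Y) <- 0
  fit <- mrm_fit(Y, list(grp = X))
  expect_gt(unname(fit$coefficients), 0)
  expect_gt(unname(fit$partial_corr), 0)
})

test_that("degenerate designs and responses raise informative errors", {
  set.seed(23)
  Y <- random_dist_matrix(6)
  zero <- matrix(0, 6, 6, dimnames = dimnames(Y))
  expect_error(mrm_fit(Y, list(flat = zero)), "flat")
  X <- random_dist_matrix(6)
  expect_error(mrm_fit(Y, list(a = X, twice_a = 2 * X)), "twice_a")
  expect_error(mrm_fit(zero, list(x = X)), "zero variance")
  Xbad <- random_dist_matrix(6, labels = paste0("s", 1:6))
  expect_error(mrm_fit(Y, list(x = Xbad)), "mismatched")
})

test_that("permutation p-values respect the add-one bounds and the perfect-fit case", {
  set.seed(29)
  # strictly increasing distance structure: only the identity reproduces it
  n <- 6
  X <- matrix(0, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
  X[lower.tri(X)] <- seq_len(n * (n - 1) / 2)
  X <- X + t(X)
  fit <- mrm(X, list(x = X), permutations = 119, seed = 7)
  expect_equal(unname(fit$p_beta), 1 / 120)
  expect_gte(min(fit$p_beta, fit$p_ss), 1 / (fit$permutations + 1))
  expect_lte(max(fit$p_beta, fit$p_ss), 1)
})

test_that("exhaustive enumeration matches an independent brute-force oracle", {
  set.seed(31)
  for (n in c(4, 5)) {
    Y <- random_dist_matrix(n)
    Xs <- list(a = random_dist_matrix(n), b = random_dist_matrix(n))
    fit <- mrm(Y, Xs, permutations = "exhaustive")
    expect_equal(fit$permutations, factorial(n))

    xs_vec <- lapply(Xs, function(x) unname(vectorize_lower(x)))
    obs <- oracle_seq_ols(unname(vectorize_lower(Y)), xs_vec)
    perms <- phylomrm:::all_permutations(n)
    cb <- matrix(0, nrow(perms), 2)
    cs <- matrix(0, nrow(perms), 2)
    for (r in seq_len(nrow(perms))) {
      yp <- unname(vectorize_lower(permute_matrix(Y, perms[r, ])))
      op <- oracle_seq_ols(yp, xs_vec)
      cb[r, ] <- abs(op$coef)
      cs[r, ] <- op$seq_ss
    }
    p_beta_oracle <- colMeans(cb >= rep(abs(obs$coef) - 1e-12, each = nrow(perms)))
    p_ss_oracle <- colMeans(cs >= rep(obs$seq_ss - 1e-9, each = nrow(perms)))
    expect_equal(unname(fit$p_beta), p_beta_oracle)
    expect_equal(unname(fit$p_ss), p_ss_oracle)
  }
})

test_that("statistics are invariant under consistent relabeling of all matrices", {
  set.seed(37)
  sim <- simulate_mrm_dataset(n = 10, seed = 41)
  perm <- sample(10)
  Y2 <- sim$Y[perm, perm]
  X2 <- lapply(sim$X, function(x) x[perm, perm])
  f1 <- mrm_fit(sim$Y, sim$X)
  f2 <- mrm_fit(Y2, X2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$seq_ss, f2$seq_ss, tolerance = 1e-8)
  expect_equal(f1$sse, f2$sse, tolerance = 1e-8)
})

test_that("the predictor-permutation sensitivity variant runs and is calibrated similarly", {
  sim <- simulate_mrm_dataset(n = 12, noise_sd = 0.5, seed = 43)
  f <- mrm(sim$Y, sim$X, permutations = 99, seed = 3, permute = "predictors")
  expect_equal(f$permute, "predictors")
  expect_lte(f$p_beta[["taxonomy"]], 0.05) # planted effect is found either way
})

test_that("variance decomposition identities hold and reproduce known footers", {
  # identities on a fitted model
  sim <- simulate_mrm_dataset(n = 12, seed = 47)
  fit <- mrm_fit(sim$Y, sim$X)
  vd <- variance_decomposition(fit$sst, fit$seq_ss)
  expect_equal(vd$sse, fit$sse, tolerance = 1e-8)
  expect_equal(vd$percent_variance, fit$percent_variance, tolerance = 1e-10)

  # an sst/seq-SS table published to 4 decimals decomposes consistently
  vd2 <- variance_decomposition(52643.5469, c(9495.1016, 1160.2305, 1.0859))
  expect_equal(vd2$sse, 41987.1289)
  expect_equal(round(vd2$percent_variance, 2), 20.24)
})

test_that("tidy and glance expose the full result as tibbles", {
  sim <- simulate_mrm_dataset(n = 10, seed = 53)
  fit <- mrm(sim$Y, sim$X, permutations = 49, seed = 9)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "partial_corr", "seq_ss", "p_beta", "p_ss"))
  expect_equal(td$term, names(sim$X))
  gl <- glance(fit)
  expect_equal(gl$sst, sum(td$seq_ss) + gl$sse, tolerance = 1e-8)
  expect_equal(gl$permutations, 49)
  expect_output(print(fit), "Error sum of squares")
})
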