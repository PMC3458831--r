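# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately avoid the code paths they verify:
# graph algorithms go through igraph on the explicit edge list, regression
# through normal equations solved step by step.

# Tip-tip path lengths in edges via shortest paths on the explicit tree
# graph; node distance is edges minus one.
oracle_node_dist <- function(tree) {
  n <- length(tree$tip.label)
  g <- igraph::make_graph(edges = as.vector(t(tree$edge)), directed = FALSE)
  d <- igraph::distances(g)[seq_len(n), seq_len(n)] - 1
  diag(d) <- 0
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# Every bipartition of the leaves induced by deleting one edge, as the set
# of tip labels on the child side.
oracle_splits <- function(tree) {
  n <- length(tree$tip.label)
  el <- tree$edge
  g <- igraph::make_graph(edges = as.vector(t(el)), directed = FALSE)
  lapply(seq_len(nrow(el)), function(r) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, el[r, ]))
    comp <- igraph::components(g2)$membership
    side <- which(comp == comp[el[r, 2]])
    sort(tree$tip.label[side[side <= n]])
  })
}

# Monophyly by exhaustive edge enumeration: some edge must separate the
# leaves exactly into (group | rest). Pass precomputed `splits` when testing
# many groups against one tree.
oracle_monophyletic <- function(tree, group, splits = oracle_splits(tree)) {
  group <- sort(group)
  rest <- sort(setdiff(tree$tip.label, group))
  any(vapply(
    splits,
    function(s) identical(s, group) || identical(s, rest),
    logical(1)
  ))
}

# Sequential OLS by stepwise normal equations: SS_k is the increment in
# regression sum of squares when predictor k joins the model.
oracle_seq_ols <- function(y, xs) {
  ssr <- function(X) {
    b <- solve(crossprod(X), crossprod(X, y))
    fit <- X %*% b
    sum((fit - mean(y))^2)
  }
  X <- matrix(1, length(y), 1)
  ssr_prev <- 0
  seq_ss <- numeric(length(xs))
  for (k in seq_along(xs)) {
    X <- cbind(X, xs[[k]])
    ssr_k <- ssr(X)
    seq_ss[k] <- ssr_k - ssr_prev
    ssr_prev <- ssr_k
  }
  coefs <- drop(solve(crossprod(X), crossprod(X, y)))
  sst <- sum((y - mean(y))^2)
  list(
    coef = coefs[-1],
    intercept = coefs[1],
    seq_ss = seq_ss,
    sse = sst - ssr_prev,
    sst = sst
  )
}

# A small labeled random symmetric distance-like matrix.
random_dist_matrix <- function(n, labels = paste0("t", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- runif(n * (n - 1) / 2, 1, 10)
  m + t(m)
}

# Apply a taxon permutation simultaneously to rows and columns, keeping the
# original labels in place (the relabelled matrix the permutation test fits).
permute_matrix <- function(m, perm) {
  out <- m[perm, perm]
  dimnames(out) <- dimnames(m)
  out
}
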