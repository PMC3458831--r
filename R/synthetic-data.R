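# Seeded simulators: every pipeline stage is testable without external data.

#' Simulate a pure-birth (Yule) tree
#'
#' Grows a topology by iterative random attachment: starting from a cherry,
#' each new leaf is grafted onto an edge chosen uniformly at random, then
#' every edge receives an independent exponential branch length. The result
#' is deterministic under a fixed seed.
#'
#' @param n Number of leaves (>= 2).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param rate Rate of the exponential branch-length distribution.
#' @param labels Optional character vector of n leaf labels (default
#'   `t1..tn`).
#' @return A rooted `ape::phylo` tree with branch lengths.
#' @export
simulate_yule_tree <- function(n, seed = NULL, rate = 1, labels = NULL) {
  if (!is.numeric(n) || n < 2) stop("`n` must be at least 2", call. = FALSE)
  n <- as.integer(n)
  labels <- labels %||% paste0("t", seq_len(n))
  stopifnot(length(labels) == n, !anyDuplicated(labels))
  with_seed(seed, {
    # Edge list over arbitrary ids: tips 1..n, internals n+1, n+2, ...
    next_id <- n + 2L
    edges <- matrix(c(n + 1L, 1L, n + 1L, 2L), ncol = 2, byrow = TRUE)
    for (tip in seq_len(n)[-(1:2)]) {
      j <- sample.int(nrow(edges), 1L)
      u <- edges[j, 1]
      v <- edges[j, 2]
      w <- next_id
      next_id <- next_id + 1L
      edges[j, ] <- c(u, w)
      edges <- rbind(edges, c(w, v), c(w, tip))
    }
    # Renumber internals to ape convention (root = n+1, preorder).
    internal <- unique(edges[, 1])
    root <- setdiff(internal, edges[, 2])
    ord <- integer(0)
    stack <- root
    children <- split(edges[, 2], edges[, 1])
    while (length(stack) > 0L) {
      node <- stack[1]
      stack <- stack[-1]
      ord <- c(ord, node)
      kids <- children[[as.character(node)]]
      stack <- c(kids[kids > n], stack)
    }
    map <- integer(max(edges))
    map[seq_len(n)] <- seq_len(n)
    map[ord] <- n + seq_along(ord)
    tr <- list(
      edge = cbind(map[edges[, 1]], map[edges[, 2]]),
      tip.label = labels,
      Nnode = length(internal),
      edge.length = rexp(nrow(edges), rate = rate)
    )
    class(tr) <- "phylo"
    tr <- ape::reorder.phylo(tr, "cladewise")
    tr
  })
}

#' Simulate a posterior-like tree set with a planted clade frequency
#'
#' Builds a pool of trees in which a focal clade occurs at a controlled
#' frequency — the stand-in for a post-burn-in posterior sample. Consistent
#' trees are built by joining an independently simulated subtree on the
#' clade's taxa with one on the remaining taxa (so the clade's bipartition
#' always exists); inconsistent trees additionally swap one taxon across
#' that split and are verified to break the clade.
#'
#' @param base A `phylo` tree supplying the taxon set.
#' @param clade Character vector of leaf labels (the planted clade),
#'   a proper subset of the base tree's leaves with >= 2 members.
#' @param f Target clade frequency in `[0, 1]`.
#' @param total Number of trees in the set.
#' @param mode `"deterministic"` — exactly `f * total` trees (which must be
#'   integral) contain the clade, at shuffled positions; `"bernoulli"` —
#'   each tree contains it independently with probability `f`.
#' @param seed Integer seed, or `NULL`.
#' @return A [tree_set()] of `total` trees.
#' @export
simulate_tree_set <- function(base, clade, f, total,
                              mode = c("deterministic", "bernoulli"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(base, "phylo"), total >= 1, f >= 0, f <= 1)
  labs <- base$tip.label
  clade <- as.character(clade)
  if (!all(clade %in% labs) || length(clade) >= length(labs) || length(clade) < 2L) {
    stop("`clade` must be a proper subset (>= 2 members) of the base tree's leaves",
      call. = FALSE
    )
  }
  rest <- setdiff(labs, clade)
  with_seed(seed, {
    if (mode == "deterministic") {
      k <- f * total
      if (abs(k - round(k)) > 1e-9) {
        stop("f * total = ", k, " is not an integer; use mode = \"bernoulli\"",
          call. = FALSE
        )
      }
      has_clade <- sample(rep(c(TRUE, FALSE), c(round(k), total - round(k))))
    } else {
      has_clade <- runif(total) < f
    }
    trees <- lapply(has_clade, function(ok) plant_tree(clade, rest, ok))
    tree_set(trees, run = "sim", generation = seq_len(total))
  })
}

# One tree on clade + rest taxa that does (ok) or does not contain the clade.
plant_tree <- function(clade, rest, ok) {
  join <- function(side_a, side_b) {
    sub_a <- subtree_on(side_a)
    sub_b <- subtree_on(side_b)
    ape::read.tree(text = paste0("(", sub_a, ",", sub_b, ");"))
  }
  if (ok) return(join(clade, rest))
  repeat {
    a <- clade
    b <- rest
    i <- sample.int(length(a), 1L)
    j <- sample.int(length(b), 1L)
    tmp <- a[i]
    a[i] <- b[j]
    b[j] <- tmp
    tr <- join(a, b)
    if (!has_split(tree_splits(tr), clade)) return(tr)
  }
}

# Newick (no trailing ';') of a random binary subtree on the given labels.
subtree_on <- function(labels) {
  if (length(labels) == 1L) return(labels)
  tr <- simulate_yule_tree(length(labels), labels = sample(labels))
  sub(";$", "", ape::write.tree(tr))
}

#' Simulate a taxon metadata table with known structure
#'
#' Assigns subgenus labels, habitat sets and coordinates to the leaves of a
#' tree. In `"clustered"` mode subgenera are actual clades of the tree
#' (found by repeatedly splitting the largest current group at its subtree
#' root), so taxonomy tracks phylogeny and a regression of node distance on
#' the taxonomy matrix has planted signal; in `"random"` mode labels are
#' shuffled and taxonomy is pure noise. Habitats are drawn per taxon from
#' `habitat_probs`, with probability `multi_habitat` of adding a second
#' distinct habitat. Coordinates are uniform in the bounding box.
#'
#' @param tree A `phylo` tree whose leaves become table rows.
#' @param subgenera Number of subgenus labels (2 <= subgenera <= n).
#' @param assignment `"clustered"` or `"random"`.
#' @param habitat_probs Named probabilities over [HABITAT_CODES] (summing
#'   to 1) for the primary habitat.
#' @param multi_habitat Probability that a taxon gets a second habitat.
#' @param bbox Bounding box `c(lat_min, lat_max, lon_min, lon_max)`; the
#'   default is a Southern-Appalachians-sized window.
#' @param seed Integer seed, or `NULL`.
#' @return A validated [taxon_table()] tibble.
#' @export
simulate_metadata <- function(tree, subgenera = 4, assignment = c("clustered", "random"),
                              habitat_probs = c(stream = 0.5, burrow = 0.3, cave = 0.2),
                              multi_habitat = 0.15,
                              bbox = c(33, 41, -90, -78), seed = NULL) {
  assignment <- match.arg(assignment)
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (subgenera > n) stop("more subgenera than taxa", call. = FALSE)
  if (subgenera < 1) stop("need at least one subgenus", call. = FALSE)
  stopifnot(setequal(names(habitat_probs), HABITAT_CODES) || all(names(habitat_probs) %in% HABITAT_CODES))
  with_seed(seed, {
    sg <- if (assignment == "clustered") {
      clade_partition(tree, subgenera)
    } else {
      g <- c(seq_len(subgenera), sample.int(subgenera, n - subgenera, replace = TRUE))
      sample(g)
    }
    codes <- names(habitat_probs)
    primary <- sample(codes, n, replace = TRUE, prob = habitat_probs)
    habitats <- vapply(primary, function(h) {
      if (runif(1) < multi_habitat) {
        extra <- sample(setdiff(HABITAT_CODES, h), 1L)
        paste(c(h, extra), collapse = "+")
      } else {
        h
      }
    }, character(1))
    taxon_table(tibble(
      taxon = tree$tip.label,
      subgenus = paste0("SG", sg),
      habitats = unname(habitats),
      lat = runif(n, bbox[1], bbox[2]),
      lon = runif(n, bbox[3], bbox[4])
    ))
  })
}

# Partition tips into k groups that are clades: start from the root set and
# repeatedly split the largest group at the root of its induced subtree.
clade_partition <- function(tree, k) {
  n <- length(tree$tip.label)
  desc <- descendant_sets(tree) # node -> tip indices
  children <- split(tree$edge[, 2], tree$edge[, 1])
  groups <- list(list(node = n + 1L, tips = seq_len(n)))
  while (length(groups) < k) {
    sizes <- vapply(groups, function(g) length(g$tips), integer(1))
    splittable <- which(sizes >= 2)
    if (length(splittable) == 0L) break
    gi <- splittable[which.max(sizes[splittable])]
    node <- groups[[gi]]$node
    kids <- children[[as.character(node)]]
    new_groups <- lapply(kids, function(ch) {
      tips <- if (ch <= n) ch else desc[[ch - n]]
      list(node = ch, tips = tips)
    })
    groups <- c(groups[-gi], new_groups)
    # splitting a multifurcation can overshoot k; accept the overshoot
  }
  out <- integer(n)
  for (g in seq_along(groups)) out[groups[[g]]$tips] <- g
  out
}

# Tip-index sets of every internal node, indexed node - n.
descendant_sets <- function(tree) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  sets <- vector("list", m)
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(edges))) {
    par <- edges[r, 1] - n
    ch <- edges[r, 2]
    sets[[par]] <- c(sets[[par]], if (ch <= n) ch else sets[[ch - n]])
  }
  sets
}

#' Simulate a distance-matrix regression dataset with known coefficients
#'
#' Generates the three predictor matrices from a random metadata table and
#' builds the response entrywise as
#' `intercept + sum(beta_k * X_k) + noise`, with i.i.d. Gaussian noise on
#' the pair scale, symmetrized, clipped at zero, zero diagonal. With
#' `noise_sd = 0` the planted coefficients are exactly identifiable.
#'
#' @param n Number of taxa (>= 4).
#' @param betas Named numeric vector of true coefficients for `taxonomy`,
#'   `geography` (per meter) and `habitat`.
#' @param noise_sd Standard deviation of the pair-level noise (>= 0).
#' @param intercept True intercept (keep it large enough that clipping at
#'   zero never binds if exact recovery is wanted).
#' @param subgenera Number of subgenus labels in the random metadata.
#' @param seed Integer seed, or `NULL`.
#' @return A list with `Y` (response matrix), `X` (named list of predictor
#'   matrices, in `betas` order), `meta` (the taxon table), `betas`,
#'   `intercept`, `noise_sd`.
#' @export
simulate_mrm_dataset <- function(n, betas = c(taxonomy = 3, geography = 2e-6, habitat = 1),
                                 noise_sd = 1, intercept = 10, subgenera = 4, seed = NULL) {
  stopifnot(n >= 4, noise_sd >= 0)
  stopifnot(all(names(betas) %in% c("taxonomy", "geography", "habitat")))
  with_seed(seed, {
    tr <- simulate_yule_tree(n)
    meta <- simulate_metadata(tr, subgenera = subgenera, assignment = "random")
    mats <- model_matrices(meta)[names(betas)]
    m <- n * (n - 1) / 2
    y <- rep(intercept, m)
    for (k in seq_along(betas)) {
      y <- y + betas[[k]] * vectorize_lower(mats[[k]])
    }
    y <- y + rnorm(m, sd = noise_sd)
    y <- pmax(y, 0)
    Y <- matrix(0, n, n, dimnames = list(meta$taxon, meta$taxon))
    Y[lower.tri(Y)] <- y[pair_index_matrix(n)[lower.tri(Y)]]
    Y <- Y + t(Y)
    list(
      Y = Y, X = mats, meta = meta,
      betas = betas, intercept = intercept, noise_sd = noise_sd
    )
  })
}
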