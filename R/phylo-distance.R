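#' Pairwise topological node distance between leaves
#'
#' Entry (i, j) is the number of internal nodes on the path between leaf i
#' and leaf j — equivalently the path length in edges minus one — so sister
#' taxa (a cherry) are at node distance 1. This is the response variable of
#' the distance-matrix regression.
#'
#' Rooting matters: the root is an internal node and sits on every path that
#' crosses it. The matrix is computed on the tree as rooted in the input;
#' `unroot = TRUE` collapses a bifurcating root first, which lowers by one
#' the distance of every pair whose path crosses the root.
#'
#' @param tree An `ape::phylo` tree with at least 2 leaves and unique labels.
#' @param taxa Optional character vector giving the canonical label order of
#'   the output (defaults to the tree's tip order). Must be a permutation of
#'   the leaf labels.
#' @param unroot Collapse a bifurcating root before computing distances.
#' @return A labeled symmetric numeric matrix with zero diagonal and
#'   attribute `units = "nodes"`.
#' @examples
#' tr <- ape::read.tree(text = "(((A,B),C),D);")
#' node_distance_matrix(tr)["A", "D"] # 3 when rooted
#' node_distance_matrix(tr, unroot = TRUE)["A", "D"] # 2
#' @export
node_distance_matrix <- function(tree, taxa = NULL, unroot = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop("tree has duplicated leaf labels", call. = FALSE)
  }
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 leaves", call. = FALSE)
  if (unroot) tree <- ape::unroot(tree)
  unit <- tree
  unit$edge.length <- rep(1, nrow(tree$edge))
  d <- stats::cophenetic(unit) - 1
  diag(d) <- 0
  d <- reorder_matrix(d, taxa %||% tree$tip.label)
  attr(d, "units") <- "nodes"
  d
}

#' Pairwise patristic distance between leaves
#'
#' Entry (i, j) is the sum of branch lengths on the path between leaves i
#' and j. Offered as an alternative response to node distance when branch
#' lengths are trusted.
#'
#' @inheritParams node_distance_matrix
#' @return A labeled symmetric numeric matrix, attribute `units =
#'   "branch-length"`.
#' @export
patristic_distance_matrix <- function(tree, taxa = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop("tree has duplicated leaf labels", call. = FALSE)
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("patristic distance needs a branch length on every edge", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) stop("negative branch length", call. = FALSE)
  d <- stats::cophenetic(tree)
  diag(d) <- 0
  d <- reorder_matrix(d, taxa %||% tree$tip.label)
  attr(d, "units") <- "branch-length"
  d
}

# Reorder a labeled square matrix to the canonical taxon order.
reorder_matrix <- function(m, taxa) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  if (!setequal(taxa, rownames(m)) || length(taxa) != nrow(m)) {
    stop(
      "`taxa` must be a permutation of the matrix labels; mismatched: ",
      paste(c(setdiff(taxa, rownames(m)), setdiff(rownames(m), taxa)), collapse = ", "),
      call. = FALSE
    )
  }
  m[taxa, taxa, drop = FALSE]
}

#' Distance matrix in long (pair per row) form
#'
#' @param m A labeled symmetric matrix.
#' @return A tibble with columns `taxon_i`, `taxon_j`, `value`, one row per
#'   unordered pair (i before j in the matrix's label order).
#' @export
dist_long <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  labs <- rownames(m)
  idx <- which(lower.tri(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tibble(
    taxon_i = labs[idx[, 2]],
    taxon_j = labs[idx[, 1]],
    value = m[idx[, c(1, 2), drop = FALSE]]
  )
}

#' Write / read the square tab-delimited matrix format
#'
#' A square matrix with a header row and first-column labels, the on-disk
#' interchange format used between pipeline stages.
#'
#' @param m A labeled square matrix.
#' @param path File path.
#' @return `read_matrix_tsv()` returns the labeled matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
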