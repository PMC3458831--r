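# Bayesian topological tests (Pp): count the posterior trees consistent with
# monophyly / backbone constraints.

# All nontrivial leaf-label sets induced by the tree's internal nodes,
# de-duplicated; bipartition existence is tested as "set or complement".
tree_splits <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sets <- lapply(pp, function(i) labs[i])
  list(sets = sets, labels = labs)
}

has_split <- function(splits, group) {
  group <- sort(unname(as.character(group)))
  all_labs <- splits$labels
  if (length(group) == length(all_labs)) return(TRUE) # trivial split
  comp <- sort(setdiff(all_labs, group))
  for (s in splits$sets) {
    if (length(s) == length(group) && identical(sort(s), group)) return(TRUE)
    if (length(s) == length(comp) && identical(sort(s), comp)) return(TRUE)
  }
  FALSE
}

#' Is a taxon group monophyletic in a tree?
#'
#' On an unrooted tree, monophyly of a group is bipartition existence: some
#' edge must split the leaves exactly into (group | everything else) — a
#' polytomy that covers the group's taxa plus others does not count. When an
#' outgroup is supplied the test is the rooted one: with the tree rooted on
#' the outgroup's attachment edge, some node's descendant set must equal the
#' group; because the outgroup is disjoint from the group, this coincides
#' with bipartition existence.
#'
#' @param tree An `ape::phylo` tree.
#' @param group Character vector of leaf labels, `1 < |group| < n`.
#' @param outgroup Optional character vector of outgroup leaf labels,
#'   disjoint from `group`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' is_monophyletic(tr, c("A", "B")) # TRUE
#' is_monophyletic(tr, c("A", "C")) # FALSE
#' @export
is_monophyletic <- function(tree, group, outgroup = NULL) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  miss <- setdiff(group, labs)
  if (length(miss) > 0L) {
    stop("group taxa missing from tree: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (length(group) < 2L || length(group) >= length(labs)) {
    stop("group must hold at least 2 and fewer than all leaves", call. = FALSE)
  }
  if (!is.null(outgroup)) {
    if (length(intersect(outgroup, group)) > 0L) {
      stop("outgroup overlaps the tested group", call. = FALSE)
    }
  }
  has_split(tree_splits(tree), group)
}

#' Define a topological constraint
#'
#' A constraint names disjoint groups of taxa (each tested for monophyly)
#' and may add a backbone tree over the group names describing required
#' relationships among the groups, plus an optional outgroup used to root
#' the backbone statement. Taxa present in a tree but in no group are
#' ignored by restriction, so ungrouped outgroup taxa cannot break a
#' backbone hypothesis.
#'
#' @param groups Named list: group name -> nonempty character vector of taxon
#'   labels. Groups must be pairwise disjoint.
#' @param backbone Optional Newick string (or `phylo`) whose leaves are group
#'   names.
#' @param outgroup Optional character vector of taxon labels, disjoint from
#'   every group.
#' @param name Optional hypothesis name (used in result tables).
#' @return An object of class `clade_constraint`.
#' @export
constraint <- function(groups, backbone = NULL, outgroup = NULL, name = NULL) {
  stopifnot(is.list(groups), length(groups) >= 1L, !is.null(names(groups)))
  groups <- lapply(groups, as.character)
  if (any(lengths(groups) == 0L)) stop("empty constraint group", call. = FALSE)
  all_taxa <- unlist(groups)
  if (anyDuplicated(all_taxa)) {
    stop(
      "constraint groups are not disjoint: ",
      paste(unique(all_taxa[duplicated(all_taxa)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.null(backbone)) {
    if (is.character(backbone)) backbone <- ape::read.tree(text = backbone)
    stopifnot(inherits(backbone, "phylo"))
    extra <- setdiff(backbone$tip.label, names(groups))
    if (length(extra) > 0L) {
      stop(
        "backbone leaves are not group names: ", paste(extra, collapse = ", "),
        call. = FALSE
      )
    }
  }
  outgroup <- as.character(outgroup %||% character())
  if (length(intersect(outgroup, all_taxa)) > 0L) {
    stop("outgroup taxa overlap constraint groups", call. = FALSE)
  }
  structure(
    list(groups = groups, backbone = backbone, outgroup = outgroup, name = name),
    class = "clade_constraint"
  )
}

#' Read constraints from a YAML file
#'
#' Accepts either a single constraint (`groups:`, optional `backbone:`
#' Newick over group names, optional `outgroup:`) or a named map of several
#' such constraints.
#'
#' @param path YAML file path.
#' @return A named list of [constraint()] objects.
#' @export
read_constraints <- function(path) {
  stopifnot(file.exists(path))
  spec <- yaml::read_yaml(path)
  parse_one <- function(s, nm) {
    constraint(
      groups = s$groups,
      backbone = s$backbone,
      outgroup = s$outgroup,
      name = nm
    )
  }
  if ("groups" %in% names(spec)) {
    nm <- file_stem(path)
    return(setNames(list(parse_one(spec, nm)), nm))
  }
  out <- lapply(seq_along(spec), function(k) parse_one(spec[[k]], names(spec)[k]))
  setNames(out, names(spec))
}

#' Is a tree consistent with a constraint?
#'
#' A tree is consistent when (a) every constraint group with two or more
#' members is monophyletic in the tree restricted to the grouped taxa (plus
#' the outgroup, when one is given), and (b) every internal bipartition of
#' the backbone, expanded to taxon sets by group membership, exists in the
#' tree restricted to the backbone groups' taxa. With an outgroup the
#' backbone is read as rooted and its clades are tested against the
#' outgroup; without one only its unrooted internal splits are testable.
#'
#' @param tree An `ape::phylo` tree.
#' @param cons A [constraint()].
#' @return `TRUE` or `FALSE`.
#' @export
constraint_consistent <- function(tree, cons) {
  stopifnot(inherits(tree, "phylo"), inherits(cons, "clade_constraint"))
  labs <- tree$tip.label
  grouped <- unlist(cons$groups)
  miss <- setdiff(grouped, labs)
  if (length(miss) > 0L) {
    stop("constraint taxa missing from tree: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  og <- intersect(cons$outgroup, labs)
  keep <- c(grouped, og)

  # With a single group and no outgroup there is nothing to restrict
  # against: the test is plain monophyly on the full tree.
  restricted <- if (length(keep) < length(labs) &&
    !(length(cons$groups) == 1L && length(og) == 0L)) {
    ape::keep.tip(tree, keep)
  } else {
    tree
  }
  splits <- tree_splits(restricted)

  for (g in cons$groups) {
    if (length(g) >= 2L && !has_split(splits, g)) return(FALSE)
  }

  bb <- cons$backbone
  if (!is.null(bb) && length(bb$tip.label) >= 2L) {
    bb_groups <- cons$groups[bb$tip.label]
    bb_taxa <- unlist(bb_groups)
    sub <- if (length(c(bb_taxa, og)) < length(splits$labels)) {
      ape::keep.tip(restricted, c(bb_taxa, og))
    } else {
      restricted
    }
    sub_splits <- tree_splits(sub)
    bsp <- tree_splits(bb)
    for (s in bsp$sets) {
      if (length(s) == length(bb$tip.label)) next # root: all groups
      # triviality is judged on the expanded taxon sets: a singleton-group
      # side can still expand to a nontrivial split of the restricted tree
      taxa <- unlist(cons$groups[s])
      if (length(taxa) < 2L || length(taxa) >= length(sub_splits$labels)) next
      if (!has_split(sub_splits, taxa)) return(FALSE)
    }
  }
  TRUE
}

#' Posterior frequency of topological hypotheses (the Pp test)
#'
#' Counts, for each constraint, the trees of a posterior set that are
#' consistent with it, and reports the posterior frequency as a percentage.
#' `pp` is the exact value `100 * N / total`; `pp_display` applies half-up
#' rounding at two decimals on the exact rational (so 33 of 12,000 prints
#' 0.28, never 0.27).
#'
#' @param trees A [tree_set()], `multiPhylo`, or list of `phylo` trees.
#' @param constraints A single [constraint()] or (named) list of them.
#' @return A tibble of class `pp_result` with columns `hypothesis`,
#'   `n_consistent`, `n_total`, `pp`, `pp_display`.
#' @export
posterior_frequency <- function(trees, constraints) {
  tl <- if (inherits(trees, "tree_set")) unclass(trees$trees) else unclass(trees)
  if (inherits(tl, "phylo")) tl <- list(tl)
  stopifnot(length(tl) >= 1L)
  if (inherits(constraints, "clade_constraint")) constraints <- list(constraints)
  nms <- names(constraints) %||% rep(NA_character_, length(constraints))
  total <- length(tl)
  rows <- purrr::map2(constraints, seq_along(constraints), function(cons, k) {
    n_ok <- sum(vapply(tl, constraint_consistent, logical(1), cons = cons))
    tibble(
      hypothesis = cons$name %||% (if (!is.na(nms[k])) nms[k] else paste0("H", k)),
      n_consistent = n_ok,
      n_total = total,
      pp = 100 * n_ok / total,
      pp_display = percent_half_up(n_ok, total, digits = 2L)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pp_result", class(out))
  out
}
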