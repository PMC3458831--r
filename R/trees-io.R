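#' Construct a tree set
#'
#' A `tree_set` is an ordered pool of trees on a single taxon set with
#' per-tree provenance (run identifier and MCMC generation index). It is the
#' package's stand-in for a post-burn-in posterior sample.
#'
#' @param trees A list of `ape::phylo` trees (or a `multiPhylo`). All trees
#'   must share one leaf-label set.
#' @param run Character vector of run identifiers, length 1 or one per tree.
#' @param generation Numeric vector of MCMC generation indices (one per tree,
#'   or `NA` when unknown). Within a run, non-missing generation indices must
#'   be strictly increasing.
#' @return An object of class `tree_set`: a list with elements `trees`
#'   (a `multiPhylo`) and `provenance` (a tibble with columns `run`,
#'   `generation`).
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' ts <- tree_set(list(tr, tr), run = "run1", generation = c(1000, 2000))
#' n_trees(ts)
#' @export
tree_set <- function(trees, run = "run1", generation = NA_real_) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  stopifnot(length(trees) >= 1L)
  if (!all(vapply(trees, inherits, logical(1), "phylo"))) {
    stop("`trees` must be a list of phylo objects", call. = FALSE)
  }
  ref <- sort(trees[[1L]]$tip.label)
  for (k in seq_along(trees)) {
    labs <- trees[[k]]$tip.label
    if (anyDuplicated(labs)) {
      stop("tree ", k, " has duplicated leaf labels", call. = FALSE)
    }
    if (!identical(sort(labs), ref)) {
      diff <- c(setdiff(labs, ref), setdiff(ref, labs))
      stop(
        "trees do not share one taxon set; symmetric difference at tree ", k,
        ": ", paste(diff, collapse = ", "),
        call. = FALSE
      )
    }
  }
  n <- length(trees)
  run <- rep_len(as.character(run), n)
  generation <- rep_len(as.numeric(generation), n)
  for (r in unique(run)) {
    g <- generation[run == r]
    g <- g[!is.na(g)]
    if (length(g) > 1L && any(diff(g) <= 0)) {
      stop("generation indices must be strictly increasing within run ", r,
        call. = FALSE
      )
    }
  }
  class(trees) <- "multiPhylo"
  structure(
    list(trees = trees, provenance = tibble(run = run, generation = generation)),
    class = "tree_set"
  )
}

#' @rdname tree_set
#' @param x A `tree_set`.
#' @export
n_trees <- function(x) {
  stopifnot(inherits(x, "tree_set"))
  length(x$trees)
}

#' @export
print.tree_set <- function(x, ...) {
  n <- n_trees(x)
  cat(
    "<tree_set> ", n, " trees on ", length(x$trees[[1]]$tip.label),
    " taxa; runs: ",
    paste(unique(x$provenance$run), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Read a file of Newick trees (one per line)
#'
#' Each nonempty line must be a single `;`-terminated Newick string. Branch
#' lengths are retained when present; underscores inside labels are kept
#' verbatim (never converted to spaces), so labels match the metadata table
#' bit-for-bit.
#'
#' @param path Path to a text file of Newick strings.
#' @param run Run identifier recorded in the provenance (defaults to the file
#'   stem).
#' @return A [tree_set()]. Generation indices are `NA` (a plain Newick file
#'   carries none); [pool_posterior()] fills them from the sampling spec.
#' @export
read_newick_trees <- function(path, run = file_stem(path)) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("no trees in ", path, call. = FALSE)
  trees <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    tr <- tryCatch(
      ape::read.tree(text = lines[ln]),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(tr) || !inherits(tr, "phylo")) {
      stop("malformed Newick at line ", ln, " of ", path, call. = FALSE)
    }
    trees[[k]] <- tr
  }
  tree_set(trees, run = run)
}

#' Write a tree set (or trees) as one Newick string per line
#'
#' @param x A [tree_set()], `multiPhylo`, list of trees, or single `phylo`.
#' @param path Output file path.
#' @export
write_newick_trees <- function(x, path) {
  trees <- if (inherits(x, "tree_set")) x$trees else x
  ape::write.tree(trees, file = path)
  invisible(path)
}

#' Read a Nexus TREES block, honouring the translate table
#'
#' Reads the tree-sample format written by Bayesian MCMC software: a TREES
#' block whose statements may reference taxa through an integer `translate`
#' table. Leaf labels in the result are the translated names. Generation
#' indices are parsed from tree names of the form `STATE_N`, `gen.N`,
#' `gen=N` or `rep.N`; when none matches, indices are left `NA` for
#' [pool_posterior()] to assign.
#'
#' @inheritParams read_newick_trees
#' @return A [tree_set()].
#' @export
read_nexus_trees <- function(path, run = file_stem(path)) {
  stopifnot(file.exists(path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("begin\\s+trees", txt, ignore.case = TRUE)) {
    stop("no TREES block found in ", path, call. = FALSE)
  }
  block <- sub("(?s).*?begin\\s+trees\\s*;", "", txt, ignore.case = TRUE, perl = TRUE)
  block <- sub("(?s)\\bend\\s*;.*", "", block, ignore.case = TRUE, perl = TRUE)

  translate <- NULL
  tr_match <- regmatches(
    block,
    regexpr("(?s)translate\\b.*?;", block, ignore.case = TRUE, perl = TRUE)
  )
  if (length(tr_match) == 1L) {
    body <- sub("(?i)^translate\\b", "", tr_match, perl = TRUE)
    body <- sub(";$", "", body)
    body <- gsub("\n", " ", body, fixed = TRUE)
    entries <- strsplit(body, ",")[[1]]
    entries <- trimws(entries)
    entries <- entries[nzchar(entries)]
    toks <- strsplit(entries, "\\s+")
    keys <- vapply(toks, `[[`, character(1), 1L)
    vals <- vapply(toks, function(t) gsub("^'|'$", "", paste(t[-1], collapse = "_")), character(1))
    translate <- setNames(vals, keys)
  }

  stmts <- regmatches(
    block,
    gregexpr("\\btree\\s+\\S+\\s*=[^;]*;", block, ignore.case = TRUE, perl = TRUE)
  )[[1]]
  if (length(stmts) == 0L) stop("TREES block of ", path, " holds no tree statements", call. = FALSE)

  trees <- vector("list", length(stmts))
  gens <- rep(NA_real_, length(stmts))
  for (k in seq_along(stmts)) {
    name <- sub("^\\s*tree\\s+(\\S+)\\s*=.*", "\\1", stmts[k], ignore.case = TRUE)
    nwk <- sub("^\\s*tree\\s+\\S+\\s*=\\s*", "", stmts[k], ignore.case = TRUE)
    nwk <- gsub("\\[[^]]*\\]", "", nwk) # strip comments such as [&U]
    tr <- tryCatch(ape::read.tree(text = nwk), error = function(e) NULL)
    if (is.null(tr)) stop("malformed tree statement '", name, "' in ", path, call. = FALSE)
    if (!is.null(translate)) {
      miss <- setdiff(tr$tip.label, names(translate))
      if (length(miss) > 0L) {
        stop(
          "translate table of ", path, " has no entry for token(s): ",
          paste(miss, collapse = ", "),
          call. = FALSE
        )
      }
      tr$tip.label <- unname(translate[tr$tip.label])
    }
    m <- regmatches(name, regexec("(?:STATE|gen|rep)[._= ]?([0-9]+)", name, ignore.case = TRUE))[[1]]
    if (length(m) == 2L) gens[k] <- as.numeric(m[2])
    trees[[k]] <- tr
  }
  tree_set(trees, run = run, generation = gens)
}

#' MCMC sampling specification
#'
#' Describes how each run was sampled, so burn-in pooling can reason about
#' generation indices: total generations per run, the thinning interval, and
#' the burn-in cutoff. The sample at exactly the cutoff generation is
#' discarded (the cutoff is inclusive on the discard side): with two runs of
#' 1e7 generations sampled every 1000 and a cutoff of 4e6, each run retains
#' 6,000 samples and the pool holds 12,000.
#'
#' @param generations Generations per run (positive).
#' @param interval Sampling (thinning) interval; must divide `generations`.
#' @param burnin Burn-in generation cutoff (non-negative, at most
#'   `generations`).
#' @return A list of class `mcmc_spec`.
#' @export
mcmc_spec <- function(generations, interval, burnin) {
  stopifnot(
    length(generations) == 1L, generations > 0,
    length(interval) == 1L, interval > 0,
    length(burnin) == 1L, burnin >= 0
  )
  if (burnin > generations) stop("`burnin` exceeds `generations`", call. = FALSE)
  if (generations %% interval != 0) {
    stop("`interval` must divide `generations` evenly", call. = FALSE)
  }
  structure(
    list(
      generations = as.numeric(generations),
      interval = as.numeric(interval),
      burnin = as.numeric(burnin)
    ),
    class = "mcmc_spec"
  )
}

#' Pool post-burn-in posterior samples across runs
#'
#' Discards every sample whose generation index is less than or equal to the
#' burn-in cutoff and concatenates the retained samples across runs,
#' preserving run order. Runs whose trees carry no generation indices are
#' assigned `i * interval` for the i-th sample (the common layout of thinned
#' tree files that omit generation zero).
#'
#' @param runs A list of [tree_set()] objects, one per independent run.
#' @param spec An [mcmc_spec()].
#' @return A pooled [tree_set()] whose provenance records the source run and
#'   generation of every retained tree.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' run <- tree_set(rep(list(tr), 10), generation = seq(1000, 10000, by = 1000))
#' pooled <- pool_posterior(list(run), mcmc_spec(10000, 1000, 4000))
#' n_trees(pooled) # 6
#' @export
pool_posterior <- function(runs, spec) {
  stopifnot(inherits(spec, "mcmc_spec"))
  if (inherits(runs, "tree_set")) runs <- list(runs)
  stopifnot(length(runs) >= 1L, all(vapply(runs, inherits, logical(1), "tree_set")))

  ref <- sort(runs[[1]]$trees[[1]]$tip.label)
  out_trees <- list()
  out_run <- character()
  out_gen <- numeric()
  for (k in seq_along(runs)) {
    rs <- runs[[k]]
    labs <- sort(rs$trees[[1]]$tip.label)
    if (!identical(labs, ref)) {
      stop(
        "taxon sets differ between runs 1 and ", k, ": ",
        paste(c(setdiff(labs, ref), setdiff(ref, labs)), collapse = ", "),
        call. = FALSE
      )
    }
    gens <- rs$provenance$generation
    if (all(is.na(gens))) {
      gens <- seq_along(rs$trees) * spec$interval
    } else if (anyNA(gens)) {
      stop("run ", k, " mixes known and unknown generation indices", call. = FALSE)
    }
    bad <- gens[gens %% spec$interval != 0 | gens > spec$generations | gens < 0]
    if (length(bad) > 0L) {
      stop(
        "run ", k, " has generation indices inconsistent with the sampling ",
        "spec (interval ", spec$interval, ", generations ", spec$generations,
        "): ", paste(head(bad, 5), collapse = ", "),
        call. = FALSE
      )
    }
    keep <- which(gens > spec$burnin)
    if (length(keep) == 0L) {
      stop("run ", k, " retains no trees after burn-in; lower the cutoff", call. = FALSE)
    }
    out_trees <- c(out_trees, unclass(rs$trees)[keep])
    out_run <- c(out_run, rs$provenance$run[keep])
    out_gen <- c(out_gen, gens[keep])
  }
  tree_set(out_trees, run = out_run, generation = out_gen)
}
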