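#' Run the full hypothesis-testing pipeline
#'
#' Ties the stages together: pool post-burn-in tree samples across runs,
#' compute the node-distance response from a summary tree, build the
#' taxonomy / geography / habitat model matrices from the metadata table,
#' fit the distance-matrix regression with permutation tests, and count the
#' posterior frequency of each topological constraint. Writes every
#' intermediate artifact plus a JSON report holding artifact checksums, the
#' regression result, the topology-test rows, the seed and the package
#' version; rerunning the same configuration byte-reproduces the report.
#'
#' @param config A named list or the path to a YAML file with fields:
#'   \describe{
#'     \item{trees}{character vector of posterior tree files (Newick or
#'       Nexus; format sniffed from content), one per run}
#'     \item{summary_tree}{path to the single summary topology used for the
#'       node-distance response}
#'     \item{metadata}{path to the taxon CSV}
#'     \item{constraints}{path to the constraints YAML (optional)}
#'     \item{mcmc}{list with `generations`, `interval`, `burnin`}
#'     \item{unroot}{collapse a bifurcating root before node distances
#'       (default `FALSE`)}
#'     \item{predictors}{predictor order (default taxonomy, geography,
#'       habitat)}
#'     \item{permutations}{permutation count (default 9999)}
#'     \item{seed}{integer seed}
#'     \item{out_dir}{output directory}
#'   }
#' @param overrides Named list of config keys to override (takes precedence).
#' @return Invisibly, the report as a list (also written to
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(config, overrides = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config[names(overrides)] <- overrides
  defaults <- list(
    predictors = c("taxonomy", "geography", "habitat"),
    permutations = 9999,
    unroot = FALSE,
    constraints = NULL,
    seed = 1L
  )
  for (k in names(defaults)) config[[k]] <- config[[k]] %||% defaults[[k]]
  for (k in c("trees", "summary_tree", "metadata", "mcmc", "out_dir")) {
    if (is.null(config[[k]])) stop("pipeline config lacks `", k, "`", call. = FALSE)
  }
  paths <- c(config$trees, config$summary_tree, config$metadata, config$constraints)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("config references missing file(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!setequal(config$predictors, c("taxonomy", "geography", "habitat"))) {
    stop("`predictors` must be a permutation of taxonomy, geography, habitat", call. = FALSE)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # 1. pool posterior samples
  pooled <- stage("pool", {
    runs <- lapply(config$trees, read_trees_auto)
    spec <- mcmc_spec(
      config$mcmc$generations, config$mcmc$interval, config$mcmc$burnin
    )
    pool_posterior(runs, spec)
  })
  pooled_path <- file.path(out_dir, "pooled.nwk")
  write_newick_trees(pooled, pooled_path)

  # 2. response matrix from the summary tree
  meta <- stage("metadata", read_taxon_table(config$metadata))
  nodedist <- stage("node-distance", {
    tr <- ape::read.tree(config$summary_tree)
    node_distance_matrix(tr, taxa = meta$taxon, unroot = isTRUE(config$unroot))
  })
  nd_path <- file.path(out_dir, "nodedist.tsv")
  write_matrix_tsv(nodedist, nd_path)

  # 3. model matrices
  mats <- stage("model-matrices", model_matrices(meta)[config$predictors])
  mat_paths <- vapply(names(mats), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_matrix_tsv(mats[[nm]], p)
    p
  }, character(1))

  # 4. regression with permutation tests
  fit <- stage("mrm", {
    mrm(nodedist, mats, permutations = config$permutations, seed = config$seed)
  })
  mrm_out <- c(
    as.list(glance(fit)),
    list(terms = as.list(tibble_to_rows(tidy(fit))))
  )
  jsonlite::write_json(
    mrm_out, file.path(out_dir, "mrm.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  # 5. topology tests
  pp <- NULL
  if (!is.null(config$constraints)) {
    pp <- stage("topology-tests", {
      posterior_frequency(pooled, read_constraints(config$constraints))
    })
    jsonlite::write_json(
      tibble_to_rows(pp), file.path(out_dir, "ptest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }

  artifacts <- c(pooled_path, nd_path, mat_paths)
  report <- list(
    version = as.character(utils::packageVersion("phylomrm")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    checksums = as.list(setNames(
      unname(tools::md5sum(artifacts)), basename(artifacts)
    )),
    n_pooled_trees = n_trees(pooled),
    mrm = mrm_out,
    topology_tests = if (is.null(pp)) NULL else tibble_to_rows(pp)
  )
  jsonlite::write_json(
    report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(report)
}

# Sniff Newick vs Nexus from file content.
read_trees_auto <- function(path) {
  first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
  if (startsWith(first, "#NEXUS")) read_nexus_trees(path) else read_newick_trees(path)
}

tibble_to_rows <- function(df) {
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}
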