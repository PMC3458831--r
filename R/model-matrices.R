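#' Habitat vocabulary
#'
#' The closed set of habitat codes accepted in taxon tables. Crayfish in this
#' genus occupy three broad habitat classes; typos are rejected at load
#' rather than silently corrupting the habitat model matrix.
#' @export
HABITAT_CODES <- c("cave", "burrow", "stream")

#' Validate a taxon metadata table
#'
#' The taxon table drives all three predictor matrices. It must hold one row
#' per sample with columns `taxon` (unique label), `subgenus`, `habitats`
#' (a `+`-separated nonempty subset of [HABITAT_CODES], e.g. `"stream+cave"`),
#' `lat` (decimal degrees, -90..90) and `lon` (decimal degrees, -180..180).
#'
#' @param df A data frame.
#' @return The validated table as a tibble (invisibly unchanged content).
#' @export
taxon_table <- function(df) {
  df <- as_tibble(df)
  need <- c("taxon", "subgenus", "habitats", "lat", "lon")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("taxon table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("taxon table is empty", call. = FALSE)
  if (anyDuplicated(df$taxon)) {
    stop(
      "duplicated taxon label(s): ",
      paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "),
      call. = FALSE
    )
  }
  hl <- habitat_sets(df$habitats)
  if (any(lengths(hl) == 0L)) {
    stop("empty habitat set for taxon ", df$taxon[which(lengths(hl) == 0L)[1]], call. = FALSE)
  }
  if (any(abs(df$lat) > 90) || anyNA(df$lat)) stop("latitude out of [-90, 90]", call. = FALSE)
  if (any(abs(df$lon) > 180) || anyNA(df$lon)) stop("longitude out of [-180, 180]", call. = FALSE)
  df
}

# Parse '+'-separated habitat strings into character sets, validating codes.
habitat_sets <- function(x) {
  sets <- strsplit(as.character(x), "+", fixed = TRUE)
  sets <- lapply(sets, function(s) trimws(s[nzchar(trimws(s))]))
  bad <- setdiff(unique(unlist(sets)), HABITAT_CODES)
  if (length(bad) > 0L) {
    stop(
      "unknown habitat code(s): ", paste(bad, collapse = ", "),
      " (allowed: ", paste(HABITAT_CODES, collapse = ", "), ")",
      call. = FALSE
    )
  }
  sets
}

#' Read a taxon metadata CSV
#'
#' Expects the header `taxon,subgenus,habitats,lat,lon`; see [taxon_table()]
#' for the column contracts.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_taxon_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  taxon_table(df)
}

#' Taxonomic model matrix
#'
#' Binary distance coding of current taxonomy: 0 for pairs of taxa within
#' the same subgenus, 1 for pairs from different subgenera.
#'
#' @param table A [taxon_table()].
#' @return Labeled symmetric 0/1 matrix (zero diagonal), in the table's row
#'   order, attribute `units = "model"`.
#' @export
taxonomy_matrix <- function(table) {
  table <- taxon_table(table)
  m <- 1 * outer(table$subgenus, table$subgenus, `!=`)
  dimnames(m) <- list(table$taxon, table$taxon)
  attr(m, "units") <- "model"
  m
}

#' Habitat model matrix
#'
#' Binary habitat distance: 0 for pairs whose habitat sets intersect, 1 for
#' pairs that share no habitat. A taxon occupying several habitats (e.g.
#' `"stream+cave"`) is thereby equally close to stream and to cave taxa.
#'
#' @inheritParams taxonomy_matrix
#' @return Labeled symmetric 0/1 matrix, attribute `units = "model"`.
#' @export
habitat_matrix <- function(table) {
  table <- taxon_table(table)
  sets <- habitat_sets(table$habitats)
  n <- nrow(table)
  m <- matrix(0, n, n, dimnames = list(table$taxon, table$taxon))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && length(intersect(sets[[i]], sets[[j]])) == 0L) {
        m[i, j] <- m[j, i] <- 1
      }
    }
  }
  attr(m, "units") <- "model"
  m
}

#' Great-circle geographic distance matrix
#'
#' Haversine distance in meters between sample coordinates, on a sphere of
#' the IUGG mean radius by default. Distances are computed between samples
#' (table rows), so several samples of one species are allowed and each
#' contributes its own coordinates.
#'
#' @inheritParams taxonomy_matrix
#' @param radius Sphere radius in meters (default the IUGG mean radius,
#'   6,371,008.8 m).
#' @return Labeled symmetric matrix of meters, attribute `units = "meters"`.
#' @export
geographic_matrix <- function(table, radius = 6371008.8) {
  table <- taxon_table(table)
  pts <- cbind(table$lon, table$lat)
  m <- geosphere::distm(pts, pts, fun = function(a, b) {
    geosphere::distHaversine(a, b, r = radius)
  })
  dimnames(m) <- list(table$taxon, table$taxon)
  diag(m) <- 0
  attr(m, "units") <- "meters"
  m
}

#' All three predictor matrices at once
#'
#' @inheritParams geographic_matrix
#' @return A named list `list(taxonomy=, geography=, habitat=)` of matrices
#'   sharing the table's taxon order — ready to hand to [mrm()].
#' @export
model_matrices <- function(table, radius = 6371008.8) {
  table <- taxon_table(table)
  list(
    taxonomy = taxonomy_matrix(table),
    geography = geographic_matrix(table, radius = radius),
    habitat = habitat_matrix(table)
  )
}
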