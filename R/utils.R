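# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Half-up rounding of the exact rational (100 * num / den) at `digits` decimal
# places, in integer arithmetic so decimal ties (e.g. 33/12000 -> 0.275%) are
# never mangled by binary floats.
percent_half_up <- function(num, den, digits = 2L) {
  stopifnot(num >= 0, den > 0, num <= den)
  scale <- 10^digits
  total <- num * 100 * scale
  q <- total %/% den
  r <- total %% den
  if (2 * r >= den) q <- q + 1
  q / scale
}

# Positions of the row-major lower triangle: pair (i, j), i > j, sits at
# (i-1)(i-2)/2 + j. Returns the n x n symmetric lookup matrix.
pair_index_matrix <- function(n) {
  m <- matrix(NA_integer_, n, n)
  for (i in 2:n) for (j in 1:(i - 1)) {
    m[i, j] <- m[j, i] <- as.integer((i - 1) * (i - 2) / 2 + j)
  }
  m
}

# All n! permutations of 1..n as an (n! x n) integer matrix.
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 8)
  res <- matrix(1L, 1L, 1L)
  if (n == 1L) return(res)
  for (m in 2:n) {
    k <- nrow(res)
    out <- matrix(0L, k * m, m)
    row <- 1L
    for (pos in 1:m) {
      block <- cbind(
        res[, seq_len(pos - 1L), drop = FALSE],
        m,
        res[, seq(pos, m - 1L)[seq_len(m - pos)], drop = FALSE]
      )
      out[row:(row + k - 1L), ] <- block
      row <- row + k
    }
    res <- out
  }
  res
}

file_stem <- function(path) tools::file_path_sans_ext(basename(path))
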