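#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif sd var
NULL

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
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

# Euclidean norm of a length-2/3 vector.
vnorm <- function(v) sqrt(sum(v^2))

# First index at which `cond` holds for m consecutive entries, NA if never.
# Returns a 1-based index into `cond`.
first_sustained <- function(cond, m) {
  cond[is.na(cond)] <- FALSE
  if (m <= 1) {
    idx <- which(cond)
    return(if (length(idx)) idx[1] else NA_integer_)
  }
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= m)
  if (length(hit)) starts[hit[1]] else NA_integer_
}

# Round-half-up to `digits` decimals (printed-percentage convention).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
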