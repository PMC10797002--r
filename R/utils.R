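# Internal helpers shared across the pipeline.

#' Evaluate an expression with a locally seeded RNG
#'
#' Sets the Mersenne-Twister RNG with the given seed, evaluates `expr`, and
#' restores the caller's RNG state afterwards, so seeded operations never
#' perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Derive a child seed from a base seed and a stream index, kept inside the
# 32-bit signed integer range expected by set.seed().
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 1117) %% 2147483647)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(as.numeric(x))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 means
#' identical partitions (up to label permutation), 0 is the expected value for
#' independent random partitions. Used to score recovery of planted community
#' structure.
#'
#' @param a,b Integer (or factor) label vectors of equal length.
#' @return A single number in \[-1, 1\].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1: same partition
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# Cosine similarity between two numeric vectors.
cosine_similarity <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("cosine similarity undefined for zero vector")
  sum(x * y) / (nx * ny)
}

# Min-max normalization to [0, 1]; a constant vector maps to all 0.5 so the
# cosine remains defined and comparable (documented fallback).
minmax_normalize <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0.5, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}
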