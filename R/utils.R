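# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package funnel through this,
# so one integer seed determines every draw and no global state leaks.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
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

# Derive a child seed from a parent seed; keeps derived seeds < 2^31.
# Double arithmetic stays exact here (products < 2^53).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483587)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to label permutation), ~0 for independent
#' ones. Used to compare recovered co-expression clusters with planted
#' archetype labels.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A single number in (-1, 1].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

assert_count_matrix <- function(x) {
  if (!inherits(x, "count_matrix")) {
    stop("expected a `count_matrix` (see `simulate_counts()` or `count_matrix()`)",
         call. = FALSE)
  }
  invisible(x)
}

assert_expression_matrix <- function(x) {
  if (!inherits(x, "expression_matrix")) {
    stop("expected an `expression_matrix` (see `vst()` or `cpm()`)", call. = FALSE)
  }
  invisible(x)
}
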