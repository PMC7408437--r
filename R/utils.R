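# Shared helpers: seeded random streams, partition agreement, validation.

# Named random streams derived from one user-facing seed.  Each simulator
# stage (expression noise, survival, censoring, ...) draws from its own
# stream so that adding a stage never perturbs the draws of another.
.stream_offsets <- c(
  expression = 1L, survival = 2L, censoring = 3L, mycn = 4L,
  clinical = 5L, kmeans = 6L, generic = 7L
)

stream_seed <- function(seed, stream) {
  if (!stream %in% names(.stream_offsets)) {
    stop("unknown random stream: ", stream)
  }
  # deterministic mix kept below 2^31; doubles are exact here (< 2^53)
  as.integer((as.numeric(seed) %% 2147483647) * 48271 %% 2147483647 +
               .stream_offsets[[stream]] * 7919) %% 2147483647L
}

with_stream_seed <- function(seed, stream, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  force(code)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects,
#' used throughout the package to score planted-model recovery.  Returns 1
#' for identical partitions (up to label permutation) and has expectation 0
#' under random labeling.
#'
#' @param a,b integer or factor vectors of equal length.
#' @return a number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

# validation error naming the offending field
abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

stopifnot_count <- function(x, field, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
    abort_field(field, sprintf("must be a single integer >= %s", min))
  }
  invisible(as.integer(x))
}
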