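#' Nearest-rank percentile
#'
#' Order statistic at ascending rank `ceiling(p * length(x))`. This is the
#' thresholding convention used throughout the package, both for retaining
#' edges of the weighted network and for selecting top-scoring genes: a value
#' passes when it is greater than or equal to the nearest-rank percentile, so
#' with distinct values roughly a fraction `1 - p` passes, and ties at the
#' threshold are all retained.
#'
#' @param x Numeric vector (no missing values).
#' @param p Percentile in (0, 1).
#' @return The threshold value.
#' @examples
#' nearest_rank_percentile(1:20, 0.95)  # 19
#' @export
nearest_rank_percentile <- function(x, p) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    stop("'x' must be a nonempty numeric vector with no missing values")
  }
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1) {
    stop("'p' must be a single number strictly between 0 and 1")
  }
  sort(x)[ceiling(p * length(x))]
}

# Derive a per-sample RNG seed from (seed, sample_index) so that any permuted
# sample can be regenerated in isolation. The multiplier is the Lehmer/Park-
# Miller constant; all arithmetic stays exact in doubles (< 2^53) and the
# result fits a 32-bit integer.
derive_seed <- function(seed, sample_index) {
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  as.integer((s * 48271 + as.double(sample_index)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
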