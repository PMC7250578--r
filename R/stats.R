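#' Symmetry score of DNA distribution to spindle poles
#'
#' Quantifies how evenly the genome was distributed among the poles of an
#' ana-/telophase cell. Each pole's fraction of total DNA signal is divided
#' by the expected even share `1/p`, and the score is the standard
#' deviation of these ratios: 0 for a perfectly symmetric division, larger
#' values for proportionally more asymmetric ones.
#'
#' By default the population standard deviation (divisor `p`) is used: the
#' `p` poles of one cell are its complete set of measurements, not a
#' sample. Set `sd_type = "sample"` for the `p - 1` divisor.
#'
#' @param fractions Numeric vector of per-pole DNA signal fractions
#'   (length 2-4), summing to 1.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @param tol Tolerance on the sum-to-1 check.
#' @return A non-negative number.
#' @examples
#' symmetry_score(c(1/3, 1/3, 1/3))   # 0
#' symmetry_score(c(0.6, 0.4))        # 0.2
#' @export
symmetry_score <- function(fractions, sd_type = c("population", "sample"),
                           tol = 1e-6) {
  sd_type <- arg_match(sd_type)
  p <- length(fractions)
  if (!is.numeric(fractions) || p < 2 || p > 4) {
    abort("`fractions` must be a numeric vector of length 2-4.")
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > tol) {
    abort("`fractions` must be non-negative and sum to 1.")
  }
  ratios <- fractions / (1 / p)
  dev2 <- sum((ratios - mean(ratios))^2)
  sqrt(dev2 / if (sd_type == "population") p else p - 1)
}

#' Chromosome-count intervals for karyotype categories
#'
#' The category boundaries are not standardized, so they are explicit,
#' mandatory-visible configuration. Defaults take near-diploid as
#' 46 +/- ~10% and near-tetraploid as 92 +/- ~10%.
#'
#' @param near_diploid Integer interval `c(lower, upper)` for near-diploid
#'   counts.
#' @param near_tetraploid Integer interval for near-tetraploid counts; must
#'   lie entirely above the near-diploid interval.
#' @return An object of class `karyotype_bins`.
#' @export
karyotype_bins <- function(near_diploid = c(41, 51),
                           near_tetraploid = c(83, 101)) {
  ok <- function(x) is.numeric(x) && length(x) == 2 && x[1] <= x[2]
  if (!ok(near_diploid) || !ok(near_tetraploid)) {
    abort("Each interval must be a numeric `c(lower, upper)` with lower <= upper.")
  }
  if (near_diploid[2] >= near_tetraploid[1]) {
    abort("Intervals must be disjoint with near-diploid below near-tetraploid.")
  }
  structure(list(near_diploid = near_diploid,
                 near_tetraploid = near_tetraploid),
            class = "karyotype_bins")
}

#' Classify chromosome counts into karyotype categories
#'
#' Assigns each count to exactly one of `"near-diploid"`,
#' `"near-tetraploid"`, or `"highly aneuploid"` (everything outside both
#' intervals). Vectorized over counts.
#'
#' @param counts Positive integer chromosome counts.
#' @param bins A [karyotype_bins()] object.
#' @return A factor with levels `near-diploid`, `highly aneuploid`,
#'   `near-tetraploid`.
#' @examples
#' classify_karyotype(c(46, 69, 92))
#' @export
classify_karyotype <- function(counts, bins = karyotype_bins()) {
  stopifnot(inherits(bins, "karyotype_bins"))
  if (!is.numeric(counts) || any(counts < 1) ||
      any(counts != round(counts))) {
    abort("`counts` must be positive integers.")
  }
  lv <- c("near-diploid", "highly aneuploid", "near-tetraploid")
  out <- rep("highly aneuploid", length(counts))
  out[counts >= bins$near_diploid[1] & counts <= bins$near_diploid[2]] <-
    "near-diploid"
  out[counts >= bins$near_tetraploid[1] & counts <= bins$near_tetraploid[2]] <-
    "near-tetraploid"
  factor(out, levels = lv)
}
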