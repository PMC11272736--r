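# Tumor-vs-normal microsatellite instability scoring.
#
# Per locus, the score is the stepwise difference between the tumor and normal
# repeat-length read distributions, defined here as the total-variation
# distance between the count-normalised histograms: 1/2 * sum_k |f_T(k) -
# f_N(k)|. It is 0 iff the distributions are identical, 1 iff their supports
# are disjoint (a fully shifted locus), symmetric in tumor/normal, and
# invariant to rescaling the counts. The sample-level score is the unweighted
# mean over usable loci and is thresholded (inclusively) to call MSI-H.
# This is an analogue of the MANTIS normal-tumor instability statistic, not a
# bit-exact port.

#' Per-locus stepwise-difference instability score
#'
#' @param normal_counts,tumor_counts non-negative read counts over a shared
#'   repeat-length support (same length, aligned element-wise).
#' @return total-variation distance in `[0, 1]`, or `NA` if either histogram
#'   has zero total depth (locus unusable).
#' @export
#' @examples
#' locus_stepwise_difference(c(50, 50, 0), c(25, 25, 50))
locus_stepwise_difference <- function(normal_counts, tumor_counts) {
  stopifnot(length(normal_counts) == length(tumor_counts),
            all(normal_counts >= 0), all(tumor_counts >= 0))
  ns <- sum(normal_counts); ts <- sum(tumor_counts)
  if (ns == 0 || ts == 0) return(NA_real_)
  sum(abs(tumor_counts / ts - normal_counts / ns)) / 2
}

#' Call microsatellite instability for one sample
#'
#' Scores every locus with [locus_stepwise_difference()], drops unusable loci
#' (total depth below `min_depth` in either sample), averages the remaining
#' scores, and calls MSI-H when the aggregate is at or above `threshold`
#' (inclusive). With no usable locus the result is `indeterminate` and the
#' sample is routed to the non-MSI branch of the cascades with a warning.
#'
#' @param loci data frame in long format with columns `locus_id`,
#'   `repeat_length`, `normal_count`, `tumor_count` (one row per length).
#' @param threshold MSI-H decision threshold on the aggregate score
#'   (default 0.3, inclusive).
#' @param min_depth minimum per-locus read depth in each of tumor and normal
#'   for the locus to be usable (default 20).
#' @return object of class `msi_result`: `per_locus_scores` (named numeric),
#'   `aggregate_score`, `call` (`"MSI-H"`, `"MSS"` or `"indeterminate"`),
#'   `threshold`, `n_usable`.
#' @export
call_msi <- function(loci, threshold = 0.3, min_depth = 20) {
  stopifnot(all(c("locus_id", "repeat_length", "normal_count",
                  "tumor_count") %in% names(loci)))
  ids <- unique(loci$locus_id)
  scores <- vapply(ids, function(id) {
    h <- loci[loci$locus_id == id, , drop = FALSE]
    if (sum(h$normal_count) < min_depth || sum(h$tumor_count) < min_depth)
      return(NA_real_)
    locus_stepwise_difference(h$normal_count, h$tumor_count)
  }, numeric(1))
  names(scores) <- ids
  usable <- scores[!is.na(scores)]
  if (length(usable) == 0L) {
    warning("MSI indeterminate: no usable locus", call. = FALSE)
    return(structure(list(per_locus_scores = scores,
                          aggregate_score = NA_real_,
                          call = "indeterminate", threshold = threshold,
                          n_usable = 0L),
                     class = "msi_result"))
  }
  agg <- mean(usable)
  structure(list(per_locus_scores = scores, aggregate_score = agg,
                 call = if (agg >= threshold) "MSI-H" else "MSS",
                 threshold = threshold, n_usable = length(usable)),
            class = "msi_result")
}

#' @export
print.msi_result <- function(x, ...) {
  cat(sprintf("MSI call: %s (aggregate stepwise difference %s over %d loci; threshold %.2f)\n",
              x$call,
              if (is.na(x$aggregate_score)) "NA" else sprintf("%.3f", x$aggregate_score),
              x$n_usable, x$threshold))
  invisible(x)
}
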