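# Global (first-order) intensity-histogram features.
#
# Mean PDFF is the plain arithmetic ROI mean. The three global texture
# features (variance, skewness, kurtosis) are moments of the binned
# intensity histogram: the bin count is the median of Sturges', Scott's and
# the Freedman-Diaconis rules, bins are equal-width over the ROI's
# [min, max], and moments are taken over bin centers weighted by relative
# frequency. Kurtosis is the non-excess convention (normal => 3). A
# raw-moment mode is provided for sensitivity analysis.

#' Mean PDFF of an ROI
#' @param values numeric vector of ROI voxel values (percent).
#' @return arithmetic mean, percent.
#' @export
mean_pdff <- function(values) {
  if (length(values) == 0L)
    stop_pdff("empty ROI: cannot compute mean PDFF",
              class = "pdff_empty_roi_error")
  mean(values)
}

#' Histogram bin count: median of Sturges / Scott / Freedman-Diaconis
#'
#' `k_Sturges = ceil(log2 n) + 1`; `k_Scott = ceil(range / (3.49 sd
#' n^(-1/3)))`; `k_FD = ceil(range / (2 IQR n^(-1/3)))`; the returned count
#' is the median of the three. Degenerate inputs (sd = 0 or IQR = 0, where
#' Scott/FD widths collapse) fall back to Sturges' count alone.
#'
#' @param values numeric vector, length >= 2.
#' @return positive integer bin count.
#' @export
bin_count <- function(values) {
  n <- length(values)
  if (n < 2L)
    stop_pdff("bin_count requires n >= 2", class = "pdff_spec_error")
  k_sturges <- ceiling(log2(n)) + 1
  s <- stats::sd(values)
  iqr <- stats::IQR(values)
  rng <- max(values) - min(values)
  if (s == 0 || iqr == 0) return(as.integer(max(1, k_sturges)))
  k_scott <- ceiling(rng / (3.49 * s * n^(-1 / 3)))
  k_fd <- ceiling(rng / (2 * iqr * n^(-1 / 3)))
  as.integer(max(1, stats::median(c(k_sturges, k_scott, k_fd))))
}

#' Global intensity-histogram features
#'
#' @param values numeric vector of ROI voxel values, length >= 2.
#' @param n_bins histogram bin count; default [bin_count()] on `values`.
#' @param raw_moments if `TRUE`, compute moments from the raw sample
#'   instead of the binned histogram (sensitivity-analysis mode).
#' @return list of class `global_features`: `mean_pdff`, `variance_global`
#'   (percent^2), `skewness_global`, `kurtosis_global` (non-excess),
#'   `n_bins`. Skewness/kurtosis are `NaN` for constant ROIs, with the
#'   reason in `attr(, "reason")`.
#' @export
global_features <- function(values, n_bins = NULL, raw_moments = FALSE) {
  n <- length(values)
  if (n < 2L)
    stop_pdff("global_features requires n >= 2", class = "pdff_spec_error")
  if (raw_moments) {
    m <- mean(values)
    ctr <- values - m
    f <- rep(1 / n, n)
  } else {
    if (is.null(n_bins)) n_bins <- bin_count(values)
    lo <- min(values); hi <- max(values)
    if (hi == lo) {
      out <- structure(
        list(mean_pdff = lo, variance_global = 0,
             skewness_global = NaN, kurtosis_global = NaN,
             n_bins = 1L),
        class = "global_features",
        reason = "constant ROI: higher moments undefined")
      log_msg("debug", "constant ROI: skewness/kurtosis undefined")
      return(out)
    }
    width <- (hi - lo) / n_bins
    idx <- pmin(n_bins, floor((values - lo) / width) + 1L)
    f <- tabulate(idx, nbins = n_bins) / n
    centers <- lo + (seq_len(n_bins) - 0.5) * width
    m <- sum(f * centers)
    ctr <- centers - m
  }
  m2 <- sum(f * ctr^2)
  m3 <- sum(f * ctr^3)
  m4 <- sum(f * ctr^4)
  if (m2 == 0) {
    skew <- NaN; kurt <- NaN
    reason <- "zero histogram variance: higher moments undefined"
    log_msg("debug", reason)
  } else {
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2
    reason <- NULL
  }
  structure(list(mean_pdff = mean(values), variance_global = m2,
                 skewness_global = skew, kurtosis_global = kurt,
                 n_bins = if (raw_moments) NA_integer_
                          else as.integer(n_bins)),
            class = "global_features", reason = reason)
}
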