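# 3D gray-level co-occurrence matrix texture features.
#
# PDFF values are quantized to Ng (default 200) equal-width gray levels
# anchored at 0 % (level 1) and 100 % (level Ng). The GLCM is built over
# the 13 unique offsets of the 26-connected 3D neighborhood (all d in
# {-1,0,1}^3 \ {0} up to sign), symmetrically (both pair orientations), in
# one aggregated matrix; pooling the 13 directions makes the features
# invariant under axis permutations and flips. Diagonal pair contributions
# are down-weighted by inverse physical pair distance (discretization-
# length correction): weight 1 for the shortest axis step, 1/sqrt(2) and
# 1/sqrt(3) for face and body diagonals at isotropic spacing.

#' The 13 canonical 3D co-occurrence offsets
#'
#' All offsets `d` in `{-1,0,1}^3`, `d != 0`, up to sign (first nonzero
#' component positive, scanning z, then y, then x).
#'
#' @return 13 x 3 integer matrix with columns dx, dy, dz.
#' @export
glcm_offsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  out <- g[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  rownames(out) <- NULL
  out
}

#' Quantize a PDFF ROI to gray levels
#'
#' `level = min(Ng, floor(v / 100 * Ng) + 1)`: equal-width bins anchored so
#' that 0 % maps to level 1 and 100 % to level `Ng`.
#'
#' @param volume a [pdff_volume] (or bare 3D array).
#' @param mask an [roi_mask] on the same grid.
#' @param ng number of gray levels (default 200).
#' @return object of class `quantized_roi`: integer `labels` array (`NA`
#'   outside the mask), `ng`, `voxel_size`.
#' @export
quantize <- function(volume, mask, ng = 200L) {
  if (is.array(volume)) volume <- pdff_volume(volume)
  v <- roi_values(volume, mask)
  if (any(v < 0 | v > 100))
    stop_pdff("quantize: values outside [0,100] (clamp at load time)",
              class = "pdff_contract_error")
  lev <- pmin(ng, floor(v / 100 * ng) + 1L)
  labels <- array(NA_integer_, dim = dim(volume$values))
  labels[mask$mask] <- as.integer(lev)
  structure(list(labels = labels, ng = as.integer(ng),
                 voxel_size = volume$voxel_size),
            class = "quantized_roi")
}

glcm_offset_weight <- function(d, voxel_size, dist_correction = TRUE) {
  if (!dist_correction) return(1)
  min(voxel_size) / sqrt(sum((d * voxel_size)^2))
}

#' Build the aggregated 13-direction 3D GLCM
#'
#' For each offset `d` and each ordered in-mask voxel pair `(x, x + d)`,
#' the weight `w(d) = min(voxel_size) / ||d * voxel_size||` is accumulated
#' into `P[i, j]` and `P[j, i]`, then `P` is normalized to sum 1.
#'
#' @param q a `quantized_roi` from [quantize()].
#' @param dist_correction apply the discretization-length weights
#'   (default `TRUE`; `FALSE` counts every pair with weight 1).
#' @param aggregate `"pooled"` (default): one matrix accumulated over all
#'   13 offsets; `"average"`: normalize each offset's matrix separately,
#'   then average the 13 (the alternative reading of direction averaging).
#' @return object of class `glcm`: `P` (`ng x ng`, symmetric, sums to 1),
#'   `ng`.
#' @export
build_glcm <- function(q, dist_correction = TRUE,
                       aggregate = c("pooled", "average")) {
  aggregate <- match.arg(aggregate)
  L <- q$labels
  ng <- q$ng
  dims <- dim(L)
  offs <- glcm_offsets()
  acc <- numeric(ng * ng)
  n_dir <- 0L
  for (r in seq_len(nrow(offs))) {
    d <- offs[r, ]
    lo <- pmax(1L, 1L - d)
    hi <- pmin(dims, dims - d)
    if (any(hi < lo)) next
    i1 <- lo[1]:hi[1]; j1 <- lo[2]:hi[2]; k1 <- lo[3]:hi[3]
    A <- L[i1, j1, k1, drop = FALSE]
    B <- L[i1 + d[1], j1 + d[2], k1 + d[3], drop = FALSE]
    ok <- !is.na(A) & !is.na(B)
    if (!any(ok)) next
    ia <- A[ok]; ib <- B[ok]
    w <- glcm_offset_weight(d, q$voxel_size, dist_correction)
    cnt <- tabulate(c((ia - 1L) * ng + ib, (ib - 1L) * ng + ia),
                    nbins = ng * ng)
    if (aggregate == "pooled") {
      acc <- acc + w * cnt
    } else {
      acc <- acc + cnt / sum(cnt)
      n_dir <- n_dir + 1L
    }
  }
  tot <- sum(acc)
  if (tot == 0)
    stop_pdff("degenerate ROI: no in-mask voxel pair under any offset",
              class = "pdff_degenerate_roi_error")
  structure(list(P = matrix(acc / tot, ng, ng), ng = ng),
            class = "glcm")
}

#' Second-order GLCM features
#'
#' With marginal `p_i(i) = sum_j P(i,j)`, `mu = sum i p_i(i)`,
#' `sigma^2 = sum (i - mu)^2 p_i(i)`:
#' energy `= sum P^2`; contrast `= sum (i-j)^2 P`; entropy
#' `= -sum P log2 P` (bits); homogeneity `= sum P / (1 + |i-j|)`;
#' correlation `= (sum i j P - mu^2) / sigma^2`; variance
#' `= sum (i-mu)^2 P(i,j) / Ng^2`; sum-average
#' `= sum_k k p_{x+y}(k) / Ng^2`; dissimilarity `= sum |i-j| P`.
#'
#' @param g a `glcm` from [build_glcm()] (or a bare normalized matrix).
#' @return named list of class `glcm_features` with the eight features.
#'   `correlation` is `NaN` for a constant ROI (`sigma = 0`), with the
#'   reason in `attr(, "reason")`.
#' @export
glcm_features <- function(g) {
  if (is.matrix(g)) g <- list(P = g, ng = nrow(g))
  P <- g$P
  ng <- g$ng
  idx <- seq_len(ng)
  pi_marg <- rowSums(P)
  mu <- sum(idx * pi_marg)
  sig2 <- sum((idx - mu)^2 * pi_marg)
  D <- outer(idx, idx, "-")
  S <- outer(idx, idx, "+")
  IJ <- outer(idx, idx)
  pos <- P > 0
  reason <- NULL
  if (sig2 == 0) {
    correlation <- NaN
    reason <- "zero marginal variance: correlation undefined"
    log_msg("debug", reason)
  } else {
    correlation <- (sum(IJ * P) - mu^2) / sig2
  }
  structure(list(
    energy = sum(P^2),
    contrast = sum(D^2 * P),
    entropy = -sum(P[pos] * log2(P[pos])),
    homogeneity = sum(P / (1 + abs(D))),
    correlation = correlation,
    variance = sum(outer((idx - mu)^2, rep(1, ng)) * P) / ng^2,
    sum_average = sum(S * P) / ng^2,
    dissimilarity = sum(abs(D) * P)),
    class = "glcm_features", reason = reason)
}

#' Volume-weighted bilateral aggregation
#'
#' `f_bilat = (V_L f_L + V_R f_R) / (V_L + V_R)` per feature. A side with
#' zero volume is ignored; an undefined (`NA`/`NaN`) side value propagates
#' only if the other side is undefined too, otherwise the defined side's
#' value is returned.
#'
#' @param left,right named numeric vectors of features (including mean
#'   PDFF), identically named.
#' @param volume_left,volume_right muscle volumes, mm^3 (nonnegative, not
#'   both zero).
#' @return named numeric vector of bilaterally aggregated features.
#' @export
bilateral_aggregate <- function(left, right, volume_left, volume_right) {
  if (volume_left < 0 || volume_right < 0)
    stop_pdff("volumes must be nonnegative", class = "pdff_spec_error")
  if (volume_left + volume_right == 0)
    stop_pdff("both sides have zero volume", class = "pdff_spec_error")
  if (!identical(names(left), names(right)))
    stop_pdff("left/right feature names differ", class = "pdff_spec_error")
  l <- as.double(left); r <- as.double(right)
  out <- (volume_left * l + volume_right * r) / (volume_left + volume_right)
  only_l <- (!is.na(l) & is.na(r)) | (volume_right == 0 & !is.na(l))
  only_r <- (is.na(l) & !is.na(r)) | (volume_left == 0 & !is.na(r))
  out[only_l] <- l[only_l]
  out[only_r] <- r[only_r]
  out[is.na(l) & is.na(r)] <- NaN
  setNames(out, names(left))
}

#' The per-muscle feature set
#' @return character vector of the 12 per-muscle feature names (mean PDFF,
#'   3 global, 8 GLCM).
#' @export
feature_names <- function() {
  c("mean_pdff", "variance_global", "skewness_global", "kurtosis_global",
    "energy", "contrast", "entropy", "homogeneity", "correlation",
    "variance", "sum_average", "dissimilarity")
}

side_features <- function(volume, mask, ng, dist_correction, aggregate,
                          raw_moments = FALSE) {
  vals <- roi_values(volume, mask)
  gf <- global_features(vals, raw_moments = raw_moments)
  g <- build_glcm(quantize(volume, mask, ng),
                  dist_correction = dist_correction, aggregate = aggregate)
  tf <- glcm_features(g)
  c(mean_pdff = gf$mean_pdff, variance_global = gf$variance_global,
    skewness_global = gf$skewness_global,
    kurtosis_global = gf$kurtosis_global,
    unlist(tf[c("energy", "contrast", "entropy", "homogeneity",
                "correlation", "variance", "sum_average", "dissimilarity")]))
}

#' Extract the bilateral feature vector for every muscle of one subject
#'
#' @param volume a [pdff_volume].
#' @param masks named list of six [roi_mask] objects (`<muscle>_<side>`).
#' @param ng gray levels for the GLCM quantization.
#' @param dist_correction,aggregate passed to [build_glcm()].
#' @param raw_moments passed to [global_features()].
#' @return data.frame, one row per muscle: `muscle`, `volume_mm3`, and the
#'   12 features of [feature_names()].
#' @export
extract_features <- function(volume, masks, ng = 200L,
                             dist_correction = TRUE, aggregate = "pooled",
                             raw_moments = FALSE) {
  rows <- lapply(MUSCLES, function(mus) {
    ml <- masks[[paste0(mus, "_left")]]
    mr <- masks[[paste0(mus, "_right")]]
    if (is.null(ml) || is.null(mr)) return(NULL)
    vl <- roi_volume_mm3(ml, volume$voxel_size)
    vr <- roi_volume_mm3(mr, volume$voxel_size)
    fl <- side_features(volume, ml, ng, dist_correction, aggregate,
                        raw_moments)
    fr <- side_features(volume, mr, ng, dist_correction, aggregate,
                        raw_moments)
    fb <- bilateral_aggregate(fl, fr, vl, vr)
    cbind(data.frame(muscle = mus, volume_mm3 = vl + vr),
          as.data.frame(as.list(fb)))
  })
  do.call(rbind, rows)
}
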