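test_that("quantization anchors 0% at level 1 and 100% at level Ng", {
  dims <- c(5, 1, 1)
  v <- array(c(0, 50, 100, 99.9999, 0.6), dims)
  msk <- roi_mask(array(TRUE, dims), "ES", "left")
  q <- quantize(pdff_volume(v, c(1, 1, 1)), msk, ng = 200)
  expect_identical(q$labels[, 1, 1], c(1L, 101L, 200L, 200L, 2L))
  # monotone in PDFF on random pairs
  set.seed(31)
  a <- runif(1000) * 100
  b <- runif(1000) * 100
  lv <- function(x) pmin(200, floor(x / 100 * 200) + 1)
  swap <- a > b
  lo <- ifelse(swap, b, a); hi <- ifelse(swap, a, b)
  expect_true(all(lv(lo) <= lv(hi)))
  # contract violation outside [0,100]
  vbad <- array(c(-1, 5, 5, 5, 5), dims)
  expect_error(quantize(pdff_volume(array(pmax(0, vbad), dims)) |>
                          (\(x) {x$values <- vbad; x})(), msk),
               class = "pdff_contract_error")
})

test_that("a single voxel pair yields the symmetric two-atom GLCM", {
  dims <- c(2, 1, 1)
  labels <- array(c(3L, 7L), dims)
  q <- structure(list(labels = labels, ng = 8L, voxel_size = c(1, 1, 1)),
                 class = "quantized_roi")
  g <- build_glcm(q)
  expect_equal(g$P[3, 7], 0.5)
  expect_equal(g$P[7, 3], 0.5)
  expect_equal(sum(g$P), 1)
})

test_that("constant ROI concentrates P on one diagonal entry", {
  vol <- pdff_volume(array(40, c(3, 3, 3)), c(1, 1, 1))
  msk <- roi_mask(array(TRUE, c(3, 3, 3)), "CE", "left")
  g <- build_glcm(quantize(vol, msk, ng = 10))
  k <- floor(40 / 100 * 10) + 1
  expect_equal(g$P[k, k], 1)
  f <- glcm_features(g)
  expect_equal(f$energy, 1)
  expect_equal(f$entropy, 0)
  expect_equal(f$contrast, 0)
  expect_equal(f$dissimilarity, 0)
  expect_equal(f$homogeneity, 1)
  expect_true(is.nan(f$correlation))
  expect_match(attr(f, "reason"), "variance")
})

test_that("no in-mask pair raises a degenerate-ROI error", {
  labels <- array(NA_integer_, c(3, 3, 3))
  labels[1, 1, 1] <- 4L; labels[3, 3, 3] <- 5L   # never adjacent
  q <- structure(list(labels = labels, ng = 8L, voxel_size = c(1, 1, 1)),
                 class = "quantized_roi")
  expect_error(build_glcm(q), class = "pdff_degenerate_roi_error")
})

test_that("uniform GLCM has closed-form energy and entropy", {
  for (ng in c(4L, 16L)) {
    P <- matrix(1 / ng^2, ng, ng)
    f <- glcm_features(P)
    expect_equal(f$energy, 1 / ng^2)
    expect_equal(f$entropy, 2 * log2(ng))
  }
})

test_that("GLCM and features match brute-force oracles on random ROIs", {
  set.seed(32)
  for (rep in 1:10) {
    q <- random_quantized_roi(c(4, 4, 4), ng = 8)
    g <- build_glcm(q)
    expect_lt(max(abs(g$P - oracle_glcm(q$labels, q$ng))), 1e-12)
    expect_feature_equal(glcm_features(g), oracle_glcm_features(g$P))
  }
  # anisotropic voxels change the distance weights; oracle must still agree
  q <- random_quantized_roi(c(4, 4, 4), ng = 6)
  q$voxel_size <- c(1, 1.5, 3)
  g <- build_glcm(q)
  expect_lt(max(abs(g$P - oracle_glcm(q$labels, q$ng, c(1, 1.5, 3)))),
            1e-12)
  # and with the correction disabled, plain pair counting
  g0 <- build_glcm(q, dist_correction = FALSE)
  expect_lt(max(abs(g0$P - oracle_glcm(q$labels, q$ng, c(1, 1.5, 3),
                                       dist_correction = FALSE))), 1e-12)
})

test_that("3D checkerboard pairs levels as parity dictates", {
  # two-level checkerboard by voxel parity: axis offsets and body
  # diagonals flip parity (pair a with b); face diagonals preserve parity
  # (pair like with like)
  dims <- c(4, 4, 4)
  par <- array(0L, dims)
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    par[i, j, k] <- (i + j + k) %% 2L
  labels <- array(2L, dims)
  labels[par == 1L] <- 6L
  q <- structure(list(labels = labels, ng = 8L, voxel_size = c(1, 1, 1)),
                 class = "quantized_roi")
  g <- build_glcm(q)
  expect_lt(max(abs(g$P - oracle_glcm(labels, 8L))), 1e-12)
  # only the four cells {2,6}x{2,6} are populated
  pop <- which(g$P > 0, arr.ind = TRUE)
  expect_true(all(pop %in% c(2L, 6L)))
  # closed-form pair weights: axis pairs 3*48 unordered at w=1 (a-b);
  # face diagonals 6*36 at 1/sqrt(2) (like-like); body diagonals 4*27 at
  # 1/sqrt(3) (a-b)
  w_ab <- 3 * 48 * 1 + 4 * 27 / sqrt(3)
  w_ll <- 6 * 36 / sqrt(2)
  tot <- w_ab + w_ll
  expect_equal(g$P[2, 6] + g$P[6, 2], w_ab / tot, tolerance = 1e-12)
  expect_equal(g$P[2, 2] + g$P[6, 6], w_ll / tot, tolerance = 1e-12)
  expect_feature_equal(glcm_features(g), oracle_glcm_features(g$P))
})

test_that("feature bounds hold on random ROIs", {
  set.seed(33)
  for (rep in 1:20) {
    q <- random_quantized_roi(c(4, 4, 4), ng = sample(3:12, 1))
    f <- glcm_features(build_glcm(q))
    expect_true(f$energy > 0 && f$energy <= 1)
    expect_true(f$homogeneity > 0 && f$homogeneity <= 1)
    expect_gte(f$entropy, 0)
    expect_gte(f$contrast, 0)
    expect_gte(f$dissimilarity, 0)
    expect_gte(f$variance, 0)
    expect_gte(f$sum_average, 0)
    if (!is.nan(f$correlation))
      expect_true(abs(f$correlation) <= 1 + 1e-12)
  }
})

test_that("per-direction averaging mode is normalized and near the pooled
           mode on homogeneous texture", {
  set.seed(34)
  q <- random_quantized_roi(c(5, 5, 5), ng = 6, p_mask = 1)
  gp <- build_glcm(q, aggregate = "pooled")
  ga <- build_glcm(q, aggregate = "average")
  expect_equal(sum(ga$P), 1)
  expect_equal(max(abs(ga$P - t(ga$P))), 0)
  # the two readings differ only through per-direction weighting; on a
  # full cubic mask they stay close but not identical
  expect_lt(max(abs(ga$P - gp$P)), 0.02)
})

test_that("contrast/dissimilarity fall and homogeneity rises with
           correlation length", {
  masks <- make_masks(c(32, 32, 10))
  tgt <- c(CE = 50, ES = 50, PS = 50)
  tau <- c(CE = 8, ES = 8, PS = 8)
  lens <- c(0.5, 1.5, 3)
  stat <- array(0, c(3, 20, 3),
                dimnames = list(c("contrast", "dissimilarity",
                                  "homogeneity"), NULL, NULL))
  for (li in seq_along(lens)) for (s in 1:20) {
    sp <- subject_spec("s", "male", 40, 24, tgt, tau,
                       correlation_length = lens[li], seed = 100 + s)
    vol <- generate_subject(sp, masks)
    f <- glcm_features(build_glcm(quantize(vol, masks$ES_left, 200)))
    stat["contrast", s, li] <- f$contrast
    stat["dissimilarity", s, li] <- f$dissimilarity
    stat["homogeneity", s, li] <- f$homogeneity
  }
  m <- apply(stat, c(1, 3), mean)
  expect_true(all(diff(m["contrast", ]) < 0))
  expect_true(all(diff(m["dissimilarity", ]) < 0))
  expect_true(all(diff(m["homogeneity", ]) > 0))
})

test_that("bilateral aggregation is the volume-weighted mean with
           one-sided fallbacks", {
  l <- c(mean_pdff = 2, energy = 0.5)
  r <- c(mean_pdff = 4, energy = 0.7)
  expect_equal(bilateral_aggregate(l, r, 100, 100),
               c(mean_pdff = 3, energy = 0.6))
  expect_equal(bilateral_aggregate(c(f = 1), c(f = 5), 300, 100),
               c(f = 2))
  expect_equal(bilateral_aggregate(l, r, 0, 250), r)
  # NaN on one side: the defined side wins; both sides NaN stays NaN
  ln <- c(a = NaN, b = 1); rn <- c(a = 2, b = NaN)
  expect_equal(bilateral_aggregate(ln, rn, 100, 300), c(a = 2, b = 1))
  expect_true(is.nan(bilateral_aggregate(c(a = NaN), c(a = NaN),
                                         1, 1)[["a"]]))
  expect_error(bilateral_aggregate(l, r, 0, 0), class = "pdff_spec_error")
  expect_error(bilateral_aggregate(l, r[2:1], 1, 1),
               class = "pdff_spec_error")
})

test_that("extract_features returns one bilateral row per muscle", {
  masks <- make_masks(c(32, 32, 10))
  sp <- subject_spec("s", "female", 50, 26,
                     c(CE = 10, ES = 25, PS = 8),
                     c(CE = 4, ES = 6, PS = 3), seed = 9)
  vol <- generate_subject(sp, masks)
  fx <- extract_features(vol, masks)
  expect_identical(fx$muscle, c("CE", "ES", "PS"))
  expect_true(all(feature_names() %in% names(fx)))
  expect_equal(fx$volume_mm3,
               rep(roi_volume_mm3(masks$CE_left, c(1.5, 1.5, 1.5)) * 2, 3))
  # bilateral mean PDFF sits between the side means
  for (i in 1:3) {
    mus <- fx$muscle[i]
    ml <- mean(roi_values(vol, masks[[paste0(mus, "_left")]]))
    mr <- mean(roi_values(vol, masks[[paste0(mus, "_right")]]))
    expect_gte(fx$mean_pdff[i], min(ml, mr) - 1e-12)
    expect_lte(fx$mean_pdff[i], max(ml, mr) + 1e-12)
  }
})
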