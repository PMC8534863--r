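# Independent oracles: literal/brute-force reimplementations used to check
# the package's vectorized paths. Kept deliberately naive (triple loops,
# full enumeration) and independent of the code under test.

# All 26 neighbor offsets (13 canonical directions and their negatives).
oracle_offsets_26 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# Brute-force GLCM: loop every voxel and every one of the 26 neighbor
# offsets, accumulate w(d) for in-mask pairs. Counting all 26 ordered
# offsets is identical to counting the 13 canonical offsets symmetrically.
oracle_glcm <- function(labels, ng, voxel_size = c(1, 1, 1),
                        dist_correction = TRUE) {
  dims <- dim(labels)
  offs <- oracle_offsets_26()
  P <- matrix(0, ng, ng)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      a <- labels[i, j, k]
      if (is.na(a)) next
      for (r in seq_len(nrow(offs))) {
        d <- offs[r, ]
        ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
        if (ii < 1 || ii > dims[1] || jj < 1 || jj > dims[2] ||
            kk < 1 || kk > dims[3]) next
        b <- labels[ii, jj, kk]
        if (is.na(b)) next
        w <- if (dist_correction)
          min(voxel_size) / sqrt(sum((d * voxel_size)^2)) else 1
        P[a, b] <- P[a, b] + w
      }
    }
  if (sum(P) == 0) stop("oracle: no pairs")
  P / sum(P)
}

# Literal-formula GLCM features, scalar loops over matrix cells.
oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  pi_m <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) pi_m[i] <- pi_m[i] + P[i, j]
  mu <- 0; for (i in 1:ng) mu <- mu + i * pi_m[i]
  sig2 <- 0; for (i in 1:ng) sig2 <- sig2 + (i - mu)^2 * pi_m[i]
  energy <- 0; contrast <- 0; entropy <- 0; homog <- 0; cross <- 0
  varf <- 0; dissim <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    energy <- energy + p^2
    contrast <- contrast + (i - j)^2 * p
    if (p > 0) entropy <- entropy - p * log2(p)
    homog <- homog + p / (1 + abs(i - j))
    cross <- cross + i * j * p
    varf <- varf + (i - mu)^2 * p
    dissim <- dissim + abs(i - j) * p
  }
  pxy <- numeric(2 * ng)
  for (i in 1:ng) for (j in 1:ng) pxy[i + j] <- pxy[i + j] + P[i, j]
  sumavg <- 0
  for (k in 2:(2 * ng)) sumavg <- sumavg + k * pxy[k]
  list(energy = energy, contrast = contrast, entropy = entropy,
       homogeneity = homog,
       correlation = if (sig2 == 0) NaN else (cross - mu^2) / sig2,
       variance = varf / ng^2, sum_average = sumavg / ng^2,
       dissimilarity = dissim)
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  comb <- c(x, y)
  r <- rank(comb)
  ustat <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- ustat(seq_len(n1))
  mu <- n1 * n2 / 2
  sets <- utils::combn(n1 + n2, n1)
  us <- apply(sets, 2, ustat)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Exact two-sided signed-rank p by enumeration of all sign patterns.
oracle_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- apply(signs, 1, function(s) sum(r[s]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Random quantized ROI on a small grid: labels in 1..ng inside a random
# mask (kept nonempty with at least one adjacent pair).
random_quantized_roi <- function(dims = c(4, 4, 4), ng = 8,
                                 p_mask = 0.6) {
  repeat {
    mask <- array(runif(prod(dims)) < p_mask, dim = dims)
    labels <- array(NA_integer_, dim = dims)
    labels[mask] <- sample.int(ng, sum(mask), replace = TRUE)
    ok <- tryCatch({
      oracle_glcm(labels, ng)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(structure(list(labels = labels, ng = as.integer(ng),
                                  voxel_size = c(1, 1, 1)),
                             class = "quantized_roi"))
  }
}

# A single-muscle pair of rectangular masks for fast feature tests.
toy_masks <- function(dims = c(12, 8, 4)) {
  mk <- function(xr, side) {
    m <- array(FALSE, dim = dims)
    m[xr, 2:(dims[2] - 1), ] <- TRUE
    roi_mask(m, "ES", side)
  }
  list(ES_left = mk(2:5, "left"), ES_right = mk(8:11, "right"))
}

expect_feature_equal <- function(a, b, tol = 1e-10) {
  for (nm in c("energy", "contrast", "entropy", "homogeneity",
               "correlation", "variance", "sum_average", "dissimilarity")) {
    av <- a[[nm]]; bv <- b[[nm]]
    if (is.nan(av) || is.nan(bv)) {
      expect_true(is.nan(av) && is.nan(bv), label = nm)
    } else {
      expect_equal(av, bv, tolerance = tol, label = nm)
    }
  }
}
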