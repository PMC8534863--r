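# Cohort-level statistics: rank-based group comparisons and age/BMI-
# adjusted partial correlations.
#
# Distributions of PDFF-derived features are non-Gaussian, so group
# comparisons are unconditional rank tests: Wilcoxon-Mann-Whitney between
# sexes, Wilcoxon signed-rank between muscle compartments within subject.
# Both use exact enumeration for small tie-free samples (combined n <= 12)
# and the tie-corrected, continuity-corrected normal approximation
# otherwise. Partial correlations residualize both variables on
# [1, age, bmi] by least squares and take the Pearson correlation of the
# residuals, with a t test on df = n - 4.

new_test_result <- function(feature, grouping, statistic, p, ns, means,
                            sds, method) {
  structure(list(feature = feature, grouping = grouping,
                 statistic = statistic, p_value = p,
                 n = ns, group_mean = means, group_sd = sds,
                 method = method),
            class = "pdff_test_result")
}

#' Wilcoxon-Mann-Whitney test (two-sided)
#'
#' The statistic is `U = R1 - n1 (n1 + 1) / 2` for group `x`. The exact
#' branch (full-enumeration null via the U distribution) is used when
#' `n1 + n2 <= 12` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors, both nonempty.
#' @return a `pdff_test_result` with `method` `"exact"` or
#'   `"asymptotic-tie-corrected"`.
#' @export
mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L)
    stop_pdff("both groups must be nonempty", class = "pdff_stats_error")
  comb <- c(x, y)
  r <- rank(comb)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(comb) > 0L
  mu <- n1 * n2 / 2
  if (!ties && n1 + n2 <= 12L) {
    p <- if (u < mu) 2 * stats::pwilcox(u, n1, n2)
         else if (u > mu) 2 * (1 - stats::pwilcox(u - 1, n1, n2))
         else 1
    method <- "exact"
  } else {
    N <- n1 + n2
    tt <- table(comb)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "asymptotic-tie-corrected"
  }
  new_test_result(NA_character_, "two-sample", u, min(1, p),
                  c(n1 = n1, n2 = n2),
                  c(mean(x), mean(y)),
                  c(stats::sd(x), stats::sd(y)), method)
}

#' Wilcoxon signed-rank test (two-sided)
#'
#' Zero differences are dropped; `W` is the sum of ranks of the positive
#' differences of `|d|`. Exact enumeration (sign-flip null) for up to 12
#' nonzero tie-free differences, tie-corrected normal approximation
#' otherwise. All-zero differences give a flagged degenerate result with
#' `p = 1`.
#'
#' @param d numeric vector of paired differences.
#' @return a `pdff_test_result`.
#' @export
wilcoxon_signed_rank <- function(d) {
  d <- d[!is.na(d)]
  if (length(d) == 0L)
    stop_pdff("no paired differences", class = "pdff_stats_error")
  dz <- d[d != 0]
  n <- length(dz)
  if (n == 0L)
    return(new_test_result(NA_character_, "paired", NA_real_, 1,
                           c(n = length(d)), mean(d), stats::sd(d),
                           "degenerate-all-zero"))
  r <- rank(abs(dz))
  w <- sum(r[dz > 0])
  mu <- n * (n + 1) / 4
  ties <- anyDuplicated(abs(dz)) > 0L
  if (!ties && n <= 12L) {
    p <- if (w < mu) 2 * stats::psignrank(w, n)
         else if (w > mu) 2 * (1 - stats::psignrank(w - 1, n))
         else 1
    method <- "exact"
  } else {
    tt <- table(abs(dz))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "asymptotic-tie-corrected"
  }
  new_test_result(NA_character_, "paired", w, min(1, p), c(n = n),
                  mean(d), stats::sd(d), method)
}

#' Partial correlation adjusting for covariates
#'
#' Residualizes `x` and `y` on `[1, covariates]` by least squares and
#' correlates the residuals (Pearson by default; `method = "spearman"`
#' rank-transforms `x` and `y` first). p-value from
#' `t = r sqrt(df / (1 - r^2))`, `df = n - 2 - n_covariates`, two-sided.
#' Zero-variance covariate columns carry no information and are dropped
#' (so the result then equals the unadjusted correlation); covariates that
#' are mutually collinear raise an error.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame or matrix of covariates (e.g. age, BMI).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list of class `pdff_partial_corr`: `r`, `p_value`, `n`, `df`,
#'   `covariates`, `method`.
#' @export
partial_correlation <- function(x, y, covariates,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  covariates <- as.matrix(covariates)
  n <- length(x)
  if (length(y) != n || nrow(covariates) != n)
    stop_pdff("x, y and covariates must have matching length",
              class = "pdff_stats_error")
  ok <- stats::complete.cases(x, y, covariates)
  x <- x[ok]; y <- y[ok]; covariates <- covariates[ok, , drop = FALSE]
  n <- length(x)
  if (n < 5L)
    stop_pdff("partial correlation requires n >= 5", class = "pdff_stats_error")
  keep <- apply(covariates, 2, function(v) stats::sd(v) > 0)
  covariates <- covariates[, keep, drop = FALSE]
  ncov <- ncol(covariates)
  X <- cbind(1, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop_pdff("covariates are collinear (rank %d < %d)", qx$rank, ncol(X),
              class = "pdff_stats_error")
  df <- n - 2L - ncov
  if (df <= 0L)
    stop_pdff("not enough observations: df = %d", df,
              class = "pdff_stats_error")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  rx <- qr.resid(qx, x)
  ry <- qr.resid(qx, y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop_pdff("zero residual variance: partial correlation undefined",
              class = "pdff_stats_error")
  r <- stats::cor(rx, ry)
  p <- if (abs(r) >= 1) 0
       else 2 * stats::pt(-abs(r * sqrt(df / (1 - r^2))), df)
  structure(list(r = r, p_value = p, n = n, df = df,
                 covariates = colnames(covariates), method = method),
            class = "pdff_partial_corr")
}

muscle_col <- function(feature, muscle) paste0(feature, "_", muscle)

validate_cohort_table <- function(table) {
  need <- c("subject_id", "sex", "age", "bmi")
  if (!all(need %in% names(table)))
    stop_pdff("cohort table must contain %s", paste(need, collapse = ", "),
              class = "pdff_stats_error")
  if (anyDuplicated(table$subject_id))
    stop_pdff("duplicated subject_id", class = "pdff_stats_error")
  if (!all(table$sex %in% c("male", "female")))
    stop_pdff("sex must be 'male'/'female'", class = "pdff_stats_error")
  invisible(table)
}

#' Full cohort statistics
#'
#' Runs the complete statistical stage on a wide cohort table
#' (`subject_id, sex, age, bmi`, then `<feature>_<muscle>` columns):
#' (a) sex comparisons (Mann-Whitney) for age, BMI and every feature in
#' every muscle; (b) pairwise Wilcoxon signed-rank comparisons between
#' muscle compartments for every feature, plus a conservative per-feature
#' summary `p` (the maximum of the three pairwise p-values);
#' (c) age/BMI-adjusted partial correlations, inter-muscle (same feature,
#' muscle pairs) and within-muscle (each texture feature vs mean PDFF),
#' for the whole cohort and each sex separately.
#'
#' @param table wide cohort data.frame.
#' @param features feature set (default [feature_names()]).
#' @param by_sex also run partial correlations within each sex
#'   (default `TRUE`).
#' @param fdr add Benjamini-Hochberg adjusted p-values (`p_adj` column;
#'   off by default, matching an unadjusted primary analysis).
#' @param corr_method `"pearson"` or `"spearman"` residual correlation.
#' @param alpha two-sided significance threshold used for the
#'   `significant` flag columns (default 0.05).
#' @return list of class `pdff_cohort_stats` with data.frames
#'   `sex_tests`, `muscle_tests`, `partial_correlations`.
#' @export
run_cohort_statistics <- function(table, features = feature_names(),
                                  by_sex = TRUE, fdr = FALSE,
                                  corr_method = "pearson", alpha = 0.05) {
  validate_cohort_table(table)
  male <- table$sex == "male"
  covs <- as.matrix(table[, c("age", "bmi")])

  # (a) sex comparisons
  sex_vars <- c(list(c("age", NA), c("bmi", NA)),
                unlist(lapply(features, function(f)
                  lapply(MUSCLES, function(m) c(f, m))), recursive = FALSE))
  sex_rows <- lapply(sex_vars, function(vm) {
    col <- if (is.na(vm[2])) vm[1] else muscle_col(vm[1], vm[2])
    if (!col %in% names(table)) return(NULL)
    v <- table[[col]]
    res <- mann_whitney(v[male], v[!male])
    data.frame(feature = vm[1], muscle = vm[2],
               n_male = sum(male), n_female = sum(!male),
               mean_male = res$group_mean[1], sd_male = res$group_sd[1],
               mean_female = res$group_mean[2], sd_female = res$group_sd[2],
               statistic = res$statistic, p = res$p_value,
               method = res$method, stringsAsFactors = FALSE)
  })
  sex_tests <- do.call(rbind, sex_rows)
  sex_tests$significant <- sex_tests$p < alpha

  # (b) pairwise muscle comparisons
  pairs <- list(c("CE", "ES"), c("CE", "PS"), c("ES", "PS"))
  mus_rows <- list()
  for (f in features) {
    ps <- numeric(0)
    for (pr in pairs) {
      c1 <- muscle_col(f, pr[1]); c2 <- muscle_col(f, pr[2])
      if (!all(c(c1, c2) %in% names(table))) next
      res <- wilcoxon_signed_rank(table[[c1]] - table[[c2]])
      ps <- c(ps, res$p_value)
      mus_rows[[length(mus_rows) + 1L]] <- data.frame(
        feature = f, pair = paste(pr, collapse = "-"),
        n = nrow(table), statistic = res$statistic, p = res$p_value,
        method = res$method, stringsAsFactors = FALSE)
    }
    if (length(ps) == 3L)
      mus_rows[[length(mus_rows) + 1L]] <- data.frame(
        feature = f, pair = "all(max-p)", n = nrow(table),
        statistic = NA_real_, p = max(ps), method = "max-of-pairwise",
        stringsAsFactors = FALSE)
  }
  muscle_tests <- do.call(rbind, mus_rows)
  muscle_tests$significant <- muscle_tests$p < alpha

  # (c) partial correlations
  scopes <- list(all = rep(TRUE, nrow(table)))
  if (by_sex) scopes <- c(scopes, list(male = male, female = !male))
  pc_rows <- list()
  add_pc <- function(scope, type, feature, xlab, ylab, sel, xcol, ycol) {
    if (!all(c(xcol, ycol) %in% names(table))) return()
    res <- tryCatch(
      partial_correlation(table[[xcol]][sel], table[[ycol]][sel],
                          covs[sel, , drop = FALSE], method = corr_method),
      pdfftexture_error = function(e) NULL)
    if (is.null(res)) return()
    pc_rows[[length(pc_rows) + 1L]] <<- data.frame(
      scope = scope, type = type, feature = feature, x = xlab, y = ylab,
      r = res$r, p = res$p_value, n = res$n, df = res$df,
      stringsAsFactors = FALSE)
  }
  for (sc in names(scopes)) {
    sel <- scopes[[sc]]
    for (f in features)
      for (pr in pairs)
        add_pc(sc, "inter-muscle", f,
               muscle_col(f, pr[1]), muscle_col(f, pr[2]), sel,
               muscle_col(f, pr[1]), muscle_col(f, pr[2]))
    for (f in setdiff(features, "mean_pdff"))
      for (m in MUSCLES)
        add_pc(sc, "within-muscle", f,
               muscle_col(f, m), muscle_col("mean_pdff", m), sel,
               muscle_col(f, m), muscle_col("mean_pdff", m))
  }
  partial_correlations <- do.call(rbind, pc_rows)
  partial_correlations$significant <- partial_correlations$p < alpha

  if (fdr) {
    sex_tests$p_adj <- stats::p.adjust(sex_tests$p, "BH")
    muscle_tests$p_adj <- stats::p.adjust(muscle_tests$p, "BH")
    partial_correlations$p_adj <-
      stats::p.adjust(partial_correlations$p, "BH")
  }
  structure(list(sex_tests = sex_tests, muscle_tests = muscle_tests,
                 partial_correlations = partial_correlations,
                 alpha = alpha),
            class = "pdff_cohort_stats")
}

#' Write cohort statistics as tidy CSVs
#' @param stats result of [run_cohort_statistics()].
#' @param dir output directory.
#' @return paths of `sex_tests.csv`, `muscle_tests.csv`,
#'   `partial_correlations.csv`, invisibly.
#' @export
write_cohort_statistics <- function(stats, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(sex_tests = file.path(dir, "sex_tests.csv"),
             muscle_tests = file.path(dir, "muscle_tests.csv"),
             partial_correlations = file.path(dir,
                                              "partial_correlations.csv"))
  utils::write.csv(stats$sex_tests, paths[1], row.names = FALSE)
  utils::write.csv(stats$muscle_tests, paths[2], row.names = FALSE)
  utils::write.csv(stats$partial_correlations, paths[3], row.names = FALSE)
  invisible(paths)
}
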