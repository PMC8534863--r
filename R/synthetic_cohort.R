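# Synthetic PDFF-phantom cohort.
#
# The generator states a world with the statistical structure the analysis
# assumes: bilateral elliptical-cylinder ROIs for three muscle compartments
# (CE cervical musculature, ES erector spinae, PS psoas) spanning 10 axial
# slices at 1.5 mm isotropic voxels; inside each ROI the PDFF field is
# mean_pdff_target + tau * G with G a zero-mean unit-variance spatially
# correlated Gaussian field (white noise smoothed to correlation_length and
# re-standardized over the ROI voxels), clipped to the physical [0, 100]
# range. Cohort-level effects are a linear model in (sex, age, BMI) whose
# default coefficients emulate the reference population: ~25 men / ~54
# women, a female-elevated ES mean PDFF (~9.5 percentage points),
# male-elevated spatial heterogeneity tau in all three muscles, and
# per-muscle independent residual fields.
#
# tau defaults reproduce the male-elevated heterogeneity *sign pattern* at
# magnitudes mild enough that zero-clipping (heaviest in the low-mean PS)
# does not invert the programmed ordering: with taus set to the literal
# square roots of the reference global-variance levels, differential
# clipping between the lean male ES (mean ~7 %) and the fattier female ES
# (~17 %) flips the realized variance ordering. Sign pattern over
# magnitude is the generator's contract.

#' Per-subject phantom specification
#'
#' @param subject_id character id.
#' @param sex `"male"` or `"female"`.
#' @param age years (positive).
#' @param bmi kg/m^2 (positive).
#' @param mean_pdff_target named numeric (CE, ES, PS), percent in `[0,100]`.
#' @param tau named numeric (CE, ES, PS), spatial heterogeneity sd, percent,
#'   nonnegative.
#' @param correlation_length Gaussian smoothing sigma of the texture field,
#'   in voxels (positive).
#' @param seed integer; identical spec + seed gives a bit-identical volume.
#' @return object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id, sex, age, bmi, mean_pdff_target, tau,
                         correlation_length = 2, seed = 1L) {
  sex <- match.arg(sex, c("male", "female"))
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            is.numeric(age), age > 0, is.numeric(bmi), bmi > 0)
  mean_pdff_target <- mean_pdff_target[MUSCLES]
  tau <- tau[MUSCLES]
  if (any(is.na(mean_pdff_target)) || any(mean_pdff_target < 0) ||
      any(mean_pdff_target > 100))
    stop_pdff("mean_pdff_target must be in [0,100] for CE, ES, PS",
              class = "pdff_spec_error")
  if (any(is.na(tau)) || any(tau < 0))
    stop_pdff("tau must be nonnegative for CE, ES, PS",
              class = "pdff_spec_error")
  if (!is.numeric(correlation_length) || correlation_length <= 0)
    stop_pdff("correlation_length must be positive",
              class = "pdff_spec_error")
  structure(list(subject_id = subject_id, sex = sex, age = age, bmi = bmi,
                 mean_pdff_target = mean_pdff_target, tau = tau,
                 correlation_length = correlation_length,
                 seed = as.integer(seed)),
            class = "subject_spec")
}

#' Default cohort effect model
#'
#' Linear effect model mapping (sex, age, bmi) to per-muscle mean PDFF
#' targets and heterogeneity tau. Intercepts are the sex-group means at the
#' reference covariates (age 40 y, BMI 24 kg/m^2); mean PDFF increases with
#' age (0.05 %/y) and BMI (0.3 % per kg/m^2). tau intercepts are the square
#' roots of the sex-group global-variance levels; `tau_mean_coupling`
#' couples tau to the subject's mean-PDFF residual so that within a muscle,
#' heterogeneity rises with fat infiltration beyond what age and BMI
#' explain.
#'
#' @return nested list of coefficients per muscle.
#' @export
default_effect_model <- function() {
  mk <- function(m_male, m_female, resid_sd, t_male, t_female) {
    list(mean = list(intercept_male = m_male, intercept_female = m_female,
                     slope_age = 0.05, slope_bmi = 0.3, resid_sd = resid_sd,
                     ref_age = 40, ref_bmi = 24),
         tau = list(intercept_male = t_male, intercept_female = t_female,
                    resid_sd = 0.3, mean_coupling = 0.07, floor = 0.5))
  }
  list(CE = mk(7.9, 9.5, 6.5, 6.0, 4.8),
       ES = mk(7.4, 16.9, 7.0, 7.0, 5.2),
       PS = mk(3.3, 4.4, 4.0, 5.5, 4.2))
}

#' Cohort-level phantom specification
#'
#' @param n_male,n_female subject counts (nonnegative).
#' @param grid_shape voxel grid (3 ints).
#' @param voxel_size mm per axis (3 positive reals).
#' @param slices_per_roi axial slices each ROI spans (>= 1).
#' @param correlation_length texture field smoothing sigma, voxels.
#' @param effect_model coefficients as from [default_effect_model()].
#' @param seed master seed; per-subject seeds are derived from it
#'   deterministically.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_male = 25L, n_female = 54L,
                        grid_shape = c(64L, 64L, 10L),
                        voxel_size = c(1.5, 1.5, 1.5),
                        slices_per_roi = 10L,
                        correlation_length = 2,
                        effect_model = default_effect_model(),
                        seed = 1L) {
  if (!is_count(n_male) || !is_count(n_female))
    stop_pdff("n_male and n_female must be nonnegative counts",
              class = "pdff_spec_error")
  if (!is_count(slices_per_roi) || slices_per_roi < 1L)
    stop_pdff("slices_per_roi must be >= 1", class = "pdff_spec_error")
  structure(list(n_male = as.integer(n_male),
                 n_female = as.integer(n_female),
                 grid_shape = as.integer(grid_shape),
                 voxel_size = as.double(voxel_size),
                 slices_per_roi = as.integer(slices_per_roi),
                 correlation_length = correlation_length,
                 effect_model = effect_model, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Build the six bilateral muscle masks
#'
#' Six pairwise-disjoint elliptical cylinders (CE/ES/PS, left/right) on the
#' given grid, each spanning `slices_per_roi` axial slices centered in z.
#' Left and right masks are exact mirror images across the mid-sagittal
#' plane (x -> nx + 1 - x).
#'
#' @param grid_shape voxel grid (3 ints).
#' @param voxel_size mm per axis.
#' @param slices_per_roi axial slices per ROI.
#' @param radius_x,radius_y ellipse semi-axes in voxels.
#' @return named list of six [roi_mask] objects (`CE_left`, ..., `PS_right`).
#' @export
make_masks <- function(grid_shape, voxel_size = c(1.5, 1.5, 1.5),
                       slices_per_roi = 10L, radius_x = 5, radius_y = 3.5) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  if (nz < slices_per_roi)
    stop_pdff("grid has %d axial slices but %d requested per ROI",
              nz, slices_per_roi, class = "pdff_sizing_error")
  z0 <- (nz - slices_per_roi) %/% 2L
  zset <- seq(z0 + 1L, z0 + slices_per_roi)
  cx_left <- (nx + 1) / 2 - nx / 4
  cx_right <- (nx + 1) - cx_left
  cy <- (ny + 1) / 2 + c(-1, 0, 1) * ny / 4
  names(cy) <- MUSCLES

  xg <- seq_len(nx); yg <- seq_len(ny)
  ellipse <- function(cx, cyy, muscle, side) {
    if (cx - radius_x < 0.5 || cx + radius_x > nx + 0.5 ||
        cyy - radius_y < 0.5 || cyy + radius_y > ny + 0.5)
      stop_pdff("grid %s too small for ROI %s_%s (semi-axes %g x %g)",
                paste(grid_shape, collapse = "x"), muscle, side,
                radius_x, radius_y, class = "pdff_sizing_error")
    inside <- outer((xg - cx)^2 / radius_x^2,
                    (yg - cyy)^2 / radius_y^2, "+") < 1
    m <- array(FALSE, dim = c(nx, ny, nz))
    m[, , zset] <- inside
    if (!any(inside))
      stop_pdff("ROI %s_%s is empty at the requested radii", muscle, side,
                class = "pdff_sizing_error")
    roi_mask(m, muscle, side)
  }

  masks <- list()
  for (mus in MUSCLES) {
    masks[[paste0(mus, "_left")]] <- ellipse(cx_left, cy[[mus]], mus, "left")
    masks[[paste0(mus, "_right")]] <- ellipse(cx_right, cy[[mus]], mus, "right")
  }
  # construction should guarantee disjointness; verify defensively
  acc <- Reduce(`+`, lapply(masks, function(m) m$mask))
  if (any(acc > 1L))
    stop_pdff("internal error: ROI masks overlap", class = "pdff_sizing_error")
  masks
}

# FFT-based circular Gaussian smoothing (separable kernel). Wrap-around
# correlation is negligible at the default sigma and irrelevant after
# per-ROI re-standardization.
gaussian_smooth_3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  dims <- dim(arr)
  kern1 <- function(n) {
    d <- pmin(0:(n - 1), n - (0:(n - 1)))   # circular distance
    k <- exp(-d^2 / (2 * sigma^2))
    k / sum(k)
  }
  Kf <- lapply(dims, function(n) stats::fft(kern1(n)))
  K3 <- outer(outer(Kf[[1]], Kf[[2]]), Kf[[3]])
  Re(stats::fft(stats::fft(arr) * K3, inverse = TRUE)) / prod(dims)
}

#' Generate one subject's PDFF phantom volume
#'
#' Inside each ROI the field is `mean_pdff_target + tau * G`, with `G`
#' white noise smoothed to `correlation_length` and re-standardized to
#' exact mean 0 / sd 1 over each side's ROI voxels, then clipped to
#' `[0, 100]`. Outside all ROIs the background is 0. The per-muscle clipped
#' fraction is recorded in `meta$clip_fraction`; a muscle with more than
#' 50 % of its ROI voxels clipped raises `meta$clip_warning` (clipping
#' distorts the programmed moments).
#'
#' @param spec a [subject_spec].
#' @param masks masks from [make_masks()].
#' @param voxel_size mm per axis.
#' @return a [pdff_volume]; bit-identical for identical spec + seed.
#' @export
generate_subject <- function(spec, masks, voxel_size = c(1.5, 1.5, 1.5)) {
  grid <- dim(masks[[1]]$mask)
  vol <- array(0, dim = grid)
  clip_frac <- setNames(numeric(length(MUSCLES)), MUSCLES)
  with_seed(spec$seed, {
    for (mus in MUSCLES) {      # fixed muscle order => deterministic draws
      noise <- array(stats::rnorm(prod(grid)), dim = grid)
      sm <- gaussian_smooth_3d(noise, spec$correlation_length)
      n_clip <- 0L; n_tot <- 0L
      for (side in SIDES) {
        mk <- masks[[paste0(mus, "_", side)]]$mask
        g <- sm[mk]
        s <- stats::sd(g)
        g <- if (is.na(s) || s == 0) rep(0, length(g)) else (g - mean(g)) / s
        v <- spec$mean_pdff_target[[mus]] + spec$tau[[mus]] * g
        n_clip <- n_clip + sum(v < 0 | v > 100)
        n_tot <- n_tot + length(v)
        vol[mk] <- pmin(100, pmax(0, v))
      }
      clip_frac[[mus]] <- n_clip / n_tot
    }
  })
  warn <- any(clip_frac > 0.5)
  if (warn)
    log_msg("warn", sprintf(
      "subject %s: >50%% of ROI voxels clipped in %s; programmed moments distorted",
      spec$subject_id, paste(MUSCLES[clip_frac > 0.5], collapse = ",")))
  pdff_volume(vol, voxel_size,
              meta = list(subject_id = spec$subject_id, seed = spec$seed,
                          clip_fraction = clip_frac, clip_warning = warn))
}

#' Generate a full synthetic cohort
#'
#' Draws covariates (age ~ Uniform(20, 70); BMI ~ Normal(24, 5) truncated
#' at 16), maps them through the effect model to per-muscle mean PDFF
#' targets and tau, and generates one phantom volume per subject on a
#' shared mask set. All randomness derives from `spec$seed`.
#'
#' @param spec a [cohort_spec].
#' @return list with `subjects` (list of `list(spec, volume)`), `masks`,
#'   and `covariates` (data.frame: subject_id, sex, age, bmi).
#' @export
generate_cohort <- function(spec) {
  n <- spec$n_male + spec$n_female
  masks <- make_masks(spec$grid_shape, spec$voxel_size, spec$slices_per_roi)
  sexes <- c(rep("male", spec$n_male), rep("female", spec$n_female))
  ids <- sprintf("S%03d", seq_len(n))

  subjects <- vector("list", n)
  cov <- NULL
  with_seed(spec$seed, {
    age <- stats::runif(n, 20, 70)
    bmi <- numeric(n)
    for (i in seq_len(n)) {
      b <- stats::rnorm(1, 24, 5)
      while (b < 16) b <- stats::rnorm(1, 24, 5)
      bmi[i] <- b
    }
    cov <- data.frame(subject_id = ids, sex = sexes, age = age, bmi = bmi,
                       stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      mt <- setNames(numeric(3), MUSCLES)
      tau <- setNames(numeric(3), MUSCLES)
      for (mus in MUSCLES) {
        em <- spec$effect_model[[mus]]
        icpt <- if (sexes[i] == "male") em$mean$intercept_male
                else em$mean$intercept_female
        resid <- stats::rnorm(1, 0, em$mean$resid_sd)
        m <- icpt + em$mean$slope_age * (age[i] - em$mean$ref_age) +
          em$mean$slope_bmi * (bmi[i] - em$mean$ref_bmi) + resid
        mt[[mus]] <- min(95, max(0.5, m))
        ticpt <- if (sexes[i] == "male") em$tau$intercept_male
                 else em$tau$intercept_female
        t <- ticpt + em$tau$mean_coupling * resid +
          stats::rnorm(1, 0, em$tau$resid_sd)
        tau[[mus]] <- max(em$tau$floor, t)
      }
      subjects[[i]] <- list(
        spec = subject_spec(ids[i], sexes[i], age[i], bmi[i], mt, tau,
                            correlation_length = spec$correlation_length,
                            seed = derive_seed(spec$seed, i)))
    }
  })
  for (i in seq_len(n))
    subjects[[i]]$volume <- generate_subject(subjects[[i]]$spec, masks,
                                             spec$voxel_size)
  list(subjects = subjects, masks = masks, covariates = cov, spec = spec)
}

#' Write a generated cohort to disk
#'
#' Writes per-subject PDFF volumes (`.nii.gz`), the shared mask set, the
#' covariate CSV, and a JSON manifest (file paths, seeds, spec echo).
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- cohort$spec$voxel_size
  mask_files <- list()
  for (nm in names(cohort$masks)) {
    p <- file.path(dir, paste0("mask_", nm, ".nii.gz"))
    write_mask(cohort$masks[[nm]], p, vs)
    mask_files[[nm]] <- basename(p)
  }
  subj <- lapply(cohort$subjects, function(s) {
    p <- file.path(dir, paste0(s$spec$subject_id, "_pdff.nii.gz"))
    write_volume(s$volume, p)
    list(subject_id = s$spec$subject_id, volume = basename(p),
         seed = s$spec$seed)
  })
  write_covariates(cohort$covariates, file.path(dir, "covariates.csv"))
  manifest <- list(
    format = "pdfftexture-cohort/1",
    grid_shape = cohort$spec$grid_shape,
    voxel_size = vs,
    slices_per_roi = cohort$spec$slices_per_roi,
    master_seed = cohort$spec$seed,
    covariates = "covariates.csv",
    masks = mask_files,
    subjects = subj)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mp)
}
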