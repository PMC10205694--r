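#' Synthetic cohort specification
#'
#' Defines the study design the cohort generator emulates: 133 subjects
#' (80 cLBP / 53 control; 61 F / 72 M with the sex split applied within
#' group), truncated-normal ages, five lumbar levels with L1-L2 out of the
#' field of view for 15 subjects (650 disc records), level-by-group NP-T1rho
#' means, a uniform -1.0 ms/year age slope except a flattened -0.3 ms/year
#' in the cLBP group at L5-S1, an 8.1 ms male-female gap, and
#' subject/residual variance components.  Level means for L1-L2 through
#' L4-L5 are calibrated so the group marginal means land near 76.4 and
#' 70.8 ms; the L5-S1 values (69.8 ms control, 11.3 ms gap) fix the
#' age-30/age-50 predictions near 84, 64 and 57 ms by construction.
#'
#' @param n_control,n_clbp subjects per group.
#' @param sex_counts list with per-group `F`/`M` counts.
#' @param age_mean,age_sd,age_range truncated-normal age distribution (years).
#' @param control_means named level-by-group means (ms) for controls at the
#'   age center, sex-averaged.
#' @param clbp_gap_ms per-level deficit of the cLBP mean below control (ms).
#' @param age_slope,clbp_l5s1_slope per-year slopes (ms/year); the second
#'   applies only to the cLBP group at L5-S1.
#' @param sex_gap_ms male-minus-female difference (ms), applied +/- half
#'   about the sex-average.
#' @param subject_sd,residual_sd variance components (ms).
#' @param n_missing_l1l2 subjects whose L1-L2 disc is out of the field of
#'   view, split proportionally (6 control / 9 cLBP) at random per seed.
#' @param pfirrmann_thresholds_ms decreasing cut-points on the true NP-T1rho
#'   mapping to grades I..V.
#' @param pfirrmann_misclass_prob probability a grade is misread by one grade.
#' @param voxels_per_disc NP voxels simulated per disc.
#' @param voxel_sd_by_grade_ms voxel-level SD per Pfirrmann grade (ms);
#'   decreasing, so early grades are the most heterogeneous.
#' @param t2_slope,t2_intercept linear map from NP-T1rho to NP-T2 (ms).
#' @param t1r_t2_r2 planted voxel-level squared correlation of T1rho and T2.
#' @param seed default RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 53, n_clbp = 80,
                        sex_counts = list(control = c(F = 26, M = 27),
                                          cLBP = c(F = 35, M = 45)),
                        age_mean = 43.9, age_sd = 13.4, age_range = c(19, 75),
                        control_means = c(L1L2 = 81.0, L2L3 = 79.0,
                                          L3L4 = 77.0, L4L5 = 75.0,
                                          L5S1 = 69.8),
                        clbp_gap_ms = c(L1L2 = 4.5, L2L3 = 4.2, L3L4 = 4.0,
                                        L4L5 = 3.8, L5S1 = 11.3),
                        age_slope = -1.0, clbp_l5s1_slope = -0.3,
                        sex_gap_ms = 8.1,
                        subject_sd = 12, residual_sd = 13,
                        n_missing_l1l2 = c(control = 6, cLBP = 9),
                        pfirrmann_thresholds_ms = c(95, 80, 62, 48),
                        pfirrmann_misclass_prob = 0.1,
                        voxels_per_disc = 225,
                        voxel_sd_by_grade_ms = c(18, 15, 10, 8, 6),
                        t2_slope = 0.857, t2_intercept = -0.3,
                        t1r_t2_r2 = 0.80,
                        seed = 20230101) {
  spec <- as.list(environment())
  if (n_control <= 0 || n_clbp <= 0) stop("group sizes must be positive")
  for (g in names(sex_counts)) {
    n_g <- if (g == "control") n_control else n_clbp
    if (sum(sex_counts[[g]]) != n_g)
      stop("sex counts for ", g, " do not sum to the group size")
  }
  if (sum(n_missing_l1l2) > n_control + n_clbp)
    stop("more missing L1-L2 discs than subjects")
  if (!all(diff(pfirrmann_thresholds_ms) < 0))
    stop("pfirrmann thresholds must be decreasing")
  if (t1r_t2_r2 <= 0 || t1r_t2_r2 >= 1) stop("t1r_t2_r2 must be in (0,1)")
  stopifnot(identical(names(control_means), disc_levels()),
            identical(names(clbp_gap_ms), disc_levels()))
  structure(spec, class = "cohort_spec")
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  u <- stats::runif(n, stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  stats::qnorm(u, mean, sd)
}

grade_from_t1rho <- function(t, thresholds) {
  g <- rep.int(5L, length(t))
  for (k in rev(seq_along(thresholds))) g[t >= thresholds[k]] <- k
  g
}

#' Generate a synthetic disc cohort with known truth
#'
#' Draws a full cohort from a [cohort_spec()]: per-subject metadata
#' (including descriptive ODI/VAS/BMI values, BMI partly missing in the
#' control arm), a disc table with true and observed NP-T1rho, NP-T2,
#' whole-disc means and Pfirrmann grades, and (optionally) a per-voxel NP
#' table whose disc-wise means/SDs match the disc records exactly and whose
#' T1rho-T2 pairs carry the planted squared correlation.  The observed disc
#' value is `level-group mean + slope * (age - age_mean) + sex term +
#' subject intercept + residual`.  Deterministic for a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed; defaults to the spec's.
#' @param voxels generate the per-voxel table (disable for speed in
#'   replicate studies that only need disc records).
#' @return list of class `disc_cohort`: `subjects`, `discs`, `voxels`
#'   (or `NULL`), `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = spec$seed,
                            voxels = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  n <- spec$n_control + spec$n_clbp
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = rep(GROUPS, c(spec$n_control, spec$n_clbp)),
    stringsAsFactors = FALSE)
  sex <- character(n)
  for (g in GROUPS) {
    i <- which(subjects$group == g)
    sex[i] <- sample(rep(SEXES, spec$sex_counts[[g]][SEXES]))
  }
  subjects$sex <- sex
  subjects$age <- rtruncnorm1(n, spec$age_mean, spec$age_sd,
                              spec$age_range[1], spec$age_range[2])
  is_ctl <- subjects$group == "control"
  subjects$odi <- pmax(0, ifelse(is_ctl, stats::rnorm(n, 0.8, 2.2),
                                 stats::rnorm(n, 26.2, 15.2)))
  subjects$vas <- pmin(10, pmax(0, ifelse(is_ctl, stats::rnorm(n, 1.1, 1.3),
                                          stats::rnorm(n, 6.4, 2.4))))
  subjects$bmi <- ifelse(is_ctl, stats::rnorm(n, 23.0, 3.6),
                         stats::rnorm(n, 26.3, 4.8))
  n_bmi_na <- max(0L, spec$n_control - 39L)            # BMI gaps, control arm
  if (n_bmi_na > 0) subjects$bmi[sample(which(is_ctl), n_bmi_na)] <- NA

  b_subj <- stats::rnorm(n, 0, spec$subject_sd)

  miss <- c(sample(which(is_ctl), spec$n_missing_l1l2["control"]),
            sample(which(!is_ctl), spec$n_missing_l1l2["cLBP"]))

  recs <- lapply(seq_len(n), function(i) {
    lv <- disc_levels()
    if (i %in% miss) lv <- setdiff(lv, "L1L2")
    data.frame(subject_id = subjects$subject_id[i], sidx = i, level = lv,
               stringsAsFactors = FALSE)
  })
  discs <- do.call(rbind, recs)
  discs$age <- subjects$age[discs$sidx]
  discs$sex <- subjects$sex[discs$sidx]
  discs$group <- subjects$group[discs$sidx]

  lvl_mean <- spec$control_means[discs$level] -
    ifelse(discs$group == "cLBP", spec$clbp_gap_ms[discs$level], 0)
  slope <- ifelse(discs$group == "cLBP" & discs$level == "L5S1",
                  spec$clbp_l5s1_slope, spec$age_slope)
  sex_term <- ifelse(discs$sex == "M", 0.5, -0.5) * spec$sex_gap_ms
  discs$np_t1rho_true <- lvl_mean + slope * (discs$age - spec$age_mean) +
    sex_term + b_subj[discs$sidx]
  discs$np_t1rho_mean <- discs$np_t1rho_true +
    stats::rnorm(nrow(discs), 0, spec$residual_sd)

  grade <- grade_from_t1rho(discs$np_t1rho_true, spec$pfirrmann_thresholds_ms)
  flip <- stats::runif(nrow(discs)) < spec$pfirrmann_misclass_prob
  shift <- ifelse(stats::runif(nrow(discs)) < 0.5, -1L, 1L)
  discs$pfirrmann <- pmin(5L, pmax(1L, grade + ifelse(flip, shift, 0L)))

  # whole-disc means: linear maps of the NP mean calibrated to the printed
  # whole-disc group means, plus independent scatter
  discs$wholedisc_t1rho_mean <- 22.6 + 0.536 * discs$np_t1rho_mean +
    stats::rnorm(nrow(discs), 0, 5)

  vox <- NULL
  sig_g <- spec$voxel_sd_by_grade_ms[discs$pfirrmann]
  if (voxels) {
    m <- spec$voxels_per_disc
    Z <- matrix(stats::rnorm(m * nrow(discs)), nrow = m)
    Z <- scale(Z)                     # exact zero mean / unit SD per disc
    t1v <- sweep(sweep(Z, 2L, sig_g, `*`), 2L, discs$np_t1rho_mean, `+`)
    var_t1v <- stats::var(as.vector(t1v))
    sd_e <- spec$t2_slope * sqrt(var_t1v * (1 - spec$t1r_t2_r2) / spec$t1r_t2_r2)
    t2v <- spec$t2_intercept + spec$t2_slope * t1v +
      stats::rnorm(length(t1v), 0, sd_e)
    vox <- data.frame(subject_id = rep(discs$subject_id, each = m),
                      level = rep(discs$level, each = m),
                      group = rep(discs$group, each = m),
                      pfirrmann = rep(discs$pfirrmann, each = m),
                      t1rho_ms = as.vector(t1v), t2_ms = as.vector(t2v),
                      stringsAsFactors = FALSE)
    discs$np_t1rho_sd <- apply(t1v, 2L, stats::sd)
    discs$np_t2_mean <- colMeans(matrix(vox$t2_ms, nrow = m))
    discs$n_valid_voxels <- m
  } else {
    discs$np_t1rho_sd <- sig_g
    sd_t1 <- stats::sd(discs$np_t1rho_mean)
    sd_e <- spec$t2_slope * sd_t1 *
      sqrt((1 - spec$t1r_t2_r2) / spec$t1r_t2_r2) / sqrt(spec$voxels_per_disc)
    discs$np_t2_mean <- spec$t2_intercept + spec$t2_slope * discs$np_t1rho_mean +
      stats::rnorm(nrow(discs), 0, sd_e)
    discs$n_valid_voxels <- spec$voxels_per_disc
  }
  discs$wholedisc_t2_mean <- 16.2 + 0.583 * discs$np_t2_mean +
    stats::rnorm(nrow(discs), 0, 4)
  discs$incomplete <- FALSE
  discs$sidx <- NULL

  structure(list(subjects = subjects, discs = discs, voxels = vox,
                 spec = spec, seed = seed),
            class = "disc_cohort")
}

#' @export
print.disc_cohort <- function(x, ...) {
  cat(sprintf("<disc_cohort> %d subjects, %d disc records%s (seed %s)\n",
              nrow(x$subjects), nrow(x$discs),
              if (!is.null(x$voxels))
                sprintf(", %d NP voxels", nrow(x$voxels)) else "",
              format(x$seed)))
  invisible(x)
}

#' Synthetic phantom specification
#'
#' Describes a five-disc digital phantom standing in for the scanner and the
#' external segmentation network: elliptical discs on four mid-sagittal
#' slices with a brighter (slower-relaxing) nucleus-pulposus core occupying
#' the central anterior-posterior fraction of each ellipse, a shared
#' spin-lock/echo time grid, and Gaussian noise on the magnitude signal at a
#' given SNR.
#'
#' @param n_slices,n_rows,n_cols image grid (rows = superior-inferior,
#'   columns = anterior-posterior).
#' @param spacing_mm voxel spacing `(slice, row, col)` in mm.
#' @param disc_center_rows row centers of the five discs (L1-L2 .. L5-S1).
#' @param col_center AP center column shared by all discs.
#' @param semi_ap_mm,semi_si_mm ellipse semi-axes.
#' @param np_fraction AP fraction of the ellipse forming the NP core
#'   (strictly < 1, so the NP stays inside the disc).
#' @param t1rho_np_ms,t1rho_annulus_ms,t2_np_ms,t2_annulus_ms ground-truth
#'   relaxation times.
#' @param s0 proton-density amplitude.
#' @param tsl_t1rho_ms,tsl_t2_ms acquisition time grids (ms).
#' @param snr signal-to-noise ratio `s0 / sigma`; noise is additive Gaussian
#'   on the magnitude (a high-SNR approximation of Rician noise).
#' @param rician use Rician magnitude noise instead of Gaussian.
#' @param angle_deg in-plane rotation of every disc (for rotation-invariance
#'   studies).
#' @param seed RNG seed.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 4, n_rows = 144, n_cols = 64,
                         spacing_mm = c(4, 1, 1),
                         disc_center_rows = seq(16, 120, by = 26),
                         col_center = 32, semi_ap_mm = 16, semi_si_mm = 6,
                         np_fraction = 0.4,
                         t1rho_np_ms = 85, t1rho_annulus_ms = 55,
                         t2_np_ms = 65, t2_annulus_ms = 45,
                         s0 = 1000,
                         tsl_t1rho_ms = c(2, 10, 20, 40, 60),
                         tsl_t2_ms = c(4, 12, 25, 50, 75),
                         snr = 50, rician = FALSE,
                         angle_deg = 0, seed = 7) {
  spec <- as.list(environment())
  if (length(disc_center_rows) != 5L) stop("need 5 disc centers")
  if (np_fraction <= 0 || np_fraction >= 1)
    stop("np_fraction must be in (0, 1) so the NP stays inside the disc")
  if (snr < 0) stop("snr must be >= 0 (0 disables noise)")
  spec$sigma <- if (snr > 0) s0 / snr else 0
  structure(spec, class = "phantom_spec")
}

#' Generate a synthetic spin-lock phantom with ground truth
#'
#' Builds the phantom image series (T1rho and T2), the disc label masks and
#' the voxel-wise ground-truth relaxation maps.  Signals follow
#' `s0 * exp(-TSL / T(x))` plus noise, clipped at zero (magnitude images
#' are non-negative); the background is pure noise.  Deterministic per seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed RNG seed; defaults to the spec's.
#' @return list of class `disc_phantom`: `series_t1rho`, `series_t2`
#'   ([spin_lock_series()]), `segmentation` ([disc_segmentation()]),
#'   `truth` (arrays `t1rho_ms`, `t2_ms`, logical `np_mask`), `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  th <- spec$angle_deg * pi / 180
  plane_lab <- matrix(0L, spec$n_rows, spec$n_cols)
  plane_np <- matrix(FALSE, spec$n_rows, spec$n_cols)
  rr <- row(plane_lab); cc <- col(plane_lab)
  for (l in seq_along(spec$disc_center_rows)) {
    ap <- cc - spec$col_center
    si <- rr - spec$disc_center_rows[l]
    u <- cos(th) * ap + sin(th) * si      # disc-frame AP coordinate
    v <- -sin(th) * ap + cos(th) * si
    inside <- (u / spec$semi_ap_mm)^2 + (v / spec$semi_si_mm)^2 <= 1 &
      plane_lab == 0L
    plane_lab[inside] <- l
    plane_np[inside & abs(u) <= spec$np_fraction * spec$semi_ap_mm] <- TRUE
  }

  sp <- c(spec$n_slices, spec$n_rows, spec$n_cols)
  labels <- aperm(array(plane_lab, dim = c(spec$n_rows, spec$n_cols,
                                           spec$n_slices)), c(3, 1, 2))
  np_mask <- aperm(array(plane_np, dim = c(spec$n_rows, spec$n_cols,
                                           spec$n_slices)), c(3, 1, 2))
  truth_of <- function(np_val, an_val) {
    t <- array(NA_real_, sp)
    t[labels > 0L] <- an_val
    t[np_mask] <- np_val
    t
  }
  truth_t1rho <- truth_of(spec$t1rho_np_ms, spec$t1rho_annulus_ms)
  truth_t2 <- truth_of(spec$t2_np_ms, spec$t2_annulus_ms)

  make_series <- function(truth, tsl, tag) {
    sig <- array(0, dim = c(sp, length(tsl)))
    for (k in seq_along(tsl)) {
      clean <- ifelse(is.na(truth), 0, spec$s0 * exp(-tsl[k] / truth))
      if (spec$sigma > 0) {
        if (spec$rician) {
          re <- clean + stats::rnorm(length(clean), 0, spec$sigma)
          im <- stats::rnorm(length(clean), 0, spec$sigma)
          clean <- sqrt(re^2 + im^2)
        } else {
          clean <- clean + stats::rnorm(length(clean), 0, spec$sigma)
        }
      }
      sig[, , , k] <- pmax(clean, 0)
    }
    spin_lock_series(sig, tsl, spec$spacing_mm, tag)
  }
  structure(list(
    series_t1rho = make_series(truth_t1rho, spec$tsl_t1rho_ms, "T1rho"),
    series_t2 = make_series(truth_t2, spec$tsl_t2_ms, "T2"),
    segmentation = disc_segmentation(labels, spec$spacing_mm),
    truth = list(t1rho_ms = truth_t1rho, t2_ms = truth_t2,
                 np_mask = np_mask),
    spec = spec), class = "disc_phantom")
}
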