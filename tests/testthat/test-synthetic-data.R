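test_that("the default cohort reproduces the study design exactly", {
  co <- generate_cohort(voxels = FALSE)
  expect_equal(nrow(co$subjects), 133L)
  expect_equal(sum(co$subjects$sex == "F"), 61L)
  expect_equal(sum(co$subjects$sex == "M"), 72L)
  expect_equal(sum(co$subjects$group == "control"), 53L)
  expect_equal(sum(co$subjects$group == "cLBP"), 80L)
  expect_equal(nrow(co$discs), 650L)
  expect_equal(sum(co$discs$level == "L1L2"), 118L)   # 15 out of view
  expect_equal(anyDuplicated(co$discs[, c("subject_id", "level")]), 0L)
  expect_equal(sum(is.na(co$subjects$bmi)), 53L - 39L)
  # within-group sex split matches the printed contingency table
  expect_equal(unname(table(co$subjects$group, co$subjects$sex)["control", ]),
               c(26L, 27L))
})

test_that("the generator is deterministic per seed and varies across seeds", {
  a <- generate_cohort(cohort_spec(seed = 5), voxels = FALSE)
  b <- generate_cohort(cohort_spec(seed = 5), voxels = FALSE)
  c <- generate_cohort(cohort_spec(seed = 6), voxels = FALSE)
  expect_identical(a$discs, b$discs)
  expect_false(identical(a$discs$np_t1rho_mean, c$discs$np_t1rho_mean))
})

test_that("a noise-free generator yields the planted L5-S1 values exactly", {
  spec <- cohort_spec(subject_sd = 0, residual_sd = 0,
                      age_mean = 43.9, age_sd = 13.4,
                      age_range = c(43.9, 43.9),    # pin every age
                      seed = 3)
  co <- generate_cohort(spec, voxels = FALSE)
  l5 <- co$discs[co$discs$level == "L5S1" & co$discs$group == "control", ]
  expect_true(all(abs(l5$np_t1rho_mean -
                      (69.8 + ifelse(l5$sex == "M", 4.05, -4.05))) < 1e-9))
  l5c <- co$discs[co$discs$level == "L5S1" & co$discs$group == "cLBP", ]
  expect_true(all(abs(l5c$np_t1rho_mean -
                      (58.5 + ifelse(l5c$sex == "M", 4.05, -4.05))) < 1e-9))
})

test_that("the within-group SD matches the generator's variance budget", {
  # budget: age 13.4^2 x slope^2 + (8.1/2)^2 + level spread + 12^2 + 13^2
  sds <- sapply(1:100, function(s) {
    co <- generate_cohort(cohort_spec(seed = 1000 + s), voxels = FALSE)
    c(sd(co$discs$np_t1rho_mean[co$discs$group == "control"]),
      sd(co$discs$np_t1rho_mean[co$discs$group == "cLBP"]))
  })
  expect_gte(min(rowMeans(sds)), 20)
  expect_lte(max(rowMeans(sds)), 25)
})

test_that("voxel bookkeeping is exact and consistent with disc records", {
  co <- generate_cohort(cohort_spec(seed = 2), voxels = TRUE)
  m <- co$spec$voxels_per_disc
  expect_equal(nrow(co$voxels), 650L * m)
  vox_means <- tapply(co$voxels$t1rho_ms,
                      paste(co$voxels$subject_id, co$voxels$level),
                      mean)
  key <- paste(co$discs$subject_id, co$discs$level)
  expect_equal(as.numeric(vox_means[key]), co$discs$np_t1rho_mean,
               tolerance = 1e-9)
  vox_sds <- tapply(co$voxels$t1rho_ms, paste(co$voxels$subject_id,
                                              co$voxels$level), sd)
  expect_equal(as.numeric(vox_sds[key]), co$discs$np_t1rho_sd,
               tolerance = 1e-9)
})

test_that("voxel heterogeneity decreases with Pfirrmann grade", {
  co <- generate_cohort(cohort_spec(seed = 2), voxels = TRUE)
  h <- pfirrmann_voxel_histograms(
    data.frame(pfirrmann = co$voxels$pfirrmann, t_ms = co$voxels$t1rho_ms))
  s <- h$summary
  expect_gt(mean(s$sd[s$grade %in% 1:2]), mean(s$sd[s$grade %in% 4:5]))
})

test_that("grade misclassification occurs at roughly the configured rate", {
  mism <- unlist(lapply(1:10, function(s) {
    co <- generate_cohort(cohort_spec(seed = 3000 + s), voxels = FALSE)
    raw <- nprelax:::grade_from_t1rho(co$discs$np_t1rho_true,
                                      co$spec$pfirrmann_thresholds_ms)
    co$discs$pfirrmann != raw
  }))
  # clamping at grades I and V cancels some flips, so the observed rate
  # sits a little below the nominal 0.1
  expect_gt(mean(mism), 0.05)
  expect_lt(mean(mism), 0.12)
})

test_that("cLBP grades are shifted toward higher grades across seeds", {
  # Grades derive from subject-level true values, so the 650 discs are
  # strongly clustered within the 133 subjects and the trend test's
  # nominal variance understates the seed-to-seed spread; the shift is
  # therefore asserted as a directional majority, not a uniform rejection.
  res <- sapply(1:50, function(s) {
    co <- generate_cohort(cohort_spec(seed = 4000 + s), voxels = FALSE)
    tab <- table(factor(co$discs$group, levels = c("control", "cLBP")),
                 factor(co$discs$pfirrmann, levels = 1:5))
    tt <- cochran_armitage_trend(as.matrix(tab))
    c(direction = tt$direction, p = tt$p)
  })
  expect_gte(mean(res["direction", ] < 0), 0.8)  # controls at lower grades
  expect_lt(median(res["p", ]), 0.05)
})

test_that("the phantom's planted geometry satisfies its invariants", {
  ph <- generate_phantom(phantom_spec(snr = 0))
  expect_true(all(ph$truth$np_mask[ph$segmentation$labels > 0] |
                  is.na(ph$truth$t1rho_ms[ph$segmentation$labels > 0]) |
                  ph$truth$t1rho_ms[ph$segmentation$labels > 0] ==
                    ph$spec$t1rho_annulus_ms))
  # NP strictly inside each disc, never touching background
  expect_true(all(ph$segmentation$labels[ph$truth$np_mask] > 0))
  # per-disc NP voxel count comfortably above the minimum-voxel threshold
  for (l in 1:5)
    expect_gt(sum(ph$truth$np_mask & ph$segmentation$labels == l), 10)
  expect_error(phantom_spec(np_fraction = 1.2), "np_fraction")
})

test_that("infeasible cohort specifications are rejected", {
  expect_error(cohort_spec(sex_counts = list(control = c(F = 10, M = 10),
                                             cLBP = c(F = 35, M = 45))),
               "sum to the group size")
  expect_error(cohort_spec(t1r_t2_r2 = 1.2), "t1r_t2_r2")
  expect_error(cohort_spec(pfirrmann_thresholds_ms = c(48, 62, 80, 95)),
               "decreasing")
})
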