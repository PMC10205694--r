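noise_free_spec <- function(seed = 99) {
  cohort_spec(subject_sd = 0, residual_sd = 0,
              pfirrmann_misclass_prob = 0, seed = seed)
}

test_that("the mixed model recovers a noise-free table exactly", {
  co <- generate_cohort(noise_free_spec(), voxels = FALSE)
  m <- fit_mixed_model(co$discs)
  expect_equal(unname(fitted(m$model)), co$discs$np_t1rho_mean,
               tolerance = 1e-8)
  mm <- marginal_effects(m)
  g <- function(q) mm$estimate[mm$quantity == q]
  expect_equal(g("age_slope"), -(570 * 1.0 + 80 * 0.3) / 650,
               tolerance = 1e-6)
  expect_equal(g("sex_male_minus_female"), 8.1, tolerance = 1e-6)
  # planted contrast averaged over the realized design; the L5-S1 gap
  # shrinks with age because controls decline faster (-1.0 vs -0.3 ms/yr)
  gap <- ifelse(co$discs$level == "L5S1",
                11.3 - 0.7 * (co$discs$age - 43.9),
                c(L1L2 = 4.5, L2L3 = 4.2, L3L4 = 4.0,
                  L4L5 = 3.8)[co$discs$level])
  expect_equal(g("group_control_minus_clbp"), mean(gap), tolerance = 1e-6)
})

test_that("level-wise OLS recovers noise-free coefficients exactly", {
  co <- generate_cohort(noise_free_spec(), voxels = FALSE)
  lw <- suppressWarnings(fit_levelwise_model(co$discs, "L4L5"))  # perfect fit
  mm <- marginal_effects(lw)
  g <- function(q) mm$estimate[mm$quantity == q]
  expect_equal(g("age_slope"), -1.0, tolerance = 1e-8)
  expect_equal(g("sex_male_minus_female"), 8.1, tolerance = 1e-8)
  expect_equal(g("group_control_minus_clbp"), 3.8, tolerance = 1e-8)
  expect_equal(g("age_slope_control"), -1.0, tolerance = 1e-8)
  expect_equal(g("age_slope_cLBP"), -1.0, tolerance = 1e-8)
  p <- predict(lw, data.frame(age = 30, group = "control"))
  expect_equal(p$fit, 75 + 13.9, tolerance = 1e-8)
})

test_that("mixed model equals OLS when each subject has one record", {
  co <- generate_cohort(cohort_spec(subject_sd = 0, seed = 31),
                        voxels = FALSE)
  set.seed(42)
  one <- do.call(rbind, lapply(split(co$discs, co$discs$subject_id),
                               function(d) d[sample(nrow(d), 1L), ]))
  m <- fit_mixed_model(one)
  fr <- nprelax:::prepare_model_frame(one, "np_t1rho_mean")$frame
  ols <- lm(y ~ age_c * sexn * level * groupn, data = fr)
  expect_equal(unname(m$beta), unname(coef(ols)), tolerance = 1e-5)
})

test_that("an empty design cell raises an error naming the cell", {
  co <- generate_cohort(noise_free_spec(), voxels = FALSE)
  d <- co$discs
  drop <- d$level == "L1L2" & d$sex == "F" & d$group == "control"
  expect_error(fit_mixed_model(d[!drop, ]),
               "empty design cell: sex=F, level=L1L2, group=control")
})

test_that("the planted L5-S1 age-by-group interaction is usually detected", {
  # planted slope difference 0.7 ms/yr against subject+residual SD ~17.7
  # gives ~85% analytic power at n = 133, so a 70% floor is asserted
  pvals <- sapply(1:60, function(s) {
    co <- generate_cohort(cohort_spec(seed = 6000 + s), voxels = FALSE)
    lw <- fit_levelwise_model(co$discs, "L5S1")
    lw$coefficients$p[lw$coefficients$term == "age_c:groupn"]
  })
  expect_gte(mean(pvals < 0.05), 0.70)
})

test_that("the reference prediction equals its intercept-derived value", {
  co <- generate_cohort(cohort_spec(seed = 12), voxels = FALSE)
  lw <- fit_levelwise_model(co$discs, "L3L4")
  p <- predict(lw, data.frame(age = lw$age_center, group = "control"))
  b <- lw$beta
  expect_equal(p$fit, unname(b["(Intercept)"] - 0.5 * b["groupn"]),
               tolerance = 1e-10)
})

test_that("Pearson correlations behave on exact, null and degenerate data", {
  tab <- data.frame(subject_id = sprintf("S%02d", 1:20), age = 1:20,
                    sex = "F", group = "control", level = "L1L2",
                    np_t1rho_mean = -(1:20) + 100)
  r <- pearson_by_group_level(tab)
  row <- r[r$group == "control" & r$level == "L1L2", ]
  expect_equal(row$r, -1.0, tolerance = 1e-12)

  tab$np_t1rho_mean <- 70                         # zero variance
  r2 <- pearson_by_group_level(tab)
  expect_true(r2$degenerate[r2$group == "control" & r2$level == "L1L2"])

  set.seed(8)
  rs <- replicate(1000, cor(rnorm(50), rnorm(50)))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("the trend test matches the permutation oracle and edge cases", {
  same <- matrix(c(10, 20, 30, 10, 20, 30), nrow = 2, byrow = TRUE)
  tt <- cochran_armitage_trend(same)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p, 1.0)
  expect_error(cochran_armitage_trend(matrix(c(0, 0, 0, 1, 2, 3), 2,
                                             byrow = TRUE)), "zero-margin")

  set.seed(13)
  for (i in 1:3) {
    p1 <- c(0.3, 0.25, 0.2, 0.15, 0.1)
    p2 <- rev(p1)
    counts <- rbind(c(rmultinom(1, 100, p1)), c(rmultinom(1, 100, p2)))
    counts <- counts + 1                          # keep margins positive
    tt <- cochran_armitage_trend(counts)
    expect_lt(abs(tt$p - perm_trend_p(counts)), 0.02)
  }
})

test_that("group comparisons match closed forms and printed designs", {
  # pooled-variance Student t on a 6-value fixture, by hand
  x <- c(10, 12, 14); y <- c(11, 15, 19)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  subj <- data.frame(subject_id = sprintf("S%d", 1:6),
                     age = c(x, y), sex = rep(c("F", "M"), 3),
                     group = rep(c("control", "cLBP"), each = 3))
  discs <- data.frame(subject_id = "S1", age = 10, sex = "F",
                      group = "control", level = "L1L2", pfirrmann = NA)
  suppressMessages(suppressWarnings(
    res <- group_comparison_suite(subj, discs)))
  expect_equal(res$statistic[res$variable == "age"], t_hand,
               tolerance = 1e-10)
  expect_equal(res$p[res$variable == "age"],
               2 * pt(-abs(t_hand), df = 4), tolerance = 1e-10)

  # identical groups: t statistic 0 / p = 1, chi-square 0
  subj2 <- data.frame(subject_id = sprintf("S%d", 1:8),
                      age = rep(c(30, 40, 50, 60), 2),
                      sex = rep(c("F", "F", "M", "M"), 2),
                      group = rep(c("control", "cLBP"), each = 4))
  suppressMessages(suppressWarnings(
    res2 <- group_comparison_suite(subj2, discs)))
  expect_equal(res2$p[res2$variable == "age"], 1.0, tolerance = 1e-12)
  expect_equal(res2$statistic[res2$variable == "sex"], 0, tolerance = 1e-12)
})

test_that("voxel-wise correlation handles exact, null and planted cases", {
  t1 <- seq(40, 120, length.out = 100)
  expect_equal(voxelwise_t1r_t2_correlation(t1, 0.8 * t1)$r2, 1.0)
  set.seed(21)
  expect_lt(voxelwise_t1r_t2_correlation(rnorm(10000), rnorm(10000))$r2,
            0.01)
  expect_true(voxelwise_t1r_t2_correlation(rep(1, 10), rnorm(10))$degenerate)
  expect_error(voxelwise_t1r_t2_correlation(1:2, 1:2), ">= 3")
})

test_that("adjusted associations match the normal-equations solution", {
  d <- data.frame(y = c(3, 5, 7, 9, 11, 13, 2, 4, 6, 8, 10, 12),
                  x = c(1, 2, 3, 4, 5, 6, 1.5, 2.5, 3.5, 4.5, 5.5, 6.5),
                  a = c(2, 1, 4, 3, 6, 5, 2, 3, 1, 5, 4, 6))
  fit <- adjusted_association(d, "y", "x", "a")
  X <- cbind(1, d$x, d$a)
  beta_hand <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(fit$estimate, beta_hand[2], tolerance = 1e-10)
  expect_equal(fit$n, 12L)

  expect_error(adjusted_association(d[1:5, ], "y", "x"), "complete cases")
  d$y_copy <- d$y                                 # exposure == outcome
  ident <- suppressWarnings(adjusted_association(d, "y", "y_copy"))
  expect_equal(ident$estimate, 1.0, tolerance = 1e-12)
  expect_lt(ident$p, 1e-10)
})

test_that("the exposure test holds its nominal type-I error under the null", {
  set.seed(99)
  rej <- mean(replicate(1000, {
    d <- data.frame(y = rnorm(30), x = rnorm(30), a = rnorm(30))
    adjusted_association(d, "y", "x", "a")$p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("histogram densities normalise and conserve counts", {
  set.seed(4)
  v <- data.frame(pfirrmann = 1L, t_ms = runif(5000, 60, 70))
  h <- pfirrmann_voxel_histograms(v)
  expect_equal(sum(h$histograms$density) * h$bin_width_ms, 1.0,
               tolerance = 1e-9)
  v2 <- data.frame(pfirrmann = rep(c(2L, 3L), each = 400),
                   t_ms = c(rnorm(400, 80, 5), rnorm(400, 60, 5)))
  suppressMessages(h2 <- pfirrmann_voxel_histograms(v2))
  expect_equal(sum(h2$histograms$count), 800L)
  expect_equal(h2$summary$n, c(400L, 400L))
})

test_that("every model reruns on the T2 outcome without code changes", {
  co <- generate_cohort(cohort_spec(seed = 77), voxels = FALSE)
  m <- fit_mixed_model(co$discs, outcome = "np_t2_mean")
  expect_s3_class(m, "np_model_fit")
  expect_equal(m$n_obs, 650L)
  lw <- fit_levelwise_model(co$discs, "L5S1", outcome = "np_t2_mean")
  mm <- marginal_effects(lw)
  # T2 is a near-linear map of T1rho, so planted effects scale by the slope
  expect_lt(abs(mm$estimate[mm$quantity == "group_control_minus_clbp"] -
                0.857 * 11.3), 6)
})
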