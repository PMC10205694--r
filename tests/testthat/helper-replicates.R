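# Planted (generator-true) values of the quantities the models estimate.
# The marginal age slope is the observation-weighted mean of the cell
# slopes: 570 of 650 discs carry -1.0 ms/yr, the 80 cLBP L5-S1 discs carry
# -0.3 ms/yr.  Level-wise L5-S1 predictions follow from the planted means
# and slopes at absolute ages, so they are centering-invariant.
planted <- list(
  age_slope = (570 * 1.0 + 80 * 0.3) / 650,     # magnitude, ms/yr
  sex_gap = 8.1,                                 # male - female, ms
  l5s1_gap_at = function(age_center)             # control - cLBP at center;
    11.3 - 0.7 * (age_center - 43.9),            # shrinks with age
  l5s1_slope_control = -1.0,
  l5s1_slope_clbp = -0.3,
  pred_control_30 = 69.8 + 1.0 * (43.9 - 30),
  pred_clbp_50 = (69.8 - 11.3) - 0.3 * (50 - 43.9),
  pred_control_50 = 69.8 - 1.0 * (50 - 43.9))

# One Monte-Carlo replicate: simulate a cohort, fit the mixed and the
# L5-S1 level-wise models, return every tracked estimate with its CI and
# the per-seed planted value of the age-center group contrast.
replicate_once <- function(seed) {
  co <- generate_cohort(cohort_spec(seed = seed), voxels = FALSE)
  mix <- fit_mixed_model(co$discs)
  mm <- marginal_effects(mix)
  lw <- fit_levelwise_model(co$discs, "L5S1")
  lm_ <- marginal_effects(lw)
  pr <- predict(lw, data.frame(age = c(30, 50, 50),
                               group = c("control", "cLBP", "control")))
  g <- function(df, q, f) df[df$quantity == q, f]
  data.frame(
    seed = seed,
    mixed_age_slope = g(mm, "age_slope", "estimate"),
    mixed_age_slope_lo = g(mm, "age_slope", "ci_lo"),
    mixed_age_slope_hi = g(mm, "age_slope", "ci_hi"),
    mixed_sex_gap = g(mm, "sex_male_minus_female", "estimate"),
    mixed_sex_gap_lo = g(mm, "sex_male_minus_female", "ci_lo"),
    mixed_sex_gap_hi = g(mm, "sex_male_minus_female", "ci_hi"),
    l5s1_gap = g(lm_, "group_control_minus_clbp", "estimate"),
    l5s1_gap_lo = g(lm_, "group_control_minus_clbp", "ci_lo"),
    l5s1_gap_hi = g(lm_, "group_control_minus_clbp", "ci_hi"),
    l5s1_gap_planted = planted$l5s1_gap_at(lw$age_center),
    l5s1_slope_control = g(lm_, "age_slope_control", "estimate"),
    l5s1_slope_control_lo = g(lm_, "age_slope_control", "ci_lo"),
    l5s1_slope_control_hi = g(lm_, "age_slope_control", "ci_hi"),
    l5s1_slope_clbp = g(lm_, "age_slope_cLBP", "estimate"),
    l5s1_slope_clbp_lo = g(lm_, "age_slope_cLBP", "ci_lo"),
    l5s1_slope_clbp_hi = g(lm_, "age_slope_cLBP", "ci_hi"),
    pred_control_30 = pr$fit[1], pred_control_30_lo = pr$ci_lo[1],
    pred_control_30_hi = pr$ci_hi[1],
    pred_clbp_50 = pr$fit[2], pred_clbp_50_lo = pr$ci_lo[2],
    pred_clbp_50_hi = pr$ci_hi[2],
    pred_control_50 = pr$fit[3], pred_control_50_lo = pr$ci_lo[3],
    pred_control_50_hi = pr$ci_hi[3],
    clbp_np_mean = mean(co$discs$np_t1rho_mean[co$discs$group == "cLBP"]))
}

.rep_cache <- new.env(parent = emptyenv())

# 200 replicate seeds, shared by the recovery and coverage checks.
replicate_study <- function(n_seeds = 200, base_seed = 1) {
  key <- paste0("s", base_seed, "_n", n_seeds)
  if (is.null(.rep_cache[[key]]))
    .rep_cache[[key]] <- do.call(rbind, lapply(
      base_seed + seq_len(n_seeds) - 1, replicate_once))
  .rep_cache[[key]]
}

mc_se <- function(x) stats::sd(x) / sqrt(length(x))
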