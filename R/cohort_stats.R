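#' @importFrom stats as.formula coef lm model.matrix pnorm qnorm terms vcov
NULL

GROUPS <- c("control", "cLBP")
SEXES <- c("F", "M")

# Effect codes used throughout: sex F = -0.5 / M = +0.5, group control = -0.5 /
# cLBP = +0.5; age centered at the sample mean; level treatment-coded with
# L1-L2 reference.  With this coding an intercept-level prediction is the
# sex-averaged value at the age center, and simple design-row differences
# give the marginal contrasts the models report.
prepare_model_frame <- function(table, outcome, age_center = NULL) {
  need <- c("subject_id", "age", "sex", "group", "level", outcome)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  keep <- !is.na(table[[outcome]])
  if ("incomplete" %in% names(table)) keep <- keep & !table$incomplete
  tab <- table[keep, , drop = FALSE]
  if (!all(tab$sex %in% SEXES)) stop("sex must be 'F' or 'M'")
  if (!all(tab$group %in% GROUPS)) stop("group must be 'control' or 'cLBP'")
  if (!all(tab$level %in% disc_levels())) stop("unknown disc level in table")
  if (is.null(age_center)) age_center <- mean(tab$age)
  frame <- data.frame(y = tab[[outcome]],
                      subject_id = factor(tab$subject_id),
                      age_c = tab$age - age_center,
                      sexn = ifelse(tab$sex == "M", 0.5, -0.5),
                      groupn = ifelse(tab$group == "cLBP", 0.5, -0.5),
                      level = factor(tab$level, levels = disc_levels()))
  frame$level <- droplevels(frame$level)
  list(frame = frame, age_center = age_center,
       n_dropped = sum(!keep), outcome = outcome)
}

new_np_model_fit <- function(kind, model, prep, fe_terms, converged,
                             level = NULL) {
  beta <- if (inherits(model, "merMod")) lme4::fixef(model) else coef(model)
  V <- as.matrix(vcov(model))
  se <- sqrt(diag(V))
  z <- beta / se
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se),
                      ci_lo = unname(beta - qnorm(0.975) * se),
                      ci_hi = unname(beta + qnorm(0.975) * se),
                      p = unname(2 * pnorm(-abs(z))),
                      row.names = NULL, stringsAsFactors = FALSE)
  if (inherits(model, "merMod")) {
    vc <- as.data.frame(lme4::VarCorr(model))
    varcomp <- c(subject_sd = vc$sdcor[vc$grp == "subject_id"][1],
                 residual_sd = vc$sdcor[vc$grp == "Residual"][1])
  } else {
    varcomp <- c(subject_sd = NA_real_,
                 residual_sd = summary(model)$sigma)
  }
  structure(list(kind = kind, level = level, outcome = prep$outcome,
                 formula_descriptor = deparse(formula(model)),
                 model = model, beta = beta, vcov = V,
                 coefficients = coefs, variance_components = varcomp,
                 n_obs = nrow(prep$frame),
                 n_subjects = length(unique(prep$frame$subject_id)),
                 converged = converged, age_center = prep$age_center,
                 frame = prep$frame, fe_terms = fe_terms),
            class = "np_model_fit")
}

#' Full-interaction mixed-effects model of a disc biomarker
#'
#' Fits the cohort-level linear mixed model of a per-disc outcome on age,
#' sex, spinal level and group with a random subject intercept.  All nested
#' two- and three-way interactions and the four-way
#' age x sex x level x group interaction are included.  Age is centered at
#' the sample mean; sex and group are effect-coded and level treatment-coded
#' (L1-L2 reference), so marginal contrasts are obtained from design-row
#' averages (see [marginal_effects()]).  Estimation is REML via
#' \pkg{lme4}; inference is Wald, two-sided.
#'
#' @param table a disc table (one row per subject x level) with columns
#'   `subject_id`, `age`, `sex` ("F"/"M"), `group` ("control"/"cLBP"),
#'   `level`, and the outcome column.  Rows flagged `incomplete` or with a
#'   missing outcome are excluded.
#' @param outcome name of the outcome column (the T2 pathway reruns every
#'   model simply by passing `"np_t2_mean"`).
#' @return An object of class `np_model_fit`.
#' @export
fit_mixed_model <- function(table, outcome = "np_t1rho_mean") {
  prep <- prepare_model_frame(table, outcome)
  fr <- prep$frame
  for (g in GROUPS)
    if (length(unique(fr$subject_id[fr$groupn == ifelse(g == "cLBP", .5, -.5)])) < 2L)
      stop("need >= 2 subjects in group ", g)
  cells <- table(sexn = fr$sexn, level = fr$level, groupn = fr$groupn)
  if (any(cells == 0L)) {
    i <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("empty design cell: sex=%s, level=%s, group=%s",
                 SEXES[i[1L]], levels(fr$level)[i[2L]], GROUPS[i[3L]]))
  }
  msgs <- character()
  model <- withCallingHandlers(
    lme4::lmer(y ~ age_c * sexn * level * groupn + (1 | subject_id),
               data = fr, REML = TRUE,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore",
                                           calc.derivs = FALSE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  converged <- length(model@optinfo$conv$lme4$messages) == 0L &&
    !any(grepl("failed to converge", msgs))
  fit <- new_np_model_fit("mixed", model, prep,
                          terms(~ age_c * sexn * level * groupn), converged)
  fit$diagnostics <- msgs
  fit
}

#' Level-wise regression with an age-by-group interaction
#'
#' Ordinary least squares for a single spinal level (one record per
#' subject): outcome on age, sex, group and the age x group interaction,
#' with the same centering/coding as [fit_mixed_model()].  Per-group age
#' slopes and the age-adjusted group contrast are derived quantities
#' ([marginal_effects()]).
#'
#' @inheritParams fit_mixed_model
#' @param level disc level, one of [disc_levels()].
#' @return An object of class `np_model_fit`.
#' @export
fit_levelwise_model <- function(table, level, outcome = "np_t1rho_mean") {
  level <- match.arg(level, disc_levels())
  sub <- table[table$level == level, , drop = FALSE]
  if (!nrow(sub)) stop("no records at level ", level)
  if (anyDuplicated(sub$subject_id))
    stop("more than one record per subject at level ", level)
  prep <- prepare_model_frame(sub, outcome)
  model <- lm(y ~ age_c + sexn + groupn + age_c:groupn, data = prep$frame)
  new_np_model_fit("levelwise", model, prep,
                   terms(~ age_c + sexn + groupn + age_c:groupn),
                   converged = TRUE, level = level)
}

#' @export
print.np_model_fit <- function(x, ...) {
  cat(sprintf("<np_model_fit> %s model of %s%s: %d obs, %d subjects%s\n",
              x$kind, x$outcome,
              if (!is.null(x$level)) paste0(" at ", x$level) else "",
              x$n_obs, x$n_subjects,
              if (x$converged) "" else " [convergence flagged]"))
  print(x$coefficients, digits = 4)
  if (!is.na(x$variance_components["subject_sd"]))
    cat(sprintf("  subject SD %.2f, residual SD %.2f\n",
                x$variance_components["subject_sd"],
                x$variance_components["residual_sd"]))
  invisible(x)
}

# Model matrix for a counterfactual version of the fitted frame
fit_design <- function(fit, frame) {
  model.matrix(fit$fe_terms, frame,
               xlev = if ("level" %in% all.vars(fit$fe_terms))
                 list(level = levels(fit$frame$level)))
}

# linear-combination inference: est = c'beta, Wald CI
lincomb <- function(fit, cvec) {
  est <- sum(cvec * fit$beta)
  se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
  c(estimate = est, se = se,
    ci_lo = est - qnorm(0.975) * se, ci_hi = est + qnorm(0.975) * se,
    p = 2 * pnorm(-abs(est / se)))
}

contrast_row <- function(fit, mutate_a, mutate_b) {
  fa <- mutate_a(fit$frame); fb <- mutate_b(fit$frame)
  cvec <- colMeans(fit_design(fit, fa)) - colMeans(fit_design(fit, fb))
  lincomb(fit, cvec)
}

#' Marginal effects of a fitted disc-biomarker model
#'
#' Derives, by averaging design rows over the observed covariate
#' distribution, the observation-weighted marginal age slope (ms/year), the
#' age-adjusted male-minus-female contrast and the age- and sex-adjusted
#' control-minus-cLBP contrast, each with Wald 95% CI and p-value.  For a
#' level-wise fit the per-group age slopes are included.
#'
#' @param fit an [fit_mixed_model()] or [fit_levelwise_model()] result.
#' @return `data.frame` with one row per quantity.
#' @export
marginal_effects <- function(fit) {
  stopifnot(inherits(fit, "np_model_fit"))
  rows <- list(
    age_slope = contrast_row(fit,
      function(f) { f$age_c <- f$age_c + 1; f }, identity),
    sex_male_minus_female = contrast_row(fit,
      function(f) { f$sexn <- 0.5; f }, function(f) { f$sexn <- -0.5; f }),
    group_control_minus_clbp = contrast_row(fit,
      function(f) { f$groupn <- -0.5; f }, function(f) { f$groupn <- 0.5; f }))
  if (fit$kind == "levelwise") {
    for (g in GROUPS) {
      gn <- if (g == "cLBP") 0.5 else -0.5
      rows[[paste0("age_slope_", g)]] <- contrast_row(fit,
        function(f) { f$age_c <- f$age_c + 1; f$groupn <- gn; f },
        function(f) { f$groupn <- gn; f })
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  out$quantity <- names(rows)
  rownames(out) <- NULL
  out[, c("quantity", "estimate", "se", "ci_lo", "ci_hi", "p")]
}

#' Predict the biomarker at given covariates
#'
#' Population-level point prediction with a Wald 95% CI.  Omitting `sex`
#' (or passing `NA`) returns the sex-averaged prediction (effect-coded sex
#' set to its midpoint).
#'
#' @param object an `np_model_fit`.
#' @param newdata `data.frame` with columns `age`, `group`, optionally `sex`
#'   and (for mixed fits) `level`.
#' @param ... unused.
#' @return `data.frame` with `fit`, `se`, `ci_lo`, `ci_hi`.
#' @export
predict.np_model_fit <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  if (!all(c("age", "group") %in% names(newdata)))
    stop("newdata needs `age` and `group` columns")
  if (!all(newdata$group %in% GROUPS))
    stop("unknown group label; use ", paste(GROUPS, collapse = "/"))
  sex <- if ("sex" %in% names(newdata)) newdata$sex else rep(NA, nrow(newdata))
  if (!all(is.na(sex) | sex %in% SEXES)) stop("unknown sex label; use F/M/NA")
  fr <- data.frame(age_c = newdata$age - object$age_center,
                   sexn = ifelse(is.na(sex), 0, ifelse(sex == "M", .5, -.5)),
                   groupn = ifelse(newdata$group == "cLBP", 0.5, -0.5))
  if (object$kind == "mixed") {
    if (!"level" %in% names(newdata))
      stop("mixed-model predictions need a `level` column")
    if (!all(newdata$level %in% levels(object$frame$level)))
      stop("unknown level label")
    fr$level <- factor(newdata$level, levels = levels(object$frame$level))
  }
  X <- fit_design(object, fr)
  est <- drop(X %*% object$beta)
  se <- sqrt(rowSums((X %*% object$vcov) * X))
  data.frame(fit = est, se = se,
             ci_lo = est - qnorm(0.975) * se, ci_hi = est + qnorm(0.975) * se)
}

#' Pearson correlation of a biomarker with age, per group and level
#'
#' @inheritParams fit_mixed_model
#' @return `data.frame` with `group`, `level`, `n`, `r`, `p`, `degenerate`.
#'   Cells with fewer than 3 records or zero variance are flagged and carry
#'   `NA`.
#' @export
pearson_by_group_level <- function(table, outcome = "np_t1rho_mean") {
  out <- expand.grid(group = GROUPS, level = disc_levels(),
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$r <- NA_real_; out$p <- NA_real_
  out$degenerate <- FALSE
  for (i in seq_len(nrow(out))) {
    sub <- table[table$group == out$group[i] & table$level == out$level[i], ]
    y <- sub[[outcome]]; x <- sub$age
    ok <- is.finite(y) & is.finite(x)
    out$n[i] <- sum(ok)
    if (sum(ok) < 3L || stats::sd(y[ok]) == 0 || stats::sd(x[ok]) == 0) {
      out$degenerate[i] <- TRUE
      next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    out$r[i] <- unname(ct$estimate); out$p[i] <- ct$p.value
  }
  out
}

#' Cochran-Armitage trend test for a 2 x K ordered table
#'
#' Tests for a linear trend in the proportion falling in row 1 across K
#' ordered categories (e.g. Pfirrmann grades I-V between study groups),
#' using the standard score statistic with a two-sided normal p-value.
#'
#' @param counts 2 x K matrix of counts, rows = groups, columns in category
#'   order.
#' @param scores category scores, default `1:K`.
#' @return list of class `trend_test`: `statistic` (standardised Z), `p`,
#'   `direction` (+1 if row 1 is shifted toward higher scores).
#' @export
cochran_armitage_trend <- function(counts, scores = seq_len(ncol(counts))) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L || ncol(counts) < 2L)
    stop("`counts` must be a 2 x K matrix with K >= 2")
  if (any(counts < 0) || any(rowSums(counts) == 0))
    stop("zero-margin table: each group needs a positive total")
  coltot <- colSums(counts)
  N <- sum(counts); R1 <- sum(counts[1L, ])
  T_obs <- sum(scores * counts[1L, ])
  ET <- R1 * sum(scores * coltot) / N
  VT <- R1 * (N - R1) / (N * (N - 1)) *
    (sum(scores^2 * coltot) - sum(scores * coltot)^2 / N)
  if (VT <= 0) stop("zero-margin table: no variance across categories")
  z <- (T_obs - ET) / sqrt(VT)
  structure(list(statistic = z, p = 2 * pnorm(-abs(z)),
                 direction = sign(z)),
            class = "trend_test")
}

#' Squared voxel-wise correlation between two relaxation parameters
#'
#' @param t1rho,t2 paired voxel values.
#' @return list with `r2`, `r`, `p`, `n`, `degenerate`.
#' @export
voxelwise_t1r_t2_correlation <- function(t1rho, t2) {
  ok <- is.finite(t1rho) & is.finite(t2)
  if (sum(ok) < 3L) stop("need >= 3 paired finite values")
  x <- t1rho[ok]; y <- t2[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r2 = NA_real_, r = NA_real_, p = NA_real_, n = sum(ok),
                degenerate = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r2 = r^2, r = r, p = ct$p.value, n = sum(ok), degenerate = FALSE)
}

#' Group-comparison suite for cohort metadata and disc outcomes
#'
#' Assembles the standard between-group table: Student's t tests for
#' continuous subject measures, a chi-square test without continuity
#' correction for sex, a Cochran-Armitage trend test for Pfirrmann grades,
#' and age- and sex-adjusted mixed-model contrasts for the disc relaxation
#' outcomes.  Continuous columns absent from `subjects` are skipped with a
#' notice (BMI may legitimately be partly missing).
#'
#' @param subjects per-subject `data.frame` with `subject_id`, `age`, `sex`,
#'   `group`, and optionally `bmi`, `odi`, `vas`.
#' @param discs disc table as for [fit_mixed_model()], with optional
#'   `pfirrmann` and `np_t2_mean` columns.
#' @return tidy `data.frame`: `variable`, `test`, `mean_control`,
#'   `sd_control`, `mean_clbp`, `sd_clbp`, `statistic`, `p`.
#' @export
group_comparison_suite <- function(subjects, discs) {
  stopifnot(all(c("subject_id", "age", "sex", "group") %in% names(subjects)))
  is_ctl <- subjects$group == "control"
  res <- list()
  row <- function(variable, test, mc = NA, sc = NA, ml = NA, sl = NA,
                  statistic = NA, p = NA)
    data.frame(variable = variable, test = test, mean_control = mc,
               sd_control = sc, mean_clbp = ml, sd_clbp = sl,
               statistic = statistic, p = p, stringsAsFactors = FALSE)

  for (v in c("age", "bmi", "odi", "vas")) {
    if (!v %in% names(subjects)) {
      message("column `", v, "` not present; skipped")
      next
    }
    x <- subjects[[v]][is_ctl]; y <- subjects[[v]][!is_ctl]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    tt <- stats::t.test(x, y, var.equal = TRUE)
    res[[v]] <- row(v, "student_t", mean(x), stats::sd(x), mean(y),
                    stats::sd(y), unname(tt$statistic), tt$p.value)
  }

  sex_tab <- table(factor(subjects$group, levels = GROUPS),
                   factor(subjects$sex, levels = SEXES))
  cs <- stats::chisq.test(sex_tab, correct = FALSE)
  res$sex <- row("sex", "chi_square", statistic = unname(cs$statistic),
                 p = cs$p.value)

  if ("pfirrmann" %in% names(discs) && any(!is.na(discs$pfirrmann))) {
    gtab <- table(factor(discs$group, levels = GROUPS),
                  factor(discs$pfirrmann, levels = 1:5))
    tr <- cochran_armitage_trend(as.matrix(gtab))
    res$pfirrmann <- row("pfirrmann", "cochran_armitage",
                         statistic = tr$statistic, p = tr$p)
  }

  for (oc in c("np_t1rho_mean", "np_t2_mean", "wholedisc_t1rho_mean",
               "wholedisc_t2_mean")) {
    if (!oc %in% names(discs) || all(is.na(discs[[oc]]))) next
    prep <- prepare_model_frame(discs, oc)
    model <- suppressWarnings(
      lme4::lmer(y ~ age_c + sexn + groupn + (1 | subject_id),
                 data = prep$frame, REML = TRUE))
    b <- lme4::fixef(model)["groupn"]
    se <- sqrt(vcov(model)["groupn", "groupn"])
    ctl <- discs[[oc]][discs$group == "control"]
    clb <- discs[[oc]][discs$group == "cLBP"]
    res[[oc]] <- row(oc, "mixed_model_contrast",
                     mean(ctl, na.rm = TRUE), stats::sd(ctl[is.finite(ctl)]),
                     mean(clb, na.rm = TRUE), stats::sd(clb[is.finite(clb)]),
                     unname(b / se), unname(2 * pnorm(-abs(b / se))))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-grade histograms of NP voxel relaxation times
#'
#' Density-normalised histograms of all NP voxels by Pfirrmann grade, with
#' per-grade mean and SD — the voxel-level view of how biochemical
#' heterogeneity evolves across structural degeneration grades.
#'
#' @param voxels `data.frame` with `pfirrmann` and `t_ms` (see
#'   [voxel_table()] or the cohort generator's voxel export).
#' @param bin_width_ms histogram bin width, ms.
#' @return list of class `pfirrmann_histograms`: `summary` (`grade`, `n`,
#'   `mean`, `sd`) and `histograms` (`grade`, `bin_mid`, `count`,
#'   `density`).  Empty grades are omitted with a notice.
#' @export
pfirrmann_voxel_histograms <- function(voxels, bin_width_ms = 2) {
  stopifnot(all(c("pfirrmann", "t_ms") %in% names(voxels)))
  v <- voxels[is.finite(voxels$t_ms) & !is.na(voxels$pfirrmann), ]
  grades <- sort(unique(v$pfirrmann))
  absent <- setdiff(1:5, grades)
  if (length(absent))
    message("no voxels for grade(s) ", paste(absent, collapse = ", "),
            "; omitted")
  breaks <- seq(floor(min(v$t_ms)),
                ceiling(max(v$t_ms)) + bin_width_ms, by = bin_width_ms)
  hs <- list(); sm <- list()
  for (g in grades) {
    x <- v$t_ms[v$pfirrmann == g]
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    hs[[as.character(g)]] <- data.frame(grade = g, bin_mid = h$mids,
                                        count = h$counts, density = h$density)
    sm[[as.character(g)]] <- data.frame(grade = g, n = length(x),
                                        mean = mean(x), sd = stats::sd(x))
  }
  structure(list(summary = do.call(rbind, sm),
                 histograms = do.call(rbind, hs),
                 bin_width_ms = bin_width_ms),
            class = "pfirrmann_histograms")
}

#' @export
plot.pfirrmann_histograms <- function(x, ...) {
  grades <- unique(x$histograms$grade)
  cols <- grDevices::hcl.colors(length(grades), "viridis")
  graphics::plot(NULL, xlim = range(x$histograms$bin_mid),
                 ylim = c(0, max(x$histograms$density)),
                 xlab = "relaxation time (ms)", ylab = "probability density",
                 main = "NP voxels by Pfirrmann grade", ...)
  for (i in seq_along(grades)) {
    h <- x$histograms[x$histograms$grade == grades[i], ]
    graphics::lines(h$bin_mid, h$density, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = paste("grade", grades),
                   col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Adjusted association between a biomarker and an exposure
#'
#' Ordinary least squares of `outcome` on `exposure` plus adjusters over
#' complete cases; reports the exposure coefficient with Wald inference
#' (e.g. an age-adjusted check of whether NP-T1rho relates to BMI).
#'
#' @param table `data.frame` subset of interest.
#' @param outcome,exposure column names.
#' @param adjusters character vector of adjustment column names.
#' @return list of class `adjusted_association`: `estimate`, `se`, `ci_lo`,
#'   `ci_hi`, `p`, `n`, `model`.
#' @export
adjusted_association <- function(table, outcome, exposure,
                                 adjusters = character()) {
  cols <- c(outcome, exposure, adjusters)
  miss <- setdiff(cols, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dat <- table[stats::complete.cases(table[, cols, drop = FALSE]),
               cols, drop = FALSE]
  if (nrow(dat) < 10L)
    stop("refusing to fit: only ", nrow(dat), " complete cases (< 10)")
  fml <- as.formula(paste(outcome, "~",
                          paste(c(exposure, adjusters), collapse = " + ")))
  model <- lm(fml, data = dat)
  b <- coef(model)[exposure]
  se <- sqrt(diag(vcov(model)))[exposure]
  z <- b / se
  structure(list(estimate = unname(b), se = unname(se),
                 ci_lo = unname(b - qnorm(0.975) * se),
                 ci_hi = unname(b + qnorm(0.975) * se),
                 p = unname(2 * stats::pt(-abs(z), df = model$df.residual)),
                 n = nrow(dat), model = model),
            class = "adjusted_association")
}
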