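#' Run the image pipeline over a phantom (or any series + segmentation)
#'
#' Composes map fitting, inertia-tensor standardization, NP extraction and
#' biomarker aggregation for every disc level present in the segmentation,
#' for one or two modalities.
#'
#' @param series named list of [spin_lock_series()] objects (e.g.
#'   `list(T1rho = ..., T2 = ...)`).
#' @param seg a [disc_segmentation()].
#' @param np_fraction central AP fraction defining the NP.
#' @param min_voxels minimum valid NP voxels for a usable mean.
#' @param config a [relax_config()] shared by all modalities.
#' @return list with `discs` (per level x modality biomarker rows, including
#'   the geometry's rotation angle), `maps`, `np_regions`, `geometry`.
#' @export
image_pipeline <- function(series, seg, np_fraction = 0.40, min_voxels = 10L,
                           config = relax_config()) {
  stopifnot(is.list(series), inherits(seg, "disc_segmentation"))
  present <- sort(unique(as.vector(seg$labels)))
  present <- present[present > 0]
  maps <- lapply(series, function(s) fit_map(s, seg$labels > 0, config))
  geom <- list(); np_regions <- list(); rows <- list()
  for (code in present) {
    lvl <- disc_levels()[code]
    std <- standardize_disc(seg, code)
    np <- extract_np(std, np_fraction)
    geom[[lvl]] <- std; np_regions[[lvl]] <- np
    for (mod in names(maps)) {
      bm <- disc_biomarkers(maps[[mod]], np, std, min_voxels)
      bm$modality <- mod
      bm$angle_deg <- std$angle_deg
      rows[[paste(lvl, mod)]] <- bm
    }
  }
  discs <- do.call(rbind, rows)
  rownames(discs) <- NULL
  list(discs = discs, maps = maps, np_regions = np_regions, geometry = geom)
}

#' Cohort statistical analysis report
#'
#' Runs the full statistical battery on a disc table: the full-interaction
#' mixed model with marginal effects, level-wise models with per-group
#' slopes and reference predictions (ages 30 and 50, sex-averaged),
#' per-group/level Pearson correlations with age, the group-comparison
#' suite, Pfirrmann voxel histograms and the voxel-wise T1rho-T2
#' correlation.
#'
#' @param cohort a [generate_cohort()] result, or a list with `subjects`,
#'   `discs` and optionally `voxels` data frames.
#' @param outcome outcome column for the regression models (the T2 pathway
#'   is `"np_t2_mean"`).
#' @return list of class `cohort_analysis`.
#' @export
analyze_cohort <- function(cohort, outcome = "np_t1rho_mean") {
  discs <- cohort$discs
  mixed <- fit_mixed_model(discs, outcome)
  levelwise <- lapply(disc_levels(), function(lv)
    fit_levelwise_model(discs, lv, outcome))
  names(levelwise) <- disc_levels()
  preds <- do.call(rbind, lapply(disc_levels(), function(lv) {
    nd <- expand.grid(age = c(30, 50), group = GROUPS,
                      stringsAsFactors = FALSE)
    cbind(level = lv, nd, predict(levelwise[[lv]], nd))
  }))
  out <- list(outcome = outcome,
              mixed = mixed,
              mixed_marginals = marginal_effects(mixed),
              levelwise = levelwise,
              levelwise_marginals = lapply(levelwise, marginal_effects),
              predictions = preds,
              pearson = pearson_by_group_level(discs, outcome),
              comparisons = if (!is.null(cohort$subjects))
                group_comparison_suite(cohort$subjects, discs))
  if (!is.null(cohort$voxels)) {
    out$histograms <- pfirrmann_voxel_histograms(
      data.frame(pfirrmann = cohort$voxels$pfirrmann,
                 t_ms = cohort$voxels$t1rho_ms))
    out$t1r_t2 <- voxelwise_t1r_t2_correlation(cohort$voxels$t1rho_ms,
                                               cohort$voxels$t2_ms)
  }
  class(out) <- "cohort_analysis"
  out
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis> outcome:", x$outcome, "\n\nMarginal effects (mixed model):\n")
  print(x$mixed_marginals, digits = 3)
  if (!is.null(x$t1r_t2))
    cat(sprintf("\nvoxel-wise T1rho-T2 R^2 = %.3f (n = %d)\n",
                x$t1r_t2$r2, x$t1r_t2$n))
  invisible(x)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the end-to-end pipeline
#'
#' Simulates (or loads) a phantom image set, fits relaxation maps, extracts
#' NP regions, aggregates biomarkers, simulates a cohort and runs the full
#' statistical analysis, writing every artifact (NIfTI maps, CSV tables,
#' JSON report with the config hash and seed) under `config$out_dir`.
#' Rerunning with the same seed and config reproduces the CSV outputs
#' byte-for-byte.
#'
#' @param config a [run_config()].
#' @param phantom optional pre-built [generate_phantom()] result; by default
#'   one is simulated from the config seed.  May also be a directory
#'   containing `t1rho`/`t2` series and a `seg` segmentation written by the
#'   package's writers.
#' @param cohort optional pre-built [generate_cohort()] result.
#' @return list with `phantom_discs`, `cohort`, `analysis`, `paths`,
#'   invisibly.
#' @export
run_pipeline <- function(config = run_config(), phantom = NULL,
                         cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(config = file.path(config$out_dir, "config.json"))
  config_hash <- write_config(config, paths$config)

  if (is.null(phantom)) {
    phantom <- pipeline_stage("synthetic_data",
      generate_phantom(phantom_spec(tsl_t1rho_ms = config$tsl_ms,
                                    seed = config$seed)))
  } else if (is.character(phantom)) {
    dir <- phantom
    phantom <- pipeline_stage("io", list(
      series_t1rho = read_spin_lock_series(file.path(dir, "t1rho")),
      series_t2 = read_spin_lock_series(file.path(dir, "t2")),
      segmentation = NULL, spec = NULL))
    phantom$segmentation <- pipeline_stage("disc_geometry",
      read_segmentation(file.path(dir, "seg")))
  }
  seg <- pipeline_stage("disc_geometry", {
    if (is.null(phantom$segmentation)) stop("segmentation missing")
    phantom$segmentation
  })
  noise_sigma <- if (!is.null(phantom$spec)) phantom$spec$sigma else
    config$noise_sigma
  rc <- relax_config(t_min = config$t_min, t_max = config$t_max,
                     noise_sigma = noise_sigma)
  img <- pipeline_stage("relaxometry_geometry_biomarkers",
    image_pipeline(list(T1rho = phantom$series_t1rho,
                        T2 = phantom$series_t2),
                   seg, config$np_fraction, config$min_voxels, rc))
  for (mod in names(img$maps))
    write_relaxation_map(img$maps[[mod]],
                         file.path(config$out_dir, paste0("map_", tolower(mod))))
  paths$phantom_discs <- file.path(config$out_dir, "phantom_discs.csv")
  utils::write.csv(img$discs, paths$phantom_discs, row.names = FALSE)

  if (is.null(cohort))
    cohort <- pipeline_stage("synthetic_data",
      generate_cohort(cohort_spec(seed = config$seed)))
  paths$subjects <- file.path(config$out_dir, "subjects.csv")
  paths$discs <- file.path(config$out_dir, "discs.csv")
  utils::write.csv(cohort$subjects, paths$subjects, row.names = FALSE)
  utils::write.csv(cohort$discs, paths$discs, row.names = FALSE)
  if (!is.null(cohort$voxels)) {
    paths$voxels <- file.path(config$out_dir, "voxels.csv")
    utils::write.csv(cohort$voxels, paths$voxels, row.names = FALSE)
  }

  analysis <- pipeline_stage("cohort_stats", analyze_cohort(cohort))
  paths$coefficients <- file.path(config$out_dir, "coefficients.csv")
  coefs <- rbind(cbind(model = "mixed", analysis$mixed$coefficients),
                 do.call(rbind, lapply(disc_levels(), function(lv)
                   cbind(model = paste0("levelwise_", lv),
                         analysis$levelwise[[lv]]$coefficients))))
  utils::write.csv(coefs, paths$coefficients, row.names = FALSE)
  paths$predictions <- file.path(config$out_dir, "predictions.csv")
  utils::write.csv(analysis$predictions, paths$predictions, row.names = FALSE)

  paths$report <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(list(
    package = "nprelax",
    version = as.character(utils::packageVersion("nprelax")),
    seed = config$seed, config_hash = config_hash,
    n_subjects = nrow(cohort$subjects), n_discs = nrow(cohort$discs),
    mixed_marginals = analysis$mixed_marginals,
    predictions = analysis$predictions,
    comparisons = analysis$comparisons),
    paths$report, auto_unbox = TRUE, digits = NA)

  invisible(list(phantom_discs = img$discs, cohort = cohort,
                 analysis = analysis, paths = paths))
}
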