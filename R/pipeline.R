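#' Default run configuration
#'
#' All pipeline tunables with their default values: missingness fraction
#' 0.5, soft power 10, deepSplit 4, minimum module size 10, merge cut
#' height 0.2, maxPOutliers 0.05, amyloid PET SUVR cut 1.55, tau PET SUVR
#' cut 1.24, CSF amyloid ratio cut 0.061, kME cut 0.6, minimum
#' observations 20, elastic-net alpha 0.7, loess span 0.75. The resolved
#' configuration is serialized into every run directory for provenance.
#'
#' @param ... overrides for any default.
#' @return named list.
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    matrix_path = NULL, metadata_path = NULL, simulate = TRUE,
    seed = 1L, out_dir = NULL,
    n_per_stage = rep(20L, 7), n_background = 300L, noise_sd = 0.5,
    missing_rate = 0.1, n_tmt_sets = 9L,
    max_missing_frac = 0.5, soft_power = 10L, auto_power = FALSE,
    deep_split = 4L, min_module_size = 10L, merge_cut_height = 0.2,
    max_p_outliers = 0.05,
    abeta_suvr_cut = 1.55, tau_suvr_cut = 1.24, abeta_ratio_cut = 0.061,
    kme_cut = 0.6, min_obs = 20L, elasticnet_alpha = 0.7,
    loess_span = 0.75, loess_degree = 2L,
    contrast = c("A+T+", "A-T-"), pool_min_n = 3L, cv_folds = 10L)
  modifyList(cfg, list(...))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full staging pipeline
#'
#' Executes every stage on one cohort: TMT normalization, missingness
#' filtering, PCA QC, signed network construction with module detection
#' and Eigenprotein/kME summaries, PET-based staging with sparse-stage
#' pooling, module-biomarker Spearman correlations, moderated differential
#' abundance for the configured AT-group contrast, loess stage
#' trajectories of control-z-scored Eigenproteins, an elastic-net staging
#' panel (early vs late Braak), demographics, and a provenance JSON with
#' the fully resolved configuration. Given the same configuration and
#' seed, two runs produce byte-identical result tables.
#'
#' @param config list from [defaultRunConfig()] (or a path to a JSON file
#'   of overrides).
#' @param outDir output directory (created if needed); overrides
#'   \code{config$out_dir}.
#' @return (invisibly) a list of the main in-memory results.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = NULL) {
  if (is.character(config))
    config <- do.call(defaultRunConfig, jsonlite::read_json(config,
                                                            simplifyVector = TRUE))
  outDir <- if (!is.null(outDir)) outDir else config$out_dir
  if (is.null(outDir)) stop("no output directory configured")
  if (!isTRUE(config$simulate)) {
    if (is.null(config$matrix_path))
      stop("config error: matrix_path required when simulate = FALSE")
    if (!file.exists(config$matrix_path))
      stop("config error: matrix_path does not exist: ", config$matrix_path)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  raw <- step("input", {
    if (isTRUE(config$simulate)) {
      sim <- simulateCohort(nPerStage = config$n_per_stage,
                            nBackground = config$n_background,
                            noiseSd = config$noise_sd,
                            missingRate = config$missing_rate,
                            nTmtSets = config$n_tmt_sets,
                            seed = config$seed)
      sim$proteome
    } else {
      md <- if (!is.null(config$metadata_path))
        readSampleMetadata(config$metadata_path) else NULL
      readAbundanceMatrix(config$matrix_path, scale = "raw_intensity",
                          sampleData = md)
    }
  })

  norm <- step("normalize", {
    x <- normalizeTMT(raw)
    x <- dropReferenceChannels(x)
    filterMissingness(x, config$max_missing_frac)
  })
  writeAbundanceMatrix(norm, file.path(outDir, "normalized_matrix.tsv"))

  qc <- step("qc", qcOutliers(norm))
  .write_tsv(data.frame(sample_id = rownames(qc$pc_coordinates),
                        pc1 = qc$pc_coordinates[, 1],
                        pc2 = qc$pc_coordinates[, 2],
                        outlier = qc$outlier_flags),
             file.path(outDir, "qc_report.tsv"))

  net <- step("network", buildNetwork(
    norm, power = if (isTRUE(config$auto_power)) NULL else config$soft_power,
    deepSplit = config$deep_split, minSize = config$min_module_size,
    mergeCutHeight = config$merge_cut_height,
    maxPOutliers = config$max_p_outliers))
  labels <- moduleLabels(net$model)
  .write_tsv(data.frame(protein = names(labels), module = unname(labels)),
             file.path(outDir, "module_labels.tsv"))
  eps <- eigenproteins(net$summary)
  .write_tsv(data.frame(sample_id = rownames(eps), eps, check.names = FALSE),
             file.path(outDir, "eigenproteins.tsv"))
  .write_tsv(data.frame(protein = rownames(kme(net$summary)),
                        kme(net$summary), check.names = FALSE),
             file.path(outDir, "kme.tsv"))

  meta <- sampleData(norm)
  stages <- step("stage", {
    st <- assignGroups(meta, basis = "pet",
                       abetaPetCut = config$abeta_suvr_cut,
                       tauPetCut = config$tau_suvr_cut,
                       abetaRatioCut = config$abeta_ratio_cut)
    pooled <- poolSparseStages(st$braak_stage, minN = config$pool_min_n)
    st$braak_stage_pooled <- pooled$stages
    st
  })
  .write_tsv(stages, file.path(outDir, "stage_assignments.tsv"))

  assoc <- step("associate", {
    biom <- meta[, grep("^csf_", colnames(meta)), drop = FALSE]
    spearmanBonferroni(net$summary, biom)
  })
  .write_tsv(assoc, file.path(outDir, "module_biomarker_correlations.tsv"))

  diff <- step("differential", fitModeratedLM(
    norm, group = stages$at_group, contrast = config$contrast,
    covariates = meta[, c("age", "sex")], minObs = config$min_obs))
  .write_tsv(volcanoTable(diff, labels),
             file.path(outDir, "differential_abundance.tsv"))

  traj <- step("trajectory", {
    pos <- stagePositions(ifelse(stages$braak_stage == "0", "CTRL",
                                 stages$braak_stage_pooled))
    ctrl <- meta$is_control
    fits <- lapply(colnames(eps), function(mcol)
      loessTrajectory(pos, zscoreToControls(eps[, mcol], ctrl),
                      span = config$loess_span,
                      degree = config$loess_degree, seriesName = mcol))
    grids <- lapply(fits, `[[`, "stage_grid")
    common <- Reduce(intersect, grids)
    fits <- lapply(fits, function(f) {
      keep <- f$stage_grid %in% common
      f$stage_grid <- f$stage_grid[keep]
      f$fitted <- f$fitted[keep]
      f$ci_low <- f$ci_low[keep]; f$ci_high <- f$ci_high[keep]
      f
    })
    summarizeTrajectories(fits)
  })
  .write_tsv(traj, file.path(outDir, "trajectories.tsv"))

  panel <- step("panel", {
    pos <- stagePositions(stages$braak_stage)
    use <- !is.na(pos)
    ylate <- as.integer(pos[use] >= 3)
    if (length(unique(ylate)) < 2) stop("late-stage contrast has one class")
    X <- t(abundance(norm))[use, , drop = FALSE]
    fitElasticNetPanel(X, ylate, alpha = config$elasticnet_alpha,
                       nFolds = config$cv_folds, seed = config$seed,
                       contrast = "Braak 0-II vs III-VI")
  })
  .write_tsv(panel$selected, file.path(outDir, "panel_coefficients.tsv"))
  .write_tsv(data.frame(lambda = panel$lambda_path,
                        cv_deviance = panel$cv_deviance,
                        cv_deviance_se = panel$cv_deviance_se),
             file.path(outDir, "panel_cv.tsv"))

  demo <- step("demographics", summarizeDemographics(
    meta, stages$at_group, variables = c("age", "sex", "diagnosis")))
  .write_tsv(demo, file.path(outDir, "demographics.tsv"))

  prov <- config
  prov$out_dir <- NULL   # keep run outputs location-independent
  prov$n_proteins_after_filter <- nrow(norm)
  prov$n_modules <- max(labels)
  prov$panel_cv_auc <- panel$cv_auc
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(proteome = norm, qc = qc, network = net, stages = stages,
                 correlations = assoc, differential = diff,
                 trajectories = traj, panel = panel, demographics = demo,
                 config = config))
}
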