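STAGE_LEVELS <- c("CTRL", "I", "II", "III", "IV", "V", "VI")

MODULE_NAMES <- c("core_markers", "endolysosomal", "immune_response",
                  "metabolic", "synapse_membrane")

#' Stage-trajectory archetypes for planted modules
#'
#' Returns the module-level mean trajectories (in Eigenprotein z-units)
#' across ordered disease stages CTRL, Braak I..VI used by the synthetic
#' cohort generator. The five named shapes are the archetypes seen in CSF
#' staging studies: a stepwise "core markers" rise that plateaus after
#' Braak V; an early endolysosomal peak that returns to near baseline; an
#' immune/immunoglobulin dip with an interior minimum; a near-linear
#' metabolic rise with a sharp Braak VI drop; and a "synapse & membrane"
#' profile that is flat through V and falls at VI. A sixth all-zero
#' \code{null_module} row is included for negative controls.
#'
#' @return 6 x 7 numeric matrix; rows are templates, columns stages
#'   CTRL..VI.
#' @export
trajectoryTemplates <- function() {
  t <- rbind(
    core_markers     = c(0.00,  0.20,  0.40,  0.80,  1.20,  1.60,  1.55),
    endolysosomal    = c(0.00,  1.10,  1.30,  0.80,  0.45,  0.25,  0.10),
    immune_response  = c(0.00, -0.50, -1.00, -1.30, -1.05, -0.60, -0.05),
    metabolic        = c(0.00,  0.35,  0.70,  1.05,  1.40,  1.75,  0.80),
    synapse_membrane = c(0.00,  0.05, -0.05,  0.05,  0.00, -0.10, -1.60),
    null_module      = rep(0, 7))
  colnames(t) <- STAGE_LEVELS
  t
}

# monotone 0..1 severity curves used for fluid biomarkers
.tau_severity <- c(0, 0.15, 0.3, 0.55, 0.75, 1.0, 1.0)   # plateau at VI
.abeta_decline <- c(0, 0.6, 0.85, 0.95, 1, 1, 1)          # early decline

.draw_clinical <- function(stage_num, rng_ok = TRUE) {
  # diagnosis mix per latent stage
  probs <- list(
    `0` = c(CU = 1),
    `1` = c(CU = 0.4, SCI = 0.3, MCI = 0.3),
    `2` = c(CU = 0.25, SCI = 0.3, MCI = 0.45),
    `3` = c(SCI = 0.1, MCI = 0.6, AD = 0.3),
    `4` = c(SCI = 0.05, MCI = 0.5, AD = 0.45),
    `5` = c(MCI = 0.25, AD = 0.75),
    `6` = c(MCI = 0.1, AD = 0.9))[[as.character(stage_num)]]
  sample(names(probs), 1, prob = probs)
}

.draw_suvr <- function(positive, cut, pos_shift = 0.4, neg_shift = 0.25) {
  if (positive) cut + 0.02 + abs(rnorm(1, pos_shift - 0.02, pos_shift / 2))
  else max(0.5, cut - 0.02 - abs(rnorm(1, neg_shift - 0.02, neg_shift / 2)))
}

.draw_tau_regions <- function(stage_num, cut = 1.24, p_concordant = 0.9) {
  pattern <- c(rep(TRUE, stage_num), rep(FALSE, 6 - stage_num))
  if (runif(1) > p_concordant) {
    flip <- sample.int(6, 1)
    pattern[flip] <- !pattern[flip]
  }
  vapply(pattern, .draw_suvr, numeric(1), cut = cut,
         pos_shift = 0.35, neg_shift = 0.22)
}

.draw_csf <- function(stage_num) {
  tau_mult <- 2^(1.2 * .tau_severity[stage_num + 1])
  ln <- function(base, mult, cv) base * mult * exp(rnorm(1, 0, cv))
  ratio <- max(0.02, min(0.12,
    0.09 - 0.035 * .abeta_decline[stage_num + 1] + rnorm(1, 0, 0.006)))
  ab40 <- ln(9000, 1, 0.15)
  c(csf_abeta40 = ab40, csf_abeta42 = ratio * ab40, csf_abeta_ratio = ratio,
    csf_ttau = ln(250, tau_mult, 0.15),
    csf_ptau181 = ln(35, tau_mult^1.1, 0.15),
    csf_ptau199 = ln(12, tau_mult^0.9, 0.18),
    csf_ptau202 = ln(8, tau_mult^0.6, 0.18),
    csf_ptau205 = ln(5, tau_mult^1.2, 0.18),
    csf_ptau217 = ln(10, tau_mult^1.4, 0.18),
    csf_ptau231 = ln(20, tau_mult^1.1, 0.18),
    csf_ptau396 = ln(6, tau_mult^0.8, 0.18))
}

.simulate_metadata <- function(stage_num, sample_ids, abeta_cut = 1.55,
                               tau_cut = 1.24) {
  n <- length(stage_num)
  p_apos <- c(0.15, 0.6, 0.75, 0.85, 0.9, 0.95, 0.98)[stage_num + 1]
  rows <- lapply(seq_len(n), function(i) {
    s <- stage_num[i]
    csf <- .draw_csf(s)
    tau <- .draw_tau_regions(s, cut = tau_cut)
    data.frame(
      sample_id = sample_ids[i],
      stage = STAGE_LEVELS[s + 1],
      age = round(min(85, max(55, rnorm(1, 62 + 2 * s, 5)))),
      sex = sample(c("F", "M"), 1),
      diagnosis = .draw_clinical(s),
      is_control = s == 0,
      abeta_pet_suvr = .draw_suvr(runif(1) < p_apos[i], abeta_cut),
      setNames(as.data.frame(t(tau)), TAU_REGION_COLS),
      as.data.frame(t(csf)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a TMT CSF discovery cohort with planted co-expression modules
#'
#' Generates raw reporter intensities for module proteins following the
#' latent factor model \code{log2(value) = baseline + loading x latent +
#' TMT-set offset + noise}, where each module's latent factor per sample is
#' its stage-trajectory template value plus per-sample jitter. Background
#' proteins carry no latent signal. Missingness is abundance dependent
#' (lower-abundance proteins are more often missing, emulating
#' left-censoring), and each TMT set carries a pooled-CSF reference channel
#' without clinical metadata.
#'
#' @param nPerStage integer vector of length 7: samples per stage CTRL..VI.
#' @param moduleSizes named integer vector of planted module sizes (names
#'   from the trajectory templates).
#' @param nBackground number of unstructured background proteins.
#' @param noiseSd residual SD of log2 abundances.
#' @param missingRate target overall missingness fraction.
#' @param nTmtSets number of TMT sets.
#' @param latentJitterSd per-sample SD of the latent factor around its stage
#'   template value.
#' @param batchSd SD of per-set, per-protein log2 offsets.
#' @param referenceChannels add one pooled reference channel per set.
#' @param seed integer RNG seed; all output is reproducible from it.
#' @return list with elements \code{proteome} (a raw-intensity
#'   [CsfProteome] with clinical colData), and \code{truth} (planted module
#'   map, loadings, latent factors, batch offsets, stages, templates, seed).
#' @export
simulateCohort <- function(nPerStage = rep(20L, 7),
                           moduleSizes = c(core_markers = 60, endolysosomal = 30,
                                           immune_response = 20, metabolic = 40,
                                           synapse_membrane = 50),
                           nBackground = 300, noiseSd = 0.5,
                           missingRate = 0.1, nTmtSets = 9,
                           latentJitterSd = 0.4, batchSd = 0.15,
                           referenceChannels = TRUE, seed = 7) {
  stopifnot(length(nPerStage) == 7, all(moduleSizes >= 3))
  set.seed(seed)
  templates <- trajectoryTemplates()
  if (!all(names(moduleSizes) %in% rownames(templates)))
    stop("unknown module names: ",
         paste(setdiff(names(moduleSizes), rownames(templates)), collapse = ", "))

  n_mod_prot <- sum(moduleSizes)
  n_prot <- n_mod_prot + nBackground
  protein_ids <- sprintf("P%04d", seq_len(n_prot))
  module_of <- setNames(rep(NA_character_, n_prot), protein_ids)
  module_of[seq_len(n_mod_prot)] <- rep(names(moduleSizes), moduleSizes)

  stage_num <- rep(0:6, nPerStage)
  n_samp <- length(stage_num)
  sample_ids <- sprintf("S%03d", seq_len(n_samp))
  meta <- .simulate_metadata(stage_num, sample_ids)

  # latent factor per module per sample: stage template + jitter
  latent <- sapply(names(moduleSizes), function(m)
    templates[m, stage_num + 1] + rnorm(n_samp, 0, latentJitterSd))
  rownames(latent) <- sample_ids

  loadings <- setNames(runif(n_prot, 0.4, 0.95), protein_ids)
  baseline <- setNames(rnorm(n_prot, 14, 1.5), protein_ids)

  tmt_set <- paste0("set", rep_len(seq_len(nTmtSets), n_samp)[sample.int(n_samp)])
  batch <- matrix(rnorm(nTmtSets * n_prot, 0, batchSd), nTmtSets, n_prot,
                  dimnames = list(paste0("set", seq_len(nTmtSets)), protein_ids))

  signal <- matrix(0, n_prot, n_samp, dimnames = list(protein_ids, sample_ids))
  for (m in names(moduleSizes)) {
    idx <- which(module_of == m)
    signal[idx, ] <- loadings[idx] %o% latent[, m]
  }
  log2val <- baseline + signal + t(batch[tmt_set, , drop = FALSE]) +
    matrix(rnorm(n_prot * n_samp, 0, noiseSd), n_prot, n_samp)

  # abundance-dependent missingness: probability decreases with baseline rank
  p_miss <- pmin(0.9, pmax(0, 2 * missingRate *
    (1 - (rank(baseline) - 0.5) / n_prot)))
  miss <- matrix(runif(n_prot * n_samp), n_prot, n_samp) < p_miss
  log2val[miss] <- NA

  values <- 2^log2val
  sdata <- meta
  sdata$tmt_set <- tmt_set
  sdata$is_reference <- FALSE

  if (referenceChannels) {
    ref_ids <- paste0("ref_", rownames(batch))
    ref <- 2^(baseline + t(batch) +
              matrix(rnorm(n_prot * nTmtSets, 0, noiseSd / 2), n_prot))
    colnames(ref) <- ref_ids
    values <- cbind(values, ref)
    ref_meta <- sdata[rep(NA_integer_, nTmtSets), ]
    ref_meta$sample_id <- ref_ids
    ref_meta$tmt_set <- rownames(batch)
    ref_meta$is_reference <- TRUE
    ref_meta$is_control <- FALSE
    sdata <- rbind(sdata, ref_meta)
  }
  rownames(sdata) <- sdata$sample_id

  proteome <- CsfProteome(values, sampleData = sdata, scale = "raw_intensity")
  truth <- list(module_of_protein = module_of, loadings = loadings,
                baseline = baseline, latent = latent, noise_sd = noiseSd,
                batch_effects = batch, stage_num = setNames(stage_num, sample_ids),
                templates = templates, module_sizes = moduleSizes, seed = seed)
  list(proteome = proteome, truth = truth)
}

#' Simulate fluid- and biopsy-staged validation cohorts
#'
#' Builds two independent cohorts from the discovery cohort's planted truth
#' (same modules, loadings and trajectory templates), already on the
#' log2-ratio scale. The fluid cohort is staged by CSF amyloid ratio
#' (positive strictly below 0.061) plus clinical diagnosis; the biopsy
#' cohort by a semiquantitative amyloid plaque score (0-3) and a
#' neurofibrillary-tangle flag, both consistent with the sample's latent
#' stage. Only \code{overlapFrac} of discovery proteins are quantified,
#' emulating cross-platform dropout.
#'
#' @param truth the \code{truth} element returned by [simulateCohort()].
#' @param overlapFrac fraction of discovery proteins present in the
#'   validation cohorts (0 < overlapFrac <= 1).
#' @param nPerStageFluid,nPerStageBiopsy integer vectors of length 7.
#' @param noiseSd residual SD; defaults to the discovery value.
#' @param seed integer RNG seed.
#' @return list with elements \code{fluid} and \code{biopsy}, each a list of
#'   \code{proteome} ([CsfProteome], log2_ratio) and \code{latent}.
#' @export
simulateValidationCohorts <- function(truth, overlapFrac = 0.7,
                                      nPerStageFluid = rep(20L, 7),
                                      nPerStageBiopsy = rep(10L, 7),
                                      noiseSd = truth$noise_sd, seed = 11) {
  stopifnot(overlapFrac > 0, overlapFrac <= 1)
  set.seed(seed)
  all_prot <- names(truth$module_of_protein)
  keep <- sort(sample(all_prot, ceiling(overlapFrac * length(all_prot))))

  one_cohort <- function(n_per_stage, prefix, basis) {
    stage_num <- rep(0:6, n_per_stage)
    n <- length(stage_num)
    ids <- sprintf("%s%03d", prefix, seq_len(n))
    templates <- truth$templates
    mods <- names(truth$module_sizes)
    latent <- sapply(mods, function(m)
      templates[m, stage_num + 1] + rnorm(n, 0, 0.4))
    rownames(latent) <- ids
    vals <- matrix(rnorm(length(keep) * n, 0, noiseSd), length(keep), n,
                   dimnames = list(keep, ids))
    for (m in mods) {
      idx <- which(truth$module_of_protein[keep] == m)
      if (length(idx))
        vals[idx, ] <- vals[idx, ] + truth$loadings[keep][idx] %o% latent[, m]
    }
    md <- data.frame(sample_id = ids, stage = STAGE_LEVELS[stage_num + 1],
                     age = round(pmin(85, pmax(55, rnorm(n, 62 + 2 * stage_num, 5)))),
                     sex = sample(c("F", "M"), n, replace = TRUE),
                     diagnosis = vapply(stage_num, .draw_clinical, character(1)),
                     is_control = stage_num == 0, stringsAsFactors = FALSE)
    if (basis == "csf") {
      apos <- runif(n) < c(0.1, 0.65, 0.8, 0.9, 0.92, 0.95, 0.98)[stage_num + 1]
      md$csf_abeta_ratio <- ifelse(apos, runif(n, 0.030, 0.060),
                                   runif(n, 0.062, 0.105))
      md$cohort <- "fluid_validation"
    } else {
      md$biopsy_abeta_score <- pmin(3, c(0, 1, 1, 2, 2, 3, 3)[stage_num + 1])
      md$biopsy_tangles <- stage_num >= 3
      md$cohort <- "biopsy_validation"
    }
    rownames(md) <- ids
    list(proteome = CsfProteome(vals, sampleData = md, scale = "log2_ratio"),
         latent = latent)
  }
  list(fluid = one_cohort(nPerStageFluid, "F", "csf"),
       biopsy = one_cohort(nPerStageBiopsy, "B", "biopsy"))
}
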