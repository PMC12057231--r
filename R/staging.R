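BRAAK_LEVELS <- c("0", "I", "II", "III", "IV", "V", "VI", "discordant",
                  "unknown")

#' Amyloid PET positivity
#'
#' Positive strictly above the SUVR cut (default 1.55); values equal to the
#' cut are negative (measured SUVRs essentially never tie the threshold, so
#' the strict convention is inconsequential in practice but documented).
#'
#' @param suvr amyloid PET SUVR (vectorized; NA allowed).
#' @param cut positivity threshold.
#' @return character vector in {"neg", "pos", "unknown"}.
#' @export
classifyAbetaPET <- function(suvr, cut = 1.55) {
  ifelse(is.na(suvr), "unknown", ifelse(suvr > cut, "pos", "neg"))
}

#' Tau PET positivity
#'
#' Positive for SUVR strictly greater than the cut (default 1.24).
#'
#' @inheritParams classifyAbetaPET
#' @export
classifyTauPET <- function(suvr, cut = 1.24) {
  ifelse(is.na(suvr), "unknown", ifelse(suvr > cut, "pos", "neg"))
}

#' CSF amyloid positivity
#'
#' Positive for an Abeta42/40 ratio strictly below the cut (default 0.061).
#'
#' @param ratio CSF Abeta42/40 ratio (vectorized; NA allowed).
#' @param cut positivity threshold.
#' @return character vector in {"neg", "pos", "unknown"}.
#' @export
classifyAbetaCSF <- function(ratio, cut = 0.061) {
  ifelse(is.na(ratio), "unknown", ifelse(ratio < cut, "pos", "neg"))
}

#' Hierarchical Braak stage from regional tau PET
#'
#' Each of the six Braak regions (I transentorhinal to VI neocortical) is
#' positive for SUVR strictly above the cut. The stage is the length of the
#' maximal all-positive prefix; a participant with any positive region
#' after the first negative one violates the hierarchical spreading order
#' and is classified "discordant". All regions negative gives stage "0";
#' any missing region gives "unknown".
#'
#' @param regionSuvrs numeric 6-vector (Braak I..VI order) or samples x 6
#'   matrix.
#' @param cut regional positivity threshold.
#' @return character vector of stages in
#'   {"0","I",...,"VI","discordant","unknown"}.
#' @export
assignBraakStage <- function(regionSuvrs, cut = 1.24) {
  if (is.null(dim(regionSuvrs))) regionSuvrs <- matrix(regionSuvrs, nrow = 1)
  stopifnot(ncol(regionSuvrs) == 6)
  apply(regionSuvrs, 1L, function(v) {
    if (anyNA(v)) return("unknown")
    pos <- v > cut
    prefix <- match(FALSE, pos, nomatch = 7L) - 1L
    if (any(pos[seq_len(6 - prefix) + prefix])) return("discordant")
    c("0", "I", "II", "III", "IV", "V", "VI")[prefix + 1L]
  })
}

#' Assign AT group, Braak stage and clinical stratum
#'
#' Derives per-sample amyloid and tau status on the cohort's staging basis
#' (PET SUVRs, CSF amyloid ratio, or cortical biopsy), the hierarchical
#' Braak stage where regional tau PET is available, the AT group, and the
#' clinical stratum diagnosis x amyloid status (CU and SCI pooled as
#' "CU/SCI"). On the PET basis overall tau status is positive iff the Braak
#' stage is at least I; on the biopsy basis amyloid is positive for plaque
#' score >= \code{biopsyAbetaMin} and tau for a tangle flag.
#'
#' @param meta metadata data.frame (see [readSampleMetadata()] /
#'   [simulateCohort()]).
#' @param basis staging basis: "pet", "csf" or "biopsy".
#' @param abetaPetCut,tauPetCut,abetaRatioCut positivity thresholds.
#' @param biopsyAbetaMin minimum plaque score for biopsy amyloid
#'   positivity.
#' @return data.frame with sample_id, abeta_status, tau_status,
#'   braak_stage, at_group, clinical_stratum, stage_basis.
#' @export
assignGroups <- function(meta, basis = c("pet", "csf", "biopsy"),
                         abetaPetCut = 1.55, tauPetCut = 1.24,
                         abetaRatioCut = 0.061, biopsyAbetaMin = 1) {
  basis <- match.arg(basis)
  n <- nrow(meta)
  braak <- rep("unknown", n)
  if (all(TAU_REGION_COLS %in% colnames(meta))) {
    braak <- assignBraakStage(as.matrix(meta[, TAU_REGION_COLS]),
                              cut = tauPetCut)
  }
  if (basis == "pet") {
    abeta <- classifyAbetaPET(meta$abeta_pet_suvr, abetaPetCut)
    tau <- ifelse(braak == "unknown", "unknown",
                  ifelse(braak %in% c("0"), "neg", "pos"))
  } else if (basis == "csf") {
    abeta <- classifyAbetaCSF(meta$csf_abeta_ratio, abetaRatioCut)
    tau <- rep("unknown", n)
  } else {
    score <- meta$biopsy_abeta_score
    abeta <- ifelse(is.na(score), "unknown",
                    ifelse(score >= biopsyAbetaMin, "pos", "neg"))
    tau <- ifelse(is.na(meta$biopsy_tangles), "unknown",
                  ifelse(meta$biopsy_tangles, "pos", "neg"))
  }
  at <- ifelse(abeta == "unknown" | tau == "unknown", "unknown",
               paste0("A", ifelse(abeta == "pos", "+", "-"),
                      "T", ifelse(tau == "pos", "+", "-")))
  dx <- if (!is.null(meta$diagnosis)) as.character(meta$diagnosis)
        else rep(NA_character_, n)
  dx_pooled <- ifelse(dx %in% c("CU", "SCI"), "CU/SCI", dx)
  stratum <- ifelse(is.na(dx_pooled) | abeta == "unknown", "unknown",
                    paste0(dx_pooled, "_A",
                           ifelse(abeta == "pos", "+", "-")))
  data.frame(sample_id = meta$sample_id, abeta_status = abeta,
             tau_status = tau, braak_stage = braak, at_group = at,
             clinical_stratum = stratum, stage_basis = basis,
             stringsAsFactors = FALSE)
}

#' Pool sparse adjacent Braak stages
#'
#' Merges any ordinal Braak level observed in fewer than \code{minN}
#' samples with the next level (the last level merges backwards), e.g. a
#' two-person Braak III pools with IV into "III-IV". "0", "discordant" and
#' "unknown" are never pooled. The full original-to-pooled mapping is
#' returned so every original level maps to exactly one pooled level.
#'
#' @param stages character vector of Braak stages.
#' @param minN minimum per-level count.
#' @return list with \code{stages} (pooled labels per sample) and
#'   \code{map} (named character: original level -> pooled level).
#' @export
poolSparseStages <- function(stages, minN = 3) {
  ord <- c("I", "II", "III", "IV", "V", "VI")
  present <- ord[ord %in% stages]
  counts <- table(factor(stages, levels = ord))
  groups <- as.list(present)
  repeat {
    sizes <- vapply(groups, function(g) sum(counts[g]), numeric(1))
    small <- which(sizes < minN)
    if (!length(small) || length(groups) == 1) break
    i <- small[1L]
    j <- if (i < length(groups)) i + 1L else i - 1L
    groups[[min(i, j)]] <- c(groups[[min(i, j)]], groups[[max(i, j)]])
    groups[[max(i, j)]] <- NULL
  }
  map <- setNames(c("0", ord, "discordant", "unknown"),
                  c("0", ord, "discordant", "unknown"))
  for (g in groups) {
    lab <- if (length(g) == 1) g else paste(g[1L], g[length(g)], sep = "-")
    map[g] <- lab
  }
  list(stages = unname(map[stages]), map = map)
}
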