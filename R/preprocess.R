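#' TMT median-ratio normalization
#'
#' Reporter-ratio normalization of raw intensities on the log2 scale: (1)
#' within each TMT set, each protein's intensities are divided by that
#' protein's set-wise median; (2) each resulting sample column is divided
#' by its own median (the total-protein-amount correction); the two median
#' steps are then repeated until both families of medians are exactly 1
#' (the first iteration is the classic two-step rule; subsequent
#' iterations apply numerically tiny corrections, needed because the
#' sample-median division perturbs the protein medians and, for
#' even-count medians, interpolation is done geometrically, i.e.
#' arithmetically in log space). At the fixed point every sample's median
#' log2 ratio is 0 and every protein's set-wise median log2 ratio is 0,
#' so the operation is exactly idempotent on its own output. Medians are
#' taken over observed values only; by default pooled reference channels
#' are excluded from the protein set-wise median statistic (they are still
#' normalized themselves). The result is invariant to global rescaling of
#' the raw intensities.
#'
#' @param raw a raw-intensity [CsfProteome].
#' @param excludeReferenceFromMedians logical; drop \code{is_reference}
#'   channels when computing protein set-wise medians.
#' @param tol convergence tolerance on the largest absolute log2 median.
#' @param maxIter iteration cap.
#' @return a log2-ratio [CsfProteome] with the same dimensions.
#' @export
normalizeTMT <- function(raw, excludeReferenceFromMedians = TRUE,
                         tol = 1e-13, maxIter = 100) {
  if (abundanceScale(raw) != "raw_intensity")
    stop("normalizeTMT expects a raw_intensity proteome")
  a <- abundance(raw)
  if (any(a <= 0, na.rm = TRUE)) stop("non-positive raw intensity")
  sd_ <- sampleData(raw)
  sets <- sd_$tmt_set
  is_ref <- isTRUE(excludeReferenceFromMedians) & sd_$is_reference
  out <- log2(a)
  set_cols <- split(seq_along(sets), sets)
  for (it in seq_len(maxIter)) {
    shift <- 0
    for (cols in set_cols) {
      med_cols <- cols[!is_ref[cols]]
      if (!length(med_cols)) med_cols <- cols
      pm <- apply(out[, med_cols, drop = FALSE], 1L, median, na.rm = TRUE)
      pm[!is.finite(pm)] <- 0      # protein all-missing in set: untouched
      out[, cols] <- out[, cols, drop = FALSE] - pm
      shift <- max(shift, max(abs(pm)))
    }
    sm <- apply(out, 2L, median, na.rm = TRUE)
    sm[!is.finite(sm)] <- 0
    out <- sweep(out, 2L, sm, "-")
    shift <- max(shift, max(abs(sm)))
    if (it > 1 && shift < tol) break
  }
  CsfProteome(out, sampleData = sd_, scale = "log2_ratio")
}

#' Filter proteins by missingness
#'
#' Keeps proteins whose missing fraction is at most \code{maxMissingFrac};
#' proteins missing in strictly more than that fraction of samples are
#' excluded (the "more than 50\%" rule at the default). Row order is
#' preserved. Reference channels count like any other sample unless removed
#' beforehand.
#'
#' @param x a log2-ratio [CsfProteome].
#' @param maxMissingFrac maximum tolerated missing fraction per protein.
#' @return filtered [CsfProteome].
#' @export
filterMissingness <- function(x, maxMissingFrac = 0.5) {
  frac <- rowMeans(is.na(abundance(x)))
  keep <- frac <= maxMissingFrac
  if (!any(keep)) stop("all proteins exceed the missingness threshold")
  x[keep, ]
}

#' Drop pooled reference channels
#'
#' @param x a [CsfProteome].
#' @return the proteome restricted to non-reference samples.
#' @export
dropReferenceChannels <- function(x) {
  x[, !sampleData(x)$is_reference]
}

#' PCA-based sample QC
#'
#' Runs PCA on the median-imputed, row-centered abundance matrix and flags
#' samples whose PC1 or PC2 coordinate lies more than \code{sdMult} robust
#' standard deviations (1.4826 x MAD) from the coordinate median. Flags are
#' advisory; nothing is removed. The PC sign is fixed by forcing the loading
#' with the largest absolute value positive, so flags are deterministic.
#'
#' @param x a log2-ratio [CsfProteome] with at least 3 samples.
#' @param sdMult robust-SD multiplier for flagging.
#' @return list with \code{pc_coordinates} (samples x 2),
#'   \code{outlier_flags} (named logical), \code{outlier_rule} (text) and
#'   \code{linkage_heights} (average-linkage merge heights on sample
#'   euclidean distances).
#' @export
qcOutliers <- function(x, sdMult = 4) {
  a <- abundance(x)
  if (ncol(a) < 3) stop("need at least 3 samples for QC")
  med <- apply(a, 1L, median, na.rm = TRUE)
  imp <- a
  for (i in seq_len(nrow(a))) imp[i, is.na(imp[i, ])] <- med[i]
  imp <- imp - rowMeans(imp)
  pc <- prcomp(t(imp), center = FALSE, scale. = FALSE, rank. = 2)
  scores <- pc$x[, 1:2, drop = FALSE]
  for (j in seq_len(ncol(scores))) {
    ld <- pc$rotation[, j]
    if (ld[which.max(abs(ld))] < 0) {
      scores[, j] <- -scores[, j]
    }
  }
  flag <- rep(FALSE, ncol(a))
  for (j in 1:2) {
    ctr <- median(scores[, j])
    sc <- mad(scores[, j])
    if (sc > 0) flag <- flag | abs(scores[, j] - ctr) > sdMult * sc
  }
  hc <- hclust(stats::dist(t(imp)), method = "average")
  list(pc_coordinates = scores,
       outlier_flags = setNames(flag, colnames(a)),
       outlier_rule = sprintf(
         "|PC coordinate - median| > %g * 1.4826*MAD on PC1 or PC2", sdMult),
       linkage_heights = hc$height)
}
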