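#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats median mad cor sd quantile var lm lm.fit pt qt ptukey
#'   p.adjust prcomp hclust cutree as.dist loess predict model.matrix
#'   complete.cases rnorm runif rbinom qnorm pnorm setNames na.omit
#'   kruskal.test chisq.test binomial coef glm aggregate vcov cutree
#' @importFrom utils read.delim write.table head modifyList
NULL

#' CsfProteome: a proteins-by-samples abundance container
#'
#' Extends \linkS4class{SummarizedExperiment}. Rows are proteins, columns are
#' samples. The single assay \code{"abundance"} holds either raw reporter
#' intensities (strictly positive where observed) or log2 relative
#' abundances, as recorded in the \code{abundanceScale} slot. Column data
#' carries the TMT set label (\code{tmt_set}), the pooled-reference flag
#' (\code{is_reference}) and any clinical metadata (age, sex, diagnosis,
#' PET SUVRs, CSF biomarkers, biopsy grades).
#'
#' @slot abundanceScale character, one of \code{"raw_intensity"} or
#'   \code{"log2_ratio"}.
#' @export
setClass("CsfProteome",
  contains = "SummarizedExperiment",
  slots = c(abundanceScale = "character")
)

setValidity("CsfProteome", function(object) {
  msg <- character(0)
  if (!object@abundanceScale %in% c("raw_intensity", "log2_ratio"))
    msg <- c(msg, "abundanceScale must be 'raw_intensity' or 'log2_ratio'")
  rn <- rownames(object); cn <- colnames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "protein ids (rownames) must be present and unique")
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  a <- SummarizedExperiment::assay(object)
  if (any(is.infinite(a)))
    msg <- c(msg, "abundance values must not be infinite")
  if (identical(object@abundanceScale, "raw_intensity") &&
      any(a <= 0, na.rm = TRUE))
    msg <- c(msg, "raw intensities must be strictly positive where observed")
  if (length(msg)) msg else TRUE
})

#' Construct a CsfProteome
#'
#' @param values numeric matrix, proteins as rows, samples as columns, with
#'   unique dimnames. \code{NA} marks missing quantification.
#' @param sampleData a data.frame (or DataFrame) of per-sample metadata,
#'   one row per sample in column order. Optional columns \code{tmt_set}
#'   and \code{is_reference} default to a single set and all-FALSE.
#' @param scale \code{"raw_intensity"} or \code{"log2_ratio"}.
#' @return a \linkS4class{CsfProteome}.
#' @export
CsfProteome <- function(values, sampleData = NULL,
                        scale = c("log2_ratio", "raw_intensity")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(sampleData)) {
    sampleData <- S4Vectors::DataFrame(row.names = colnames(values))
  } else {
    sampleData <- S4Vectors::DataFrame(sampleData,
                                       row.names = colnames(values))
  }
  if (is.null(sampleData$tmt_set))
    sampleData$tmt_set <- rep("set1", ncol(values))
  if (is.null(sampleData$is_reference))
    sampleData$is_reference <- rep(FALSE, ncol(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values), colData = sampleData)
  new("CsfProteome", se, abundanceScale = scale)
}

#' @describeIn CsfProteome abundance matrix accessor
#' @param x a CsfProteome
#' @export
abundance <- function(x) SummarizedExperiment::assay(x, "abundance")

#' @describeIn CsfProteome measurement scale accessor
#' @export
abundanceScale <- function(x) x@abundanceScale

#' @describeIn CsfProteome per-sample metadata as a data.frame
#' @export
sampleData <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

setMethod("show", "CsfProteome", function(object) {
  a <- SummarizedExperiment::assay(object)
  cat("CsfProteome:", nrow(a), "proteins x", ncol(a), "samples\n")
  cat("  scale:", object@abundanceScale,
      "| missing:", sprintf("%.1f%%", 100 * mean(is.na(a))),
      "| TMT sets:", length(unique(object$tmt_set)), "\n")
})

#' NetworkModel: a signed weighted co-expression network
#'
#' Holds the robust correlation matrix, the soft-threshold power, the signed
#' adjacency, the topological overlap matrix (TOM), the average-linkage
#' dendrogram on 1 - TOM, and the module labels (0 = unassigned/"gray").
#'
#' @slot correlation proteins x proteins biweight midcorrelation matrix.
#' @slot power integer soft-threshold exponent.
#' @slot adjacency signed adjacency, entries in [0, 1].
#' @slot tom topological overlap matrix, entries in [0, 1].
#' @slot dendrogram an \code{hclust} tree over proteins.
#' @slot labels named integer vector of module labels per protein.
#' @export
setClass("NetworkModel", slots = c(
  correlation = "matrix", power = "integer", adjacency = "matrix",
  tom = "matrix", dendrogram = "ANY", labels = "integer"
))

setValidity("NetworkModel", function(object) {
  msg <- character(0)
  for (nm in c("correlation", "adjacency", "tom")) {
    m <- slot(object, nm)
    if (nrow(m) != ncol(m) || !isSymmetric(unname(m), tol = 1e-8))
      msg <- c(msg, paste(nm, "must be square and symmetric"))
  }
  if (any(object@labels < 0)) msg <- c(msg, "labels must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NetworkModel", function(object) {
  k <- max(object@labels)
  cat("NetworkModel:", nrow(object@correlation), "proteins, power",
      object@power, "\n  modules:", k, "| unassigned:",
      sum(object@labels == 0), "\n")
})

#' @describeIn NetworkModel module labels accessor
#' @param x a NetworkModel
#' @export
moduleLabels <- function(x) x@labels

#' ModuleSummary: Eigenproteins and module membership (kME)
#'
#' @slot eigenproteins samples x modules matrix of first-principal-component
#'   scores (unit-norm columns), signed so each correlates positively with
#'   its module's mean standardized abundance.
#' @slot varianceExplained per-module fraction of module variance captured.
#' @slot kme proteins x modules Pearson correlations with Eigenproteins.
#' @slot moduleSizes named integer member counts.
#' @export
setClass("ModuleSummary", slots = c(
  eigenproteins = "matrix", varianceExplained = "numeric",
  kme = "matrix", moduleSizes = "integer"
))

setMethod("show", "ModuleSummary", function(object) {
  cat("ModuleSummary:", ncol(object@eigenproteins), "modules over",
      nrow(object@eigenproteins), "samples\n  variance explained:",
      paste(sprintf("%.2f", object@varianceExplained), collapse = " "), "\n")
})

#' @describeIn ModuleSummary Eigenprotein score matrix accessor
#' @param x a ModuleSummary
#' @export
eigenproteins <- function(x) x@eigenproteins

#' @describeIn ModuleSummary kME matrix accessor
#' @export
kme <- function(x) x@kme

#' SoftThresholdDiagnostics: scale-free fit across candidate powers
#'
#' @slot table data.frame with columns \code{power}, \code{sft_r2} (signed
#'   scale-free fit index), \code{mean_k}, \code{median_k}.
#' @slot chosenPower integer selected soft-threshold power.
#' @export
setClass("SoftThresholdDiagnostics", slots = c(
  table = "data.frame", chosenPower = "integer"
))

setMethod("show", "SoftThresholdDiagnostics", function(object) {
  cat("SoftThresholdDiagnostics: chosen power", object@chosenPower, "\n")
  print(head(object@table, 12))
})
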