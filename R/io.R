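MISSING_TOKENS <- c("", "NA", "NaN", "nan")

#' Read a protein abundance matrix from TSV/CSV
#'
#' Expects the first column to hold protein identifiers and the header row to
#' hold sample identifiers. The tokens \code{""}, \code{"NA"}, \code{"NaN"}
#' and \code{"nan"} become missing entries.
#'
#' @param path file path.
#' @param sep field separator; \code{"\t"} (default) or \code{","}.
#' @param scale measurement scale of the stored values.
#' @param sampleData optional per-sample metadata data.frame keyed by
#'   \code{sample_id} (see [readSampleMetadata()]).
#' @return a [CsfProteome].
#' @export
readAbundanceMatrix <- function(path, sep = "\t",
                                scale = c("log2_ratio", "raw_intensity"),
                                sampleData = NULL) {
  scale <- match.arg(scale)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   na.strings = MISSING_TOKENS, colClasses = "character")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicated protein ids: ", paste(dup, collapse = ", "))
  }
  sid <- colnames(df)[-1L]
  if (anyDuplicated(sid)) {
    stop("duplicated sample ids: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at protein '%s', sample '%s': '%s'",
                 ids[bad[1, 1]], sid[bad[1, 2]], vals[bad[1, , drop = FALSE]]))
  }
  dimnames(num) <- list(ids, sid)
  md <- NULL
  if (!is.null(sampleData)) {
    missing_meta <- setdiff(sid, sampleData$sample_id)
    if (length(missing_meta))
      warning("samples in matrix without metadata: ",
              paste(missing_meta, collapse = ", "))
    md <- sampleData[match(sid, sampleData$sample_id), , drop = FALSE]
  }
  CsfProteome(num, sampleData = md, scale = scale)
}

#' Write a CsfProteome abundance matrix to TSV
#'
#' Missing entries are written as \code{NA}; the round trip through
#' [readAbundanceMatrix()] reproduces finite values and the missingness mask
#' exactly (values are serialized at full double precision).
#'
#' @param x a [CsfProteome].
#' @param path output file path.
#' @export
writeAbundanceMatrix <- function(x, path) {
  a <- abundance(x)
  df <- data.frame(protein_id = rownames(a),
                   format(a, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

SEX_MAP <- c(f = "F", female = "F", "F" = "F", m = "M", male = "M", "M" = "M")

TAU_REGION_COLS <- paste0("tau_suvr_braak", 1:6)

#' Read per-sample cohort metadata
#'
#' Reads a wide table keyed by \code{sample_id}. Recognized columns are
#' typed and normalized (sex variants "f"/"female"/"F" collapse to "F",
#' likewise for "M"); six regional tau PET SUVR columns
#' \code{tau_suvr_braak1..tau_suvr_braak6} are kept in Braak I to VI order;
#' unknown columns pass through untouched.
#'
#' @param path file path to a TSV/CSV table.
#' @param sep field separator.
#' @return data.frame with one row per sample.
#' @export
readSampleMetadata <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   na.strings = MISSING_TOKENS)
  if (is.null(df$sample_id)) stop("metadata must contain a sample_id column")
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!is.null(df$sex)) {
    key <- trimws(as.character(df$sex))
    mapped <- SEX_MAP[tolower(key)]
    unmapped <- !is.na(key) & is.na(mapped)
    if (any(unmapped))
      stop("unrecognized sex codes: ",
           paste(unique(key[unmapped]), collapse = ", "))
    df$sex <- unname(mapped)
  }
  num_cols <- intersect(
    c("age", "abeta_pet_suvr", TAU_REGION_COLS, "biopsy_abeta_score",
      grep("^csf_", colnames(df), value = TRUE)),
    colnames(df))
  for (cc in num_cols) df[[cc]] <- as.numeric(df[[cc]])
  if (!is.null(df$biopsy_tangles)) df$biopsy_tangles <- as.logical(df$biopsy_tangles)
  if (!is.null(df$is_reference)) df$is_reference <- as.logical(df$is_reference)
  if (!is.null(df$is_control)) df$is_control <- as.logical(df$is_control)
  df
}

#' Extract the six regional tau SUVRs in Braak order
#'
#' @param meta metadata data.frame from [readSampleMetadata()].
#' @return samples x 6 numeric matrix ordered Braak I to VI.
#' @export
tauRegionMatrix <- function(meta) {
  missing_cols <- setdiff(TAU_REGION_COLS, colnames(meta))
  if (length(missing_cols))
    stop("missing tau SUVR columns: ", paste(missing_cols, collapse = ", "))
  m <- as.matrix(meta[, TAU_REGION_COLS])
  rownames(m) <- meta$sample_id
  m
}
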