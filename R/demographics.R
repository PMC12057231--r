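#' Cohort demographics table with group tests
#'
#' Summarizes each requested variable across strata: continuous variables
#' are reported as median (IQR) and compared with the Kruskal-Wallis test;
#' categorical variables as counts (percent) compared with the Pearson
#' chi-square test (no continuity correction by default). Strata with zero
#' samples are dropped with a note.
#'
#' @param meta metadata data.frame.
#' @param strata character/factor of stratum membership per row.
#' @param variables columns of \code{meta} to summarize; defaults to all
#'   columns except \code{sample_id} and the stratum itself.
#' @param correct logical; apply the chi-square continuity correction.
#' @return data.frame with variable, type, per-stratum summaries, test,
#'   statistic, df (chi-square only) and p.
#' @export
summarizeDemographics <- function(meta, strata, variables = NULL,
                                  correct = FALSE) {
  strata <- as.factor(strata)
  empty <- levels(strata)[table(strata) == 0]
  if (length(empty)) {
    message("dropping empty strata: ", paste(empty, collapse = ", "))
    strata <- droplevels(strata)
  }
  if (nlevels(strata) < 2) stop("need at least 2 non-empty strata")
  if (is.null(variables))
    variables <- setdiff(colnames(meta), c("sample_id"))
  rows <- lapply(variables, function(v) {
    x <- meta[[v]]
    if (is.numeric(x)) {
      summ <- vapply(levels(strata), function(g) {
        xv <- x[strata == g]
        sprintf("%.3g (%.3g-%.3g)", median(xv, na.rm = TRUE),
                quantile(xv, 0.25, na.rm = TRUE),
                quantile(xv, 0.75, na.rm = TRUE))
      }, character(1))
      kt <- kruskal.test(x, strata)
      data.frame(variable = v, type = "continuous",
                 t(summ), test = "Kruskal-Wallis",
                 statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value, stringsAsFactors = FALSE,
                 check.names = FALSE)
    } else {
      xf <- factor(x)
      tab <- table(xf, strata)
      summ <- vapply(levels(strata), function(g) {
        n <- tab[, g]
        paste(sprintf("%s: %d (%.0f%%)", rownames(tab), n,
                      100 * n / max(1, sum(n))), collapse = "; ")
      }, character(1))
      ct <- suppressWarnings(chisq.test(tab, correct = correct))
      data.frame(variable = v, type = "categorical",
                 t(summ), test = "Pearson chi-square",
                 statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, stringsAsFactors = FALSE,
                 check.names = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
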