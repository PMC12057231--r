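#' Z-score values to a control group
#'
#' z = (x - mean(controls)) / sd(controls), with the usual n - 1 SD
#' denominator. Control samples themselves get mean 0 and SD 1.
#'
#' @param values numeric vector.
#' @param controlMask logical vector marking control samples.
#' @return z-scored vector.
#' @export
zscoreToControls <- function(values, controlMask) {
  ctrl <- values[controlMask & !is.na(values)]
  if (length(ctrl) < 2) stop("need >= 2 controls with finite values")
  s <- sd(ctrl)
  if (s == 0) stop("control SD is zero; z-scores undefined")
  (values - mean(ctrl)) / s
}

#' Numeric positions for ordered stage labels
#'
#' CTRL = 0, Braak I..VI = 1..6; pooled levels such as "III-IV" sit at the
#' midpoint of their range. Discordant/unknown map to NA.
#'
#' @param stages character vector of (possibly pooled) stage labels.
#' @return numeric positions.
#' @export
stagePositions <- function(stages) {
  base <- c(CTRL = 0, `0` = 0, I = 1, II = 2, III = 3, IV = 4, V = 5, VI = 6)
  vapply(as.character(stages), function(s) {
    if (s %in% names(base)) return(unname(base[s]))
    parts <- strsplit(s, "-", fixed = TRUE)[[1L]]
    if (all(parts %in% names(base))) return(mean(base[parts]))
    NA_real_
  }, numeric(1), USE.NAMES = FALSE)
}

#' Loess trajectory across ordered stages
#'
#' Fits a tricube-weighted local polynomial (default degree 2) of the
#' values on numeric stage positions and evaluates it, with pointwise 95%
#' confidence bands from the linear-smoother standard errors, on the
#' observed stage positions only (no extrapolation).
#'
#' @param stagePos numeric stage positions per sample (see
#'   [stagePositions()]); NA positions are dropped.
#' @param values numeric response per sample.
#' @param span loess span.
#' @param degree local polynomial degree (1 or 2).
#' @param seriesName label carried into the output.
#' @return list with series_name, stage_grid, fitted, ci_low, ci_high,
#'   span, degree, n_per_stage, and the loess \code{fit} object.
#' @export
loessTrajectory <- function(stagePos, values, span = 0.75, degree = 2,
                            seriesName = "series") {
  ok <- !is.na(stagePos) & !is.na(values)
  x <- stagePos[ok]; y <- values[ok]
  if (length(unique(x)) < degree + 2)
    stop("need at least degree + 2 distinct stage positions")
  fit <- tryCatch(
    loess(y ~ x, span = span, degree = degree, family = "gaussian",
          control = stats::loess.control(surface = "direct")),
    error = function(e) e, warning = function(w) w)
  if (inherits(fit, "condition"))
    stop("loess failed (span ", span, " may be too small for the window ",
         "population; try span >= ", signif(3 * (degree + 1) / length(x), 2),
         "): ", conditionMessage(fit))
  grid <- sort(unique(x))
  pr <- predict(fit, data.frame(x = grid), se = TRUE)
  fitted <- unname(pr$fit)
  half <- unname(qt(0.975, pr$df) * pr$se.fit)
  list(series_name = seriesName, stage_grid = grid, fitted = fitted,
       ci_low = fitted - half, ci_high = fitted + half, span = span,
       degree = degree,
       n_per_stage = as.integer(table(factor(x, levels = grid))),
       fit = fit)
}

#' Align and summarize several stage trajectories
#'
#' Z-scores each fitted series over the common grid, applies vertical
#' display offsets so series are visually separated, records the offsets
#' (un-shifting reproduces the standardized fits exactly), and flags grid
#' points where the first difference changes sign (candidate inflection
#' points).
#'
#' @param fits list of [loessTrajectory()] results on a common stage grid.
#' @param offsetStep vertical display offset between consecutive series
#'   (0 disables shifting).
#' @param standardize z-score each series before shifting.
#' @return data.frame with series, stage, fitted (raw), display (shifted),
#'   offset, sign_change.
#' @export
summarizeTrajectories <- function(fits, offsetStep = 0, standardize = TRUE) {
  grid <- fits[[1L]]$stage_grid
  for (f in fits)
    if (!isTRUE(all.equal(f$stage_grid, grid)))
      stop("trajectories must share a common stage grid")
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    y <- f$fitted
    if (standardize) y <- (y - mean(y)) / ifelse(sd(y) > 0, sd(y), 1)
    off <- (i - 1) * offsetStep
    d <- diff(y)
    sign_change <- c(FALSE, diff(sign(d)) != 0, FALSE)
    data.frame(series = f$series_name, stage = grid, fitted = y,
               display = y + off, offset = off, sign_change = sign_change,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
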