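#' Spearman correlation of Eigenproteins with biomarkers, Bonferroni-adjusted
#'
#' Computes Spearman rank-order correlations between every module
#' Eigenprotein and every biomarker column over pairwise-complete samples,
#' with p-values from the t approximation and Bonferroni adjustment over
#' the full family of computed pairs.
#'
#' @param summary a [ModuleSummary-class] (or samples x modules matrix).
#' @param biomarkers data.frame of numeric biomarker columns, rows aligned
#'   with the Eigenprotein samples.
#' @param minPairs minimum paired observations per correlation.
#' @return data.frame with module, biomarker, rho, p, p_bonferroni,
#'   n_pairs, n_tests.
#' @export
spearmanBonferroni <- function(summary, biomarkers, minPairs = 5) {
  eps <- if (is(summary, "ModuleSummary")) eigenproteins(summary)
         else as.matrix(summary)
  rows <- list()
  for (m in colnames(eps)) {
    for (b in colnames(biomarkers)) {
      x <- eps[, m]; y <- biomarkers[[b]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < minPairs) next
      if (sd(y[ok]) == 0) {
        warning("constant biomarker '", b, "' skipped")
        next
      }
      rx <- rank(x[ok]); ry <- rank(y[ok])
      rho <- cor(rx, ry)
      n <- sum(ok)
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- if (abs(rho) >= 1) 0 else 2 * pt(-abs(tstat), n - 2)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, biomarker = b, rho = rho, p = p, n_pairs = n,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no correlation had enough paired observations")
  tab$p_bonferroni <- pmin(1, tab$p * nrow(tab))
  tab$n_tests <- nrow(tab)
  tab
}

# inverse of trigamma by Newton iteration (monotone decreasing function)
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (it in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

# moment-matching of log residual variances to a scaled F prior:
# returns prior df d0 and prior variance s0^2
.squeeze_var <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- var(e) * (length(e) - 1) / length(e) -
    mean(trigamma(df[ok] / 2))
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s0 <- exp(emean)
  } else {
    d0 <- 2 * .trigamma_inverse(evar)
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  list(df_prior = d0, var_prior = s0)
}

#' Moderated differential abundance with empirical-Bayes shrinkage
#'
#' Fits, per protein, an ordinary least-squares model of log2 abundance on
#' a group factor plus covariates over available cases, then shrinks the
#' residual variances toward a common prior by empirical Bayes: the prior
#' degrees of freedom d0 and prior variance s0^2 are estimated by moment
#' matching of the log residual variances (the standard scaled-F model),
#' the posterior variance is (d0 s0^2 + d s^2) / (d0 + d), and the
#' moderated t uses d + d0 degrees of freedom. Proteins observed in fewer
#' than \code{minObs} samples are excluded.
#'
#' @param x a log2-ratio [CsfProteome] or proteins x samples matrix.
#' @param group factor/character of group membership per sample.
#' @param contrast length-2 character: groups to compare as
#'   \code{contrast[1] - contrast[2]} (log2 fold change).
#' @param covariates data.frame of per-sample covariates (e.g. age, sex);
#'   NULL for none.
#' @param minObs minimum observed samples per protein.
#' @param adjust multiplicity adjustment: "BH" or "bonferroni".
#' @param priorDf override the estimated prior df (0 disables moderation,
#'   reproducing the ordinary t-test; NULL estimates it).
#' @return data.frame with protein, contrast, log2_fc, se, t_moderated,
#'   df_total, p, p_adj, adj_method, n_obs; attribute
#'   \code{"eb"} carries the estimated (df_prior, var_prior).
#' @export
fitModeratedLM <- function(x, group, contrast, covariates = NULL,
                           minObs = 20, adjust = c("BH", "bonferroni"),
                           priorDf = NULL) {
  adjust <- match.arg(adjust)
  m <- if (is(x, "CsfProteome")) abundance(x) else as.matrix(x)
  group <- as.character(group)
  keep_s <- group %in% contrast
  m <- m[, keep_s, drop = FALSE]
  group <- factor(group[keep_s], levels = rev(contrast))
  dat <- data.frame(group = group)
  if (!is.null(covariates))
    dat <- cbind(dat, as.data.frame(covariates)[keep_s, , drop = FALSE])
  X <- model.matrix(~ ., dat)
  if (qr(X)$rank < ncol(X)) {
    bad <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("collinear design; aliased columns: ", paste(bad, collapse = ", "))
  }
  res <- lapply(seq_len(nrow(m)), function(i) {
    y <- m[i, ]
    ok <- !is.na(y)
    if (sum(ok) < minObs) return(NULL)
    Xi <- X[ok, , drop = FALSE]
    if (qr(Xi)$rank < ncol(Xi)) return(NULL)
    fit <- lm.fit(Xi, y[ok])
    df <- sum(ok) - ncol(Xi)
    if (df <= 0) return(NULL)
    s2 <- sum(fit$residuals^2) / df
    xtx_inv <- chol2inv(chol(crossprod(Xi)))
    j <- which(colnames(X) == paste0("group", contrast[1L]))
    data.frame(protein = rownames(m)[i], log2_fc = fit$coefficients[j],
               unscaled_se = sqrt(xtx_inv[j, j]), s2 = s2, df = df,
               n_obs = sum(ok), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  if (is.null(tab)) stop("no protein passed the minimum-observation filter")
  eb <- if (is.null(priorDf)) .squeeze_var(tab$s2, tab$df)
        else list(df_prior = priorDf,
                  var_prior = if (priorDf > 0) mean(tab$s2) else NA_real_)
  d0 <- eb$df_prior
  post_s2 <- if (d0 == 0) tab$s2
             else if (is.infinite(d0)) rep(eb$var_prior, nrow(tab))
             else (d0 * eb$var_prior + tab$df * tab$s2) / (d0 + tab$df)
  tab$se <- sqrt(post_s2) * tab$unscaled_se
  tab$t_moderated <- tab$log2_fc / tab$se
  tab$df_total <- tab$df + d0
  tab$p <- 2 * pt(-abs(tab$t_moderated), tab$df_total)
  tab$p_adj <- p.adjust(tab$p, method = adjust)
  tab$adj_method <- adjust
  tab$contrast <- paste(contrast, collapse = " - ")
  rownames(tab) <- NULL
  out <- tab[, c("protein", "contrast", "log2_fc", "se", "t_moderated",
                 "df_total", "p", "p_adj", "adj_method", "n_obs")]
  attr(out, "eb") <- eb
  out
}

#' Covariate-adjusted group contrasts with Tukey HSD
#'
#' Fits a linear model of the response on a group factor plus covariates,
#' forms covariate-adjusted group means (predictions at the covariate
#' means), and tests all pairwise differences against the studentized
#' range distribution with the model's residual degrees of freedom,
#' controlling the family-wise error rate. Unadjusted t-test p-values are
#' also reported. With two groups the Tukey-adjusted p equals the
#' model-based t-test p (q = t * sqrt(2)).
#'
#' @param values numeric response per sample (Eigenprotein or protein).
#' @param groups factor/character group per sample.
#' @param covariates data.frame of covariates or NULL.
#' @return data.frame with group1, group2, estimate, se, t, df, p_unadj,
#'   p_tukey.
#' @export
groupContrastTukey <- function(values, groups, covariates = NULL) {
  groups <- factor(as.character(groups))
  ok <- !is.na(values) & !is.na(groups)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    ok <- ok & complete.cases(covariates)
  }
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  if (k < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with >= 2 samples each")
  dat <- data.frame(y = values, group = groups)
  if (!is.null(covariates)) dat <- cbind(dat, covariates[ok, , drop = FALSE])
  fit <- lm(y ~ ., data = dat)
  if (anyNA(coef(fit))) stop("singular design in group contrast model")
  V <- vcov(fit)
  cf <- coef(fit)
  lev <- levels(groups)
  cmat <- matrix(0, length(lev), length(cf),
                 dimnames = list(lev, names(cf)))
  cmat[, "(Intercept)"] <- 1
  for (l in lev[-1L]) cmat[l, paste0("group", l)] <- 1
  if (!is.null(covariates)) {
    for (cc in colnames(covariates)) {
      v <- covariates[ok, cc]
      if (is.numeric(v)) {
        cmat[, grep(paste0("^", cc, "$"), names(cf))] <- mean(v)
      } else {
        f <- factor(v)
        for (l2 in levels(f)[-1L]) {
          nm <- paste0(cc, l2)
          if (nm %in% names(cf)) cmat[, nm] <- mean(f == l2)
        }
      }
    }
  }
  df <- fit$df.residual
  out <- list()
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    cv <- cmat[j, ] - cmat[i, ]
    est <- sum(cv * cf)
    se <- sqrt(drop(t(cv) %*% V %*% cv))
    tstat <- est / se
    out[[length(out) + 1L]] <- data.frame(
      group1 = lev[j], group2 = lev[i], estimate = est, se = se,
      t = tstat, df = df, p_unadj = 2 * pt(-abs(tstat), df),
      p_tukey = ptukey(abs(tstat) * sqrt(2), k, df, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Joint amyloid + tau PET linear models per protein
#'
#' Per protein, regresses log2 abundance on amyloid PET SUVR and tau PET
#' SUVR jointly, adjusting for age, sex and clinical diagnosis, and
#' reports both partial coefficients with BH adjustment across proteins
#' per predictor. Warns (but still fits) when the two SUVRs are nearly
#' collinear.
#'
#' @param x a log2-ratio [CsfProteome] or matrix.
#' @param meta metadata data.frame with abeta_pet_suvr, the regional tau
#'   SUVRs or a \code{tau_pet_suvr} column, age, sex, diagnosis.
#' @param tauSuvr optional explicit tau SUVR vector (defaults to the mean
#'   of the six regional SUVRs).
#' @param minObs minimum observed samples per protein.
#' @return data.frame with one row per protein: coefficients, p and BH
#'   adjusted p for both predictors, and n_obs.
#' @export
dualPETModel <- function(x, meta, tauSuvr = NULL, minObs = 20) {
  m <- if (is(x, "CsfProteome")) abundance(x) else as.matrix(x)
  abeta <- meta$abeta_pet_suvr
  if (is.null(tauSuvr)) {
    tauSuvr <- if (!is.null(meta$tau_pet_suvr)) meta$tau_pet_suvr
               else rowMeans(as.matrix(meta[, TAU_REGION_COLS]))
  }
  keep <- !is.na(abeta) & !is.na(tauSuvr)
  rr <- abs(cor(abeta[keep], tauSuvr[keep]))
  if (is.finite(rr) && rr > 0.99)
    warning("amyloid and tau SUVR nearly collinear (|r| = ",
            signif(rr, 3), ")")
  dat <- data.frame(abeta_suvr = abeta, tau_suvr = tauSuvr,
                    age = meta$age, sex = factor(meta$sex),
                    diagnosis = factor(meta$diagnosis))
  ok_s <- complete.cases(dat)
  X <- model.matrix(~ ., dat[ok_s, , drop = FALSE])
  mi <- m[, ok_s, drop = FALSE]
  res <- lapply(seq_len(nrow(mi)), function(i) {
    y <- mi[i, ]
    ok <- !is.na(y)
    if (sum(ok) < minObs) return(NULL)
    Xi <- X[ok, , drop = FALSE]
    if (qr(Xi)$rank < ncol(Xi)) return(NULL)
    fit <- lm.fit(Xi, y[ok])
    df <- sum(ok) - ncol(Xi)
    s2 <- sum(fit$residuals^2) / df
    xtx_inv <- chol2inv(chol(crossprod(Xi)))
    ja <- which(colnames(X) == "abeta_suvr")
    jt <- which(colnames(X) == "tau_suvr")
    tt <- fit$coefficients[c(ja, jt)] / sqrt(s2 * diag(xtx_inv)[c(ja, jt)])
    data.frame(protein = rownames(mi)[i],
               coef_abeta = fit$coefficients[ja],
               coef_tau = fit$coefficients[jt],
               p_abeta = 2 * pt(-abs(tt[1L]), df),
               p_tau = 2 * pt(-abs(tt[2L]), df),
               n_obs = sum(ok), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  if (is.null(tab)) stop("no protein passed the minimum-observation filter")
  tab$p_adj_abeta <- p.adjust(tab$p_abeta, "BH")
  tab$p_adj_tau <- p.adjust(tab$p_tau, "BH")
  rownames(tab) <- NULL
  tab
}

#' Project a discovery module's Eigenprotein into another cohort
#'
#' Restricts the module to proteins with discovery kME above
#' \code{kmeCut} that are quantified in the target cohort, standardizes
#' each member there, and takes the first principal component across
#' target samples as the comparative Eigenprotein. The sign is aligned so
#' the score correlates positively with the kME-sign-weighted mean member
#' abundance. Scores are z-scored to the target cohort's control samples.
#'
#' @param target a log2-ratio [CsfProteome] (or matrix) for the target
#'   cohort.
#' @param summary the discovery [ModuleSummary-class].
#' @param module module column name (e.g. "ME1") or index.
#' @param kmeCut kME membership threshold.
#' @param controlMask logical per target sample marking controls.
#' @return list with module, member_proteins_used, values (per-sample
#'   scores), z_to_controls, coverage_frac.
#' @export
projectEigenprotein <- function(target, summary, module, kmeCut = 0.6,
                                controlMask) {
  m <- if (is(target, "CsfProteome")) abundance(target) else as.matrix(target)
  kmat <- kme(summary)
  if (is.numeric(module)) module <- colnames(kmat)[module]
  kv <- kmat[, module]
  eligible <- rownames(kmat)[!is.na(kv) & kv > kmeCut]
  members <- intersect(eligible, rownames(m))
  if (length(members) < 3)
    stop("only ", length(members), " of ", length(eligible),
         " eligible module proteins present in target (need >= 3)")
  z <- t(apply(m[members, , drop = FALSE], 1L, function(v) {
    mu <- mean(v, na.rm = TRUE); s <- sd(v, na.rm = TRUE)
    (v - mu) / ifelse(is.finite(s) && s > 0, s, 1)
  }))
  for (i in seq_len(nrow(z)))
    if (anyNA(z[i, ])) z[i, is.na(z[i, ])] <- median(z[i, ], na.rm = TRUE)
  sv <- svd(t(z), nu = 1, nv = 0)
  u <- sv$u[, 1L]
  wsign <- sign(kv[members])
  ref <- colMeans(z * wsign)
  if (cor(u, ref) < 0) u <- -u
  zc <- zscoreToControls(u, controlMask)
  list(module = module, member_proteins_used = members,
       values = setNames(u, colnames(m)),
       z_to_controls = setNames(zc, colnames(m)),
       coverage_frac = length(members) / length(eligible))
}

#' Volcano-plot table from a differential table
#'
#' Joins log2 fold changes, -log10 p-values, module membership labels and
#' significance flags at the unadjusted and adjusted 0.05 thresholds.
#' Unlabeled proteins get module 0 ("gray").
#'
#' @param diff output of [fitModeratedLM()].
#' @param labels named integer module labels.
#' @param alpha significance threshold.
#' @return plot-ready data.frame.
#' @export
volcanoTable <- function(diff, labels, alpha = 0.05) {
  lab <- labels[diff$protein]
  lab[is.na(lab)] <- 0L
  dir <- ifelse(diff$log2_fc > 0, "up", "down")
  data.frame(diff,
             neg_log10_p = -log10(diff$p),
             module = unname(lab),
             significance = ifelse(diff$p_adj < alpha,
                                   paste(dir, "adjusted", sep = ", "),
                                   ifelse(diff$p < alpha,
                                          paste(dir, "unadjusted", sep = ", "),
                                          "ns")),
             stringsAsFactors = FALSE)
}
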