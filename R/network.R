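#' Biweight midcorrelation matrix
#'
#' Robust correlation between all protein pairs. For each protein vector x,
#' u_i = (x_i - med(x)) / (9 MAD(x)) and the Tukey biweight
#' w_i = (1 - u_i^2)^2 for |u_i| < 1, else 0. Side-capping limits the mass
#' each tail may zero out: if more than \code{maxPOutliers} of the samples
#' on one side have |u| >= 1, u is rescaled on that side so the
#' corresponding quantile sits at 1. A protein with MAD = 0 falls back to
#' Pearson weighting (centered by the mean); a fully constant protein gets
#' correlation 0 with a warning. Entries are computed over pairwise-complete
#' observations; pairs with fewer than \code{minPairs} joint observations
#' become 0 with a warning.
#'
#' @param x a [CsfProteome] or a proteins x samples numeric matrix.
#' @param maxPOutliers maximum fraction of samples per tail allowed to
#'   receive zero weight.
#' @param minPairs minimum jointly observed samples per pair.
#' @return proteins x proteins correlation matrix with unit diagonal.
#' @export
bicorMatrix <- function(x, maxPOutliers = 0.05, minPairs = 10) {
  m <- if (is(x, "CsfProteome")) abundance(x) else as.matrix(x)
  n <- ncol(m)
  w <- .bicor_weights(m, maxPOutliers)
  a <- w$a                       # weighted centered values, NA -> 0
  obs <- w$obs                   # observation indicator
  num <- a %*% t(a)
  ss <- (a * a) %*% t(obs)       # sum of a_i^2 over joint obs (row i vs obs j)
  den <- sqrt(ss * t(ss))
  r <- num / den
  r[!is.finite(r)] <- 0
  npairs <- obs %*% t(obs)
  few <- npairs < minPairs
  if (any(few & upper.tri(few))) {
    warning(sum(few[upper.tri(few)]),
            " protein pairs with fewer than ", minPairs,
            " joint observations set to 0")
    r[few] <- 0
  }
  if (any(w$constant))
    warning("constant proteins (correlation undefined, set to 0): ",
            paste(rownames(m)[w$constant], collapse = ", "))
  r[w$constant, ] <- 0
  r[, w$constant] <- 0
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  dimnames(r) <- list(rownames(m), rownames(m))
  (r + t(r)) / 2
}

# per-row biweight (or Pearson-fallback) centered weighted values
.bicor_weights <- function(m, maxPOutliers) {
  p <- nrow(m)
  a <- matrix(0, p, ncol(m))
  obs <- 1 * !is.na(m)
  constant <- logical(p)
  for (i in seq_len(p)) {
    x <- m[i, ]
    ok <- !is.na(x)
    xi <- x[ok]
    medx <- median(xi)
    madx <- mad(xi, constant = 1)
    if (madx == 0) {
      if (sd(xi) == 0) { constant[i] <- TRUE; next }
      a[i, ok] <- xi - mean(xi)        # Pearson fallback
      next
    }
    u <- (xi - medx) / (9 * madx)
    if (maxPOutliers < 0.5) {
      qL <- quantile(u, maxPOutliers, names = FALSE, type = 7)
      if (qL < -1) u[u < 0] <- u[u < 0] / (-qL)
      qU <- quantile(u, 1 - maxPOutliers, names = FALSE, type = 7)
      if (qU > 1) u[u > 0] <- u[u > 0] / qU
    }
    wgt <- (1 - u^2)^2 * (abs(u) < 1)
    a[i, ok] <- wgt * (xi - medx)
  }
  list(a = a, obs = obs, constant = constant)
}

#' Biweight midcorrelation of two vectors
#'
#' Scalar convenience wrapper around [bicorMatrix()].
#' @param x,y numeric vectors of equal length.
#' @param maxPOutliers per-tail outlier cap.
#' @return correlation in [-1, 1].
#' @export
bicor <- function(x, y, maxPOutliers = 0.05) {
  bicorMatrix(rbind(x = x, y = y), maxPOutliers = maxPOutliers,
              minPairs = 3)["x", "y"]
}

#' Signed adjacency from a correlation matrix
#'
#' a_ij = ((1 + cor_ij) / 2)^beta off the diagonal; a_ii = 1. Positive
#' correlations map near 1, negative correlations are suppressed toward 0,
#' giving a signed weighted network.
#'
#' @param cor correlation matrix.
#' @param beta positive integer soft-threshold power.
#' @return adjacency matrix with entries in [0, 1].
#' @export
signedAdjacency <- function(cor, beta) {
  stopifnot(beta >= 1)
  a <- ((1 + cor) / 2)^beta
  diag(a) <- 1
  a
}

#' Scale-free soft-threshold selection
#'
#' For each candidate power, forms the signed adjacency and the
#' connectivities k_i = sum_{j != i} a_ij, bins k into \code{nBins} bins,
#' and regresses log10 mean frequency on log10 mean connectivity; the
#' scale-free fit index is R^2 signed by the negative of the slope. The
#' chosen power is the smallest one reaching \code{r2Target} with mean
#' connectivity below \code{maxMeanConnectivity}; if none reaches the
#' target, the power maximizing the fit subject to the connectivity bound
#' is chosen with a warning.
#'
#' @param cor correlation matrix.
#' @param candidates integer powers to scan.
#' @param r2Target target scale-free fit.
#' @param maxMeanConnectivity upper bound on mean connectivity.
#' @param nBins histogram bins for the fit.
#' @return a [SoftThresholdDiagnostics-class] object.
#' @export
pickSoftThreshold <- function(cor, candidates = 1:20, r2Target = 0.9,
                              maxMeanConnectivity = 100, nBins = 10) {
  offdiag <- cor[upper.tri(cor)]
  if (max(offdiag) - min(offdiag) < 1e-12)
    stop("degenerate correlation matrix: all off-diagonal entries equal")
  base <- (1 + cor) / 2
  diag(base) <- 0
  rows <- lapply(candidates, function(beta) {
    k <- rowSums(base^beta)
    data.frame(power = beta, sft_r2 = scaleFreeFitIndex(k, nBins),
               mean_k = mean(k), median_k = median(k))
  })
  tab <- do.call(rbind, rows)
  ok_k <- tab$mean_k < maxMeanConnectivity & tab$median_k < maxMeanConnectivity
  hit <- which(tab$sft_r2 >= r2Target & ok_k)
  if (length(hit)) {
    chosen <- tab$power[hit[1L]]
  } else {
    cand <- which(ok_k)
    if (!length(cand)) cand <- seq_len(nrow(tab))
    chosen <- tab$power[cand[which.max(tab$sft_r2[cand])]]
    warning("no candidate power reached scale-free fit ", r2Target,
            "; using power ", chosen, " with best fit ",
            signif(max(tab$sft_r2[cand]), 3))
  }
  new("SoftThresholdDiagnostics", table = tab, chosenPower = as.integer(chosen))
}

#' Scale-free topology fit index
#'
#' Bins connectivities, regresses log10 frequency on log10 mean
#' connectivity per bin, and returns R^2 signed by the negative of the
#' slope (positive when the degree distribution decays, as in scale-free
#' networks).
#'
#' @param k vector of node connectivities.
#' @param nBins number of histogram bins.
#' @return signed fit index in [-1, 1].
#' @export
scaleFreeFitIndex <- function(k, nBins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(NA_real_)
  brk <- seq(min(k), max(k), length.out = nBins + 1)
  bin <- cut(k, brk, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  keep <- !is.na(dk) & !is.na(pk) & dk > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  -sign(coef(fit)[2L]) * r2
}

#' Topological overlap matrix
#'
#' TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' L_ij = sum_{u != i,j} a_iu a_uj and k_i = sum_{u != i} a_iu; the diagonal
#' is 1. The dissimilarity used for clustering is 1 - TOM.
#'
#' @param a symmetric adjacency with unit diagonal and entries in [0, 1].
#' @return TOM matrix with entries in [0, 1].
#' @export
topologicalOverlap <- function(a) {
  stopifnot(isSymmetric(unname(a), tol = 1e-10),
            all(a >= 0 & a <= 1), all(abs(diag(a) - 1) < 1e-12))
  a0 <- a
  diag(a0) <- 0
  L <- a0 %*% a0   # zero diagonal makes the sum skip u = i and u = j
  k <- rowSums(a0)
  denom <- outer(k, k, pmin) + 1 - a0
  tom <- (L + a0) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  (tom + t(tom)) / 2
}

# per-deepSplit minimum separation gap, as a fraction of the merge-height
# range: smaller gap splits branches more aggressively
DEEP_SPLIT_GAP_FRAC <- c(`0` = 0.25, `1` = 0.2, `2` = 0.15, `3` = 0.1,
                         `4` = 0.05)

#' Dynamic tree cutting with PAM assignment
#'
#' A documented simplification of hybrid dynamic tree cutting. Proteins
#' are clustered by average linkage on the dissimilarity. The tree is
#' first cut at h = h_min + 0.95 (h_max - h_min) over the merge-height
#' range (the range-relative form keeps the rule meaningful on TOM
#' dendrograms, whose merge heights concentrate near 1); leaves detaching
#' above that height are unassigned. Each resulting cluster with at least
#' \code{minSize} members is then decomposed recursively top-down: walking
#' down its subtree past stray single leaves to the first partition with
#' two or more branches of \code{minSize}+ leaves, the split is accepted
#' when the smallest mean between-branch dissimilarity exceeds the largest
#' mean within-branch dissimilarity by a deepSplit-dependent gap (25, 20,
#' 15, 10, 5 percent of the merge-height range for deepSplit 0..4, so
#' higher deepSplit accepts subtler splits and yields more, smaller
#' modules). Modules are relabeled 1, 2, ... by decreasing size. If
#' \code{pamStage}, each unassigned protein joins the module with smallest
#' mean dissimilarity to its members; with \code{pamRespectsDendro} the
#' assignment is accepted only if that mean dissimilarity is no larger
#' than the 90th percentile of the members' own peripherality (mean
#' dissimilarity to the rest of the module), so proteins outside the
#' branch stay unassigned (label 0). A zero-range (all-equal)
#' dissimilarity has no branch structure and leaves everything unassigned.
#'
#' @param dissim symmetric dissimilarity matrix (1 - TOM).
#' @param deepSplit integer 0..4.
#' @param minSize minimum module size.
#' @param pamStage assign leftover proteins to nearest module.
#' @param pamRespectsDendro restrict PAM assignments to dendrogram-
#'   consistent candidates.
#' @param maxDepth maximum recursive split depth.
#' @return list with \code{dendrogram} (hclust) and \code{labels} (named
#'   integer; 0 = unassigned).
#' @export
cutTreeDynamic <- function(dissim, deepSplit = 4, minSize = 10,
                           pamStage = TRUE, pamRespectsDendro = TRUE,
                           maxDepth = 8) {
  stopifnot(deepSplit %in% 0:4)
  n <- nrow(dissim)
  ids <- rownames(dissim)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  dimnames(dissim) <- list(ids, ids)
  hc <- hclust(as.dist(dissim), method = "average")
  labels <- setNames(integer(n), ids)
  if (n < minSize) {
    warning("fewer proteins than minSize; all unassigned")
    return(list(dendrogram = hc, labels = labels))
  }
  hr <- range(hc$height)
  if (hr[2L] - hr[1L] < 1e-12)
    return(list(dendrogram = hc, labels = labels))
  gap <- DEEP_SPLIT_GAP_FRAC[[as.character(deepSplit)]] * (hr[2L] - hr[1L])
  raw <- cutree(hc, h = hr[1L] + 0.95 * (hr[2L] - hr[1L]))
  out <- list()
  recurse <- function(ix, depth) {
    if (length(ix) < 2 * minSize || depth >= maxDepth) {
      out[[length(out) + 1L]] <<- ix
      return()
    }
    sub <- dissim[ix, ix]
    shc <- hclust(as.dist(sub), method = "average")
    if (max(shc$height) - min(shc$height) >= 1e-12) {
      kmax <- min(length(ix) - 1L, 2L + length(ix) %/% minSize)
      for (k in 2:kmax) {
        sp <- cutree(shc, k = k)
        tab <- table(sp)
        vb <- as.integer(names(tab)[tab >= minSize])
        if (length(vb) < 2) next
        parts <- lapply(vb, function(v) which(sp == v))
        within <- vapply(parts, function(ii)
          mean(sub[ii, ii][upper.tri(diag(length(ii)))]), numeric(1))
        cross <- Inf
        for (a in seq_along(parts)) for (b in seq_along(parts))
          if (a < b) cross <- min(cross, mean(sub[parts[[a]], parts[[b]]]))
        if (cross > max(within) + gap) {
          for (p in parts) recurse(ix[p], depth + 1L)
          return()
        }
        break
      }
    }
    out[[length(out) + 1L]] <<- ix
  }
  tab <- table(raw)
  for (b in names(tab)[tab >= minSize])
    recurse(which(raw == as.integer(b)), 1L)
  ord <- order(-vapply(out, length, integer(1)))
  for (j in seq_along(ord)) labels[out[[ord[j]]]] <- j
  K <- length(out)
  if (pamStage && K) {
    thr <- vapply(seq_len(K), function(j) {
      ixj <- which(labels == j)
      quantile(vapply(ixj, function(i) mean(dissim[i, setdiff(ixj, i)]),
                      numeric(1)), 0.9, names = FALSE)
    }, numeric(1))
    for (i in which(labels == 0)) {
      meand <- vapply(seq_len(K), function(j)
        mean(dissim[i, labels == j]), numeric(1))
      j <- which.min(meand)
      if (!pamRespectsDendro || meand[j] <= thr[j]) labels[i] <- j
    }
  }
  list(dendrogram = hc, labels = labels)
}

#' Merge modules with similar Eigenproteins
#'
#' Iteratively merges the currently most-correlated pair of module
#' Eigenproteins whenever their dissimilarity (1 - correlation) is below
#' \code{cutHeight}, recomputing Eigenproteins after each merge until no
#' pair qualifies. Merging most-similar-first makes the result independent
#' of label order.
#'
#' @param x a log2-ratio [CsfProteome] (or matrix) over the labeled
#'   proteins.
#' @param labels named integer module labels (0 = unassigned).
#' @param cutHeight Eigenprotein dissimilarity below which modules merge.
#' @return relabeled named integer vector (labels renumbered 1..K by
#'   decreasing size).
#' @export
mergeCloseModules <- function(x, labels, cutHeight = 0.2) {
  m <- if (is(x, "CsfProteome")) abundance(x) else as.matrix(x)
  labels <- labels[rownames(m)]
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    eps <- .eigenprotein_scores(m, labels)$scores
    cc <- cor(eps, use = "pairwise.complete.obs")
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    if (1 - max(cc) >= cutHeight) break
    from <- mods[max(best)]; to <- mods[min(best)]
    labels[labels == from] <- to
  }
  .relabel_by_size(labels)
}

.relabel_by_size <- function(labels) {
  mods <- sort(unique(labels[labels > 0]))
  sizes <- vapply(mods, function(j) sum(labels == j), integer(1))
  newlab <- integer(length(labels))
  for (j in seq_along(mods[order(-sizes)]))
    newlab[labels == mods[order(-sizes)][j]] <- j
  setNames(newlab, names(labels))
}

# samples x modules eigenprotein scores; also returns variance explained
.eigenprotein_scores <- function(m, labels) {
  mods <- sort(unique(labels[labels > 0]))
  scores <- matrix(NA_real_, ncol(m), length(mods),
                   dimnames = list(colnames(m), paste0("ME", mods)))
  ve <- numeric(length(mods))
  for (jj in seq_along(mods)) {
    sub <- m[labels == mods[jj], , drop = FALSE]
    z <- t(apply(sub, 1L, function(v) {
      mu <- mean(v, na.rm = TRUE); s <- sd(v, na.rm = TRUE)
      if (!is.finite(s) || s == 0) s <- 1
      (v - mu) / s
    }))
    for (i in seq_len(nrow(z))) {
      nas <- is.na(z[i, ])
      if (any(nas)) z[i, nas] <- median(z[i, ], na.rm = TRUE)
    }
    z[is.na(z)] <- 0
    sv <- svd(t(z), nu = 1, nv = 0)
    u <- sv$u[, 1L]
    if (cor(u, colMeans(z)) < 0) u <- -u
    scores[, jj] <- u
    ve[jj] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  list(scores = scores, var_explained = ve, modules = mods)
}

#' Module Eigenproteins
#'
#' Summarizes each module by its first principal component across samples:
#' member proteins are z-scored over their observed values, residual missing
#' entries are median-imputed, and the first right singular vector over
#' samples (unit norm) is the Eigenprotein. Its sign is fixed so it
#' correlates positively with the module's mean standardized abundance.
#'
#' @param x a log2-ratio [CsfProteome] or proteins x samples matrix.
#' @param labels named integer module labels (0 = unassigned).
#' @return a [ModuleSummary-class] with Eigenproteins, variance explained,
#'   kME, and module sizes.
#' @export
computeEigenproteins <- function(x, labels) {
  m <- if (is(x, "CsfProteome")) abundance(x) else as.matrix(x)
  labels <- labels[rownames(m)]
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no modules to summarize")
  small <- mods[vapply(mods, function(j) sum(labels == j), integer(1)) < 2]
  if (length(small)) stop("modules with fewer than 2 proteins: ",
                          paste(small, collapse = ", "))
  ep <- .eigenprotein_scores(m, labels)
  summ <- new("ModuleSummary", eigenproteins = ep$scores,
              varianceExplained = setNames(ep$var_explained,
                                           colnames(ep$scores)),
              kme = matrix(0, 0, 0),
              moduleSizes = setNames(
                vapply(mods, function(j) sum(labels == j), integer(1)),
                colnames(ep$scores)))
  summ@kme <- computeKME(m, summ)
  summ
}

#' Module membership (kME)
#'
#' Pearson correlation of each protein with each module Eigenprotein over
#' jointly observed samples; entries with fewer than 3 joint observations
#' are missing.
#'
#' @param x a [CsfProteome] or proteins x samples matrix.
#' @param summary a [ModuleSummary-class] (or samples x modules matrix of
#'   Eigenprotein scores).
#' @return proteins x modules kME matrix.
#' @export
computeKME <- function(x, summary) {
  m <- if (is(x, "CsfProteome")) abundance(x) else as.matrix(x)
  eps <- if (is(summary, "ModuleSummary")) eigenproteins(summary) else summary
  k <- matrix(NA_real_, nrow(m), ncol(eps),
              dimnames = list(rownames(m), colnames(eps)))
  for (j in seq_len(ncol(eps))) {
    e <- eps[, j]
    for (i in seq_len(nrow(m))) {
      ok <- !is.na(m[i, ]) & !is.na(e)
      if (sum(ok) >= 3 && sd(m[i, ok]) > 0)
        k[i, j] <- cor(m[i, ok], e[ok])
    }
  }
  k
}

#' Build a signed weighted co-expression network end to end
#'
#' Runs bicor, soft-threshold selection (or a fixed power), signed
#' adjacency, TOM, average-linkage clustering on 1 - TOM, dynamic tree
#' cutting with PAM, and Eigenprotein-based module merging.
#'
#' @param x a log2-ratio [CsfProteome] (reference channels should be
#'   dropped first; see [dropReferenceChannels()]).
#' @param power fixed soft power; \code{NULL} selects automatically via
#'   [pickSoftThreshold()].
#' @param deepSplit,minSize,mergeCutHeight,maxPOutliers,pamStage,
#'   pamRespectsDendro tuning parameters (defaults follow common CSF TMT
#'   practice: power 10, deepSplit 4, minSize 10, merge cut 0.2,
#'   maxPOutliers 0.05).
#' @return list with \code{model} (a [NetworkModel-class]), \code{summary}
#'   (a [ModuleSummary-class]) and \code{softThreshold} (diagnostics or
#'   NULL).
#' @export
buildNetwork <- function(x, power = 10, deepSplit = 4, minSize = 10,
                         mergeCutHeight = 0.2, maxPOutliers = 0.05,
                         pamStage = TRUE, pamRespectsDendro = TRUE) {
  m <- if (is(x, "CsfProteome")) abundance(x) else as.matrix(x)
  cor_ <- bicorMatrix(m, maxPOutliers = maxPOutliers)
  sft <- NULL
  if (is.null(power)) {
    sft <- pickSoftThreshold(cor_)
    power <- sft@chosenPower
  }
  adj <- signedAdjacency(cor_, power)
  tom <- topologicalOverlap(adj)
  cut <- cutTreeDynamic(1 - tom, deepSplit = deepSplit, minSize = minSize,
                        pamStage = pamStage,
                        pamRespectsDendro = pamRespectsDendro)
  labels <- mergeCloseModules(m, cut$labels, cutHeight = mergeCutHeight)
  model <- new("NetworkModel", correlation = cor_, power = as.integer(power),
               adjacency = adj, tom = tom, dendrogram = cut$dendrogram,
               labels = labels)
  summary <- computeEigenproteins(m, labels)
  list(model = model, summary = summary, softThreshold = sft)
}
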