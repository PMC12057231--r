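# small deterministic proteome: p proteins x n samples, optional rank-1
# module structure
makeProteome <- function(p = 6, n = 8, seed = 1, scale = "log2_ratio") {
  set.seed(seed)
  m <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("P%02d", seq_len(p)),
                              sprintf("S%02d", seq_len(n))))
  CsfProteome(m, scale = scale)
}

# rank-1 module block: proteins = loading x factor (+ noise)
makeModuleMatrix <- function(nProt, factor, loadings = NULL, noiseSd = 0,
                             seed = 1, prefix = "M") {
  set.seed(seed)
  if (is.null(loadings)) loadings <- runif(nProt, 0.4, 0.95)
  m <- loadings %o% factor +
    matrix(rnorm(nProt * length(factor), 0, noiseSd), nProt)
  rownames(m) <- sprintf("%s%03d", prefix, seq_len(nProt))
  colnames(m) <- sprintf("S%03d", seq_along(factor))
  m
}

# independent Braak staging oracle: prefix length / discordance by direct
# enumeration logic
braakOracle <- function(pos) {
  prefix <- sum(cumprod(as.integer(pos)))
  if (any(pos & cumsum(!pos) > 0)) return("discordant")
  c("0", "I", "II", "III", "IV", "V", "VI")[prefix + 1]
}

# independent biweight midcorrelation oracle: direct formula, scalar loops
bicorOracle <- function(x, y, maxPOutliers = 0.05) {
  prep <- function(v) {
    med <- median(v)
    madv <- mad(v, constant = 1)
    if (madv == 0) return(v - mean(v))
    u <- (v - med) / (9 * madv)
    qL <- quantile(u, maxPOutliers, names = FALSE)
    if (qL < -1) u[u < 0] <- u[u < 0] / (-qL)
    qU <- quantile(u, 1 - maxPOutliers, names = FALSE)
    if (qU > 1) u[u > 0] <- u[u > 0] / qU
    w <- (1 - u^2)^2 * (abs(u) < 1)
    w * (v - med)
  }
  a <- prep(x); b <- prep(y)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# brute-force TOM oracle: explicit double sum
tomOracle <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    L <- 0
    for (u in seq_len(n)) if (u != i && u != j) L <- L + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    tom[i, j] <- (L + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  tom
}

# random valid signed adjacency with unit diagonal
randomAdjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)

plantedPanelData <- function(n = 160, pSignal = 10, pNoise = 90,
                             effect = 0.8, seed = 11) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * (pSignal + pNoise)), n,
              dimnames = list(NULL, c(paste0("sig", seq_len(pSignal)),
                                      paste0("bg", seq_len(pNoise)))))
  X[y == 1, seq_len(pSignal)] <- X[y == 1, seq_len(pSignal)] + effect
  list(X = X, y = y)
}
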