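test_that("bicor honours its exact and asymptotic contracts", {
  set.seed(1)
  x <- rnorm(50)
  expect_true(bicor(x, x) == 1)
  expect_true(bicor(x, -x) == -1)

  # outlier-free bivariate normal: close to Pearson
  set.seed(2)
  n <- 1000
  u <- rnorm(n); v <- 0.6 * u + sqrt(1 - 0.36) * rnorm(n)
  expect_lt(abs(bicor(u, v) - cor(u, v)), 0.05)

  # direct weighted-formula oracle, including the capping branch
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(30); b <- 0.5 * a + rnorm(30)
    a[1:3] <- a[1:3] + 8   # heavy outliers exercise side-capping
    expect_equal(bicor(a, b), bicorOracle(a, b), tolerance = 1e-12)
  }
})

test_that("bicor falls back to exact Pearson for MAD-zero vectors", {
  # median-dominated vectors: MAD = 0 but variance > 0
  x <- c(rep(0, 6), 3, -2, 1.5, -1)
  y <- c(rep(1, 6), 2, -1, 0.5, 4)
  expect_equal(bicor(x, y), cor(x, y), tolerance = 1e-12)
})

test_that("bicor matrix handles missingness, constants and short pairs", {
  m <- makeModuleMatrix(4, rnorm(30, 0, 1), noiseSd = 0.3, seed = 4)
  m[1, 1:22] <- NA   # only 8 joint observations with anything
  expect_warning(r <- bicorMatrix(m, minPairs = 10), "joint observations")
  expect_equal(unname(r[1, 2]), 0)
  m2 <- m
  m2[2, ] <- 5
  expect_warning(r2 <- bicorMatrix(m2, minPairs = 5), "constant")
  expect_equal(unname(r2[2, 3]), 0)
  expect_true(isSymmetric(r2))
})

test_that("signed adjacency follows its closed form", {
  cc <- matrix(c(1, 1, -1, 0, 1, 1, -1, 0, -1, -1, 1, 0, 0, 0, 0, 1), 4)
  a <- signedAdjacency(cc, 10)
  expect_equal(a[1, 2], 1)
  expect_equal(a[1, 3], 0)
  expect_equal(a[1, 4], 0.5^10)
  expect_equal(diag(a), rep(1, 4))
})

test_that("topological overlap matches the brute-force oracle and its bounds", {
  for (s in 1:5) {
    a <- randomAdjacency(8, seed = s)
    tom <- topologicalOverlap(a)
    expect_lt(max(abs(tom - tomOracle(a))), 1e-10)
    expect_true(all(tom >= 0 & tom <= 1))
    expect_true(isSymmetric(tom))
  }
  clique <- matrix(1, 3, 3)
  expect_equal(unname(topologicalOverlap(clique)), matrix(1, 3, 3))
  empty <- diag(3)
  expect_equal(unname(topologicalOverlap(empty)), diag(3))
})

test_that("scale-free fit detects planted power laws; connectivity shrinks with power", {
  # counts halving as connectivity doubles: p(k) ~ k^-1
  k <- rep(2^(1:8), times = 2^(8:1))
  expect_gte(scaleFreeFitIndex(k), 0.9)

  m <- makeModuleMatrix(40, rnorm(60), noiseSd = 1, seed = 6)
  cc <- bicorMatrix(m)
  sft <- suppressWarnings(pickSoftThreshold(cc, candidates = 1:12))
  expect_true(all(diff(sft@table$mean_k) <= 1e-8))
  expect_true(sft@chosenPower %in% 1:12)

  flat <- matrix(0.5, 5, 5); diag(flat) <- 1
  expect_error(pickSoftThreshold(flat), "degenerate")
})

test_that("dynamic tree cut recovers planted blocks and rejects structureless input", {
  D <- matrix(0.9, 40, 40)
  D[1:20, 1:20] <- 0.1; D[21:40, 21:40] <- 0.1
  diag(D) <- 0
  dimnames(D) <- list(paste0("p", 1:40), paste0("p", 1:40))
  cut <- cutTreeDynamic(D)
  expect_equal(max(cut$labels), 2)
  expect_equal(adjustedRand(cut$labels, rep(1:2, each = 20)), 1)

  De <- matrix(0.5, 30, 30); diag(De) <- 0
  dimnames(De) <- list(paste0("q", 1:30), paste0("q", 1:30))
  expect_true(all(cutTreeDynamic(De)$labels == 0))

  small <- De[1:4, 1:4]
  expect_warning(res <- cutTreeDynamic(small, minSize = 10), "minSize")
  expect_true(all(res$labels == 0))
})

test_that("module count is non-decreasing in deepSplit on nested blocks", {
  Dn <- matrix(0.9, 60, 60)
  for (b in 0:2) { ix <- b * 20 + 1:20; Dn[ix, ix] <- 0.5 }
  for (b in 0:5) { ix <- b * 10 + 1:10; Dn[ix, ix] <- 0.1 }
  diag(Dn) <- 0
  dimnames(Dn) <- list(paste0("r", 1:60), paste0("r", 1:60))
  counts <- vapply(0:4, function(ds)
    max(cutTreeDynamic(Dn, deepSplit = ds)$labels), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("module merging joins near-duplicate modules independent of order", {
  set.seed(8)
  f1 <- rnorm(60)
  f2 <- 0.5 * f1 + sqrt(0.75) * rnorm(60)   # EP correlation ~0.5: keep apart
  m <- rbind(makeModuleMatrix(12, f1, noiseSd = 0.05, seed = 1, prefix = "A"),
             makeModuleMatrix(12, f1, noiseSd = 0.05, seed = 2, prefix = "B"),
             makeModuleMatrix(12, f2, noiseSd = 0.05, seed = 3, prefix = "C"))
  colnames(m) <- paste0("S", 1:60)
  labels <- setNames(rep(1:3, each = 12), rownames(m))
  merged <- mergeCloseModules(m, labels)
  expect_equal(max(merged), 2)               # A and B merge, C survives
  expect_equal(length(unique(merged[1:24])), 1)

  # three mutually similar modules collapse to one, order-invariant
  m3 <- rbind(makeModuleMatrix(10, f1, noiseSd = 0.05, seed = 4, prefix = "X"),
              makeModuleMatrix(10, f1, noiseSd = 0.05, seed = 5, prefix = "Y"),
              makeModuleMatrix(10, f1, noiseSd = 0.05, seed = 6, prefix = "Z"))
  colnames(m3) <- paste0("S", 1:60)
  for (perm in list(1:3, 3:1, c(2, 1, 3))) {
    labs <- setNames(rep(perm, each = 10), rownames(m3))
    expect_equal(max(mergeCloseModules(m3, labs)), 1)
  }
})

test_that("eigenproteins are exact for rank-1 modules with the documented sign", {
  set.seed(10)
  f <- rnorm(40)
  m <- makeModuleMatrix(8, f, noiseSd = 0, seed = 10)
  labels <- setNames(rep(1L, 8), rownames(m))
  summ <- computeEigenproteins(m, labels)
  ep <- eigenproteins(summ)[, "ME1"]
  expect_equal(abs(cor(ep, f)), 1, tolerance = 1e-10)
  expect_gte(summ@varianceExplained[["ME1"]], 0.999)

  # increasing module -> increasing eigenprotein (sign convention)
  inc <- makeModuleMatrix(6, seq(-1, 1, length.out = 30), noiseSd = 0,
                          seed = 2)
  s2 <- computeEigenproteins(inc, setNames(rep(1L, 6), rownames(inc)))
  expect_gt(cor(eigenproteins(s2)[, 1], seq(-1, 1, length.out = 30)), 0.999)

  expect_error(computeEigenproteins(m, setNames(c(1L, rep(0L, 7)),
                                                rownames(m))),
               "fewer than 2")
})

test_that("kME is Pearson correlation with the eigenprotein", {
  set.seed(11)
  f <- rnorm(140)
  m <- rbind(makeModuleMatrix(10, f, noiseSd = 0.4, seed = 3),
             noise = rnorm(140))
  labels <- setNames(c(rep(1L, 10), 0L), rownames(m))
  summ <- computeEigenproteins(m, labels)
  k <- kme(summ)
  ep <- eigenproteins(summ)[, 1]
  expect_equal(k["M001", 1], cor(m["M001", ], ep), tolerance = 1e-12)
  expect_lt(abs(k["noise", 1]), 0.3)

  m2 <- rbind(m, self = ep)
  k2 <- computeKME(m2, summ)
  expect_equal(unname(k2["self", 1]), 1, tolerance = 1e-12)
})

test_that("network pipeline is equivariant under protein permutation", {
  sim <- simulateCohort(nPerStage = rep(8L, 7),
                        moduleSizes = c(core_markers = 25, metabolic = 20),
                        nBackground = 60, seed = 13)
  norm <- filterMissingness(dropReferenceChannels(normalizeTMT(sim$proteome)))
  m <- abundance(norm)
  net1 <- buildNetwork(m)
  set.seed(1)
  perm <- sample(nrow(m))
  net2 <- buildNetwork(m[perm, ])
  l1 <- moduleLabels(net1$model)
  l2 <- moduleLabels(net2$model)[names(l1)]
  expect_equal(adjustedRand(l1, l2), 1)
})
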