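test_that("trajectory templates satisfy their shape contracts", {
  t <- trajectoryTemplates()
  expect_equal(unname(t["null_module", ]), rep(0, 7))
  core <- t["core_markers", ]
  expect_true(all(diff(core[1:6]) >= 0))           # non-decreasing to V
  endo <- t["endolysosomal", ]
  expect_lte(which.max(endo), 3)                   # peak at stage <= II
  expect_lte(endo[["VI"]], 0.2)
  imm <- t["immune_response", ]
  expect_true(which.min(imm) %in% 2:6)             # strictly interior minimum
  syn <- t["synapse_membrane", ]
  expect_true(all(abs(syn[1:6]) <= 0.15))          # ~0 through V
  expect_lt(syn[["VI"]], syn[["V"]])               # sharp terminal decrease
  expect_lt(t["metabolic", "VI"], t["metabolic", "V"])
})

test_that("cohort generation is reproducible from the seed", {
  a <- simulateCohort(nPerStage = rep(4L, 7), nBackground = 30, seed = 5)
  b <- simulateCohort(nPerStage = rep(4L, 7), nBackground = 30, seed = 5)
  expect_identical(abundance(a$proteome), abundance(b$proteome))
  expect_identical(sampleData(a$proteome), sampleData(b$proteome))
  expect_identical(a$truth$latent, b$truth$latent)
})

test_that("in the noiseless limit module proteins track their latent factor exactly", {
  sim <- simulateCohort(nPerStage = rep(4L, 7), nBackground = 10,
                        noiseSd = 0, missingRate = 0, batchSd = 0,
                        referenceChannels = FALSE, seed = 2)
  m <- log2(abundance(sim$proteome))
  truth <- sim$truth
  for (pid in c("P0001", "P0070", "P0150")) {
    mod <- truth$module_of_protein[pid]
    expect_equal(abs(cor(m[pid, ], truth$latent[, mod])), 1, tolerance = 1e-12)
  }
})

test_that("missingness increases monotonically across abundance terciles", {
  sim <- simulateCohort(seed = 3)
  a <- abundance(sim$proteome)
  terc <- cut(rank(sim$truth$baseline), 3, labels = c("low", "mid", "high"))
  rates <- tapply(rowMeans(is.na(a)), terc, mean)
  expect_gt(rates[["low"]], rates[["mid"]])
  expect_gt(rates[["mid"]], rates[["high"]])
})

test_that("planted modules are more correlated than background (seeds 1-5)", {
  for (s in 1:5) {
    sim <- simulateCohort(seed = s)
    norm <- dropReferenceChannels(normalizeTMT(sim$proteome))
    m <- abundance(norm)
    truth <- sim$truth$module_of_protein[rownames(m)]
    cc <- cor(t(m), use = "pairwise.complete.obs")
    within <- unlist(lapply(unique(na.omit(truth)), function(mod) {
      idx <- which(truth == mod)
      cc[idx, idx][upper.tri(diag(length(idx)))]
    }))
    bgidx <- which(is.na(truth))[1:100]
    bg <- cc[bgidx, bgidx][upper.tri(diag(100))]
    expect_gte(mean(within) - mean(bg), 0.3)
  }
})

test_that("stage means recover the planted templates within 0.1 z (pooled seeds 1-5)", {
  templates <- trajectoryTemplates()
  mods <- rownames(templates)[1:5]
  est <- array(0, c(5, 7), dimnames = list(mods, colnames(templates)))
  nseeds <- 5
  for (s in seq_len(nseeds)) {
    sim <- simulateCohort(nPerStage = rep(50L, 7), noiseSd = 0.2,
                          referenceChannels = FALSE, seed = s)
    truth <- sim$truth
    lv <- log2(abundance(sim$proteome))
    sets <- sampleData(sim$proteome)$tmt_set
    stage <- truth$stage_num
    for (mod in mods) {
      pids <- names(truth$module_of_protein)[
        !is.na(truth$module_of_protein) & truth$module_of_protein == mod]
      # invert the generative model per protein, then average
      lat_hat <- colMeans(
        (lv[pids, ] - truth$baseline[pids] -
           t(truth$batch_effects[sets, pids])) / truth$loadings[pids],
        na.rm = TRUE)
      est[mod, ] <- est[mod, ] +
        tapply(lat_hat, stage, mean, na.rm = TRUE) / nseeds
    }
  }
  expect_lt(max(abs(est - templates[mods, ])), 0.1)
})

test_that("validation cohorts honour overlap, fluid amyloid cut and biopsy rules", {
  sim <- simulateCohort(nPerStage = rep(6L, 7), nBackground = 60, seed = 4)
  val <- simulateValidationCohorts(sim$truth, overlapFrac = 1, seed = 9)
  expect_setequal(rownames(abundance(val$fluid$proteome)),
                  names(sim$truth$module_of_protein))

  val2 <- simulateValidationCohorts(sim$truth, overlapFrac = 0.5, seed = 9)
  expect_equal(nrow(abundance(val2$fluid$proteome)),
               ceiling(0.5 * length(sim$truth$module_of_protein)))

  fl <- sampleData(val$fluid$proteome)
  st <- classifyAbetaCSF(fl$csf_abeta_ratio)
  expect_true(all(fl$csf_abeta_ratio[st == "pos"] < 0.061))
  expect_true(all(fl$csf_abeta_ratio[st == "neg"] >= 0.061))

  bp <- sampleData(val$biopsy$proteome)
  groups <- assignGroups(bp, basis = "biopsy")
  expect_true(all(bp$biopsy_tangles[groups$at_group == "A+T+"]))
})
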