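test_that("Spearman tables match the closed-form rank statistic and its invariances", {
  set.seed(30)
  eps <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("ME1", "ME2")))
  biom <- data.frame(b1 = rnorm(20), b2 = rnorm(20))
  tab <- spearmanBonferroni(eps, biom)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$p_bonferroni >= tab$p))
  expect_equal(tab$p_bonferroni, pmin(1, tab$p * 4))
  # untied data: rho equals 1 - 6 sum d^2 / (n (n^2-1))
  for (i in seq_len(nrow(tab))) {
    x <- eps[, tab$module[i]]; y <- biom[[tab$biomarker[i]]]
    d <- rank(x) - rank(y)
    expect_equal(tab$rho[i], 1 - 6 * sum(d^2) / (20 * 399), tolerance = 1e-12)
  }
  # invariance to strictly monotone transforms; antitonic pairs hit -1
  t2 <- spearmanBonferroni(eps, data.frame(b1 = exp(biom$b1)))
  expect_equal(t2$rho, tab$rho[tab$biomarker == "b1"], tolerance = 1e-12)
  t3 <- spearmanBonferroni(cbind(ME1 = eps[, 1]),
                           data.frame(neg = -eps[, 1]^3))
  expect_equal(t3$rho, -1)
  expect_warning(
    spearmanBonferroni(cbind(ME1 = eps[, 1]),
                       data.frame(flat = rep(1, 20), b1 = biom$b1)),
    "constant")
})

test_that("moderated fit reduces to ordinary t at zero prior df and matches limma", {
  set.seed(31)
  n <- 50; p <- 120
  grp <- rep(c("g1", "g0"), each = n / 2)
  age <- rnorm(n, 70, 5); sex <- sample(c("F", "M"), n, TRUE)
  m <- matrix(rnorm(p * n, sd = rep(sqrt(rchisq(p, 6) / 6), n)), p, n,
              dimnames = list(paste0("P", 1:p), paste0("S", 1:n)))
  cov <- data.frame(age = age, sex = sex)

  plain <- fitModeratedLM(m, grp, c("g1", "g0"), cov, minObs = 20,
                          priorDf = 0)
  for (i in c(1, 50, 120)) {
    fit <- lm(m[i, ] ~ factor(grp, levels = c("g0", "g1")) + age +
                factor(sex))
    cf <- summary(fit)$coefficients[2, ]
    expect_equal(plain$log2_fc[i], unname(cf["Estimate"]), tolerance = 1e-8)
    expect_equal(plain$t_moderated[i], unname(cf["t value"]),
                 tolerance = 1e-8)
    expect_equal(plain$p[i], unname(cf["Pr(>|t|)"]), tolerance = 1e-8)
  }

  mod <- fitModeratedLM(m, grp, c("g1", "g0"), cov, minObs = 20)
  eb <- attr(mod, "eb")
  lf <- limma::lmFit(m, stats::model.matrix(
    ~ factor(grp, levels = c("g0", "g1")) + age + factor(sex)))
  lb <- limma::eBayes(lf)
  expect_equal(eb$df_prior, lb$df.prior, tolerance = 0.05)
  expect_equal(eb$var_prior, lb$s2.prior, tolerance = 0.05)
  expect_gt(cor(mod$t_moderated, lb$t[mod$protein, 2]), 0.9999)
})

test_that("posterior variances are shrunk between sample and prior variance", {
  set.seed(32)
  m <- matrix(rnorm(80 * 40, sd = rep(runif(80, 0.5, 2), 40)), 80, 40,
              dimnames = list(paste0("P", 1:80), paste0("S", 1:40)))
  grp <- rep(c("a", "b"), 20)
  mod <- fitModeratedLM(m, grp, c("a", "b"), minObs = 10)
  eb <- attr(mod, "eb")
  gf <- factor(grp, levels = c("b", "a"))
  for (i in c(1, 25, 80)) {
    s2 <- sum(lm(m[i, ] ~ gf)$residuals^2) / 38
    row <- mod[mod$protein == paste0("P", i), ]
    # recover posterior s2 from se and the known unscaled SE sqrt(2/20)
    post <- (row$se / sqrt(2 / 20))^2
    expect_gte(post, min(s2, eb$var_prior) - 1e-10)
    expect_lte(post, max(s2, eb$var_prior) + 1e-10)
  }
})

test_that("moderated tests control false discoveries and detect planted shifts", {
  # null: average BH discovery rate at most 5%
  rates <- vapply(1:3, function(s) {
    set.seed(s)
    m <- matrix(rnorm(200 * 60, sd = 0.5), 200, 60,
                dimnames = list(paste0("P", 1:200), paste0("S", 1:60)))
    grp <- rep(c("a", "b"), each = 30)
    mean(fitModeratedLM(m, grp, c("a", "b"), minObs = 20)$p_adj < 0.05)
  }, numeric(1))
  expect_lte(mean(rates), 0.05)

  # power: 1 log2-unit shift, n = 30/group, sd 0.5
  recalls <- vapply(1:3, function(s) {
    set.seed(100 + s)
    m <- matrix(rnorm(300 * 60, sd = 0.5), 300, 60,
                dimnames = list(paste0("P", 1:300), paste0("S", 1:60)))
    grp <- rep(c("a", "b"), each = 30)
    m[1:50, grp == "a"] <- m[1:50, grp == "a"] + 1
    tab <- fitModeratedLM(m, grp, c("a", "b"), minObs = 20)
    mean(tab$p_adj[match(paste0("P", 1:50), tab$protein)] < 0.05)
  }, numeric(1))
  expect_true(all(recalls >= 0.9))
})

test_that("BH and Bonferroni agree with their brute-force definitions", {
  set.seed(33)
  p <- runif(1000)
  bh <- p.adjust(p, "BH")
  # brute force: min over j >= i of n p_(j) / j
  o <- order(p)
  n <- length(p)
  brute <- numeric(n)
  sorted <- p[o] * n / seq_len(n)
  brute[o] <- pmin(1, rev(cummin(rev(sorted))))
  expect_equal(bh, brute, tolerance = 1e-12)
  expect_equal(p.adjust(p, "bonferroni"), pmin(1, p * n), tolerance = 1e-12)
})

test_that("Tukey contrasts equal the model t-test with two groups and flag planted pairs", {
  set.seed(34)
  y <- rnorm(40); g <- rep(c("a", "b"), each = 20)
  cov <- data.frame(age = rnorm(40, 70, 5))
  tt <- groupContrastTukey(y, g, cov)
  fit <- lm(y ~ factor(g) + age, data = cbind(data.frame(y = y, g = g), cov))
  expect_equal(tt$p_tukey, summary(fit)$coefficients["factor(g)b", 4],
               tolerance = 1e-6)
  expect_equal(tt$p_unadj, tt$p_tukey, tolerance = 1e-6)

  # identical group values: adjusted p exactly 1
  y0 <- rep(c(1, 2, 3, 4, 5), 4)
  g0 <- rep(c("a", "b"), each = 10)
  expect_equal(groupContrastTukey(y0, g0)$p_tukey, 1)

  # matches TukeyHSD on a balanced 3-group design without covariates
  set.seed(35)
  y3 <- rnorm(45); g3 <- rep(c("a", "b", "c"), each = 15)
  tt3 <- groupContrastTukey(y3, g3)
  hsd <- TukeyHSD(aov(y3 ~ g3))$g3
  expect_equal(sort(tt3$p_tukey), unname(sort(hsd[, "p adj"])),
               tolerance = 1e-8)

  # planted means (0, 0, 1): exactly the two pairs involving group 3
  for (s in 1:3) {
    set.seed(200 + s)
    y <- c(rnorm(20, 0, 0.5), rnorm(20, 0, 0.5), rnorm(20, 1, 0.5))
    g <- rep(c("g1", "g2", "g3"), each = 20)
    res <- groupContrastTukey(y, g)
    sig <- res$p_tukey < 0.05
    involves3 <- res$group1 == "g3" | res$group2 == "g3"
    expect_identical(sig, involves3)
  }
})

test_that("dual-PET models attribute signal to the generating predictor", {
  set.seed(36)
  n <- 120
  meta <- data.frame(
    sample_id = paste0("S", 1:n),
    abeta_pet_suvr = runif(n, 1.0, 2.5),
    tau_pet_suvr = runif(n, 0.8, 2.2),
    age = rnorm(n, 70, 6), sex = sample(c("F", "M"), n, TRUE),
    diagnosis = sample(c("CU", "MCI", "AD"), n, TRUE))
  m <- rbind(
    abeta_only = 0.8 * meta$abeta_pet_suvr + rnorm(n, 0, 0.3),
    both = 0.6 * meta$abeta_pet_suvr + 0.6 * meta$tau_pet_suvr +
      rnorm(n, 0, 0.3),
    noise = rnorm(n))
  colnames(m) <- meta$sample_id
  tab <- dualPETModel(m, meta, minObs = 20)
  expect_lt(tab$p_adj_abeta[tab$protein == "abeta_only"], 0.05)
  expect_gt(tab$p_adj_tau[tab$protein == "abeta_only"], 0.05)
  expect_lt(tab$p_adj_abeta[tab$protein == "both"], 0.05)
  expect_lt(tab$p_adj_tau[tab$protein == "both"], 0.05)
  expect_gt(tab$p_adj_abeta[tab$protein == "noise"], 0.05)
  expect_gt(tab$p_adj_tau[tab$protein == "noise"], 0.05)
})

test_that("eigenprotein projection is faithful in-cohort and across cohorts", {
  sim <- simulateCohort(nPerStage = rep(10L, 7), seed = 21)
  norm <- filterMissingness(dropReferenceChannels(normalizeTMT(sim$proteome)))
  net <- buildNetwork(norm)
  ctrl <- sampleData(norm)$is_control
  eps <- eigenproteins(net$summary)
  for (mcol in colnames(eps)) {
    pr <- projectEigenprotein(norm, net$summary, mcol, controlMask = ctrl)
    expect_gte(abs(cor(pr$values, eps[, mcol])), 0.95)
    z <- pr$z_to_controls[ctrl]
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sd(z), 1, tolerance = 1e-9)
    expect_true(all(pr$coverage_frac <= 1, pr$coverage_frac > 0))
  }
  val <- simulateValidationCohorts(sim$truth, overlapFrac = 0.7, seed = 22)
  fl <- val$fluid
  pr <- projectEigenprotein(fl$proteome, net$summary, "ME1",
                            controlMask = sampleData(fl$proteome)$is_control)
  expect_gte(max(abs(cor(pr$values, fl$latent))), 0.85)

  expect_error(projectEigenprotein(abundance(fl$proteome)[1:2, ],
                                   net$summary, "ME1",
                                   controlMask = rep(TRUE, 140)),
               "need >= 3")
})

test_that("volcano tables join labels and significance flags consistently", {
  diff <- data.frame(protein = c("P1", "P2", "P3"),
                     contrast = "x - y",
                     log2_fc = c(1, -0.5, 0.2),
                     se = 0.1, t_moderated = 1, df_total = 10,
                     p = c(0.001, 0.03, 0.4),
                     p_adj = c(0.01, 0.2, 0.8),
                     adj_method = "BH", n_obs = 30)
  v <- volcanoTable(diff, labels = c(P1 = 2L, P3 = 1L))
  expect_identical(v$module, c(2L, 0L, 1L))
  expect_identical(v$significance,
                   c("up, adjusted", "down, unadjusted", "ns"))
  expect_equal(nrow(v), nrow(diff))
})
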