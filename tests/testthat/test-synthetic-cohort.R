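# Genotype, phenotype and partition simulation: determinism, allele
# frequencies, LD structure against independent Monte-Carlo, and the causal
# chain encoded by the phenotype model.

test_that("locus and model constructors reject malformed inputs", {
  expect_error(locus_spec("l", "1", 100, 2000, 5, maf_range = c(0, 0.5)),
               "maf_range")
  expect_error(locus_spec("l", "1", 100, 2000, 5, maf_range = c(0.1, 0.6)),
               "maf_range")
  expect_error(locus_spec("l", "1", 2000, 100, 5), "end_bp")
  expect_error(locus_spec("l", "1", 100, 2000, 5, causal_indices = 6,
                          causal_effects = 0.1), "causal_indices")
  expect_error(locus_spec("l", "1", 100, 2000, 5, causal_indices = 1,
                          causal_effects = c(0.1, 0.2)), "causal_effects")
  expect_error(simulate_genotypes(fixture_locus(), 1, seed = 1),
               "n_individuals")
  expect_error(phenotype_model("E", metabolite_loadings = matrix(1, 2, 1),
                               metabolite_noise_sd = 0), "noise_sd")
})

test_that("genotype simulation is deterministic given the seed and leaves the global RNG alone", {
  spec <- fixture_locus()
  set.seed(999)
  before <- .Random.seed
  g1 <- simulate_genotypes(spec, 500, seed = 7)
  expect_identical(before, .Random.seed)
  g2 <- simulate_genotypes(spec, 500, seed = 7)
  expect_identical(g1, g2)
  g3 <- simulate_genotypes(spec, 500, seed = 8)
  expect_false(identical(g1$dosages, g2$dosages) &&
                 identical(g1$dosages, g3$dosages))
  expect_true(all(g1$dosages %in% 0:2))
  expect_false(anyDuplicated(g1$variants$SNP) > 0)
  expect_true(all(diff(g1$variants$POS) > 0))
})

test_that("empirical allele frequencies match the specification", {
  spec <- fixture_locus()
  g <- simulate_genotypes(spec, 20000, seed = 11)
  eaf <- colMeans(g$dosages) / 2
  se_binom <- sqrt(spec$mafs * (1 - spec$mafs) / (2 * 20000))
  expect_true(all(abs(eaf - spec$mafs) < 3.5 * se_binom))
})

test_that("independent variants (rho = 0) have adjacent dosage correlation near zero", {
  spec <- locus_spec("ind", "2", 1e5, 2e5, n_variants = 6,
                     maf_range = c(0.2, 0.4), ld_decay_rho = 0)
  g <- simulate_genotypes(spec, 50000, seed = 3)
  adj <- sapply(1:5, function(j) cor(g$dosages[, j], g$dosages[, j + 1]))
  expect_true(all(abs(adj) < 0.02))
})

test_that("AR(1) dosage LD matches an independent Monte-Carlo oracle", {
  rho <- 0.8
  spec <- locus_spec("ld", "2", 1e5, 2e5, n_variants = 5,
                     maf_range = c(0.3, 0.3001), ld_decay_rho = rho)
  # oracle: direct threshold-model Monte-Carlo over 10 replicate seeds
  oracle <- mean(sapply(1:10, function(s) {
    oracle_adjacent_dosage_cor(rho, 0.3, 0.3, 50000, seed = 1000 + s)
  }))
  g <- simulate_genotypes(spec, 50000, seed = 21)
  adj <- mean(sapply(1:4, function(j) cor(g$dosages[, j], g$dosages[, j + 1])))
  expect_lt(abs(adj - oracle), 0.02)
  # analytic pairwise covariance agrees with the empirical one
  V <- targetmr:::locus_dosage_cov(spec)
  emp <- cov(g$dosages)
  expect_lt(max(abs(V - emp)), 0.02)
})

test_that("latent LD decays as rho^|i-j|", {
  rho <- 0.7
  spec <- locus_spec("dec", "3", 1e5, 2e5, n_variants = 8,
                     maf_range = c(0.25, 0.35), ld_decay_rho = rho)
  g <- simulate_genotypes(spec, 50000, seed = 5)
  # dosage correlations must be monotone decreasing in distance on average
  cm <- cor(g$dosages)
  by_lag <- sapply(1:4, function(lag) {
    mean(cm[cbind(1:(8 - lag), (1 + lag):8)])
  })
  expect_true(all(diff(by_lag) < 0))
})

test_that("null genetic effects give no genotype-exposure correlation", {
  spec <- locus_spec("nul", "4", 1e5, 2e5, n_variants = 5,
                     maf_range = c(0.2, 0.4), ld_decay_rho = 0.5,
                     causal_indices = c(1, 3), causal_effects = c(0, 0),
                     exposure = "E")
  model <- phenotype_model("E")
  g <- simulate_genotypes(spec, 50000, seed = 2)
  ph <- simulate_phenotypes(g$dosages, list(spec), model, seed = 3)
  cors <- abs(cor(g$dosages, ph$E))
  expect_true(all(cors < 0.02))
})

test_that("exposures are standardised and ground-truth effects are recovered empirically", {
  spec <- fixture_locus(effect_scale = 1.5)
  model <- phenotype_model("LDL")
  g <- simulate_genotypes(spec, 50000, seed = 13)
  ph <- simulate_phenotypes(g$dosages, spec, model, seed = 14)
  expect_lt(abs(sd(ph$LDL) - 1), 0.02)
  truth <- attr(ph, "truth")
  # per-allele regression slope of the exposure on a causal dosage should
  # match the marginal ground truth (direct effect + LD with neighbours)
  V <- targetmr:::locus_dosage_cov(spec)
  marg <- drop(V[, spec$causal_indices] %*% truth$gamma$gamma_std) / diag(V)
  for (j in seq_along(spec$causal_indices)) {
    ci <- spec$causal_indices[j]
    slope <- cov(g$dosages[, ci], ph$LDL) / var(g$dosages[, ci])
    expect_lt(abs(slope - marg[ci]), 0.02)
  }
})

test_that("disease prevalence matches the intercept chosen by logistic-normal integration", {
  model <- fixture_disease_model(theta = 0.5, prevalence = 0.20, exposure = "E")
  spec <- locus_spec("prv", "1", 1e5, 2e5, n_variants = 3,
                     maf_range = c(0.2, 0.4), causal_indices = 1,
                     causal_effects = 0.1, exposure = "E")
  prev <- sapply(1:10, function(s) {
    g <- simulate_genotypes(spec, 10000, seed = 50 + s)
    ph <- simulate_phenotypes(g$dosages, spec, model, seed = 150 + s)
    mean(ph$disease)
  })
  expect_lt(abs(mean(prev) - 0.20), 0.01)
})

test_that("metabolites approach their exposure as loading dominates noise", {
  spec <- fixture_locus()
  A <- matrix(1, 1, 1, dimnames = list("m1", "LDL"))
  model <- phenotype_model("LDL", metabolite_loadings = A,
                           metabolite_noise_sd = 1e-4)
  g <- simulate_genotypes(spec, 2000, seed = 4)
  ph <- simulate_phenotypes(g$dosages, spec, model, seed = 5)
  expect_gt(cor(ph$m1, ph$LDL), 0.9999)
})

test_that("without pleiotropy, metabolites are independent of genotype given the exposures", {
  spec <- fixture_locus()
  A <- matrix(0.6, 2, 1, dimnames = list(c("m1", "m2"), "LDL"))
  model <- phenotype_model("LDL", metabolite_loadings = A,
                           metabolite_noise_sd = 0.8)
  g <- simulate_genotypes(spec, 50000, seed = 6)
  ph <- simulate_phenotypes(g$dosages, spec, model, seed = 7)
  rm_expo <- function(v) residuals(lm(v ~ ph$LDL))
  m_res <- rm_expo(ph$m1)
  pc <- abs(cor(apply(g$dosages[, spec$causal_indices], 2, rm_expo), m_res))
  expect_true(all(pc < 0.02))
})

test_that("pleiotropic direct effects do reach metabolites", {
  spec <- fixture_locus()
  A <- matrix(0, 1, 1, dimnames = list("m1", "LDL"))
  snp <- sprintf("%s_v%02d", spec$locus_id, 5)
  D <- matrix(0.3, 1, 1, dimnames = list("m1", snp))
  model <- phenotype_model("LDL", metabolite_loadings = A,
                           metabolite_noise_sd = 0.5,
                           pleiotropy_effects = D)
  g <- simulate_genotypes(spec, 20000, seed = 8)
  ph <- simulate_phenotypes(g$dosages, spec, model, seed = 9)
  expect_gt(cor(g$dosages[, snp], ph$m1), 0.2)
})

test_that("split_cohort partitions are exact, disjoint, exhaustive and deterministic", {
  spec <- locus_spec("sp", "1", 1e5, 2e5, n_variants = 3,
                     maf_range = c(0.2, 0.4))
  model <- phenotype_model("E")
  cohort <- simulate_cohort(spec, model, 1000, fractions = c(a = 0.7, b = 0.2,
                                                             c = 0.1),
                            seed = 30)
  expect_equal(unname(table(cohort$partition)[c("a", "b", "c")]),
               c(700, 200, 100), ignore_attr = TRUE)
  expect_false(anyNA(cohort$partition))
  c2 <- split_cohort(cohort, c(a = 0.5, b = 0.5), seed = 9)
  c3 <- split_cohort(cohort, c(a = 0.5, b = 0.5), seed = 9)
  expect_identical(c2$partition, c3$partition)
  expect_equal(sum(c2$partition == "a"), 500)
  expect_error(split_cohort(cohort, c(0.6, 0.5), seed = 1), "sum to 1")
})

test_that("confounder switch induces exposure correlation absent from the default", {
  specs <- list(
    locus_spec("cA", "1", 1e5, 2e5, 3, maf_range = c(0.2, 0.4),
               causal_indices = 1, causal_effects = 0.2, exposure = "E1"),
    locus_spec("cB", "2", 1e5, 2e5, 3, maf_range = c(0.2, 0.4),
               causal_indices = 1, causal_effects = 0.2, exposure = "E2")
  )
  g <- do.call(cbind, lapply(seq_along(specs), function(i) {
    simulate_genotypes(specs[[i]], 20000, seed = 60 + i)$dosages
  }))
  ph0 <- simulate_phenotypes(g, specs, phenotype_model(c("E1", "E2")), seed = 70)
  ph1 <- simulate_phenotypes(g, specs,
                             phenotype_model(c("E1", "E2"), confounder_sd = 1),
                             seed = 70)
  expect_lt(abs(cor(ph0$E1, ph0$E2)), 0.03)
  expect_gt(cor(ph1$E1, ph1$E2), 0.3)
})
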