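# Rank-based inverse normal transform, the per-variant association scan
# against a closed-form least-squares oracle, calibration under the null,
# and hit/locus counting.

test_that("rank inverse normal transform matches direct quantile evaluation", {
  out <- rank_inverse_normal(c(5, 1, 9))
  q <- qnorm((1 - 0.375) / (3 - 2 * 0.375 + 1))
  expect_equal(out[1], 0)            # median rank maps exactly to 0
  expect_equal(out[2], q)
  expect_equal(out[3], -q)
  expect_equal(mean(out), 0, tolerance = 1e-12)
})

test_that("transform is rank-idempotent, preserves missing values and handles ties", {
  x <- c(3.2, NA, -1, 7, 7, 0.5, NA, 12)
  t1 <- rank_inverse_normal(x)
  t2 <- rank_inverse_normal(t1)
  expect_equal(t1, t2)
  expect_identical(is.na(t1), is.na(x))
  expect_equal(t1[4], t1[5])         # tied values share the mean rank
  expect_error(rank_inverse_normal(rep(2, 10)), "identical")
  expect_error(rank_inverse_normal(c(1, NA, NA)), "3 non-missing")
})

test_that("transformed samples have near-unit SD for n >= 100", {
  for (s in 1:5) {
    x <- withr::with_seed(s, rexp(100 + 37 * s))
    expect_lt(abs(sd(rank_inverse_normal(x)) - 1), 0.05)
  }
})

test_that("linear scan equals closed-form joint least squares and recovers the slope", {
  spec <- locus_spec("olsA", "5", 9e5, 9.5e5, n_variants = 3,
                     maf_range = c(0.25, 0.35), ld_decay_rho = 0.3,
                     causal_indices = 2, causal_effects = 0.4,
                     exposure = "E")
  model <- phenotype_model("E")
  cohort <- simulate_cohort(spec, model, 20000,
                            fractions = c(discovery = 1), seed = 77)
  stats <- gwas_scan(cohort, "E", family = "linear")
  # oracle: explicit normal-equations solve on the transformed trait
  rows <- targetmr::partition_rows(cohort, "discovery")
  y <- rank_inverse_normal(cohort$phenotypes$E[rows])
  C <- as.matrix(cohort$covariates[rows, c("age", "sex", "fasting", "chip")])
  for (j in 1:3) {
    oc <- oracle_ols(y, cohort$genotypes[rows, j], C)
    expect_equal(stats$BETA[j], oc$beta, tolerance = 1e-10)
    expect_equal(stats$SE[j], oc$se, tolerance = 1e-10)
  }
  # causal slope recovered within 3 SEs of the marginal ground truth
  truth <- cohort$truth$gamma$gamma_std
  V <- targetmr:::locus_dosage_cov(spec)
  marg <- drop(V[, spec$causal_indices, drop = FALSE] %*% truth) / diag(V)
  expect_true(all(abs(stats$BETA - marg) < 3 * stats$SE))
})

test_that("multi-trait scan is numerically identical to per-trait scans", {
  spec <- fixture_locus()
  A <- matrix(c(0.5, 0.1, 0.8), 3, 1,
              dimnames = list(c("m1", "m2", "m3"), "LDL"))
  model <- phenotype_model("LDL", metabolite_loadings = A,
                           metabolite_noise_sd = 0.7)
  cohort <- simulate_cohort(spec, model, 4000,
                            fractions = c(discovery = 0.5, outcome = 0.5),
                            seed = 5)
  multi <- gwas_scan_multi(cohort, c("m1", "m2", "m3"), partition = "outcome")
  for (tr in c("m1", "m2", "m3")) {
    single <- gwas_scan(cohort, tr, family = "linear", partition = "outcome")
    expect_equal(multi[[tr]]$BETA, single$BETA, tolerance = 1e-12)
    expect_equal(multi[[tr]]$SE, single$SE, tolerance = 1e-12)
  }
})

test_that("scan P values are calibrated under a fully null trait", {
  reps <- 200
  pvals <- unlist(lapply(seq_len(reps), function(r) {
    spec <- locus_spec("nullcal", "1", 1e5, 1e6, n_variants = 100,
                       maf_range = c(0.1, 0.45), ld_decay_rho = 0)
    model <- phenotype_model("E")
    cohort <- simulate_cohort(spec, model, 800,
                              fractions = c(discovery = 1), seed = 3000 + r)
    gwas_scan(cohort, "E", family = "linear")$P
  }))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.02)
})

test_that("an extra covariate orthogonal to the dosages leaves beta unchanged", {
  spec <- fixture_locus()
  cohort <- simulate_cohort(spec, phenotype_model("LDL"), 3000,
                            fractions = c(discovery = 1), seed = 12)
  base_cov <- c("age", "sex", "fasting", "chip")
  rows <- targetmr::partition_rows(cohort, "discovery")
  X <- cbind(1, as.matrix(cohort$covariates[rows, base_cov]),
             cohort$genotypes[rows, ])
  raw <- withr::with_seed(1, rnorm(length(rows)))
  ortho <- residuals(lm(raw ~ X - 1))
  cohort$covariates$ortho <- ortho
  s0 <- gwas_scan(cohort, "LDL", covariates = base_cov)
  s1 <- gwas_scan(cohort, "LDL", covariates = c(base_cov, "ortho"))
  expect_equal(s0$BETA, s1$BETA, tolerance = 1e-8)
})

test_that("swapping effect and other allele labels flips beta exactly", {
  spec <- fixture_locus()
  cohort <- simulate_cohort(spec, phenotype_model("LDL"), 3000,
                            fractions = c(discovery = 1), seed = 19)
  s0 <- gwas_scan(cohort, "LDL")
  flipped <- cohort
  flipped$genotypes <- 2 - flipped$genotypes
  ea <- flipped$variants$EA
  flipped$variants$EA <- flipped$variants$NEA
  flipped$variants$NEA <- ea
  flipped$variants$EAF <- 1 - flipped$variants$EAF
  s1 <- gwas_scan(flipped, "LDL")
  expect_equal(s1$BETA, -s0$BETA, tolerance = 1e-10)
  expect_equal(s1$SE, s0$SE, tolerance = 1e-10)
})

test_that("logistic scan recovers a marginal disease effect and flags monomorphic variants", {
  spec <- locus_spec("logA", "5", 9e5, 9.5e5, n_variants = 4,
                     maf_range = c(0.25, 0.4), ld_decay_rho = 0,
                     causal_indices = 1, causal_effects = 0.5, exposure = "E")
  model <- fixture_disease_model(theta = 0.6, prevalence = 0.3, exposure = "E")
  cohort <- simulate_cohort(spec, model, 12000,
                            fractions = c(discovery = 1), seed = 23)
  cohort$genotypes <- cbind(cohort$genotypes, mono = 0L)
  cohort$variants <- rbind(cohort$variants,
                           data.frame(SNP = "mono", CHR = "5", POS = 960000,
                                      EA = "A", NEA = "G", EAF = 0))
  stats <- gwas_scan(cohort, "disease", family = "logistic")
  expect_gt(stats$BETA[1], 0)
  expect_lt(stats$P[1], 1e-3)
  expect_equal(stats$BETA[5], 0)
  expect_true(is.na(stats$SE[5]))
  # binary check
  expect_error(gwas_scan(cohort, "E", family = "logistic"), "binary")
})

test_that("hit and locus counting follows the greedy clustering rule", {
  none <- make_stats(pos = c(1000, 2000), p = c(0.5, 0.9))
  expect_equal(count_gwas_hits(none, threshold = 5e-8),
               list(n_hits = 0L, n_loci = 0L))
  three <- make_stats(pos = c(1000, 2000, 900000), p = c(1e-10, 1e-9, 1e-12))
  res <- count_gwas_hits(three, threshold = 5e-8, locus_window_bp = 500000)
  expect_equal(res$n_hits, 3L)
  expect_equal(res$n_loci, 2L)
  dup <- make_stats(pos = c(5000, 5000), p = c(1e-10, 1e-9),
                    snp = c("a", "b"))
  expect_equal(count_gwas_hits(dup, locus_window_bp = 0)$n_loci, 1L)
  # different chromosomes never share a locus
  twochr <- make_stats(pos = c(1000, 1000), p = c(1e-10, 1e-10),
                       chr = c("1", "2"), snp = c("a", "b"))
  expect_equal(count_gwas_hits(twochr)$n_loci, 2L)
})
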