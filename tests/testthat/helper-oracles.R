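# Independent oracles and small fixture builders shared across test files.
# Oracles deliberately use direct, explicit formulations (plain matrix
# inversion, hand-coded step-up rules, direct Monte-Carlo) so they stay
# independent of the implementation paths they check.

# Explicit generalised-least-squares solve for the correlated-instrument
# IVW: plain solve() on the normal equations.
oracle_gls <- function(beta_x, beta_y, se_y, rho) {
  omega <- outer(se_y, se_y) * rho
  oi <- solve(omega)
  prec <- drop(t(beta_x) %*% oi %*% beta_x)
  list(theta = drop(t(beta_x) %*% oi %*% beta_y) / prec,
       se = sqrt(1 / prec))
}

# Inverse-variance weighted mean of per-instrument Wald ratios.
oracle_ivw <- function(beta_x, beta_y, se_y) {
  w <- beta_x^2 / se_y^2
  ratios <- beta_y / beta_x
  list(theta = sum(w * ratios) / sum(w), se = sqrt(1 / sum(w)))
}

# Hand-coded Benjamini-Hochberg step-up: find the largest i with
# p_(i) <= i/m * alpha and reject everything at or below it.
oracle_bh_discoveries <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= seq_len(m) / m * alpha)
  rej <- logical(m)
  if (length(below)) rej[o[seq_len(max(below))]] <- TRUE
  rej
}

# Direct Monte-Carlo of the adjacent-variant dosage correlation implied by
# the latent AR(1) threshold model: sample correlated standard-normal pairs
# per haplotype, threshold at the MAF quantiles, sum two haplotypes.
oracle_adjacent_dosage_cor <- function(rho, maf1, maf2, n, seed) {
  set.seed(seed)
  hap <- function() {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    cbind((z1 < qnorm(maf1)) * 1, (z2 < qnorm(maf2)) * 1)
  }
  d <- hap() + hap()
  cor(d[, 1], d[, 2])
}

# Closed-form joint least squares via the normal equations, for checking
# the Frisch-Waugh-Lovell scan.
oracle_ols <- function(y, g, C) {
  X <- cbind(1, g, C)
  xtx_inv <- solve(t(X) %*% X)
  b <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% b
  s2 <- sum(res^2) / (length(y) - ncol(X))
  list(beta = b[2], se = sqrt(s2 * xtx_inv[2, 2]))
}

# A random positive-semi-definite correlation matrix.
random_corr <- function(k) {
  A <- matrix(rnorm(k * k), k)
  S <- crossprod(A) + diag(k) * 0.05
  cov2cor(S)
}

# --- fixture builders -------------------------------------------------------

# One-locus AR(1) spec with a handful of causal variants; effect scale
# adjustable so tests can set instrument strength for their sample size.
fixture_locus <- function(effect_scale = 1, n_variants = 30, rho = 0.6,
                          exposure = "LDL", locus_id = "locA", chrom = "5") {
  locus_spec(locus_id, chrom, 900000, 1150000, n_variants = n_variants,
             maf_range = c(0.1, 0.45), ld_decay_rho = rho,
             causal_indices = c(5, 12, 20, 26),
             causal_effects = effect_scale * c(0.12, 0.10, -0.08, 0.09),
             exposure = exposure)
}

fixture_target <- function(exposure = "LDL", chrom = "5", window_kb = 100) {
  drug_target("TEST_TARGET", chrom, 1000000, 1050000, exposure,
              therapeutic_direction = -1, window_kb = window_kb)
}

# Disease-only phenotype model with a chosen causal log-odds per SD.
fixture_disease_model <- function(theta = -0.25, prevalence = 0.15,
                                  exposure = "LDL") {
  th <- matrix(theta, 1, 1, dimnames = list("disease", exposure))
  phenotype_model(
    exposure_names = exposure,
    disease_intercepts = disease_intercept_for_prevalence(prevalence, theta),
    disease_log_odds_per_exposure = th
  )
}

# Summary-stats table built by hand for selection / harmonisation tests.
make_stats <- function(pos, p, chr = "5", beta = 0.1, se = 0.02,
                       ea = "A", nea = "G", snp = NULL, n = 10000) {
  k <- length(pos)
  df <- data.frame(
    SNP = snp %||% sprintf("rs%03d", seq_len(k)),
    CHR = chr, POS = pos, EA = ea, NEA = nea, EAF = 0.3,
    BETA = rep_len(beta, k), SE = rep_len(se, k), P = rep_len(p, k),
    N = n, stringsAsFactors = FALSE
  )
  # keep P consistent with BETA/SE under the normal approximation
  df$BETA <- sign(df$BETA) * abs(qnorm(df$P / 2)) * df$SE
  summary_stats(df, trait_name = "fixture")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
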