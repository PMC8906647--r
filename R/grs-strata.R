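# Individual-level sensitivity analysis: weighted genetic risk scores per
# drug target, regressed on phenotypes within age strata. Stratifying on
# age rather than adjusting for age-linked treatments (e.g. statin use)
# avoids conditioning on a collider.

#' Define genetic risk score weights
#'
#' @param target_name label.
#' @param variant_ids ordered variant IDs.
#' @param weights per-variant weights (typically instrument-exposure betas,
#'   oriented to the therapeutic direction).
#' @param effect_alleles effect allele per variant (weights apply per copy).
#' @return an object of class `grs_weights`.
#' @export
grs_weights <- function(target_name, variant_ids, weights, effect_alleles) {
  k <- length(variant_ids)
  if (length(weights) != k || length(effect_alleles) != k) {
    stop("variant_ids, weights and effect_alleles must have equal length",
         call. = FALSE)
  }
  if (any(!is.finite(weights))) stop("weights must be finite", call. = FALSE)
  structure(list(target_name = target_name,
                 variant_ids = as.character(variant_ids),
                 weights = as.numeric(weights),
                 effect_alleles = as.character(effect_alleles)),
            class = "grs_weights")
}

#' Build GRS weights from a pruned instrument set
#'
#' Weights are the instrument-exposure betas multiplied by the target's
#' therapeutic direction, so higher scores correspond to the drug-mimicking
#' exposure change.
#'
#' @param iset an `instrument_set` from [select_instruments()].
#' @return a [grs_weights()].
#' @export
grs_weights_from <- function(iset) {
  stopifnot(inherits(iset, "instrument_set"), !is.null(iset$target))
  grs_weights(iset$target$target_name, iset$variants$SNP,
              iset$variants$BETA * iset$target$therapeutic_direction,
              iset$variants$EA)
}

#' Per-individual weighted genetic risk score
#'
#' `score_i = sum_j w_j * dosage_ij`, with dosages counted per copy of each
#' weight's stated effect allele: a genotype column whose effect allele is
#' the weight's other allele contributes `2 - dosage`. Sparse missing
#' dosages are mean-imputed (per variant, capped at 10% missingness);
#' more than 10% of weight variants absent from the genotypes is an error.
#'
#' @param cohort a `cohort_data` (or a dosage matrix; then `variants` must
#'   supply the `SNP`/`EA`/`NEA` table).
#' @param weights a [grs_weights()].
#' @param variants variant table when `cohort` is a bare matrix.
#' @return numeric score vector, one per individual.
#' @export
build_grs <- function(cohort, weights, variants = NULL) {
  stopifnot(inherits(weights, "grs_weights"))
  if (inherits(cohort, "cohort_data")) {
    G <- cohort$genotypes
    variants <- cohort$variants
  } else {
    G <- as.matrix(cohort)
    if (is.null(variants)) stop("`variants` table required", call. = FALSE)
  }
  present <- weights$variant_ids %in% colnames(G)
  if (mean(!present) > 0.10) {
    stop(sprintf("%d of %d weight variants absent from genotypes (> 10%%)",
                 sum(!present), length(present)), call. = FALSE)
  }
  if (any(!present)) {
    message(sum(!present), " weight variant(s) absent; omitted from the score")
  }
  ids <- weights$variant_ids[present]
  w <- weights$weights[present]
  ea <- weights$effect_alleles[present]
  vt <- variants[match(ids, variants$SNP), , drop = FALSE]
  X <- G[, ids, drop = FALSE]
  flip <- !is.na(vt$SNP) & ea == vt$NEA
  if (any(flip)) X[, flip] <- 2 - X[, flip]
  mismatch <- !is.na(vt$SNP) & ea != vt$EA & ea != vt$NEA
  if (any(mismatch)) {
    stop("effect allele not present at variant(s): ",
         paste(ids[mismatch], collapse = ", "), call. = FALSE)
  }
  n_missing <- colSums(is.na(X))
  if (any(n_missing > 0.10 * nrow(X))) {
    stop("variant(s) exceed 10% dosage missingness: ",
         paste(ids[n_missing > 0.10 * nrow(X)], collapse = ", "),
         call. = FALSE)
  }
  if (any(n_missing > 0)) {
    message(sum(n_missing), " missing dosage(s) mean-imputed")
    for (j in which(n_missing > 0)) {
      X[is.na(X[, j]), j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  drop(X %*% w)
}

#' Regress a phenotype on a genetic risk score within age strata
#'
#' Within each stratum the score is standardised to unit SD and the
#' (inverse-normal transformed) phenotype regressed on it with covariate
#' adjustment by least squares, so slopes are per SD of score. A two-sample
#' z statistic for the difference between the first two strata formalises
#' the visual comparison of stratum estimates.
#'
#' @param cohort a `cohort_data`.
#' @param scores per-individual score vector (whole cohort,
#'   from [build_grs()]).
#' @param phenotype phenotype column name.
#' @param covariates covariate column names (default age, sex and the 10
#'   principal components).
#' @param strata named list of inclusive age ranges; defaults to the
#'   youngest (40-54) and oldest (61-71) bands.
#' @param max_per_stratum optional cap: a random subsample of this size is
#'   drawn per stratum (seeded for reproducibility).
#' @param normalise apply [rank_inverse_normal()] to the phenotype within
#'   each stratum (default TRUE).
#' @param seed seed for the optional subsampling.
#' @return data frame `stratum n beta se p`, with attribute `z_diff`
#'   comparing the first two strata.
#' @export
strata_regression <- function(cohort, scores, phenotype,
                              covariates = c("age", "sex", paste0("PC", 1:10)),
                              strata = list(youngest = c(40, 54),
                                            oldest = c(61, 71)),
                              max_per_stratum = NULL, normalise = TRUE,
                              seed = 1L) {
  stopifnot(inherits(cohort, "cohort_data"))
  y_all <- cohort$phenotypes[[phenotype]]
  if (is.null(y_all)) stop("phenotype not found: ", phenotype, call. = FALSE)
  age <- cohort$covariates$age
  sub_seeds <- derive_seeds(seed, length(strata))
  rows <- lapply(seq_along(strata), function(i) {
    rng <- strata[[i]]
    idx <- which(age >= rng[1] & age <= rng[2])
    if (!length(idx)) {
      stop("empty stratum: ", names(strata)[i] %||% i, call. = FALSE)
    }
    if (!is.null(max_per_stratum) && length(idx) > max_per_stratum) {
      idx <- with_seed(sub_seeds[i], sample(idx, max_per_stratum))
    }
    if (length(idx) < length(covariates) + 3L) {
      stop("stratum too small for the covariate set: ",
           names(strata)[i] %||% i, call. = FALSE)
    }
    s <- scores[idx]
    if (sd(s) == 0) stop("score is constant within stratum", call. = FALSE)
    s <- (s - mean(s)) / sd(s)
    y <- y_all[idx]
    if (normalise) y <- rank_inverse_normal(y)
    C <- as.matrix(cohort$covariates[idx, covariates, drop = FALSE])
    fit <- lm(y ~ s + C)
    cf <- summary(fit)$coefficients["s", ]
    data.frame(stratum = names(strata)[i] %||% as.character(i),
               n = length(idx), beta = cf[1], se = cf[2],
               p = 2 * pnorm(-abs(cf[1] / cf[2])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (nrow(out) >= 2L) {
    z <- (out$beta[1] - out$beta[2]) / sqrt(out$se[1]^2 + out$se[2]^2)
    attr(out, "z_diff") <- z
    attr(out, "p_diff") <- 2 * pnorm(-abs(z))
  }
  out
}
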