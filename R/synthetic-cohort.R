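# Synthetic cohort generator: genotypes with AR(1) linkage disequilibrium,
# lipid-like exposures, a metabolite panel, covariates and binary disease
# outcomes with known ground-truth parameters, partitioned into
# non-overlapping samples for the two-sample MR design.

#' Define a genetic locus for simulation
#'
#' A locus is a set of variants on one chromosome with an AR(1) haplotype
#' correlation structure: the latent Gaussian correlation between variants
#' `i` and `j` is `ld_decay_rho^|i-j|`. A subset of variants is causal for
#' one named exposure, with per-allele effects `causal_effects` expressed in
#' (unstandardised) exposure units per effect allele.
#'
#' Variant positions are evenly spaced across `[start_bp, end_bp]` and
#' minor-allele frequencies evenly spaced across `maf_range`, so a spec fully
#' determines its variant table without randomness and the same variants are
#' obtained for every sample drawn from it.
#'
#' @param locus_id character label, used to form variant IDs.
#' @param chromosome chromosome label.
#' @param start_bp,end_bp integer bounds of the locus (base pairs).
#' @param n_variants number of variants (>= 1).
#' @param maf_range length-2 numeric in (0, 0.5]: range of minor-allele
#'   frequencies assigned across variants.
#' @param ld_decay_rho adjacent-variant latent haplotype correlation in
#'   `[0, 1)`.
#' @param causal_indices integer indices (1-based) of causal variants.
#' @param causal_effects per-allele exposure effects, one per causal index.
#' @param exposure name of the exposure this locus drives (matched against
#'   `exposure_names` of the [phenotype_model()]).
#' @return an object of class `locus_spec`.
#' @export
locus_spec <- function(locus_id, chromosome, start_bp, end_bp, n_variants,
                       maf_range = c(0.05, 0.5), ld_decay_rho = 0,
                       causal_indices = integer(), causal_effects = numeric(),
                       exposure = NA_character_) {
  assert_scalar_number(n_variants, "n_variants", lower = 1)
  assert_scalar_number(ld_decay_rho, "ld_decay_rho", lower = 0, upper = 1 - 1e-12)
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("`maf_range` must be an increasing pair within (0, 0.5]", call. = FALSE)
  }
  if (end_bp <= start_bp) stop("`end_bp` must exceed `start_bp`", call. = FALSE)
  if (end_bp - start_bp < n_variants - 1) {
    stop("locus too narrow for `n_variants` strictly increasing positions",
         call. = FALSE)
  }
  causal_indices <- as.integer(causal_indices)
  if (length(causal_effects) != length(causal_indices)) {
    stop("`causal_effects` must match `causal_indices` in length", call. = FALSE)
  }
  if (length(causal_indices) &&
      (any(causal_indices < 1L) || any(causal_indices > n_variants) ||
       anyDuplicated(causal_indices))) {
    stop("`causal_indices` must be unique indices in [1, n_variants]",
         call. = FALSE)
  }
  positions <- unique(round(seq(start_bp, end_bp, length.out = n_variants)))
  stopifnot(length(positions) == n_variants)
  mafs <- if (n_variants == 1L) mean(maf_range) else
    seq(maf_range[1], maf_range[2], length.out = n_variants)
  spec <- structure(list(
    locus_id = as.character(locus_id),
    chromosome = as.character(chromosome),
    start_bp = as.integer(start_bp), end_bp = as.integer(end_bp),
    n_variants = as.integer(n_variants),
    maf_range = maf_range, ld_decay_rho = ld_decay_rho,
    causal_indices = causal_indices,
    causal_effects = as.numeric(causal_effects),
    exposure = exposure,
    positions = as.integer(positions), mafs = mafs
  ), class = "locus_spec")
  spec
}

#' @export
print.locus_spec <- function(x, ...) {
  cat(sprintf("<locus_spec> %s: chr%s:%d-%d, %d variants, rho = %.2f, %d causal (exposure: %s)\n",
              x$locus_id, x$chromosome, x$start_bp, x$end_bp, x$n_variants,
              x$ld_decay_rho, length(x$causal_indices), x$exposure))
  invisible(x)
}

variant_table_for <- function(spec) {
  data.frame(
    SNP = sprintf("%s_v%02d", spec$locus_id, seq_len(spec$n_variants)),
    CHR = spec$chromosome,
    POS = spec$positions,
    EA = "A", NEA = "G",
    EAF = spec$mafs,
    stringsAsFactors = FALSE
  )
}

#' Simulate Hardy-Weinberg genotype dosages for one locus
#'
#' Each individual carries two independent haplotypes. A haplotype's alleles
#' arise from a latent standard-normal AR(1) process across variants with
#' adjacent correlation `ld_decay_rho`; the effect allele is carried when the
#' latent value falls below the minor-allele-frequency quantile, so the
#' effect-allele frequency equals the specified MAF and dosages are in
#' Hardy-Weinberg proportions by construction.
#'
#' @param spec a [locus_spec()].
#' @param n_individuals number of individuals (>= 2).
#' @param seed integer seed; the same spec and seed reproduce the matrix
#'   exactly.
#' @return list with `dosages` (individuals x variants integer matrix with
#'   values 0/1/2, columns named by variant ID) and `variants` (data frame
#'   with columns `SNP CHR POS EA NEA EAF`).
#' @export
simulate_genotypes <- function(spec, n_individuals, seed) {
  stopifnot(inherits(spec, "locus_spec"))
  if (!is.numeric(n_individuals) || length(n_individuals) != 1L ||
      n_individuals < 2) {
    stop("`n_individuals` must be a single count >= 2", call. = FALSE)
  }
  n <- as.integer(n_individuals)
  m <- spec$n_variants
  thr <- qnorm(spec$mafs)
  rho <- spec$ld_decay_rho
  with_seed(seed, {
    haplo <- function() {
      z <- matrix(0, n, m)
      z[, 1] <- rnorm(n)
      if (m > 1) {
        innov_sd <- sqrt(1 - rho^2)
        for (j in 2:m) z[, j] <- rho * z[, j - 1] + innov_sd * rnorm(n)
      }
      # allele indicator: latent below the MAF quantile
      sweep(z, 2, thr, `<`) * 1L
    }
    dos <- haplo() + haplo()
    vt <- variant_table_for(spec)
    colnames(dos) <- vt$SNP
    list(dosages = dos, variants = vt)
  })
}

# Analytic covariance of dosages among a subset of variants in one locus.
# Haplotype alleles are indicators of a latent AR(1) Gaussian falling below
# the MAF quantile, so Cov(b_i, b_j) = Phi2(q_i, q_j; rho^|i-j|) - p_i p_j
# and dosages (two independent haplotypes) carry twice that.
locus_dosage_cov <- function(spec, indices = seq_len(spec$n_variants)) {
  p <- spec$mafs[indices]
  q <- qnorm(p)
  k <- length(indices)
  V <- matrix(0, k, k)
  for (a in seq_len(k)) {
    V[a, a] <- 2 * p[a] * (1 - p[a])
    if (a < k) for (b in (a + 1):k) {
      r <- spec$ld_decay_rho^abs(indices[a] - indices[b])
      cab <- 2 * (pbinorm(q[a], q[b], r) - p[a] * p[b])
      V[a, b] <- V[b, a] <- cab
    }
  }
  V
}

#' Define the phenotype-generating model
#'
#' Encodes the causal chain variant -> exposure -> metabolite / disease that
#' drug-target MR assumes. Exposures are weighted sums of causal dosages plus
#' Gaussian noise, standardised by their analytic (model-implied) standard
#' deviation so that each exposure has unit variance in expectation and the
#' stated disease effects `disease_log_odds_per_exposure` are exact in
#' log-odds per 1 SD of exposure. Metabolites load linearly on the exposures;
#' optional `pleiotropy_effects` add direct variant -> metabolite paths.
#' Diseases are Bernoulli draws from a logistic model in the exposures.
#'
#' @param exposure_names character vector of exposure labels.
#' @param metabolite_loadings metabolite x exposure numeric matrix (row names
#'   become trait names), or NULL for no metabolite panel.
#' @param metabolite_noise_sd per-metabolite residual SD (> 0); recycled.
#' @param exposure_noise_sd per-exposure residual SD (> 0); recycled.
#' @param disease_intercepts named numeric vector of logistic intercepts.
#' @param disease_log_odds_per_exposure disease x exposure matrix of causal
#'   log-odds per SD of exposure (row names become disease names).
#' @param pleiotropy_effects optional metabolite x variant matrix of direct
#'   effects (columns named by variant ID), or NULL.
#' @param confounder_sd SD of a shared latent confounder added to every
#'   exposure (0 disables; used for negative-control analyses).
#' @return an object of class `phenotype_model`.
#' @export
phenotype_model <- function(exposure_names,
                            metabolite_loadings = NULL,
                            metabolite_noise_sd = 1,
                            exposure_noise_sd = 1,
                            disease_intercepts = numeric(),
                            disease_log_odds_per_exposure = NULL,
                            pleiotropy_effects = NULL,
                            confounder_sd = 0) {
  k <- length(exposure_names)
  stopifnot(k >= 1)
  if (!is.null(metabolite_loadings)) {
    metabolite_loadings <- as.matrix(metabolite_loadings)
    if (ncol(metabolite_loadings) != k) {
      stop("`metabolite_loadings` must have one column per exposure",
           call. = FALSE)
    }
    if (is.null(rownames(metabolite_loadings))) {
      rownames(metabolite_loadings) <-
        sprintf("metab_%03d", seq_len(nrow(metabolite_loadings)))
    }
    metabolite_noise_sd <- rep_len(metabolite_noise_sd,
                                   nrow(metabolite_loadings))
    if (any(metabolite_noise_sd <= 0)) {
      stop("`metabolite_noise_sd` must be > 0", call. = FALSE)
    }
  }
  exposure_noise_sd <- rep_len(exposure_noise_sd, k)
  if (any(exposure_noise_sd <= 0)) {
    stop("`exposure_noise_sd` must be > 0", call. = FALSE)
  }
  if (!is.null(disease_log_odds_per_exposure)) {
    disease_log_odds_per_exposure <- as.matrix(disease_log_odds_per_exposure)
    if (ncol(disease_log_odds_per_exposure) != k) {
      stop("`disease_log_odds_per_exposure` must have one column per exposure",
           call. = FALSE)
    }
    if (is.null(rownames(disease_log_odds_per_exposure))) {
      rownames(disease_log_odds_per_exposure) <-
        sprintf("disease_%d", seq_len(nrow(disease_log_odds_per_exposure)))
    }
    if (length(disease_intercepts) != nrow(disease_log_odds_per_exposure)) {
      stop("`disease_intercepts` must match the disease count", call. = FALSE)
    }
  }
  assert_scalar_number(confounder_sd, "confounder_sd", lower = 0)
  structure(list(
    exposure_names = exposure_names,
    metabolite_loadings = metabolite_loadings,
    metabolite_noise_sd = metabolite_noise_sd,
    exposure_noise_sd = exposure_noise_sd,
    disease_intercepts = disease_intercepts,
    disease_log_odds_per_exposure = disease_log_odds_per_exposure,
    pleiotropy_effects = pleiotropy_effects,
    confounder_sd = confounder_sd
  ), class = "phenotype_model")
}

#' Choose a logistic intercept yielding a target disease prevalence
#'
#' Integrates the logistic mean over the standard-normal distribution of the
#' genetic liability `theta' E` (exposures are unit-variance and treated as
#' independent) and solves for the intercept by root finding.
#'
#' @param prevalence target population prevalence in (0, 1).
#' @param theta vector of log-odds-per-SD effects across exposures.
#' @return intercept (log-odds scale).
#' @export
disease_intercept_for_prevalence <- function(prevalence, theta) {
  assert_scalar_number(prevalence, "prevalence", lower = 1e-6, upper = 1 - 1e-6)
  s <- sqrt(sum(theta^2))
  f <- function(c0) {
    if (s < 1e-12) return(plogis(c0) - prevalence)
    integrate(function(x) plogis(c0 + s * x) * dnorm(x), -Inf, Inf,
              rel.tol = 1e-10)$value - prevalence
  }
  uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Simulate exposures, metabolites and disease outcomes from genotypes
#'
#' For each exposure `k`, the raw liability is the sum of causal dosage
#' effects across the loci assigned to that exposure, a shared latent
#' confounder (if enabled) and Gaussian noise; it is divided by its analytic
#' standard deviation (computed from the effect sizes, allele frequencies and
#' the AR(1) LD structure) so the exposure has unit variance in expectation
#' and ground-truth effects are exact. Metabolites are linear in the
#' exposures plus optional direct variant effects and noise; diseases are
#' Bernoulli draws from a logistic model in the exposures.
#'
#' @param genotypes dosage matrix with columns named by variant ID (as from
#'   [simulate_genotypes()], possibly column-bound across loci).
#' @param specs list of [locus_spec()] objects covering all causal variants.
#' @param model a [phenotype_model()].
#' @param seed integer seed.
#' @return data frame of phenotypes (exposures, metabolites, diseases), with
#'   attribute `truth` holding the ground-truth parameters actually realised:
#'   per-variant standardised exposure effects, exposure SDs, disease effects
#'   and analytic metabolite SDs.
#' @export
simulate_phenotypes <- function(genotypes, specs, model, seed) {
  stopifnot(inherits(model, "phenotype_model"))
  if (inherits(specs, "locus_spec")) specs <- list(specs)
  n <- nrow(genotypes)
  k <- length(model$exposure_names)
  spec_expo <- vapply(specs, function(s) s$exposure, character(1))
  unknown <- setdiff(spec_expo[!is.na(spec_expo)], model$exposure_names)
  if (length(unknown)) {
    stop("locus exposure(s) not in the model: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (s in specs) {
    ids <- variant_table_for(s)$SNP[s$causal_indices]
    if (!all(ids %in% colnames(genotypes))) {
      stop("genotype columns do not cover causal variants of locus ", s$locus_id,
           call. = FALSE)
    }
  }
  with_seed(seed, {
    U <- if (model$confounder_sd > 0) rnorm(n) else numeric(n)
    E <- matrix(0, n, k, dimnames = list(NULL, model$exposure_names))
    gamma_std <- list()
    exposure_sd <- numeric(k)
    for (i in seq_len(k)) {
      nm <- model$exposure_names[i]
      raw <- rep(0, n)
      gvar <- 0
      for (s in specs[which(spec_expo == nm)]) {
        if (!length(s$causal_indices)) next
        vt <- variant_table_for(s)
        ids <- vt$SNP[s$causal_indices]
        G <- genotypes[, ids, drop = FALSE]
        centred <- sweep(G, 2, 2 * s$mafs[s$causal_indices])
        raw <- raw + drop(centred %*% s$causal_effects)
        V <- locus_dosage_cov(s, s$causal_indices)
        gvar <- gvar + drop(crossprod(s$causal_effects, V %*% s$causal_effects))
        gamma_std[[length(gamma_std) + 1L]] <-
          data.frame(SNP = ids, exposure = nm, gamma = s$causal_effects,
                     stringsAsFactors = FALSE)
      }
      sd_i <- sqrt(gvar + model$confounder_sd^2 + model$exposure_noise_sd[i]^2)
      exposure_sd[i] <- sd_i
      E[, i] <- (raw + model$confounder_sd * U +
                   rnorm(n, sd = model$exposure_noise_sd[i])) / sd_i
    }
    truth_gamma <- if (length(gamma_std)) {
      g <- do.call(rbind, gamma_std)
      g$gamma_std <- g$gamma / exposure_sd[match(g$exposure, model$exposure_names)]
      g
    } else NULL
    pheno <- as.data.frame(E)

    metab_sd <- NULL
    if (!is.null(model$metabolite_loadings)) {
      A <- model$metabolite_loadings
      M <- E %*% t(A)
      if (!is.null(model$pleiotropy_effects)) {
        D <- as.matrix(model$pleiotropy_effects)
        ids <- colnames(D)
        if (is.null(ids) || !all(ids %in% colnames(genotypes))) {
          stop("`pleiotropy_effects` columns must name genotype variants",
               call. = FALSE)
        }
        M <- M + genotypes[, ids, drop = FALSE] %*% t(D)
      }
      M <- M + matrix(rnorm(n * nrow(A)), n, nrow(A), byrow = FALSE) *
        rep(model$metabolite_noise_sd, each = n)
      colnames(M) <- rownames(A)
      # analytic SD treating exposures as independent unit-variance factors
      metab_sd <- sqrt(rowSums(A^2) + model$metabolite_noise_sd^2)
      names(metab_sd) <- rownames(A)
      pheno <- cbind(pheno, as.data.frame(M))
    }

    if (!is.null(model$disease_log_odds_per_exposure)) {
      Th <- model$disease_log_odds_per_exposure
      eta <- sweep(E %*% t(Th), 2, model$disease_intercepts, `+`)
      Dz <- matrix(rbinom(length(eta), 1L, plogis(eta)), nrow(eta), ncol(eta))
      colnames(Dz) <- rownames(Th)
      pheno <- cbind(pheno, as.data.frame(Dz))
    }

    attr(pheno, "truth") <- list(
      gamma = truth_gamma,
      exposure_sd = setNames(exposure_sd, model$exposure_names),
      theta = model$disease_log_odds_per_exposure,
      metabolite_loadings = model$metabolite_loadings,
      metabolite_sd = metab_sd
    )
    pheno
  })
}

#' Simulate covariates uninformative of genotype
#'
#' Age (years, uniform over 40-71), sex (0/1), fasting time (hours), a binary
#' genotyping-chip indicator and 10 genetic principal components, all drawn
#' independently of the genotypes.
#'
#' @param n_individuals count.
#' @param seed integer seed.
#' @return data frame with columns `age sex fasting chip PC1..PC10`.
#' @export
simulate_covariates <- function(n_individuals, seed) {
  n <- as.integer(n_individuals)
  with_seed(seed, {
    cv <- data.frame(
      age = sample(40:71, n, replace = TRUE),
      sex = rbinom(n, 1L, 0.5),
      fasting = round(runif(n, 2, 15), 1),
      chip = rbinom(n, 1L, 0.3)
    )
    pcs <- matrix(rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("PC", 1:10)))
    cbind(cv, as.data.frame(pcs))
  })
}

#' Assemble a full synthetic cohort
#'
#' Simulates genotypes for every locus, phenotypes from the model, covariates
#' and a disjoint partition into named samples (by default discovery /
#' outcome / reference, emulating the two-sample MR design with a separate
#' LD reference panel).
#'
#' @param specs list of [locus_spec()] objects.
#' @param model a [phenotype_model()].
#' @param n_individuals total cohort size.
#' @param fractions named partition fractions summing to 1.
#' @param seed integer master seed; genotype, phenotype, covariate and
#'   partition randomness are derived from it.
#' @return an object of class `cohort_data`: list with `genotypes`,
#'   `variants`, `phenotypes`, `covariates`, `partition`, `specs`, `model`
#'   and `truth`.
#' @export
simulate_cohort <- function(specs, model, n_individuals,
                            fractions = c(discovery = 0.5, outcome = 0.49,
                                          reference = 0.01),
                            seed = 1L) {
  if (inherits(specs, "locus_spec")) specs <- list(specs)
  seeds <- derive_seeds(seed, length(specs) + 3L)
  gl <- lapply(seq_along(specs), function(i) {
    simulate_genotypes(specs[[i]], n_individuals, seeds[i])
  })
  genotypes <- do.call(cbind, lapply(gl, `[[`, "dosages"))
  variants <- do.call(rbind, lapply(gl, `[[`, "variants"))
  if (anyDuplicated(variants$SNP)) {
    stop("duplicate variant IDs across loci; use distinct locus_id values",
         call. = FALSE)
  }
  rownames(variants) <- NULL
  phenotypes <- simulate_phenotypes(genotypes, specs, model,
                                    seeds[length(specs) + 1L])
  covariates <- simulate_covariates(n_individuals, seeds[length(specs) + 2L])
  cohort <- structure(list(
    genotypes = genotypes, variants = variants,
    phenotypes = phenotypes, covariates = covariates,
    partition = rep(NA_character_, n_individuals),
    specs = specs, model = model,
    truth = attr(phenotypes, "truth")
  ), class = "cohort_data")
  split_cohort(cohort, fractions, seeds[length(specs) + 3L])
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("<cohort_data> %d individuals x %d variants; traits: %s\n",
              nrow(x$genotypes), ncol(x$genotypes),
              paste(names(x$phenotypes), collapse = ", ")))
  if (!all(is.na(x$partition))) {
    print(table(x$partition))
  }
  invisible(x)
}

#' Partition a cohort into disjoint named samples
#'
#' @param cohort a `cohort_data`.
#' @param fractions named numeric fractions summing to 1 (within 1e-9);
#'   unnamed fractions get default labels discovery/outcome/reference/...
#' @param seed integer seed controlling the random assignment.
#' @return the cohort with its `partition` field set; every individual
#'   receives exactly one tag and realised sizes are the rounded cumulative
#'   fractions (exact when `fractions * n` are integers).
#' @export
split_cohort <- function(cohort, fractions, seed) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must sum to 1 (got ", format(sum(fractions)), ")",
         call. = FALSE)
  }
  labels <- names(fractions)
  if (is.null(labels) || any(labels == "")) {
    defaults <- c("discovery", "outcome", "reference")
    labels <- if (length(fractions) <= 3L) defaults[seq_along(fractions)] else
      sprintf("sample_%d", seq_along(fractions))
  }
  n <- nrow(cohort$genotypes)
  sizes <- diff(c(0L, round(cumsum(fractions) * n)))
  perm <- with_seed(seed, sample.int(n))
  part <- rep(NA_character_, n)
  offset <- 0L
  for (i in seq_along(sizes)) {
    if (sizes[i] > 0) part[perm[(offset + 1L):(offset + sizes[i])]] <- labels[i]
    offset <- offset + as.integer(sizes[i])
  }
  cohort$partition <- part
  cohort
}

#' Row indices of one partition of a cohort
#' @param cohort a `cohort_data`.
#' @param partition partition label (e.g. "discovery").
#' @return integer vector of row indices.
#' @export
partition_rows <- function(cohort, partition) {
  idx <- which(cohort$partition == partition)
  if (!length(idx)) stop("empty partition: ", partition, call. = FALSE)
  idx
}
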