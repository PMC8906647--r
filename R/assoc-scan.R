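# Per-variant association scans producing GWAS summary statistics, plus the
# rank-based inverse-normal phenotype transformation and hit counting.

#' Rank-based inverse normal transformation
#'
#' Maps values to standard-normal quantiles of their offset ranks,
#' `qnorm((rank - c) / (n - 2c + 1))` with the Blom offset `c = 3/8`. Ties
#' receive the mean of their tied ranks; missing values are preserved. The
#' result has mean approximately 0 and SD approximately 1, making effect
#' sizes comparable across traits.
#'
#' @param values numeric vector (>= 3 non-missing values).
#' @param offset rank offset constant; default 3/8 (Blom).
#' @return transformed numeric vector of the same length.
#' @export
rank_inverse_normal <- function(values, offset = 3 / 8) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 3L) {
    stop("rank_inverse_normal needs at least 3 non-missing values",
         call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("rank_inverse_normal is undefined when all values are identical",
         call. = FALSE)
  }
  r <- rank(x, ties.method = "average")
  out <- values
  out[ok] <- qnorm((r - offset) / (length(x) - 2 * offset + 1))
  out
}

#' Construct/validate a summary-statistics table
#'
#' Standardises a per-variant association table to the canonical columns
#' `SNP CHR POS EA NEA EAF BETA SE P N` and checks its invariants: positive
#' standard errors, unique variant IDs and P values consistent with the
#' normal approximation `2 * pnorm(-|BETA/SE|)`.
#'
#' @param df data frame containing the canonical columns.
#' @param trait_name trait label attached as an attribute.
#' @return a `summary_stats` data frame.
#' @export
summary_stats <- function(df, trait_name = attr(df, "trait_name") %||% "trait") {
  req <- c("SNP", "CHR", "POS", "EA", "NEA", "EAF", "BETA", "SE", "P", "N")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("summary statistics missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[req]
  usable <- !is.na(df$SE)
  if (any(df$SE[usable] <= 0)) {
    stop("summary statistics contain non-positive SE", call. = FALSE)
  }
  if (anyDuplicated(df$SNP)) {
    stop("duplicate variant IDs in summary statistics", call. = FALSE)
  }
  chk <- usable & !is.na(df$P) & df$P > 1e-300
  if (any(chk)) {
    pn <- 2 * pnorm(-abs(df$BETA[chk] / df$SE[chk]))
    rel <- abs(df$P[chk] - pn) / pmax(pn, 1e-300)
    if (any(rel > 0.1 & abs(df$P[chk] - pn) > 1e-12)) {
      stop("P values inconsistent with the normal approximation to |BETA/SE|",
           call. = FALSE)
    }
  }
  attr(df, "trait_name") <- trait_name
  class(df) <- c("summary_stats", "data.frame")
  df
}

# Residualise columns of a matrix on an intercept + covariate design.
residualise <- function(M, C) {
  X <- cbind(`(Intercept)` = 1, C)
  qr_x <- qr(X)
  M - X %*% qr.coef(qr_x, M)
}

# Joint-regression coefficients of each dosage column for each trait column,
# via Frisch-Waugh-Lovell: residualise G and Y on the covariates once, then
# per (variant, trait) slope, SE and the exact least-squares residual df.
# Returns list of beta / se matrices (variants x traits).
linear_scan_core <- function(G, Y, C) {
  Gt <- residualise(G, C)
  Yt <- residualise(Y, C)
  gg <- colSums(Gt^2)
  yy <- colSums(Yt^2)
  gy <- crossprod(Gt, Yt)                    # variants x traits
  df_resid <- nrow(G) - ncol(C) - 2L
  ok <- gg > 1e-12
  beta <- gy / ifelse(ok, gg, NA_real_)
  rss <- pmax(outer(rep(1, length(gg)), yy) - beta^2 * gg, 0)
  se <- sqrt(rss / df_resid / gg)
  beta[!ok, ] <- NA_real_
  se[!ok, ] <- NA_real_
  list(beta = beta, se = se)
}

#' Per-variant genome-wide association scan
#'
#' For each variant, the reported coefficient is that of the dosage in a
#' joint regression of the (optionally inverse-normal transformed) trait on
#' dosage plus covariates. Linear scans are computed for all variants at once
#' via Frisch-Waugh-Lovell residualisation, which is numerically identical to
#' per-variant joint least squares; logistic scans fit one `glm` per variant.
#' Two-sided P values use the normal approximation, the large-sample GWAS
#' convention. Monomorphic variants are emitted with `BETA = 0` and missing
#' `SE`/`P` so downstream stages can exclude them.
#'
#' @param cohort a `cohort_data`.
#' @param trait phenotype column to analyse.
#' @param covariates covariate column names (default age, sex, fasting, chip).
#' @param family `"linear"` or `"logistic"`.
#' @param partition which cohort partition to analyse (default "discovery").
#' @param normalise apply [rank_inverse_normal()] to the trait first
#'   (linear scans only; default TRUE).
#' @return a [summary_stats()] data frame.
#' @export
gwas_scan <- function(cohort, trait,
                      covariates = c("age", "sex", "fasting", "chip"),
                      family = c("linear", "logistic"),
                      partition = "discovery", normalise = TRUE) {
  family <- match.arg(family)
  stopifnot(inherits(cohort, "cohort_data"))
  if (!trait %in% names(cohort$phenotypes)) {
    stop("trait not found in cohort phenotypes: ", trait, call. = FALSE)
  }
  missing_cov <- setdiff(covariates, names(cohort$covariates))
  if (length(missing_cov)) {
    stop("covariate(s) not found: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  rows <- partition_rows(cohort, partition)
  y <- cohort$phenotypes[[trait]][rows]
  G <- cohort$genotypes[rows, , drop = FALSE]
  C <- as.matrix(cohort$covariates[rows, covariates, drop = FALSE])
  n <- length(y)
  m <- ncol(G)
  mono <- apply(G, 2, function(g) length(unique(g)) < 2L)

  beta <- rep(NA_real_, m); se <- rep(NA_real_, m)

  if (family == "linear") {
    if (normalise) y <- rank_inverse_normal(y)
    core <- linear_scan_core(G, matrix(y, ncol = 1), C)
    beta <- drop(core$beta)
    se <- drop(core$se)
    beta[mono] <- NA_real_
    se[mono] <- NA_real_
  } else {
    yf <- y
    if (length(unique(yf[!is.na(yf)])) != 2L) {
      stop("logistic scan requires a binary trait with both classes present",
           call. = FALSE)
    }
    for (j in seq_len(m)) {
      if (mono[j]) next
      fit <- suppressWarnings(
        glm(yf ~ G[, j] + C, family = binomial())
      )
      if (!fit$converged) next
      cf <- summary(fit)$coefficients
      if (nrow(cf) < 2L || !is.finite(cf[2, 2]) || cf[2, 2] > 100) next
      beta[j] <- cf[2, 1]
      se[j] <- cf[2, 2]
    }
  }
  beta[mono] <- 0
  se[mono] <- NA_real_
  p <- ifelse(is.na(se), NA_real_, 2 * pnorm(-abs(beta / se)))
  vt <- cohort$variants
  out <- data.frame(
    SNP = vt$SNP, CHR = vt$CHR, POS = vt$POS, EA = vt$EA, NEA = vt$NEA,
    EAF = colMeans(G) / 2, BETA = beta, SE = se, P = p, N = n,
    stringsAsFactors = FALSE
  )
  summary_stats(out, trait_name = trait)
}

#' Linear association scans for a panel of traits at once
#'
#' Equivalent to calling [gwas_scan()] with `family = "linear"` for each
#' trait, but residualises the dosages on the covariates only once, which
#' makes metabolome-size panels cheap. Results are numerically identical to
#' the single-trait scan.
#'
#' @inheritParams gwas_scan
#' @param traits character vector of phenotype columns.
#' @return named list of [summary_stats()], one per trait.
#' @export
gwas_scan_multi <- function(cohort, traits,
                            covariates = c("age", "sex", "fasting", "chip"),
                            partition = "outcome", normalise = TRUE) {
  stopifnot(inherits(cohort, "cohort_data"))
  missing_tr <- setdiff(traits, names(cohort$phenotypes))
  if (length(missing_tr)) {
    stop("trait(s) not found: ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }
  rows <- partition_rows(cohort, partition)
  G <- cohort$genotypes[rows, , drop = FALSE]
  C <- as.matrix(cohort$covariates[rows, covariates, drop = FALSE])
  Y <- as.matrix(cohort$phenotypes[rows, traits, drop = FALSE])
  if (normalise) Y <- apply(Y, 2, rank_inverse_normal)
  core <- linear_scan_core(G, Y, C)
  mono <- apply(G, 2, function(g) length(unique(g)) < 2L)
  vt <- cohort$variants
  eaf <- colMeans(G) / 2
  setNames(lapply(seq_along(traits), function(t) {
    beta <- core$beta[, t]; se <- core$se[, t]
    beta[mono] <- 0; se[mono] <- NA_real_
    p <- ifelse(is.na(se), NA_real_, 2 * pnorm(-abs(beta / se)))
    summary_stats(data.frame(
      SNP = vt$SNP, CHR = vt$CHR, POS = vt$POS, EA = vt$EA, NEA = vt$NEA,
      EAF = eaf, BETA = beta, SE = se, P = p, N = nrow(G),
      stringsAsFactors = FALSE), trait_name = traits[t])
  }), traits)
}

#' Count genome-wide significant hits and independent loci
#'
#' Hits are records with `P < threshold`. Loci are counted by greedy
#' clustering: repeatedly seed at the smallest remaining P and absorb all
#' hits within `locus_window_bp` either side of the seed position (same
#' chromosome).
#'
#' @param stats a [summary_stats()] data frame.
#' @param threshold P-value cutoff (default the conventional genome-wide
#'   5e-8).
#' @param locus_window_bp clustering half-window in base pairs
#'   (default 500 kb).
#' @return list with `n_hits` and `n_loci`.
#' @export
count_gwas_hits <- function(stats, threshold = 5e-8, locus_window_bp = 5e5) {
  hits <- stats[!is.na(stats$P) & stats$P < threshold, , drop = FALSE]
  n_hits <- nrow(hits)
  n_loci <- 0L
  while (nrow(hits)) {
    seed <- which.min(hits$P)
    keep <- hits$CHR != hits$CHR[seed] |
      abs(hits$POS - hits$POS[seed]) > locus_window_bp
    hits <- hits[keep, , drop = FALSE]
    n_loci <- n_loci + 1L
  }
  list(n_hits = n_hits, n_loci = n_loci)
}
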