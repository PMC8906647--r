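# Causal-estimation engine: Wald ratio, standard IVW, correlated-instrument
# IVW (generalised weighted regression with an LD-derived covariance),
# instrument-strength F statistics, therapeutic orientation and odds-ratio
# conversion.

#' Bundle harmonised summary statistics for MR estimation
#'
#' @param beta_x,se_x instrument-exposure effects and standard errors
#'   (exposure-SD units per effect allele).
#' @param beta_y,se_y instrument-outcome effects and standard errors
#'   (outcome units or log-odds per effect allele).
#' @param rho signed LD correlation matrix over the same ordered instruments
#'   (identity assumed when NULL).
#' @param snps optional instrument IDs.
#' @return an object of class `mr_input`.
#' @export
mr_input <- function(beta_x, se_x, beta_y, se_y, rho = NULL, snps = NULL) {
  k <- length(beta_x)
  if (k < 1L) stop("at least one instrument is required", call. = FALSE)
  if (length(se_x) != k || length(beta_y) != k || length(se_y) != k) {
    stop("beta/se vectors must have equal length", call. = FALSE)
  }
  if (any(!is.finite(c(beta_x, se_x, beta_y, se_y)))) {
    stop("non-finite values in MR input", call. = FALSE)
  }
  if (any(se_x <= 0) || any(se_y <= 0)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  if (is.null(rho)) rho <- diag(k)
  rho <- as.matrix(rho)
  if (!all(dim(rho) == k)) {
    stop("`rho` dimension does not match the instrument count", call. = FALSE)
  }
  if (max(abs(rho - t(rho))) > 1e-8 || max(abs(diag(rho) - 1)) > 1e-8) {
    stop("`rho` must be symmetric with unit diagonal", call. = FALSE)
  }
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("`rho` is not positive semi-definite", call. = FALSE)
  }
  if (is.null(snps)) snps <- sprintf("snp_%d", seq_len(k))
  structure(list(beta_x = as.numeric(beta_x), se_x = as.numeric(se_x),
                 beta_y = as.numeric(beta_y), se_y = as.numeric(se_y),
                 rho = unname(rho), snps = as.character(snps)),
            class = "mr_input")
}

#' Assemble an MR input from a harmonised table and an instrument set
#'
#' @param harmonised output of [harmonise()].
#' @param ld LD matrix covering the harmonised instruments (rows/columns are
#'   subset to them), or NULL for independent instruments.
#' @return an `mr_input`.
#' @export
mr_input_from <- function(harmonised, ld = NULL) {
  ids <- harmonised$SNP
  rho <- if (is.null(ld)) NULL else ld[ids, ids, drop = FALSE]
  mr_input(harmonised$beta_x, harmonised$se_x,
           harmonised$beta_y, harmonised$se_y, rho = rho, snps = ids)
}

new_mr_estimate <- function(theta, se, k, f_stat, method,
                            orientation_applied = 1) {
  structure(list(
    theta = theta, se = se,
    ci_low = theta - 1.96 * se, ci_high = theta + 1.96 * se,
    p_value = 2 * pnorm(-abs(theta / se)),
    n_instruments = as.integer(k), f_statistic = f_stat,
    method = method, orientation_applied = orientation_applied
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "<mr_estimate> %s: theta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], P = %.3g, k = %d, F = %.1f\n",
    x$method, x$theta, x$se, x$ci_low, x$ci_high, x$p_value,
    x$n_instruments, x$f_statistic))
  invisible(x)
}

#' Mean instrument strength (F statistic)
#'
#' Summary-level approximation: the mean squared z-score of the
#' instrument-exposure associations, `mean((beta_x / se_x)^2)`. Values below
#' roughly 10 conventionally indicate weak-instrument bias risk.
#'
#' @param beta_x,se_x instrument-exposure effects and SEs.
#' @return non-negative scalar.
#' @export
f_statistic <- function(beta_x, se_x) {
  stopifnot(length(beta_x) >= 1L, length(beta_x) == length(se_x))
  mean((beta_x / se_x)^2)
}

#' Wald ratio causal estimate (single instrument)
#'
#' `theta = beta_y / beta_x`, with first-order delta-method standard error
#' `se_y / |beta_x|` (exposure-side uncertainty enters only the F statistic,
#' standard two-sample practice).
#'
#' @param input an [mr_input()] with exactly one instrument.
#' @return an `mr_estimate`.
#' @export
wald_ratio <- function(input) {
  stopifnot(inherits(input, "mr_input"))
  if (length(input$beta_x) != 1L) {
    stop("wald_ratio requires exactly one instrument", call. = FALSE)
  }
  if (abs(input$beta_x) == 0) {
    stop("wald_ratio undefined for beta_x = 0", call. = FALSE)
  }
  new_mr_estimate(input$beta_y / input$beta_x,
                  input$se_y / abs(input$beta_x), 1L,
                  f_statistic(input$beta_x, input$se_x), "wald")
}

#' Standard (independent-instrument) IVW estimate
#'
#' Fixed-effect inverse-variance-weighted average of per-instrument Wald
#' ratios with weights `beta_x^2 / se_y^2`. Instruments with `beta_x = 0`
#' are rejected.
#'
#' @param input an [mr_input()] with >= 2 instruments (rho is ignored).
#' @return an `mr_estimate`.
#' @export
ivw_standard <- function(input) {
  stopifnot(inherits(input, "mr_input"))
  if (length(input$beta_x) < 2L) {
    stop("ivw_standard requires >= 2 instruments (use wald_ratio)",
         call. = FALSE)
  }
  if (any(input$beta_x == 0)) {
    stop("instrument(s) with beta_x = 0 rejected: ",
         paste(input$snps[input$beta_x == 0], collapse = ", "), call. = FALSE)
  }
  w <- input$beta_x^2 / input$se_y^2
  ratios <- input$beta_y / input$beta_x
  theta <- sum(w * ratios) / sum(w)
  se <- sqrt(1 / sum(w))
  new_mr_estimate(theta, se, length(w),
                  f_statistic(input$beta_x, input$se_x), "ivw")
}

#' IVW estimate accounting for correlation between instruments
#'
#' Generalised weighted least squares of the instrument-outcome effects on
#' the instrument-exposure effects with covariance
#' `Omega[j,k] = se_y[j] * se_y[k] * rho[j,k]`, so the LD correlations are
#' incorporated into the standard-error terms:
#' `theta = (bx' Omega^-1 bx)^-1 bx' Omega^-1 by` and
#' `se = sqrt((bx' Omega^-1 bx)^-1)`. Reduces exactly to [ivw_standard()]
#' when `rho` is the identity and to [wald_ratio()] for one instrument.
#'
#' An ill-conditioned `Omega` (smallest eigenvalue below `1e-10` times the
#' largest) is an error naming the most collinear variant pair: it signals
#' insufficient LD pruning rather than a quantity to regularise away.
#'
#' @param input an [mr_input()].
#' @param random_effects inflate the standard error by the square root of
#'   the residual mean generalised chi-square, floored at 1 (multiplicative
#'   random-effects model); default FALSE, the plain fixed-effect estimator.
#' @return an `mr_estimate` with method `"ivw_correlated"`.
#' @export
ivw_correlated <- function(input, random_effects = FALSE) {
  stopifnot(inherits(input, "mr_input"))
  k <- length(input$beta_x)
  omega <- tcrossprod(input$se_y) * input$rho
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev)) {
    off <- abs(input$rho); diag(off) <- 0
    worst <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "Omega is near-singular (eigenvalue ratio %.2e); most collinear pair: %s / %s — prune instruments harder",
      min(ev) / max(ev), input$snps[worst[1]], input$snps[worst[2]]),
      call. = FALSE)
  }
  ch <- chol(omega)
  a <- backsolve(ch, input$beta_x, transpose = TRUE)
  b <- backsolve(ch, input$beta_y, transpose = TRUE)
  precision <- sum(a^2)
  theta <- sum(a * b) / precision
  se <- sqrt(1 / precision)
  if (random_effects && k > 1L) {
    q <- sum((b - theta * a)^2)          # residual generalised chi-square
    se <- se * max(1, sqrt(q / (k - 1)))
  }
  new_mr_estimate(theta, se, k,
                  f_statistic(input$beta_x, input$se_x), "ivw_correlated")
}

#' Orient an MR estimate to the therapeutic direction
#'
#' Reports effects per 1 SD of exposure change in the direction the drug
#' acts (lower LDL / lower triglycerides / higher HDL): the estimate and its
#' confidence bounds are multiplied by `therapeutic_direction` (bounds
#' swapped for direction -1); SE and P are unchanged. Applying the same
#' orientation twice restores the original estimate.
#'
#' @param estimate an `mr_estimate`.
#' @param target a [drug_target()] (or a bare direction in `{-1, +1}`).
#' @return the oriented `mr_estimate` with `orientation_applied` recorded.
#' @export
orient <- function(estimate, target) {
  stopifnot(inherits(estimate, "mr_estimate"))
  dir <- if (inherits(target, "drug_target")) target$therapeutic_direction
         else target
  if (!dir %in% c(-1, 1)) stop("direction must be -1 or +1", call. = FALSE)
  if (dir == -1) {
    ci <- c(estimate$ci_low, estimate$ci_high)
    estimate$theta <- -estimate$theta
    estimate$ci_low <- -ci[2]
    estimate$ci_high <- -ci[1]
  }
  estimate$orientation_applied <- estimate$orientation_applied * dir
  estimate
}

#' Convert a log-odds MR estimate to an odds ratio
#'
#' @param estimate an `mr_estimate` whose outcome is binary-trait log-odds.
#' @return list with `or`, `ci_low`, `ci_high`, `p_value`.
#' @export
to_odds_ratio <- function(estimate) {
  stopifnot(inherits(estimate, "mr_estimate"))
  list(or = exp(estimate$theta),
       ci_low = exp(estimate$theta - 1.96 * estimate$se),
       ci_high = exp(estimate$theta + 1.96 * estimate$se),
       p_value = estimate$p_value)
}
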