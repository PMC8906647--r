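# Cross-target signature comparison: scaling to equal disease effect,
# pairwise coefficients of determination, and plot-ready scatter tables.

#' Scale a metabolic signature by a target's disease effect
#'
#' Divides every trait estimate and its SE by the absolute genetically
#' predicted disease (e.g. CAD) log-odds effect of the same target, so
#' signatures are expressed in trait-SD per unit of disease-risk reduction
#' and are comparable across targets. The disease estimate must be oriented
#' to the therapeutic direction first; scaling by a zero effect is
#' undefined.
#'
#' @param signature a `metabolic_signature` from [run_screen()].
#' @param disease_estimate the target's oriented `mr_estimate` on the
#'   disease (log-odds scale).
#' @return the signature with `theta`, `se`, `ci_low`, `ci_high` divided by
#'   `|disease theta|`; the factor is recorded as attribute
#'   `scaling_factor`.
#' @export
scale_by_disease_effect <- function(signature, disease_estimate) {
  stopifnot(inherits(disease_estimate, "mr_estimate"))
  f <- abs(disease_estimate$theta)
  if (f == 0) stop("disease effect is zero: scaling undefined", call. = FALSE)
  for (col in c("theta", "se", "ci_low", "ci_high")) {
    signature[[col]] <- signature[[col]] / f
  }
  attr(signature, "scaling_factor") <- f
  signature
}

#' Concordance between two scaled metabolic signatures
#'
#' Least-squares regression (with intercept) of signature `b`'s estimates on
#' signature `a`'s over their shared non-missing traits. The coefficient of
#' determination is the quotient of the variances of the fitted and observed
#' values of the dependent variable. The regression direction (comparator on
#' baseline) is fixed: r-squared is near direction-symmetric but the slope
#' is not.
#'
#' @param sig_a baseline signature (independent variable).
#' @param sig_b comparator signature (dependent variable).
#' @return a `concordance_result` list: `target_a`, `target_b`, `n_traits`,
#'   `r_squared`, `slope`, `intercept`.
#' @export
pairwise_r2 <- function(sig_a, sig_b) {
  shared <- merge(
    sig_a[!sig_a$missing, c("trait", "theta")],
    sig_b[!sig_b$missing, c("trait", "theta")],
    by = "trait", suffixes = c("_a", "_b")
  )
  shared <- shared[complete.cases(shared), , drop = FALSE]
  if (nrow(shared) < 3L) {
    stop("fewer than 3 shared traits between signatures", call. = FALSE)
  }
  if (var(shared$theta_a) < 1e-24) {
    stop("baseline estimates are constant; r-squared undefined",
         call. = FALSE)
  }
  fit <- lm(theta_b ~ theta_a, data = shared)
  structure(list(
    target_a = attr(sig_a, "target")$target_name %||% "a",
    target_b = attr(sig_b, "target")$target_name %||% "b",
    n_traits = nrow(shared),
    r_squared = var(fitted(fit)) / var(shared$theta_b),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1])
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "<concordance> %s ~ %s: r2 = %.3f, slope = %.3f, intercept = %.3f (%d traits)\n",
    x$target_b, x$target_a, x$r_squared, x$slope, x$intercept, x$n_traits))
  invisible(x)
}

#' All pairwise signature concordances
#'
#' Scales every signature by its disease effect, then computes
#' [pairwise_r2()] for every unordered target pair, flagging the comparisons
#' against the chosen baseline target. Pairing is by trait name, so row
#' order within signatures is irrelevant.
#'
#' @param signatures named list of `metabolic_signature`s (as from
#'   [run_screen()]).
#' @param disease_estimates named list of oriented `mr_estimate`s on the
#'   disease, one per target.
#' @param baseline baseline target name (default the first signature).
#' @return data frame with one row per unordered pair: `target_a target_b
#'   n_traits r_squared slope intercept vs_baseline`; the scaled signatures
#'   are attached as attribute `scaled`.
#' @export
all_pairs <- function(signatures, disease_estimates,
                      baseline = names(signatures)[1]) {
  if (length(signatures) < 2L) {
    stop("at least two signatures are required", call. = FALSE)
  }
  if (!baseline %in% names(signatures)) {
    stop("baseline target not among the signatures: ", baseline,
         call. = FALSE)
  }
  scaled <- lapply(names(signatures), function(nm) {
    de <- disease_estimates[[nm]]
    if (is.null(de)) stop("no disease estimate for target ", nm, call. = FALSE)
    scale_by_disease_effect(signatures[[nm]], de)
  })
  names(scaled) <- names(signatures)
  nms <- names(scaled)
  pairs <- utils::combn(nms, 2, simplify = FALSE)
  # baseline always the independent variable when it is in the pair
  rows <- lapply(pairs, function(pr) {
    if (pr[2] == baseline) pr <- rev(pr)
    r <- pairwise_r2(scaled[[pr[1]]], scaled[[pr[2]]])
    data.frame(target_a = pr[1], target_b = pr[2], n_traits = r$n_traits,
               r_squared = r$r_squared, slope = r$slope,
               intercept = r$intercept,
               vs_baseline = baseline %in% pr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "scaled") <- scaled
  out
}

#' Plot-ready forest table across targets
#'
#' One row per (target, trait) with the oriented (optionally scaled)
#' estimate and its confidence bounds, for forest-style comparison of a
#' trait subset across drug targets.
#'
#' @param signatures named list of `metabolic_signature`s (scaled or not).
#' @param traits optional trait subset (default: all traits present).
#' @return data frame `target trait subcategory theta ci_low ci_high`.
#' @export
forest_data <- function(signatures, traits = NULL) {
  do.call(rbind, lapply(names(signatures), function(nm) {
    s <- signatures[[nm]]
    s <- s[!s$missing, , drop = FALSE]
    if (!is.null(traits)) s <- s[s$trait %in% traits, , drop = FALSE]
    data.frame(target = nm, trait = s$trait, subcategory = s$subcategory,
               theta = s$theta, ci_low = s$ci_low, ci_high = s$ci_high,
               stringsAsFactors = FALSE)
  }))
}

#' Minimal scatter / forest renderers
#'
#' Base-graphics renderers for the plot-ready tables; publication-quality
#' figures are out of scope.
#'
#' @param sc a [scatter_data()] table.
#' @param ... passed to [plot()].
#' @return invisibly, the input table.
#' @export
plot_scatter <- function(sc, ...) {
  groups <- factor(ifelse(is.na(sc$subcategory), "trait", sc$subcategory))
  graphics::plot(sc$est_a, sc$est_b, col = as.integer(groups), pch = 19,
                 xlab = "baseline estimate", ylab = "comparator estimate",
                 ...)
  graphics::abline(lm(est_b ~ est_a, data = sc), lty = 2)
  graphics::abline(h = 0, v = 0, col = "grey70")
  invisible(sc)
}

#' @param fd a [forest_data()] table.
#' @rdname plot_scatter
#' @export
plot_forest <- function(fd, ...) {
  fd$y <- seq_len(nrow(fd))
  graphics::plot(fd$theta, fd$y, xlim = range(c(fd$ci_low, fd$ci_high)),
                 pch = 15, yaxt = "n", ylab = "",
                 xlab = "estimate (95% CI)", ...)
  graphics::segments(fd$ci_low, fd$y, fd$ci_high, fd$y)
  graphics::abline(v = 0, col = "grey70")
  graphics::axis(2, at = fd$y, labels = paste(fd$target, fd$trait),
                 las = 1, cex.axis = 0.6)
  invisible(fd)
}

#' Plot-ready scatter table for one target pair
#'
#' @param sig_a,sig_b scaled signatures (see [all_pairs()]).
#' @return data frame `trait subcategory est_a est_b` over shared traits.
#' @export
scatter_data <- function(sig_a, sig_b) {
  shared <- merge(
    sig_a[!sig_a$missing, c("trait", "subcategory", "theta")],
    sig_b[!sig_b$missing, c("trait", "theta")],
    by = "trait", suffixes = c("_a", "_b")
  )
  data.frame(trait = shared$trait, subcategory = shared$subcategory,
             est_a = shared$theta_a, est_b = shared$theta_b,
             stringsAsFactors = FALSE)
}
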