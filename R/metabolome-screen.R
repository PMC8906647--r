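# Metabolome-wide screening: MR of every drug target against every
# metabolite trait, with per-target false-discovery-rate control.

#' Benjamini-Hochberg q-values and discovery flags
#'
#' Step-up FDR q-values (monotone, capped at 1) via [stats::p.adjust()],
#' with discoveries flagged at `q < alpha`. Applied within one FDR family —
#' here one drug target across its metabolite traits, never pooled across
#' targets.
#'
#' @param p_values numeric vector in (0, 1]; may be empty.
#' @param alpha discovery threshold (default 0.05).
#' @return data frame with columns `p`, `q`, `discovery`.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) {
    return(data.frame(p = numeric(), q = numeric(), discovery = logical()))
  }
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1] with no missing values", call. = FALSE)
  }
  q <- p.adjust(p_values, method = "BH")
  data.frame(p = p_values, q = q, discovery = q < alpha)
}

#' Metabolome-wide MR screen across drug targets
#'
#' For each target, instruments are selected once from its exposure GWAS
#' ([select_instruments()]) and reused across all outcome traits; each
#' (target, trait) cell is harmonised, estimated by [ivw_correlated()] and
#' oriented to the therapeutic direction. Per-target Benjamini-Hochberg FDR
#' control is then applied across that target's traits. A trait losing more
#' than half of a target's instruments during harmonisation is flagged
#' missing and excluded from the FDR family rather than imputed.
#'
#' @param targets list of [drug_target()] objects.
#' @param exposure_stats named list of exposure [summary_stats()], indexed by
#'   exposure trait name.
#' @param outcome_stats named list of outcome [summary_stats()], one per
#'   metabolite trait.
#' @param panel reference panel for LD (see [compute_ld()]).
#' @param subcategories optional named character vector mapping trait ->
#'   subcategory label.
#' @param fdr FDR discovery threshold (default 0.05).
#' @param min_instruments targets with fewer pruned instruments are skipped
#'   with a message (default 2, excluding single-instrument targets whose
#'   gene-centric estimates are vulnerable to confounding by neighbours).
#' @param drop_palindromic passed to [harmonise()].
#' @return named list of `metabolic_signature` data frames (columns
#'   `trait subcategory theta se ci_low ci_high p q discovery missing`),
#'   each with attributes `target` and `instruments`.
#' @export
run_screen <- function(targets, exposure_stats, outcome_stats, panel,
                       subcategories = NULL, fdr = 0.05,
                       min_instruments = 2L, drop_palindromic = FALSE) {
  if (inherits(targets, "drug_target")) targets <- list(targets)
  out <- list()
  for (tg in targets) {
    ex <- exposure_stats[[tg$exposure_trait]]
    if (is.null(ex)) {
      stop("no exposure statistics for trait ", tg$exposure_trait,
           call. = FALSE)
    }
    iset <- select_instruments(ex, tg, panel)
    if (is.null(iset) || nrow(iset$variants) < min_instruments) {
      message("target ", tg$target_name, " skipped: fewer than ",
              min_instruments, " instruments")
      next
    }
    ids <- iset$variants$SNP
    rows <- lapply(names(outcome_stats), function(trait) {
      oc <- outcome_stats[[trait]]
      harm <- tryCatch(
        suppressMessages(harmonise(ex, oc, ids,
                                   drop_palindromic = drop_palindromic)),
        error = function(e) NULL)
      if (is.null(harm) || nrow(harm) < length(ids) / 2) {
        return(data.frame(trait = trait, theta = NA_real_, se = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p = NA_real_, missing = TRUE,
                          stringsAsFactors = FALSE))
      }
      est <- orient(ivw_correlated(mr_input_from(harm, iset$ld)), tg)
      data.frame(trait = trait, theta = est$theta, se = est$se,
                 ci_low = est$ci_low, ci_high = est$ci_high,
                 p = est$p_value, missing = FALSE, stringsAsFactors = FALSE)
    })
    sig <- do.call(rbind, rows)
    sig$subcategory <- if (is.null(subcategories)) NA_character_ else
      unname(subcategories[sig$trait])
    sig$q <- NA_real_
    sig$discovery <- NA
    ok <- !sig$missing
    if (any(ok)) {
      fd <- bh_fdr(sig$p[ok], alpha = fdr)
      sig$q[ok] <- fd$q
      sig$discovery[ok] <- fd$discovery
    }
    if (any(!ok)) {
      message("target ", tg$target_name, ": ", sum(!ok),
              " trait(s) flagged missing and excluded from FDR")
    }
    sig <- sig[, c("trait", "subcategory", "theta", "se", "ci_low",
                   "ci_high", "p", "q", "discovery", "missing")]
    attr(sig, "target") <- tg
    attr(sig, "instruments") <- iset
    class(sig) <- c("metabolic_signature", "data.frame")
    out[[tg$target_name]] <- sig
  }
  out
}
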