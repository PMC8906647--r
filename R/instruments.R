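# Cis instrument selection for drug targets: window + P-value filtering,
# reference-panel LD computation, greedy LD pruning and two-sample
# harmonisation of effect alleles.

#' Define a drug target for instrument selection
#'
#' A drug target is the gene region encoding it, the lipid exposure whose
#' GWAS supplies candidate instruments, the therapeutic direction (whether
#' the drug lowers or raises the exposure) and the selection thresholds:
#' variants with `P < p_threshold` within `window_kb` kilobases either side
#' of the gene, pruned to pairwise `r^2 < r2_threshold`.
#'
#' @param target_name label, e.g. "HMGCR".
#' @param chromosome,gene_start,gene_end encoding-gene region (1-based bp).
#' @param exposure_trait exposure GWAS trait name.
#' @param therapeutic_direction -1 if the drug lowers the exposure (LDL and
#'   triglyceride targets), +1 if it raises it (HDL via CETP).
#' @param window_kb flank size in kb (default 100; 50 for the sensitivity
#'   analysis).
#' @param p_threshold instrument P-value cutoff (default 1e-6).
#' @param r2_threshold LD pruning cutoff (default 0.1).
#' @return an object of class `drug_target`.
#' @export
drug_target <- function(target_name, chromosome, gene_start, gene_end,
                        exposure_trait, therapeutic_direction = -1,
                        window_kb = 100, p_threshold = 1e-6,
                        r2_threshold = 0.1) {
  assert_scalar_number(window_kb, "window_kb", lower = 1e-9)
  assert_scalar_number(p_threshold, "p_threshold", lower = 1e-300, upper = 1)
  assert_scalar_number(r2_threshold, "r2_threshold", lower = 1e-12, upper = 1)
  if (!therapeutic_direction %in% c(-1, 1)) {
    stop("`therapeutic_direction` must be -1 or +1", call. = FALSE)
  }
  if (gene_end < gene_start) stop("`gene_end` before `gene_start`", call. = FALSE)
  structure(list(
    target_name = as.character(target_name),
    chromosome = as.character(chromosome),
    gene_start = as.numeric(gene_start), gene_end = as.numeric(gene_end),
    exposure_trait = exposure_trait,
    therapeutic_direction = therapeutic_direction,
    window_kb = window_kb, p_threshold = p_threshold,
    r2_threshold = r2_threshold
  ), class = "drug_target")
}

#' @export
print.drug_target <- function(x, ...) {
  cat(sprintf(
    "<drug_target> %s (chr%s:%s-%s +/- %g kb), exposure %s, direction %+d, P < %g, r2 < %g\n",
    x$target_name, x$chromosome, format(x$gene_start, big.mark = ","),
    format(x$gene_end, big.mark = ","), x$window_kb, x$exposure_trait,
    x$therapeutic_direction, x$p_threshold, x$r2_threshold))
  invisible(x)
}

#' Select cis candidate instruments for a drug target
#'
#' Returns the summary-statistics records on the target's chromosome with
#' position inside the closed interval
#' `[gene_start - window, gene_end + window]` and `P < p_threshold`, sorted
#' by ascending P (ties broken by position then variant ID). Records without
#' a usable SE (e.g. monomorphic variants) are excluded.
#'
#' @param stats exposure-side [summary_stats()].
#' @param target a [drug_target()].
#' @return a `summary_stats` subset (possibly empty, with a warning).
#' @export
select_cis_variants <- function(stats, target) {
  stopifnot(inherits(target, "drug_target"))
  w <- target$window_kb * 1000
  lo <- target$gene_start - w
  hi <- target$gene_end + w
  keep <- stats$CHR == target$chromosome &
    stats$POS >= lo & stats$POS <= hi &
    !is.na(stats$P) & stats$P < target$p_threshold &
    !is.na(stats$SE)
  out <- stats[keep, , drop = FALSE]
  out <- out[order(out$P, out$POS, out$SNP), , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) {
    warning("no cis variants pass P < ", target$p_threshold, " for target ",
            target$target_name, call. = FALSE)
  }
  out
}

#' Compute a signed LD correlation matrix from a reference panel
#'
#' Pairwise Pearson correlations of effect-allele dosage vectors in the
#' reference panel. The sign is relative to each variant's stated effect
#' allele: flipping a variant's effect/other allele labels (dosage `2 - g`)
#' negates its row and column.
#'
#' @param panel reference genotypes: a `cohort_data` (its "reference"
#'   partition is used), or a dosage matrix with variant-ID column names.
#' @param variant_ids variants to include, in order.
#' @return an `ld_matrix`: correlation matrix with variant-ID dimnames.
#' @export
compute_ld <- function(panel, variant_ids) {
  if (inherits(panel, "cohort_data")) {
    rows <- partition_rows(panel, "reference")
    panel <- panel$genotypes[rows, , drop = FALSE]
  }
  panel <- as.matrix(panel)
  missing_ids <- setdiff(variant_ids, colnames(panel))
  if (length(missing_ids)) {
    stop("variant(s) absent from the reference panel: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  G <- panel[, variant_ids, drop = FALSE]
  mono <- apply(G, 2, function(g) length(unique(g)) < 2L)
  if (any(mono)) {
    stop("monomorphic in the reference panel: ",
         paste(variant_ids[mono], collapse = ", "), call. = FALSE)
  }
  r <- cor(G)
  dimnames(r) <- list(variant_ids, variant_ids)
  structure(r, class = c("ld_matrix", class(r)))
}

#' Greedy LD pruning of candidate instruments
#'
#' Iterates candidates in ascending-P order (the order produced by
#' [select_cis_variants()]) and keeps a candidate iff its squared correlation
#' with every already-kept variant is below `r2_threshold`; the best-P
#' candidate is always kept. The result is maximal under the greedy order:
#' adding back any dropped candidate would violate the threshold against
#' some kept variant.
#'
#' @param candidates candidate records sorted by ascending P.
#' @param ld an [compute_ld()] matrix covering all candidates.
#' @param r2_threshold pruning cutoff (default 0.1).
#' @return an `instrument_set`: list with `variants` (the kept records) and
#'   `ld` (the signed LD matrix over exactly the kept variants, in order).
#' @export
greedy_ld_prune <- function(candidates, ld, r2_threshold = 0.1) {
  if (!nrow(candidates)) stop("no candidates to prune", call. = FALSE)
  ids <- candidates$SNP
  if (!all(ids %in% rownames(ld))) {
    stop("LD matrix does not cover all candidates", call. = FALSE)
  }
  kept <- character()
  for (id in ids) {
    if (!length(kept) || all(ld[id, kept]^2 < r2_threshold)) {
      kept <- c(kept, id)
    }
  }
  variants <- candidates[match(kept, candidates$SNP), , drop = FALSE]
  rownames(variants) <- NULL
  structure(list(
    variants = variants,
    ld = structure(ld[kept, kept, drop = FALSE],
                   class = c("ld_matrix", "matrix", "array"))
  ), class = "instrument_set")
}

#' Select and prune instruments for a drug target
#'
#' Convenience wrapper: cis selection, removal of variants absent from the
#' reference panel, LD computation and greedy pruning.
#'
#' @param stats exposure-side [summary_stats()].
#' @param target a [drug_target()].
#' @param panel reference panel (see [compute_ld()]).
#' @return an `instrument_set` with the target attached, or NULL (with a
#'   warning) when no candidate survives selection.
#' @export
select_instruments <- function(stats, target, panel) {
  cand <- select_cis_variants(stats, target)
  if (!nrow(cand)) return(NULL)
  panel_mat <- if (inherits(panel, "cohort_data")) {
    panel$genotypes[partition_rows(panel, "reference"), , drop = FALSE]
  } else as.matrix(panel)
  absent <- setdiff(cand$SNP, colnames(panel_mat))
  if (length(absent)) {
    message(length(absent), " candidate variant(s) absent from the reference ",
            "panel excluded before pruning (", target$target_name, ")")
    cand <- cand[!cand$SNP %in% absent, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
  }
  ld <- compute_ld(panel_mat, cand$SNP)
  iset <- greedy_ld_prune(cand, ld, target$r2_threshold)
  iset$target <- target
  iset
}

#' Restrict a pruned instrument set to a narrower cis window
#'
#' Builds the sensitivity-analysis instrument set by keeping the instruments
#' of an already-pruned set whose positions fall inside a narrower window
#' around the same gene. The result is nested within the original set by
#' construction and still satisfies the pairwise r-squared bound (a subset
#' of a valid set cannot violate it). A fresh re-selection at the narrower
#' window would not guarantee nesting: removing an out-of-window variant can
#' un-block a correlated proxy that greedy pruning had dropped, so the
#' comparison would confound window choice with instrument swaps.
#'
#' @param iset an `instrument_set` from [select_instruments()].
#' @param window_kb the narrower flank in kb (default 50); must not exceed
#'   the window the set was selected with.
#' @return an `instrument_set` over the retained variants, with the target's
#'   `window_kb` updated, or NULL (with a warning) when none remain.
#' @export
sensitivity_instruments <- function(iset, window_kb = 50) {
  stopifnot(inherits(iset, "instrument_set"), !is.null(iset$target))
  tg <- iset$target
  if (window_kb > tg$window_kb) {
    stop("sensitivity window must be narrower than the selection window",
         call. = FALSE)
  }
  w <- window_kb * 1000
  keep <- iset$variants$POS >= tg$gene_start - w &
    iset$variants$POS <= tg$gene_end + w
  if (!any(keep)) {
    warning("no instrument of ", tg$target_name, " lies within the ",
            window_kb, "-kb window", call. = FALSE)
    return(NULL)
  }
  variants <- iset$variants[keep, , drop = FALSE]
  rownames(variants) <- NULL
  tg$window_kb <- window_kb
  structure(list(
    variants = variants,
    ld = structure(iset$ld[variants$SNP, variants$SNP, drop = FALSE],
                   class = c("ld_matrix", "matrix", "array")),
    target = tg
  ), class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  nm <- if (!is.null(x$target)) x$target$target_name else "instrument set"
  cat(sprintf("<instrument_set> %s: %d instruments (%s)\n", nm,
              nrow(x$variants), paste(x$variants$SNP, collapse = ", ")))
  invisible(x)
}

#' Swap effect/other allele labels for selected variants
#'
#' Relabels the effect allele of the given variants, negating BETA and
#' complementing EAF. Useful for testing the harmonisation invariance of
#' downstream estimates.
#'
#' @param stats a [summary_stats()] data frame.
#' @param snps variant IDs to flip.
#' @return the modified summary statistics.
#' @export
flip_alleles <- function(stats, snps) {
  i <- stats$SNP %in% snps
  ea <- stats$EA[i]
  stats$EA[i] <- stats$NEA[i]
  stats$NEA[i] <- ea
  stats$BETA[i] <- -stats$BETA[i]
  stats$EAF[i] <- 1 - stats$EAF[i]
  stats
}

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns outcome records to the exposure's effect alleles for a set of
#' instruments. Exact allele matches pass through; records whose effect and
#' other alleles are swapped relative to the exposure have their beta
#' negated and frequency complemented; any other allele configuration, and
#' instruments missing from the outcome, are dropped with a reported reason.
#' Palindromic (A/T, C/G) variants are kept and aligned by exact label match
#' by default, appropriate when both samples share one genotyping pipeline;
#' set `drop_palindromic = TRUE` for cross-consortium analyses.
#'
#' @param exposure,outcome [summary_stats()] tables.
#' @param variant_ids ordered instrument IDs present in the exposure set.
#' @param drop_palindromic drop A/T and C/G variants (default FALSE).
#' @return data frame with one row per retained instrument, in input order:
#'   `SNP beta_x se_x beta_y se_y`; attribute `dropped` records excluded
#'   variants and reasons. Errors if no instrument survives.
#' @export
harmonise <- function(exposure, outcome, variant_ids,
                      drop_palindromic = FALSE) {
  ex <- exposure[match(variant_ids, exposure$SNP), , drop = FALSE]
  if (anyNA(ex$SNP)) {
    stop("instrument(s) missing from the exposure statistics: ",
         paste(setdiff(variant_ids, exposure$SNP), collapse = ", "),
         call. = FALSE)
  }
  oc <- outcome[match(variant_ids, outcome$SNP), , drop = FALSE]
  rows <- vector("list", length(variant_ids))
  dropped <- list()
  palindromes <- c("A/T", "T/A", "C/G", "G/C")
  for (i in seq_along(variant_ids)) {
    id <- variant_ids[i]
    if (is.na(oc$SNP[i])) {
      dropped[[id]] <- "absent from outcome"
      next
    }
    if (is.na(oc$BETA[i]) || is.na(oc$SE[i])) {
      dropped[[id]] <- "unusable outcome record"
      next
    }
    if (drop_palindromic &&
        paste(ex$EA[i], ex$NEA[i], sep = "/") %in% palindromes) {
      dropped[[id]] <- "palindromic"
      next
    }
    by <- oc$BETA[i]
    if (identical(oc$EA[i], ex$EA[i]) && identical(oc$NEA[i], ex$NEA[i])) {
      # aligned
    } else if (identical(oc$EA[i], ex$NEA[i]) &&
               identical(oc$NEA[i], ex$EA[i])) {
      by <- -by
    } else {
      dropped[[id]] <- sprintf("alleles irreconcilable (%s/%s vs %s/%s)",
                               ex$EA[i], ex$NEA[i], oc$EA[i], oc$NEA[i])
      next
    }
    rows[[i]] <- data.frame(SNP = id, beta_x = ex$BETA[i], se_x = ex$SE[i],
                            beta_y = by, se_y = oc$SE[i],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || !nrow(out)) {
    stop("no instrument could be harmonised between exposure and outcome",
         call. = FALSE)
  }
  if (length(dropped)) {
    message(length(dropped), " instrument(s) dropped during harmonisation")
  }
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
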