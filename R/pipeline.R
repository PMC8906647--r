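# End-to-end orchestration: simulate -> association scans -> instrument
# selection -> disease MR -> metabolome screen -> concordance -> GRS strata,
# with a manifest recording inputs, seeds and per-stage row counts.

#' Assemble a pipeline configuration
#'
#' @param specs list of [locus_spec()] objects.
#' @param model a [phenotype_model()].
#' @param targets list of [drug_target()] objects.
#' @param n_individuals total synthetic cohort size.
#' @param fractions partition fractions (discovery / outcome / reference).
#' @param seed master seed.
#' @param baseline baseline target for concordance (default first target).
#' @param fdr per-target FDR threshold.
#' @param gwas_threshold genome-wide significance threshold for hit counts.
#' @param sensitivity_50kb also derive the nested 50-kb sensitivity
#'   instrument sets (see [sensitivity_instruments()]).
#' @param drop_palindromic passed to [harmonise()].
#' @param grs_phenotypes phenotype names for the age-stratified GRS
#'   analysis (default the exposures).
#' @param write_cohort also write the full cohort (VCF, dosage and phenotype
#'   tables) into the output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(specs, model, targets, n_individuals = 20000,
                            fractions = c(discovery = 0.5, outcome = 0.49,
                                          reference = 0.01),
                            seed = 1L, baseline = NULL, fdr = 0.05,
                            gwas_threshold = 5e-8, sensitivity_50kb = FALSE,
                            drop_palindromic = FALSE, grs_phenotypes = NULL,
                            write_cohort = FALSE) {
  if (inherits(specs, "locus_spec")) specs <- list(specs)
  if (inherits(targets, "drug_target")) targets <- list(targets)
  stopifnot(inherits(model, "phenotype_model"))
  structure(list(
    specs = specs, model = model, targets = targets,
    n_individuals = n_individuals, fractions = fractions, seed = seed,
    baseline = baseline %||% targets[[1]]$target_name,
    fdr = fdr, gwas_threshold = gwas_threshold,
    sensitivity_50kb = isTRUE(sensitivity_50kb),
    drop_palindromic = isTRUE(drop_palindromic),
    grs_phenotypes = grs_phenotypes %||% model$exposure_names,
    write_cohort = isTRUE(write_cohort)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]: lists `loci` (fields of
#' [locus_spec()]), `model` (fields of [phenotype_model()]; matrices as
#' row-major lists with `traits` / `diseases` name vectors) and `targets`
#' (fields of [drug_target()]), plus the scalar options.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  specs <- lapply(y$loci, function(l) {
    do.call(locus_spec, l[intersect(names(l), names(formals(locus_spec)))])
  })
  m <- y$model
  loadings <- NULL
  if (!is.null(m$metabolite_loadings)) {
    loadings <- do.call(rbind, lapply(m$metabolite_loadings, unlist))
    rownames(loadings) <- m$metabolite_names %||%
      sprintf("metab_%03d", seq_len(nrow(loadings)))
  }
  theta <- NULL
  if (!is.null(m$disease_log_odds)) {
    theta <- do.call(rbind, lapply(m$disease_log_odds, unlist))
    rownames(theta) <- m$disease_names %||%
      sprintf("disease_%d", seq_len(nrow(theta)))
  }
  model <- phenotype_model(
    exposure_names = unlist(m$exposure_names),
    metabolite_loadings = loadings,
    metabolite_noise_sd = unlist(m$metabolite_noise_sd) %||% 1,
    exposure_noise_sd = unlist(m$exposure_noise_sd) %||% 1,
    disease_intercepts = unlist(m$disease_intercepts) %||% numeric(),
    disease_log_odds_per_exposure = theta,
    confounder_sd = m$confounder_sd %||% 0
  )
  targets <- lapply(y$targets, function(t) {
    do.call(drug_target, t[intersect(names(t), names(formals(drug_target)))])
  })
  args <- y[intersect(names(y), setdiff(names(formals(pipeline_config)),
                                        c("specs", "model", "targets")))]
  args$fractions <- unlist(y$fractions) %||% formals(pipeline_config)$fractions
  do.call(pipeline_config, c(list(specs = specs, model = model,
                                  targets = targets), args))
}

#' Run the full drug-target MR pipeline on a synthetic cohort
#'
#' Executes, in order: cohort simulation; exposure GWAS on the discovery
#' partition and outcome GWAS (metabolites linear, diseases logistic) on the
#' non-overlapping outcome partition; cis instrument selection and LD
#' pruning against the reference partition; correlated-instrument IVW for
#' every target on every disease; the metabolome-wide screen with per-target
#' FDR; cross-target concordance scaled by the first disease's effects; and
#' the age-stratified GRS regressions. Results are returned and, when `dir`
#' is given, written as TSVs with a JSON manifest; identical configurations
#' yield identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param dir optional output directory.
#' @return list with `cohort`, `exposure_stats`, `outcome_stats`,
#'   `disease_stats`, `instruments`, `instruments_50kb` (when requested),
#'   `disease_estimates` (data frame), `signatures`, `concordance`, `grs`
#'   and `manifest`.
#' @export
run_pipeline <- function(config, dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage_env <- new.env(parent = emptyenv())
  stage_env$stage <- "config"
  tryCatch(
    run_pipeline_stages(config, dir, stage_env),
    error = function(e) {
      # abort with the failing stage's name and a machine-readable code
      stop(structure(class = c("targetmr_stage_error", "error", "condition"),
                     list(message = sprintf("[stage:%s] %s", stage_env$stage,
                                            conditionMessage(e)),
                          call = NULL, stage = stage_env$stage,
                          code = paste0("E_", toupper(stage_env$stage)))))
    })
}

run_pipeline_stages <- function(config, dir, stage_env) {
  set_stage <- function(s) stage_env$stage <- s
  t0 <- Sys.time()
  manifest <- list(seed = config$seed,
                   n_individuals = config$n_individuals,
                   fractions = as.list(config$fractions),
                   versions = list(
                     targetmr = as.character(utils::packageVersion("targetmr")),
                     R = paste(R.version$major, R.version$minor, sep = ".")),
                   stages = list())
  note <- function(stage, rows) {
    manifest$stages[[stage]] <<- list(rows = rows)
    message(sprintf("[%s] %d rows", stage, rows))
  }

  set_stage("simulate")
  cohort <- simulate_cohort(config$specs, config$model, config$n_individuals,
                            config$fractions, config$seed)
  note("simulate", nrow(cohort$genotypes))

  set_stage("gwas_exposure")
  exposures <- unique(vapply(config$targets, function(t) t$exposure_trait,
                             character(1)))
  exposure_stats <- setNames(lapply(exposures, function(tr) {
    gwas_scan(cohort, tr, family = "linear", partition = "discovery")
  }), exposures)
  note("gwas_exposure", sum(vapply(exposure_stats, nrow, integer(1))))

  set_stage("gwas_metabolites")
  metab_traits <- if (!is.null(config$model$metabolite_loadings)) {
    rownames(config$model$metabolite_loadings)
  } else character()
  outcome_stats <- if (length(metab_traits)) {
    gwas_scan_multi(cohort, metab_traits, partition = "outcome")
  } else list()
  note("gwas_metabolites", length(outcome_stats))

  set_stage("gwas_disease")
  diseases <- if (!is.null(config$model$disease_log_odds_per_exposure)) {
    rownames(config$model$disease_log_odds_per_exposure)
  } else character()
  disease_stats <- setNames(lapply(diseases, function(d) {
    gwas_scan(cohort, d, family = "logistic", partition = "outcome")
  }), diseases)
  note("gwas_disease", length(disease_stats))

  set_stage("select_instruments")
  instruments <- list()
  for (tg in config$targets) {
    iset <- select_instruments(exposure_stats[[tg$exposure_trait]], tg, cohort)
    if (is.null(iset) || nrow(iset$variants) < 2L) {
      message("target ", tg$target_name, " has < 2 instruments; skipped")
      next
    }
    instruments[[tg$target_name]] <- iset
  }
  if (!length(instruments)) stop("no target has usable instruments",
                                 call. = FALSE)
  note("select_instruments",
       sum(vapply(instruments, function(i) nrow(i$variants), integer(1))))

  set_stage("select_instruments_50kb")
  instruments_50kb <- NULL
  if (config$sensitivity_50kb) {
    instruments_50kb <- list()
    for (nm in names(instruments)) {
      iset <- tryCatch(sensitivity_instruments(instruments[[nm]], 50),
                       warning = function(w) NULL)
      if (!is.null(iset)) instruments_50kb[[nm]] <- iset
    }
    note("select_instruments_50kb",
         sum(vapply(instruments_50kb, function(i) nrow(i$variants),
                    integer(1))))
  }

  set_stage("mr_disease")
  disease_estimates <- list()
  disease_mr <- list()
  for (nm in names(instruments)) {
    iset <- instruments[[nm]]
    tg <- iset$target
    for (d in diseases) {
      harm <- suppressMessages(
        harmonise(exposure_stats[[tg$exposure_trait]], disease_stats[[d]],
                  iset$variants$SNP,
                  drop_palindromic = config$drop_palindromic))
      est <- orient(ivw_correlated(mr_input_from(harm, iset$ld)), tg)
      or <- to_odds_ratio(est)
      disease_mr[[nm]][[d]] <- est
      disease_estimates[[length(disease_estimates) + 1L]] <- data.frame(
        target = nm, outcome = d, method = est$method,
        n_snps = est$n_instruments, theta = est$theta, se = est$se,
        ci_low = est$ci_low, ci_high = est$ci_high, p = est$p_value,
        f_stat = est$f_statistic, or = or$or, or_ci_low = or$ci_low,
        or_ci_high = or$ci_high, stringsAsFactors = FALSE)
    }
  }
  disease_estimates <- if (length(disease_estimates)) {
    do.call(rbind, disease_estimates)
  } else NULL
  note("mr_disease", if (is.null(disease_estimates)) 0L else
    nrow(disease_estimates))

  set_stage("screen")
  signatures <- NULL
  if (length(outcome_stats)) {
    active <- Filter(function(tg) tg$target_name %in% names(instruments),
                     config$targets)
    signatures <- run_screen(active, exposure_stats, outcome_stats, cohort,
                             fdr = config$fdr,
                             drop_palindromic = config$drop_palindromic)
    note("screen", sum(vapply(signatures, nrow, integer(1))))
  }

  set_stage("concordance")
  concordance <- NULL
  if (!is.null(signatures) && length(signatures) >= 2L && length(diseases)) {
    d1 <- diseases[1]
    dest <- lapply(disease_mr, `[[`, d1)
    baseline <- if (config$baseline %in% names(signatures)) config$baseline
                else names(signatures)[1]
    concordance <- all_pairs(signatures, dest, baseline = baseline)
    note("concordance", nrow(concordance))
  }

  set_stage("grs_strata")
  grs <- list()
  for (nm in names(instruments)) {
    w <- grs_weights_from(instruments[[nm]])
    scores <- build_grs(cohort, w)
    for (ph in config$grs_phenotypes) {
      res <- strata_regression(cohort, scores, ph, seed = config$seed)
      res$target <- nm; res$phenotype <- ph
      res$z_diff <- attr(res, "z_diff")
      grs[[length(grs) + 1L]] <- res
    }
  }
  grs <- if (length(grs)) do.call(rbind, grs) else NULL
  note("grs_strata", if (is.null(grs)) 0L else nrow(grs))

  set_stage("write_outputs")
  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  result <- list(cohort = cohort, exposure_stats = exposure_stats,
                 outcome_stats = outcome_stats, disease_stats = disease_stats,
                 instruments = instruments, instruments_50kb = instruments_50kb,
                 disease_estimates = disease_estimates,
                 disease_mr = disease_mr, signatures = signatures,
                 concordance = concordance, grs = grs, manifest = manifest)
  if (!is.null(dir)) write_pipeline_outputs(result, config, dir)
  result
}

write_pipeline_outputs <- function(result, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (config$write_cohort) write_cohort(result$cohort, file.path(dir, "cohort"))
  for (nm in names(result$exposure_stats)) {
    write_sumstats(result$exposure_stats[[nm]],
                   file.path(dir, sprintf("gwas_%s.tsv.gz", nm)))
  }
  inst_tab <- do.call(rbind, lapply(names(result$instruments), function(nm) {
    v <- result$instruments[[nm]]$variants; v$target <- nm; v
  }))
  write_tsv(inst_tab, file.path(dir, "instruments.tsv"))
  for (nm in names(result$instruments)) {
    write_ld_matrix(result$instruments[[nm]]$ld,
                    file.path(dir, sprintf("ld_%s.tsv", nm)))
  }
  if (!is.null(result$instruments_50kb)) {
    t50 <- do.call(rbind, lapply(names(result$instruments_50kb), function(nm) {
      v <- result$instruments_50kb[[nm]]$variants; v$target <- nm; v
    }))
    write_tsv(t50, file.path(dir, "instruments_50kb.tsv"))
  }
  if (!is.null(result$disease_estimates)) {
    write_tsv(result$disease_estimates, file.path(dir, "disease_mr.tsv"))
  }
  if (!is.null(result$signatures)) {
    long <- do.call(rbind, lapply(names(result$signatures), function(nm) {
      s <- as.data.frame(result$signatures[[nm]]); s$target <- nm; s
    }))
    write_tsv(long, file.path(dir, "metabolome_screen.tsv"))
    for (nm in names(result$signatures)) {
      write_tsv(as.data.frame(result$signatures[[nm]]),
                file.path(dir, sprintf("signature_%s.tsv", nm)))
    }
  }
  if (!is.null(result$concordance)) {
    write_tsv(result$concordance, file.path(dir, "concordance.tsv"))
    scaled <- attr(result$concordance, "scaled")
    for (i in seq_len(nrow(result$concordance))) {
      a <- result$concordance$target_a[i]; b <- result$concordance$target_b[i]
      write_tsv(scatter_data(scaled[[a]], scaled[[b]]),
                file.path(dir, sprintf("scatter_%s_vs_%s.tsv", b, a)))
    }
  }
  if (!is.null(result$concordance)) {
    scaled <- attr(result$concordance, "scaled")
    write_tsv(forest_data(scaled), file.path(dir, "forest_data.tsv"))
  }
  if (!is.null(result$grs)) write_tsv(result$grs, file.path(dir, "grs_strata.tsv"))
  manifest <- result$manifest
  manifest$thresholds <- list(
    fdr = config$fdr, gwas_threshold = config$gwas_threshold,
    windows_kb = vapply(config$targets, function(t) t$window_kb, numeric(1)),
    p_thresholds = vapply(config$targets, function(t) t$p_threshold,
                          numeric(1)),
    r2_thresholds = vapply(config$targets, function(t) t$r2_threshold,
                           numeric(1)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' A small ready-made demonstration configuration
#'
#' Three drug-target analogues on two exposure pathways: two targets whose
#' loci drive an LDL-like exposure and one driving a triglyceride-like
#' exposure, a 24-trait metabolite panel (one third loading on each
#' exposure, one third on neither) and a CAD-like disease caused by both
#' exposures. Defaults emulate the study design at desk scale.
#'
#' @param n_individuals cohort size (default 20000).
#' @param seed master seed.
#' @param effect_scale multiplier on the causal variant effects (default 1,
#'   calibrated for instrument discovery at the default cohort size; raise
#'   it when running the demo on much smaller cohorts).
#' @param ... passed on to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
demo_config <- function(n_individuals = 20000, seed = 1L, effect_scale = 1,
                        ...) {
  specs <- list(
    locus_spec("ldlA", "5", 900000, 1150000, n_variants = 30,
               maf_range = c(0.1, 0.45), ld_decay_rho = 0.6,
               causal_indices = c(5, 12, 20, 26),
               causal_effects = effect_scale * c(0.12, 0.10, -0.08, 0.09),
               exposure = "LDL"),
    locus_spec("ldlB", "1", 4900000, 5150000, n_variants = 30,
               maf_range = c(0.1, 0.45), ld_decay_rho = 0.6,
               causal_indices = c(4, 13, 22, 27),
               causal_effects = effect_scale * c(0.11, -0.09, 0.10, 0.08),
               exposure = "LDL"),
    locus_spec("tgA", "8", 19700000, 19950000, n_variants = 30,
               maf_range = c(0.1, 0.45), ld_decay_rho = 0.6,
               causal_indices = c(6, 14, 21, 25),
               causal_effects = effect_scale * c(0.12, 0.09, -0.10, 0.08),
               exposure = "TG")
  )
  model <- demo_phenotype_model(seed)
  targets <- list(
    drug_target("LDLTA", "5", 1000000, 1050000, "LDL", -1),
    drug_target("LDLTB", "1", 5000000, 5050000, "LDL", -1),
    drug_target("TGTA", "8", 19800000, 19850000, "TG", -1)
  )
  pipeline_config(specs, model, targets, n_individuals = n_individuals,
                  seed = seed, baseline = "LDLTA", ...)
}

# Metabolite panel + disease model shared by the demo configuration:
# 8 traits per block (LDL-loading, TG-loading, non-lipid), loadings spread
# over 0.25-0.95 with small cross-loadings, and a CAD-like disease at ~10%
# prevalence caused by both exposures.
demo_phenotype_model <- function(seed = 1L) {
  loadings <- with_seed(seed + 7L, {
    A <- matrix(0, 24, 2, dimnames = list(
      c(sprintf("ldl_trait_%02d", 1:8), sprintf("tg_trait_%02d", 1:8),
        sprintf("other_trait_%02d", 1:8)),
      c("LDL", "TG")))
    A[1:8, "LDL"] <- seq(0.25, 0.95, length.out = 8)
    A[9:16, "TG"] <- seq(0.25, 0.95, length.out = 8)
    A[1:16, ] <- A[1:16, ] + matrix(rnorm(32, sd = 0.03), 16, 2)
    A
  })
  theta <- matrix(c(0.35, 0.25), 1, 2,
                  dimnames = list("CAD", c("LDL", "TG")))
  phenotype_model(
    exposure_names = c("LDL", "TG"),
    metabolite_loadings = loadings,
    metabolite_noise_sd = 0.6,
    exposure_noise_sd = 1,
    disease_intercepts = disease_intercept_for_prevalence(0.10, theta["CAD", ]),
    disease_log_odds_per_exposure = theta
  )
}
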