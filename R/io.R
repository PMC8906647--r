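# File-format plumbing: summary-statistics TSV (canonical header
# `SNP CHR POS EA NEA EAF BETA SE P N`), LD-matrix TSV, gene-region TSV,
# dosage TSV and a minimal VCF writer. All TSV readers/writers are
# gzip-transparent via the .gz suffix.

tsv_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

write_tsv <- function(df, path, col.names = TRUE) {
  con <- tsv_connection(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names)
}

read_tsv <- function(path, ...) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Write / read GWAS summary statistics
#'
#' TSV with the exact header `SNP CHR POS EA NEA EAF BETA SE P N`;
#' `.gz` paths are compressed/decompressed transparently.
#'
#' @param stats a [summary_stats()] data frame.
#' @param path file path.
#' @return `read_sumstats` returns a validated [summary_stats()].
#' @export
write_sumstats <- function(stats, path) {
  write_tsv(as.data.frame(stats), path)
  invisible(path)
}

#' @param trait_name trait label for the returned object.
#' @rdname write_sumstats
#' @export
read_sumstats <- function(path, trait_name = sub("\\.tsv(\\.gz)?$", "",
                                                 basename(path))) {
  summary_stats(read_tsv(path, colClasses = list(CHR = "character")),
                trait_name = trait_name)
}

#' Write / read an LD matrix
#'
#' TSV with a variant-ID header row and a leading variant-ID column.
#'
#' @param ld matrix from [compute_ld()].
#' @param path file path.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- data.frame(SNP = rownames(ld), as.data.frame(unclass(ld),
                                                     check.names = FALSE),
                   check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$SNP
  structure(m, class = c("ld_matrix", "matrix", "array"))
}

#' Read drug-target gene regions from a TSV
#'
#' Expects columns `target chrom start end` plus optionally
#' `exposure direction window_kb p_threshold r2_threshold`.
#'
#' @param path file path.
#' @param exposure_trait,therapeutic_direction defaults applied when the
#'   optional columns are absent.
#' @return list of [drug_target()] objects.
#' @export
read_gene_regions <- function(path, exposure_trait = "exposure",
                              therapeutic_direction = -1) {
  df <- read_tsv(path, colClasses = list(chrom = "character"))
  req <- c("target", "chrom", "start", "end")
  if (!all(req %in% names(df))) {
    stop("gene-region file must have columns: ", paste(req, collapse = " "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    drug_target(
      df$target[i], df$chrom[i], df$start[i], df$end[i],
      exposure_trait = df$exposure[i] %||% exposure_trait,
      therapeutic_direction = df$direction[i] %||% therapeutic_direction,
      window_kb = df$window_kb[i] %||% 100,
      p_threshold = df$p_threshold[i] %||% 1e-6,
      r2_threshold = df$r2_threshold[i] %||% 0.1
    )
  })
}

#' Write cohort genotypes as a minimal VCF
#'
#' Unphased diploid GT records (`0/0`, `0/1`, `1/1`), REF = other allele,
#' ALT = effect allele, one sample column per individual.
#'
#' @param cohort a `cohort_data` (or dosage matrix with `variants` given).
#' @param path output path (plain text or `.gz`).
#' @param variants variant table when `cohort` is a bare matrix.
#' @export
write_vcf <- function(cohort, path, variants = NULL) {
  if (inherits(cohort, "cohort_data")) {
    G <- cohort$genotypes
    variants <- cohort$variants
  } else {
    G <- as.matrix(cohort)
    if (is.null(variants)) stop("`variants` table required", call. = FALSE)
  }
  n <- nrow(G)
  samples <- rownames(G) %||% sprintf("ind_%05d", seq_len(n))
  con <- tsv_connection(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=targetmr",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(G))) {
    gt <- gt_codes[G[, j] + 1L]
    gt[is.na(G[, j])] <- "./."
    writeLines(paste(c(variants$CHR[j], variants$POS[j], variants$SNP[j],
                       variants$NEA[j], variants$EA[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read effect-allele dosages from a VCF
#'
#' Parses GT fields into ALT-allele (= effect allele) dosage counts using
#' the vcfR package.
#'
#' @param path VCF path.
#' @return list with `dosages` (individuals x variants matrix) and
#'   `variants` (`SNP CHR POS EA NEA` table; EA is ALT).
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c("./.", ".|."), NA_integer_,
           vapply(strsplit(x, "[/|]"), function(a) sum(a == "1"), integer(1)))
  }
  dos <- t(apply(gt, 1, count_alt))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  variants <- data.frame(SNP = fix$ID, CHR = fix$CHROM,
                         POS = as.integer(fix$POS),
                         EA = fix$ALT, NEA = fix$REF,
                         stringsAsFactors = FALSE)
  dos <- t(dos)  # individuals x variants
  colnames(dos) <- variants$SNP
  rownames(dos) <- colnames(gt)
  list(dosages = dos, variants = variants)
}

#' Write a cohort to a directory
#'
#' Emits genotypes as VCF and as a dosage TSV, phenotypes and covariates as
#' TSV with headers, the partition assignment, and the ground-truth
#' generative parameters as YAML.
#'
#' @param cohort a `cohort_data`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(cohort, file.path(dir, "genotypes.vcf"))
  dos <- data.frame(individual = sprintf("ind_%05d",
                                         seq_len(nrow(cohort$genotypes))),
                    cohort$genotypes, check.names = FALSE)
  write_tsv(dos, file.path(dir, "dosages.tsv.gz"))
  write_tsv(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_tsv(cohort$covariates, file.path(dir, "covariates.tsv"))
  write_tsv(data.frame(individual = dos$individual,
                       partition = cohort$partition),
            file.path(dir, "partition.tsv"))
  truth <- cohort$truth
  yaml::write_yaml(list(
    exposure_sd = as.list(truth$exposure_sd),
    gamma = if (!is.null(truth$gamma)) {
      lapply(seq_len(nrow(truth$gamma)), function(i) as.list(truth$gamma[i, ]))
    },
    theta = if (!is.null(truth$theta)) {
      lapply(rownames(truth$theta), function(d) as.list(truth$theta[d, ]))
    }
  ), file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}
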