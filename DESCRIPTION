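Package: targetmr
Title: Drug-Target Mendelian Randomisation with Correlated Instruments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for drug-target mendelian randomisation:
    cis instrument selection around drug-target genes, linkage-disequilibrium
    pruning against a reference panel, inverse-variance-weighted causal
    estimation accounting for correlation between instruments, metabolome-wide
    screening with per-target false-discovery-rate control, cross-target
    signature concordance, and age-stratified genetic-risk-score sensitivity
    analyses. Includes a synthetic cohort generator with known ground-truth
    parameters (autoregressive linkage disequilibrium, lipid exposures,
    a metabolite panel, binary disease outcomes) so every stage is verifiable
    end to end without individual-level biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
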