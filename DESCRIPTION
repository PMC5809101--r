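Package: esrtree
Title: Branch-Specific Effective Sex Ratios from Autosomal and X-Linked SNP Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian inference of per-branch drift times and effective
    sex ratios (ESR) on a fixed population tree, from paired autosomal and X-linked
    SNP allele-count tables. Allele frequencies are modelled along each branch with
    Kimura's time-dependent pure-drift diffusion, the likelihood is conditioned on
    SNP polymorphism through the coalescent distribution of ancestral lineage counts
    at the root, and a Metropolis-within-Gibbs sampler with joint reflected updates
    of the autosomal and X-linked branch lengths explores the posterior. Includes
    posterior summaries (ESR, support statistic, DIC-based topology comparison) and
    a sex-specific demography simulator (model-faithful forward mode and a
    generation-by-generation coalescent mode with migration, size changes and
    discovery-panel ascertainment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    ape,
    readr,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
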