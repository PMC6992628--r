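Package: traitvolume
Title: Trait Probability Density Functional Diversity for Saproxylic Beetle Assemblages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for functional-trait analysis of insect
    community data: species-level trait derivation (robustness residuals,
    elytra and eye ratios, activity period and thermal range), rare-species
    and missing-trait filters, Gower dissimilarity and principal coordinates
    reduction of mixed trait tables, trait probability density (TPD)
    functional diversity (functional richness, evenness, divergence and
    redundancy) on a discretised trait space, area-restricted matrix-swap
    null models with standardised effect sizes for functional richness and
    mean pairwise distance, taxonomic and functional turnover (Bray-Curtis
    and TPD-overlap dissimilarity, PERMANOVA, PERMDISP, NMDS), and factorial
    inference with false-discovery-rate control. Includes a
    synthetic-community generator with plantable assembly signals (niche
    filtering, limiting similarity) for end-to-end validation without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    cluster,
    Rcpp,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
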