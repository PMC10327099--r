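Package: charr
Title: Contamination Estimation from Reference Reads at Homozygous-Alternate
    Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates DNA sample contamination directly from variant-level
    genotype data (VCF), without BAM/CRAM access, by measuring the
    infiltration of reference reads at high-quality homozygous-alternate
    genotypes. Implements the allele-frequency-adjusted per-sample estimator
    (mean of RR / (p * (AR + RR)) over filtered hom-alt sites), a per-sample
    binomial likelihood with grid-search maximum-likelihood estimation of the
    contamination rate, the recommended variant-selection filter chain
    (autosomal bi-allelic SNVs, GQ >= 20, 20 <= DP <= 100, 10% < reference
    AF < 90%), and a genotype-level contamination simulator supporting
    two-way and pooled (n-way) read mixing with a flat-prior maximum
    likelihood genotype caller, so that hom-alt to het conversion at high
    contamination emerges in simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    S4Vectors,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
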