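Package: itgh
Title: Intratumoral Genetic Heterogeneity from Somatic Variant Allele Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intratumoral genetic heterogeneity (ITGH) from somatic
    single-nucleotide variant calls. Reads variant tables (VCF, TCGA MAF, or a
    plain TSV dialect), computes per-sample mutant-allele frequency (MAF)
    distributions and the MATH score (mutant-allele tumor heterogeneity),
    detects per-variant allele-frequency shifts between matched pre- and
    post-treatment tumor samples with exact binomial tests and multiple-testing
    correction ("enriched mutations"), summarizes substitution spectra (6-class
    and 96 trinucleotide contexts with signature-exposure refitting), and runs
    cohort-level association statistics (stage, nodal status, copy-number
    burden, purity). Includes a seeded simulator of matched tumor pairs with
    known clonal architecture, purity dilution and binomial read sampling, so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    vcfR,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'SampleVariants-class.R'
    'cli.R'
    'clonal-dynamics.R'
    'cohort.R'
    'itgh-package.R'
    'math.R'
    'simulate.R'
    'spectrum.R'
    'variant-io.R'
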