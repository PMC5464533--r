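Package: mendelkit
Title: Variant Annotation, Filtering and Prioritization for Mendelian Disorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing candidate disease variants in whole-exome and
    whole-genome VCF files from patients with suspected Mendelian disorders.
    Normalizes and validates patient VCFs, annotates them against reference
    frequency panels (1000 Genomes-, ESP-, dbSNP-like), per-allele pathogenicity
    score tables and gene/disease catalogs, and filters the annotated variants
    with composable criteria (zygosity, consequence impact, read depth, quality,
    population frequency, dbSNP build, gene panels, score thresholds), Mendelian
    inheritance models for trios (autosomal recessive homozygous, compound
    heterozygous, autosomal dominant, de novo, X-linked hemizygous), a one-call
    preset reproducing a conservative default filter chain, genotype concordance
    comparison between call sets, and a deterministic synthetic-family generator
    with planted causal variants for end-to-end testing and training.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
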