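# mendelkit

Variant annotation, filtering and prioritization for the diagnosis of
Mendelian disorders from whole-exome or whole-genome VCF files.

When a patient with a suspected monogenic condition is exome-sequenced, the
caller emits tens of thousands of variants and the diagnostic question is
which *one* (or, for compound heterozygotes, which pair) explains the
phenotype. mendelkit implements the computational core of that triage as a
plain R library plus a small command line: it normalizes and validates the
patient VCF, joins it against reference panels (population frequencies,
rs-identifier builds, per-allele pathogenicity scores) into namespaced INFO
annotations, and then prunes the variant list with composable filters,
family segregation models and gene-catalog restrictions until a short
manually-reviewable candidate list remains. A deterministic synthetic-data
generator produces complete families, panels and catalogs with a planted
causal variant, so the whole pipeline is testable end to end without any
external database.

## The filtering model

A record survives [`apply_filters()`] iff it satisfies **every** active
criterion of a declarative `filter_spec()` (conjunction); allele-level
criteria (population frequency, scores) are evaluated per ALT allele.
The preset chain `default_spec()` is:

* drop variants first catalogued in **dbSNP build ≤ 129** (the last build
  predating large-scale inclusion of pathogenic SNVs),
* drop calls with **read depth < 10**,
* keep only **HIGH / MODERATE** consequence impacts,
* drop variants with **frequency > 1%** in the 1000 Genomes-, dbSNP- and
  ESP6500-like panels (unannotated — i.e. novel — variants are kept),
* no pathogenicity-score thresholds by default.

Missing values are never treated as zero: a record lacking DP, QUAL, a
frequency or a score passes the corresponding criterion (configurable via
`strict_depth` / `keep_unannotated_frequency`).

Family structure enters through `filter_inheritance()` with five
segregation models over a pedigree: `AR_HOM` (proband 1/1, parents
heterozygous carriers), `AR_COMPHET` (≥ 2 heterozygous variants in one
gene, in *trans* by parental transmission), `AD_HET` (heterozygous,
segregating with affection status), `DE_NOVO` (heterozygous, verifiably
absent from both parents) and `XL_HEMI` (hemizygous alternate on X in a
male proband, carrier mother). `one_click()` composes the preset, the
per-individual filters, the common-genes intersection, an inheritance
model and a known-disease-gene restriction into a single call with
per-stage counts.

## Worked example

```r
library(mendelkit)

cfg    <- synth_config(seed = 1, model = "AR_HOM")   # 20,000 sites, 1,000 genes
dir    <- tempfile()
panels <- make_panels(cfg, dir)                      # frequency/score panels + catalogs
fam    <- make_family(cfg, dir)                      # trio VCF with planted culprit

ann <- annotate_all(fam$variant_set, annotation_config(panels$panels))
rep <- one_click(ann, fam$pedigree,
                 one_click_options("PROBAND", inheritance_model = "AR_HOM",
                                   disease_catalogs = list(panels$disease_catalog)))
print(rep)
#> <CandidateReport> 1 of 4211 record(s) surviving in 1 gene(s)
#>                           stage n_in n_out
#>           apply_filters:PROBAND 4211    48
#>              inheritance_AR_HOM   48     1
#>  gene_panel:known_disease_genes    1     1

as.data.frame(rep)[, c("gene", "chrom", "pos", "ref", "alt", "impact",
                       "GT_PROBAND", "GT_MOTHER", "GT_FATHER")]
#>     gene chrom    pos ref alt impact GT_PROBAND GT_MOTHER GT_FATHER
#> 1 GN0440     3 286664   T   A   HIGH        1/1       0/1       0/1

fam$truth$gene
#> [1] "GN0440"
```

The trio VCF holds the 4,211 sites at which the family carries an
alternate allele. The preset filters leave 48 candidates, the recessive
segregation model leaves exactly one — the planted causal variant, a
homozygous HIGH-impact change absent from every frequency panel, in the
gene the generator registered in the disease catalog.

The same operations are scriptable from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/mendelkit.R", package = "mendelkit"))')
Rscript $CLI synth --model ar_hom --seed 1 --out demo
Rscript $CLI one-click demo/trio.vcf --config demo/panels.cfg \
        --diseases demo/diseases.tsv --ped demo/trio.ped --model ar_hom -o report.tsv
Rscript $CLI summary demo/trio.vcf --json
Rscript $CLI compare demo/trio.vcf demo/trio.vcf --json
```

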