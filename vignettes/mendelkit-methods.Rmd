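---
title: "mendelkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mendelkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mendelkit)
```

mendelkit prioritizes candidate disease variants for patients with
suspected Mendelian disorders. This vignette records the package's model
of the problem, the semantics of each processing stage, the parameters
that matter, and the design decisions taken where more than one reasonable
choice existed. It states no empirical claim that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The data model

A `VariantSet` mirrors a VCF file: header meta lines, sample names, typed
fixed fields per record, an ordered INFO map, and per-sample GT/DP/GQ.
Three narrowing choices:

* **Only GT, DP and GQ are retained from FORMAT.** These are the only
  per-call fields any downstream operation consumes (zygosity, the depth
  filter, and quality display). Other FORMAT fields are dropped at parse
  time; round-trip identity (`parse_vcf(write_vcf(x)) == x`) holds on this
  model, not on arbitrary foreign FORMAT content.
* **INFO values are typed by the header.** `##INFO` declarations drive
  Integer/Float/Flag conversion; undeclared keys stay strings. Writing
  declares any keys the header lacks, so files the package emits always
  re-parse with identical types.
* **Zygosity classes** are `missing` (any missing allele), `hom_ref`,
  `het`, `hom_alt`, and `hemi` (a single-allele non-reference call).
  A single-allele reference call ("0", a male X reference site) counts as
  `hom_ref`, which makes it removable by the sanity check like any other
  non-carrier record.

File reading is delegated to `vcfR` (plain and gzip); writing is plain
VCF 4.2 text.

## Sanity check

`sanity_check()` prepares an uploaded file for annotation: it removes
records at which no sample carries an alternate allele, strips `chr`
prefixes in any capitalization, sorts, and deletes leftover `EFF`/`ANN`
consequence annotations from earlier runs. Two interpretations are fixed
here:

* **Multi-sample files.** Removing every record *containing* a 0/0 call
  would destroy trio analysis (a de novo candidate necessarily has 0/0
  parents), so a record is removed only when **every** sample call is
  homozygous-reference or missing.
* **Chromosome order** is the natural human order 1–22, X, Y, MT, with
  unknown contigs after MT lexicographically; within a chromosome,
  position, then REF, then ALT. "Sorted by chromosome name" alone does not
  decide between lexicographic and natural order; natural order matches
  genome-browser convention and keeps 2 before 10.

The operation is idempotent, which the test suite checks on randomized
inputs.

## Annotation

Each reference panel (a coordinate-sorted VCF or a per-allele score table)
is loaded into an in-memory index with two access paths: a per-chromosome
sorted position vector for interval queries (binary search via
`findInterval`, logarithmic per query) and an exact
(chrom, pos, ref, alt) key map for the annotation join. The interval-query
contract is what an on-disk tabix index provides; at the panel sizes this
package targets an in-memory index gives the same results (the test suite
checks equivalence against a linear scan) without bgzip file management.

Joins are **allele-exact**, not position-only: frequency and score values
attach to a target allele only when chromosome, position, REF and that ALT
allele all agree. Position-only matching would attach wrong-allele
frequencies, and the rare-variant filters downstream are only meaningful
with allele-level frequencies. Multi-allelic targets are annotated per
alt in ALT order (comma lists, `.` for alleles without a match) and are
*not* decomposed into biallelic records, preserving the input's line
structure.

Every copied field lands in INFO as `<panel>_<field>` — e.g. `1000g_AF`,
`dbsnp_build`, `dbnsfp_sift_score`. Prefix uniqueness is enforced and a
collision with an existing key is a hard error, so with hundreds of
annotated fields every value stays traceable to its source, and the merge
is commutative: `annotate_all()` canonicalizes the added keys so its
output is identical for any panel evaluation order and for chunked
processing. Consequence impact (`impact`) and gene assignment (`gene`)
are consumed as INFO fields produced upstream (by an effect predictor) or
by the synthetic generator; re-implementing effect prediction is out of
scope. The dbSNP first-build number is likewise expected as an integer
field (`dbsnp_build`) copied from a dbSNP-like panel.

## Filter semantics

`filter_spec()` is declarative; `NULL` means "criterion inactive", and a
record survives the conjunction of all active criteria, so criterion order
is irrelevant and tightening any criterion can only shrink the survivor
set. Three policies deserve emphasis:

* **Missing is absent, never zero.** Records lacking DP, QUAL, a
  frequency or a score **pass** the corresponding criterion by default.
  Many VCF dialects omit per-call DP; silently discarding those records
  would be surprising. `strict_depth = TRUE` and
  `keep_unannotated_frequency = FALSE` switch to the conservative
  readings.
* **Frequency direction.** The tool this package models describes its
  preset as excluding variants "with frequency lower than 1%", which
  taken literally would discard exactly the rare variants Mendelian
  analysis seeks and retain common polymorphism. Every validated use of
  the preset recovered *rare* pathogenic variants, which is only possible
  if common variants are the ones excluded. mendelkit therefore excludes
  variants whose panel frequency **exceeds** the cutoff and keeps rare and
  unobserved ones. This interpretation is deliberate and surfaced here
  because the original wording is ambiguous.
* **Multi-allelic records.** Allele-level criteria (frequencies, scores)
  are evaluated per ALT allele; the record survives the allele-level block
  if *any* allele passes all of them. Record-level criteria (zygosity,
  impact, depth, quality, build, region, gene) apply once.

The dbSNP-build criterion excludes records whose first build is present
and ≤ the cutoff; build 129 is the preset value because it is the last
dbSNP release predating large-scale inclusion of pathogenic clinical
variants — excluding "old" rs numbers removes long-known polymorphism
without touching recently catalogued pathogenic variants.

## Inheritance models

All five models key on the proband and degrade gracefully when relatives
are absent or uncalled, with one deliberate exception:

* `AR_HOM`: proband `hom_alt`; each *available* parent must be a
  heterozygous carrier of that allele (exactly one copy, not `hom_alt`).
  An uncalled parental genotype skips that parent's check rather than
  failing it.
* `AR_COMPHET`: a gene qualifies with ≥ 2 distinct heterozygous proband
  variants; with both parents present the configuration must be *trans by
  transmission* — at least one variant carried by the mother and not the
  father, and at least one by the father and not the mother. Without both
  parents the gene still qualifies (single-proband studies could not use
  the model otherwise) but every record carries a `phase_unverified`
  provenance flag.
* `AD_HET`: proband heterozygous; available *affected* members must carry
  the allele and available *unaffected* members must not. Parents are
  **not** implicitly treated as unaffected: a dominant disorder may be
  inherited from an affected parent, so requiring parental absence would
  conflate dominant inheritance with de novo origin. Callers who want
  that constraint list the parents among the unaffected members — or use:
* `DE_NOVO`: proband heterozygous and both parents verifiably reference:
  the model errors without both parents, and a site with an uncalled
  parental genotype is dropped, because "absent from both parents" cannot
  be asserted from missing data.
* `XL_HEMI`: X-chromosome sites in a male proband (the model errors when
  the proband's sex is unknown). Upstream callers disagree on how male X
  genotypes are written, so both a single-allele call ("1") and an
  effectively homozygous call ("1/1") count as hemizygous alternate; when
  the mother is available she must be a heterozygous carrier.

## The one-call preset

`one_click()` fixes the pipeline order: per-individual preset filters →
intersection of genes with survivors in every individual → inheritance
model → disease-gene restriction. Filtering before the common-genes step
means the intersection is taken over *plausible* variants rather than raw
calls; each stage's input/output counts are recorded in the report so the
order is auditable. The known-disease-gene restriction is on by default
(the preset's purpose is a clinician-reviewable list in catalogued genes)
but can be disabled, since novel-gene discovery requires the unrestricted
path. Candidates are ordered by gene symbol then locus; no pathogenicity
ranking is applied by default — score thresholds are deliberately absent
from the preset so a variant mis-scored by one predictor is not silently
dropped.

## Call-set comparison

`compare_vcfs()` matches records by position only (two call sets need not
encode ALT alleles identically) and then compares genotypes as **allele
multisets** resolved to strings, ignoring phase, so `0/1` against an
`A>T,G` record's `0/2` compares correctly. Sites at which either side's
genotype is missing are excluded from both the shared-position count and
the denominator: a missing call is evidence of absence of data, not of
discordance. With no shared called positions the percentage is reported
as absent rather than 0. The percentage retains full precision
internally; display rounds to one decimal.

## The synthetic generator

`synth_config()` + `make_panels()` + `make_family()` emulate the complete
input universe: an exome-like background of variant sites over a gene
layout, frequency panels, a dbSNP-like panel with first-build numbers, a
per-allele score table, gene/disease catalogs, and a trio VCF with a
planted causal variant. Defaults, with rationale:

* **Site pool**: 20,000 sites over 1,000 genes laid out round-robin on
  chromosomes 1–22 and X. The family VCF contains the subset at which the
  trio carries an alternate allele (≈ 4,000–4,500 records) — a patient
  VCF likewise only contains called variant lines.
* **Frequency mixture**: 30% common sites (AF ~ Uniform(0.05, 0.5)), 70%
  rare (AF ~ Uniform(0.0001, 0.01)). Because common alleles are far more
  likely to appear in any given family, the *emitted* records are
  dominated by common variants, which is what makes the preset's
  frequency and build filters bite, mirroring real exomes.
* **dbSNP builds**: 95% of common sites carry builds 80–129, the rest are
  post-129 or absent; rare sites are mostly unassigned (10% carry builds
  130–150). This encodes "old rs number ⇒ long-known polymorphism".
* **Depth**: Poisson around 60× (exome-like), with 5% of records forced
  below DP 10 to exercise the depth filter. **Impact**: 5% HIGH,
  15% MODERATE, 40% LOW, 40% MODIFIER.
* **Genotypes**: parents drawn from Hardy–Weinberg proportions at the
  site frequency; the proband receives one allele from each parent
  (single-allele paternal and proband calls on X — the proband is male,
  which lets one generator serve the X-linked model). Background sites
  are therefore Mendelian-consistent by construction.
* **The planted truth**: causal variant(s) in a catalogued disease gene
  matching the model's inheritance label, HIGH impact, DP ≥ 10 in all
  members, absent from every panel, with genotypes segregating exactly
  under the model (e.g. 1/1 proband with 0/1 parents for `AR_HOM`; two
  hets in one gene, one from each parent, for `AR_COMPHET`).

Everything is fixed by a single seed: equal configurations produce
byte-identical files.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: linkage disequilibrium and haplotype structure,
indels and multi-nucleotide variants (background sites are SNVs),
genotyping error and Mendelian violations, population stratification in
the panels, batch effects, and incomplete penetrance. The planted-truth
recovery results are statements about the pipeline's correctness, not
about clinical sensitivity.

## Numerical and testing choices

Problem sizes in the acceptance suite were chosen as the package's
standard demonstration scale: four 20,000-site trios (one per inheritance
model) for planted-culprit recovery, 1,000 annotated records × 200 random
specifications against a brute-force per-record evaluator, exhaustive
trio-genotype enumeration (343 single-site combinations per model, 256
two-variant phase configurations for compound heterozygosity), 1,000
interval queries against a linear scan on a 10,000-site panel, and 100
randomized cases for the sanity-check property suite. Floating-point
values written to generated files are rounded (frequencies to 6 decimals,
scores to 4) so that write/parse round trips are exact.

## Known limitations

* Indel normalization (left alignment) is not performed beyond what the
  input provides; allele-exact joins assume consistent representation
  between target and panels.
* Symbolic ALT alleles (`<DEL>` etc.) are rejected by validation rather
  than interpreted.
* `.zip`/`.rar` archives are not read; inputs are plain or gzipped VCF.
* Gene identity is by symbol string; no identifier mapping across
  nomenclature revisions.
* The compound-heterozygosity trans check uses transmission, not read
  phase; two variants both transmitted by the same parent alongside a
  third from the other parent make the gene qualify on the pair that is
  informative.
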