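---
title: "Methods: gene-panel triage of annotated exome variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-panel triage of annotated exome variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pidtriage)
```

## The problem

Common variable immunodeficiency (CVID) is the most common symptomatic
primary immunodeficiency (PID), and genetically one of the least
homogeneous: dominant, recessive, and X-linked defects in dozens of genes
produce overlapping antibody-deficiency phenotypes, and most cases are
sporadic. A practical diagnostic strategy is whole-exome sequencing
followed by a *targeted* screen: restrict the exome to a curated panel of
PID-associated genes, remove variants that are too common in the general
population for the inheritance model under consideration, gate on a
deleteriousness score, and then judge the survivors by inheritance mode,
familial segregation, and phenotype fit. `pidtriage` implements that
triage as a deterministic, auditable pipeline.

## The filtering cascade

Input is a multi-sample VCF with per-sample `GT`/`DP`/`GQ`, variant
annotations (gene, HGVS, CADD-scaled score, ExAC allele frequency, HGMD
status) carried either in INFO keys or in a sidecar TSV, a 6-column PED
pedigree, a panel table, and per-patient phenotype tags. Four gates are
applied to every carrier call (het or hom_alt) of every proband, in
order; each decision is logged with a machine-readable reason:

1. **Call quality.** A call is removed when read depth ≤ 2 or
   Phred-scaled quality ≤ 20. The source protocol conjoins the two
   conditions in prose; we remove on *either* by default — the stricter
   reading, which protects downstream claims from marginally supported
   calls — and expose `quality_connective = "both"` for the conjunctive
   reading. Calls with *absent* depth or quality pass: orthogonally
   confirmed genotypes (Sanger, IGV review) carry no such metadata and
   must not be dropped for it.
2. **Panel membership.** Case-insensitive gene-symbol match against the
   panel. The panel is content, not engine logic: excluding, say,
   X-linked agammaglobulinemia genes from a CVID screen is done by
   editing the panel table.
3. **Population frequency.** A variant never observed in the reference
   population (absent frequency) passes as *novel*. Otherwise the
   governing threshold depends on the inheritance hypothesis:
   `het_af_max = 1e-4` (0.01%) under a monoallelic hypothesis,
   `biallelic_af_max = 1e-2` (1%) under a biallelic one. Exclusion is
   strict (`> threshold` fails), so a frequency exactly at the cutoff
   passes — the published rule is phrased as an exclusion of variants
   *above* the cutoff. The heterozygous default deserves a note: the
   source material prints the heterozygous cutoff both as "0.01" and as
   "<0.1%" in different places. We default to the tighter 0.01% reading
   (the only heterozygous survivor with a reported frequency,
   8.256e-6, passes either way) and make both thresholds configurable.
4. **CADD vs MSC.** A variant passes when its CADD-scaled score reaches
   the gene-specific mutation significance cutoff (MSC). Which
   confidence level the MSC values were derived at is consumed, not
   chosen, here: `msc` is panel content. Two escapes exist: variants
   with no CADD score, or genes with no MSC, pass "ungated" (and are
   flagged as such); and a sub-MSC variant is rescued when
   `msc_override_enabled` and the patient's phenotype matches the gene.
   The override is the auditable form of the expert judgement that
   retains, for example, sub-MSC biallelic LRBA variants in a patient
   whose phenotype closely matches LRBA deficiency; it always leaves the
   reason `msc_override_phenotype` in the decision log.

### Hypothesis routing

The published frequency rule is zygosity-dependent, but a compound
heterozygote is functionally biallelic while each of its variants is
individually heterozygous. We therefore route by the patient's zygosity
*pattern* per gene, computed on the quality- and panel-surviving calls: a
hom_alt call, or a het call in an AR/XL-capable panel gene holding at
least two het calls, is judged under the biallelic (1%) threshold;
everything else under the monoallelic threshold. This reproduces the
retention of a compound-het LRBA allele at frequency 0.2165%, which the
0.01% heterozygous bound would otherwise discard. The pattern is fixed
once, before the frequency and CADD gates run, which makes those two
stages pure per-call predicates — they commute, and the cascade is
idempotent on its own survivors under this routing.

## Inheritance grouping and trio phasing

Survivors are grouped per patient and gene: hom_alt calls become
`biallelic_hom` groups (hemizygous male X calls are encoded hom_alt and
route the same way); two or more het calls in an AR-capable gene become a
compound-het candidate; any other het call is `monoallelic`. A lone het
call in an AR-only gene deliberately stays monoallelic — the classifier
demotes it as a zygosity mismatch rather than hiding it.

Compound-het candidates are phased through parental genotypes. For each
variant, the donor parent must carry the alternate allele and the other
parent must be able to donate the reference allele; a variant is
*maternal*, *paternal*, *ambiguous* (both parents could have donated),
or *inconsistent* (neither could — a Mendelian error, which logs a
warning). Once two variants trace unambiguously to different parents the
group is in trans (`biallelic_comphet`); if all variants trace to one
parent the pair is in cis and splits back into monoallelic groups (a
false compound heterozygote); anything else — an ungenotyped parent or
unresolved ambiguity — stays `biallelic_unphased` with flag
`phase_unknown`. The test suite checks this decision procedure against a
brute-force enumeration of all consistent parental-origin assignments
over every two-variant trio genotype configuration (and sampled
three-variant ones); during development the oracle exposed and corrected
a too-conservative handling of groups mixing determinate and ambiguous
origins. Sibling-only phasing is not attempted: the inference rule used
by studies that phase through sibling exomes is not specified precisely
enough to reimplement, so sibling-only pedigrees stay `phase_unknown`.

Monoallelic groups in full trios are tested for de novo status (proband
het, both parents genotyped hom_ref); a genotyped carrier parent who is
unaffected yields `inherited_unaffected_parent` instead — the two flags
are mutually exclusive by construction. Segregation over all genotyped
relatives in the family adds `incomplete_penetrance` (an unaffected
carrier of the full genotype pattern), `variable_expressivity` (a mildly
affected carrier), and `segregates_with_disease` (every genotyped
affected relative carries the pattern and no unaffected relative does).
Unaffected carriers only ever *flag* a group; they never reject it —
dominant CVID-gene variants with three unaffected carrier relatives have
been judged causal, so penetrance-based auto-rejection would be wrong.

## Classification

Each group receives exactly one tier:

* `disease_associated` — the gene carries an association-tier override in
  the panel (used for TNFRSF13B/TACI, whose variants are common enough in
  CVID and in controls that they are reported as associated, never as
  causal), regardless of all other checks;
* `likely_disease_causing` — the hypothesis is compatible with the
  gene's published inheritance modes (monoallelic↔AD, homozygous or
  phased compound-het↔AR, hemizygous↔XL) *and* the patient's phenotype
  tags intersect the gene's;
* `other_damaging` — everything else, with the failed checks
  (`zygosity_mismatch`, `phenotype_mismatch`, `phase_unknown`) as
  reasons.

Phenotype matching is non-empty intersection of controlled tag sets.
This is curation, not inference: the published judgements are
case-specific and occasionally generous (a compound-het STXBP2 patient
was retained despite lacking the hemophagocytosis that usually defines
STXBP2 disease), and the packaged fixture's tags are set so that the
documented tiers are reproduced. HGMD support is reported as evidence
(`hgmd_support`) and never raises a tier on its own.

Cohort summaries count distinct variant keys in the top tier (a variant
shared by related patients counts once), patients with at least one
top-tier finding, and diagnostic yield as their ratio over the proband
count. In per-gene breakdowns each patient appears under exactly one
gene, top tier first — a patient with both a causal PIK3CD variant and
an associated TACI variant counts only under PIK3CD. CADD summary
fractions (scores ≥ 20 and ≥ 30, the top 1% and 0.1% of reference SNVs)
are computed over the distinct private-or-rare variant set; they are
reporting thresholds only, never filters.

## The synthetic cohort generator

`generate_cohort()` emulates the study design the pipeline targets: a
default 50-patient severe-phenotype cohort with 15 causal patients
(intended yield 30%) split across de novo, penetrant-familial,
incomplete-penetrance, homozygous, and compound-het configurations,
three weakly-associated-gene carriers, one false compound heterozygote
in cis, one decoy per filter stage, and 8 familial patients (4 affected
pairs sharing a family, genetically unexplained — as most familial CVID
pairs are). Every planted scenario writes a truth-table row with its
intended tier; `recovery_report()` scores a pipeline run against it.

Defaults are the *separable* regime: causal variants are novel or
ultra-rare (half absent from the reference population, half log-uniform
on [1e-6, 5e-5]), score 2–20 CADD points above their gene's MSC, have
clean calls, and match the patient's phenotype tag; each decoy violates
exactly one gate (frequency log-uniform on [0.02, 0.5]; CADD 1–10 points
below MSC in a phenotype-mismatched gene; an off-panel gene; depth 1 /
GQ 10). Under separability, recovery is exact (sensitivity =
specificity = 1) for every scenario kind except those designed to be
indeterminate. Background variants — 10 per patient by default — live in
off-panel genes with allele frequencies log-uniform on [1e-6, 0.5] and
CADD uniform on [0, 40]; the distributions are test scaffolding chosen
for coverage of the threshold space, not estimates of real site
frequency spectra, and are configurable.

What the generator does *not* emulate matters for interpreting green
tests: real exomes put hundreds of common, benign variants *inside* the
panel (a real 50-patient cohort produced 433 panel-gene variant calls
before rarity filtering), annotation is noisy, multi-allelic and
low-complexity sites misbehave, and phenotype assignment is not a clean
controlled vocabulary. Passing recovery tests therefore demonstrates
correctness of the decision logic under stated conditions, not expected
field performance of the thresholds.

Determinism: the generator seeds R's RNG from `cohort_config(seed=)`,
restores the caller's RNG state afterwards, and writes byte-identical
VCF/PED/TSV files for identical configurations.

## Numerical and design choices

* Variant identity is `chrom:pos:ref:alt`, unique per call set;
  multi-allelic VCF rows are decomposed to one record per alternate
  allele before anything else looks at them, with zygosity per allele
  derived from allele counts in the genotype.
* Positions are 1-based as in VCF and never shifted; the packaged
  fixture uses synthetic one-gene-per-contig coordinates because tier
  logic reads only annotations and genotypes.
* Frequency comparisons are non-strict passes at the boundary (see
  above); all thresholds live in one configuration object validated to
  `0 < het_af_max ≤ biallelic_af_max ≤ 1`.
* Missing annotations stay missing (`NA`) and route to explicit
  "ungated"/"novel" branches; they are never coerced to zero.
* Ties and ordering: report rows sort by patient, gene, position;
  candidate groups by patient, gene, first variant key — output order is
  deterministic everywhere.
* Probands are the affected samples by default; when an affected carrier
  parent is itself part of a family study, pass the proband list
  explicitly (`triage_run(..., patients = )`), as the generator's
  `patient_ids` does.

## Problem sizes

The test suite runs the full pipeline on the packaged 50-patient
fixture, exhausts all 81 two-variant trio genotype configurations (and
60 sampled three-variant ones) against the phasing oracle, and verifies
exact planted recovery on a 200-patient synthetic cohort with 140
scenario patients and ten background variants per patient; the whole
suite completes in well under a minute on one CPU. These sizes were
chosen to cover every decision branch and all threshold boundaries while
keeping the suite quick to iterate on.

## Known limitations

* No sibling-based or population-based phasing; no mosaicism,
  imprinting, or copy-number events.
* Phenotype matching cannot reproduce expert judgement beyond what the
  tag curation encodes.
* A single global population frequency per variant is consumed;
  per-population frequencies are not modelled.
* CADD and MSC values are consumed as annotations; the package never
  computes them.
* The biallelic frequency threshold applies to any variant in a
  multi-het AR-gene pattern even if phasing later shows the pair in
  cis; the demotion happens at classification, not by re-filtering.
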