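---
title: "Comprehensive genomic diagnosis of respiratory chain deficiencies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comprehensive genomic diagnosis of respiratory chain deficiencies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodx)
```

## The diagnostic problem

Childhood-onset mitochondrial respiratory chain complex deficiencies are
biochemically defined (reduced complex I–V activities relative to citrate
synthase or complex II) but genetically heterogeneous: causal defects occur
in mtDNA point mutations and large deletions, mtDNA copy-number depletion,
biallelic or de novo nuclear variants in dozens of genes, and — more rarely
than once assumed — large chromosomal deletions. No single assay covers this
spectrum, so diagnosis runs three screens per patient in parallel:

1. **Whole-mtDNA sequencing** for catalogued pathogenic point mutations,
   heteroplasmy and large single deletions, plus qPCR for depletion (MTDPS);
2. **Whole-exome sequencing** with a rare-variant filter cascade and
   inheritance-model reasoning for nuclear candidates;
3. **High-density SNP arrays** for copy-number changes >100 kb and long
   contiguous stretches of homozygosity (LCSH).

`mitodx` implements these screens as composable, data-frame-first functions,
integrates their findings per patient, grades each finding *firm* vs *pVUS*
(prioritized variant of unknown significance) on molecular evidence, and
assigns one diagnostic category per patient. A synthetic-cohort generator
with planted causal mechanisms and an exported truth table makes the whole
chain testable end to end without any patient data.

## The exome filter cascade

Variants are annotated upstream (gene, functional class, per-panel MAFs,
SIFT, GERP, segmental-duplication flag); the cascade is a conjunction of
independent predicates, so the survivor set does not depend on evaluation
order, and the per-variant audit trace records each filter's verdict:

| filter | default rule | note |
|---|---|---|
| functional class | keep nonsense, splice site, coding indel, missense | unknown labels are an error |
| manual inspection | drop `artifact_flag` | human read review, modelled as input |
| population frequency | drop if MAF > 1.0% dbSNP137 / 0.1% ESP6500 / 1.0% 1KG / 0.1% ExAC / 0.4% HGVD | strict `>`; missing MAF = novel; dbSNP waived for known-medical-impact entries |
| case recurrence | drop at ≥10 alleles among cases | het 1, hom 2, hemizygous 1 |
| segmental duplication | drop if inside a region | |
| deleteriousness | drop if SIFT > 0.15 or GERP < 2.5 | missing scores never drop (truncating variants lack SIFT) |
| 1KJPN | drop if MAF > 0.4% or panel homozygote seen | threshold not fixed by the source workflow; 0.4% mirrors HGVD, homozygote veto optional |

A **recovery pass** then re-examines removed variants with the segmental
duplication, SIFT and GERP filters waived, restoring those in
mitochondria-related genes: stringent score filters are known to discard
true causal alleles, and restricting the waiver to the mitochondrial
proteome keeps the false-positive cost bounded. Frequency, class, artifact
and recurrence failures are never waived.

The direction of the SIFT/GERP rule (drop tolerated/unconserved, rather
than keep) is one of the genuinely open readings of the filter list; it is
adopted here because every retained missense variant in the diagnostic
tables is reported with GERP > 2.5. Whether homozygotes count two alleles
in the recurrence filter is likewise unstated; standard allele counting is
used.

## Inheritance reasoning

Per gene, prioritized genotypes are classified: one homozygous variant
(homozygous recessive), a single variant on the male X (hemizygous), two or
more heterozygotes (compound-het candidate), or a lone inherited autosomal
heterozygote (rejected as inconsistent with recessive inheritance). A
confirmed de novo event — child carries, both genotyped parents homozygous
reference — bypasses the recessive rejection, reproducing the documented
dominant de novo diagnoses. Heterozygous male X calls are coerced to
hemizygous with a warning (array/VCF dialect tolerance).

Compound-het phasing from trio genotypes takes the consensus over all
parental haplotype assignments consistent with the trio: each parent's
transmittable alleles are intersected with what the other parent must
supply for a het/het child, and the pair is called in trans or in cis only
when every consistent assignment agrees (a parent homozygous at one site
pins its transmission). This matches exhaustive enumeration over all 81
parental genotype combinations by construction, is `unknown` otherwise, and
flags Mendelian violations rather than phasing them. Molecular phase groups
(cloned gDNA/cDNA sequencing, supplied as a column) override genotype
reasoning. Cis pairs are excluded; unknown-phase pairs survive as
candidates but can never be graded firm.

Segregation is consistent when every genotyped affected relative carries
the qualifying configuration and no unaffected relative does. Note a
deliberate asymmetry: trio parents alone are vacuously consistent for a
recessive model (unaffected carriers do not carry the configuration), so
the pipeline converts segregation into a *firmness evidence tag* only when
at least one affected non-proband relative is informative — otherwise every
inherited biallelic genotype would certify itself.

## mtDNA arm

Point variants are prioritized against a two-tier pathogenicity catalog
(`confirmed` → firm-eligible, `reported` → pVUS-eligible); heteroplasmy is
`alt/(ref+alt)` with a depth gate (default 20x) and is scale-invariant.
Large deletions are detected from the per-base coverage profile of the
16,569-bp circular reference: bases below `drop_factor` (default 0.5) of
the median depth form candidate arcs; runs are merged across noise gaps up
to 50 bp, the profile is rotated to start inside the longest intact
stretch so wrapping arcs stay contiguous, and breakpoints are the first
and last low bases. Deletion length is the inclusive circular span
(`last − first + 1`, or wrapping `L − first + 1 + last`); the residual
intact fraction is reported but not used for classification. The depletion
rule is deliberately conservative: MTDPS only when *all four* qPCR
replicate ratios are strictly below 35% of the control mean.

A detected large single deletion is tagged `known_pathogenic`: this event
class is an established primary cause of respiratory chain deficiency, so
the finding is firm without further assay. A positive depletion call
contributes a `functional_assay` tag to a biallelic nuclear finding in a
known disease gene — depletion is the functional readout of a
mtDNA-maintenance defect — rather than forming a category of its own.

## Array arm

Copy-number segmentation is a deterministic threshold/run-length segmenter
(log2 ratio ≤ −0.3 for deletions, ≥ +0.26 for duplications, ≥10 qualifying
probes, ≤2-probe gaps), replacing the vendor hidden-Markov callers the
screen originally sat on: the contribution here is the prioritization, and
a fully specified segmenter keeps results exactly reproducible.
Prioritization keeps segments strictly larger than 100 kb whose reciprocal
overlap with any control-panel CNV stays below 50% (the panel membership
rule is not defined by the source workflow; reciprocal overlap is the
field's convention), then annotates survivors with known genomic-disorder
regions — database curation reduced to a region file plus a free-text
curation column. Disorder-region CNVs are tagged `known_pathogenic`.

LCSH detection reports maximal runs of homozygous calls (no-calls neutral,
isolated het interrupts configurable, default 0) with span ≥1.0 Mb by
default; founder stretches down to ~0.1 Mb can be surfaced by lowering the
threshold, since informative stretches in practice span 0.1–3.2 Mb. An
LCSH overlapping a homozygous candidate gene contributes an `lcsh_support`
tag.

The founder screen applies the exact conditional Hardy–Weinberg test
(probabilities by the stable recurrence over heterozygote counts;
two-sided p sums all heterozygote counts no more probable than the
observed one) to every prioritized variant's case genotype counts, with
Bonferroni adjustment at α = 0.05. In an outbred series, homozygote excess
at a rare variant is the founder-allele signature; violations contribute a
`shared_rare_variant` tag to carriers' findings.

Composite events: a heterozygous deletion overlapping a gene promotes any
prioritized heterozygous variant in that gene to a biallelic candidate
(the variant sits on the remaining allele); an apparently homozygous call
inside a het deletion is reported as hemizygous with a note.

## Firmness and categories

A finding is **firm** only when its genotype configuration is established
(homozygous, hemizygous, confirmed de novo dominant, compound het phased
in trans, composite CNV+SNV, or an mtDNA/chromosomal event) *and* at least
one molecular evidence tag supports pathogenicity (`rescue`,
`segregation`, `de_novo`, `known_pathogenic`, `lcsh_support`,
`shared_rare_variant`, `no_detectable_protein`, `functional_assay`,
`splice_defect`). Wet-lab tags arrive as input columns; pipeline-derived
tags come from the trio, catalog, array and qPCR logic above. Candidates
without molecular evidence stay pVUS even in well-known disease genes.

Each patient receives the category of their highest-priority firm finding
under the order mtDNA mutation > known nuclear gene > novel
mitochondria-related gene > other monogenic gene > chromosomal aberration
(configurable; the order follows the diagnostic narrative and reproduces
the documented resolution of a patient with both a firm de novo nuclear
mutation and an inherited pVUS deletion). Patients with only pVUS findings
are `pvus_only`; with none, `unresolved`. Cohort percentages are rounded
half-up to one decimal; Bernier severity uses the major (<20% tissue /
<30% fibroblast / <30% in ≥2 tissues) and minor (<30% / <40% / <40%)
residual-activity thresholds on pre-normalized percent-of-control values.

## Enrichment evaluation

The pipeline's plausibility check asks whether cases are enriched, relative
to controls, for individuals harbouring prioritized genes from (a) known
disease genes, (b) mitochondria-related genes, and (c) 908 genes drawn at
random from the pool excluding both, redrawn 1000 times (mean ± sample SD
over draws). The simplified cascade used here omits the manual-inspection,
validation, 1KJPN and HGVD steps (control exomes are themselves part of the
HGVD-like reference). Whether "harbouring" requires a full qualifying
inheritance configuration or any surviving variant is open; the package
defaults to the configuration reading with `require_configuration = FALSE`
available, and the fold is reported as undefined (NA) with both
percentages whenever the control percentage is zero — which is the
expected state of the known-gene set, where controls harbour nothing.

## The synthetic cohort: what it emulates, and what it does not

Defaults (48 cases with trio parents, 48 controls) plant one patient group
per mechanism: 3 founder homozygotes sharing one allele inside a 2.8 Mb
homozygosity window (plus one background het carrier, mirroring the
carrier-plus-homozygotes founder pattern), 5 compound heterozygotes (one
with an affected sibling to make segregation informative, the rest with
rescue-assay tags), 2 autosomal de novo dominants, 2 X-hemizygous males
(one de novo, one maternally inherited with a no-detectable-protein tag),
4 heteroplasmic catalogued mtDNA point mutations (heteroplasmy uniform on
[0.3, 1]; no distribution is stated for real cohorts, so a
noncommittal uniform is used), 1 mtDNA deletion at breakpoints
11359/15068 at 70% deleted molecules, 2 depletion patients (qPCR ratios
centred on 0.2 of control, 4 replicates, on top of a biallelic variant in
a known gene), 2 patients sharing a 1,675 kb disorder-region deletion, and
1 composite patient with a 1,387 kb deletion plus a het missense on the
remaining allele.

The genome is scaled down (six autosomes + X, ~300 Mb, 5,000 genes of
20 kb; 60 known disease genes nested in a 1,000-gene mitochondria-related
set, leaving a 4,000-gene pool so 908-gene draws are well defined) with
probes every 25 kb; the mtDNA circle is full length. Background variation
is calibrated, not realistic: each individual receives on average 1.5
cascade-surviving and 6 cascade-removed variants (split across failure
flavours: common, tolerated, unconserved, segmental-duplication, artifact,
synonymous), all inherited from a parent in cases so that no spurious de
novo events arise; the surviving rate is a free parameter chosen for test
sensitivity, since per-patient post-filter yields are not published. A
cohort-recurrent rare variant carried by 12 cases exercises the
recurrence filter.

Deliberately **not** emulated: linkage disequilibrium and realistic
haplotype structure, read-level data, population demography, genotyping
error, parents' own private variants, and realistic per-panel MAF joint
distributions (panel frequencies are drawn independently below their
thresholds). Passing the planted-recovery test therefore demonstrates the
decision logic end to end — filters, phasing, tags, categories — but says
nothing about sensitivity on real exomes, where coverage gaps, artifacts
and annotation errors dominate.

## Numerical and scale choices

Everything stochastic flows from one integer seed (`withr::with_seed`);
fixed seed means byte-identical outputs, which the tests assert on the
serialized files. Exact-test probabilities use the multiplicative
recurrence walked from the conditional mode with a `1 + 1e-12` tolerance
on the tail inclusion; the test oracle recomputes them by direct
`lgamma` closed form. Percent rounding is half-up (base `round()`'s
round-to-even differs at exact ties). Deletion detection defaults
(`drop_factor` 0.5, `min_span` 100, `max_gap` 50) give exact breakpoint
recovery with probability ≈1 at 150x coverage and 70% deletion load. Test
and example problem sizes (48+48 cohort, 200-profile and 200-individual
Monte-Carlo checks, 1000-draw nulls) run the whole suite in about two
minutes on one CPU.

## Known limitations

* Phasing uses trio genotypes and declared phase groups only; no
  statistical read-backed phasing, imprinting or mosaicism.
* Singleton heterozygotes in dominant disease genes without trio data are
  rejected rather than surfaced as pVUS — a policy choice where the
  evidence base is silent.
* The precedence between `novel_mito_related_gene` and
  `other_monogenic_gene` when both are firm in one patient never occurs in
  the reference cohort; the default order is a configuration choice.
* CNV inheritance is annotated only via presence/absence lookups, not
  trio-aware copy-number calling; amplicon-interval restriction stands in
  for NUMT-avoiding primer design.
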