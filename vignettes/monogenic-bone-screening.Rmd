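---
title: "Screening AFF cohorts for monogenic bone disorders: methods and design"
author: "affpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening AFF cohorts for monogenic bone disorders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affpanel)
```

## The problem

Atypical femur fractures (AFFs) are rare, low-trauma femoral shaft
fractures usually discussed as an adverse association of long-term
bisphosphonate therapy. A fraction of AFF patients, however, turn out to
carry an undiagnosed monogenic bone disorder — osteogenesis imperfecta,
hypophosphatasia, X-linked osteoporosis, osteopetrosis and related
conditions — and recognising these patients changes their management.
`affpanel` implements a reusable screening pipeline for this question: it
takes annotated per-patient variant tables over a curated panel of 37
monogenic bone-disorder genes, filters them by call quality, consequence
and population rarity under the gene's inheritance mode, classifies the
survivors with an ACMG/AMP evidence-combination engine, estimates carrier
prevalence in the cohort, tests for enrichment against a background
population rate, and screens SNP-array copy-number calls against the same
panel with ClinGen copy-number-loss scoring.

The package deliberately consumes *annotated* data. Alignment, variant
calling and annotation (consequence class, population frequencies, CADD,
ClinVar assertions) belong to upstream tools; CNV detection from LRR/BAF
signals likewise. What the package owns is everything downstream:
filtering, classification, prevalence, inference and reporting.

## The variant-retention funnel

Three stages run in a fixed order; each input variant receives exactly
one trace record, so retained + removed always equals input.

1. **Quality by depth.** Variants with QD ≤ 5 are removed. A variant
   without a QD value (for example one merged from an orthogonally
   validated source) is retained with a warning: the filter targets raw
   caller output, and absence of the score is not evidence of a bad call.
2. **Consequence restriction.** Analysis is restricted to nonsynonymous,
   stopgain, stoploss and splicing variants, UTR variants and exonic
   indels. Synonymous and intergenic/other classes are removed.
3. **Population rarity.** A variant survives iff the *maximum* of its two
   reference-database frequencies is strictly below the cutoff of its
   gene: 0.001 for the 15 dominant-class genes (the X-linked `PLS3` and
   `PHEX` are grouped here) and 0.01 for the 22 recessive-class genes,
   because a single disease allele of a recessive disorder need not be
   extremely rare. Taking the maximum over databases encodes "common in
   either reference means not rare". An absent frequency means *not
   observed* in that database — the rarest possible state — and counts as
   0 for the comparison; a provenance flag (`af_absent`) records that
   this interpretation was applied. The inequality is strict; strictness
   only matters at exact equality with the cutoff, and the tests pin it.

After filtering, genotype patterns are flagged per patient and gene:
heterozygous variants in dominant-class genes (`dominant_het`),
hemizygous male X genotypes (`hemizygous`), homozygous variants in
recessive-class genes (`recessive_hom`), two or more heterozygous
variants in one recessive gene (`recessive_compound_het`), and single
heterozygous variants in recessive genes (`recessive_carrier`).
Compound-heterozygote detection is *phase-unaware*: without trio data any
two retained heterozygous variants in one gene count, and reports carry
the phase-unknown caveat. Carrier findings in recessive genes remain
reportable — the worked example's `TCIRG1` stopgain carrier is exactly
such a finding.

## Two classification layers

### The ACMG engine

Evidence codes (PVS1; PS1–PS4; PM1–PM6; PP1–PP5; BA1; BS1–BS4; BP1–BP7)
carry a default strength from their prefix and may be individually
re-weighted — the canonical example being PVS1 applied at *strong* for a
truncating variant that may escape nonsense-mediated decay. The
combining matrix ships as an editable table
(`inst/extdata/acmg_combining_rules.csv`) rather than being hard-coded,
so refined combining recommendations can be swapped in; the engine
evaluates the pathogenic arm (pathogenic before likely pathogenic) and
the benign arm (benign before likely benign) on the effective strength
counts. Evidence satisfying both arms is contradictory and yields
uncertain significance, as does evidence satisfying neither. The engine
is a pure function of the profile, and the test suite checks it against
an independently written boolean-logic oracle for every code set of size
up to three.

The automatable codes are assigned from annotation: PM2 iff the maximum
database frequency is below 10⁻⁴; PP3 iff CADD > 15 (strict); PVS1 for
loss-of-function consequences, where "splicing" counts only at canonical
±1/±2 sites (a `splice_canonical = FALSE` column marks non-canonical
splice-region variants); PS1 for ClinVar pathogenic; PP5 for ClinVar
likely pathogenic; BP6 for ClinVar (likely) benign. Curated codes and
strength overrides are merged from the variant table's `evidence_extra`
and `evidence_override` columns.

### The proxy classifier

Manually curating evidence is impossible for a reference population of
tens of thousands of exomes, so a filter-based proxy stands in: a variant
is (likely) pathogenic iff it is (i) extremely rare (max frequency
< 10⁻⁴), (ii) computationally supported (CADD > 15, or CADD unavailable
for a loss-of-function consequence), and (iii) loss-of-function or
asserted (likely) pathogenic in ClinVar; ClinVar (likely) benign
assertions form the benign bucket; everything else is a VUS.

The proxy is *not* equivalent to the engine, and the package preserves
both asymmetries rather than papering over them:

* **Proxy misses clinically classifiable variants.** An in-frame indel
  without a CADD score cannot satisfy criterion (ii) even when curated
  moderate evidence (PM4, phenotype specificity) supports it — the worked
  example's `ALPL` single-residue deletion is exactly this case. The
  proxy therefore counts 8 carriers where the engine counts 9.
* **Proxy over-calls supporting-level ClinVar assertions.** A rare
  non-LOF variant with CADD > 15 and a ClinVar *likely pathogenic*
  assertion passes the proxy filter, but its automatable profile
  {PM2, PP3, PP5} is one moderate plus two supporting — below the
  combining matrix's likely-pathogenic bar. The property test asserts
  the containment with exactly this documented exception class.

## Prevalence and inference

A patient is a carrier iff at least one variant in the counted verdict
classes survives; prevalence assumes one qualifying variant per carrier
(the same assumption needed to convert per-variant allele counts in a
reference population into a carrier fraction). Family deduplication
retains one carrier per family identifier and shrinks the denominator
accordingly, so the worked example's sibling pair counts once: 8 proxy
carriers of 60 become 7 of 59.

Enrichment against a background carrier rate `p0` uses the exact
binomial tail. The default is one-sided (`greater`): the scientific
hypothesis is enrichment, not difference. A two-sided option uses the
minimum-likelihood convention. Both reduce to `stats::binom.test`; the
tests verify them against direct tail summation.

Cohort covariate comparisons follow the clinical-table convention:
Pearson chi-square *without* continuity correction when every observed
cell is at least 5, otherwise Fisher's exact test — dispatch on observed,
not expected, counts, because that is the stated rule being reproduced.
One note on sidedness: for the glucocorticoid-use table
[[4,11],[31,14]], the two-sided (minimum-likelihood) Fisher p is 0.0062
while the one-sided p is 0.0051; published clinical tables that print
0.005 for this comparison are consistent with the one-sided value. The
package defaults to two-sided and exposes `alternative`. Continuous
variables use the two-group one-way ANOVA F test, which the tests pin to
the squared equal-variance t statistic.

Reported percentages are rounded half-up at the stated precision
(`roundHalfUp`), not banker's-rounded; counts, not printed percentages,
are the quantities the pipeline asserts (a printed "54%" for 8/15 is a
rounding anomaly of the source material, and 8 is the reliable number).

## Copy-number screening

SNPs with cluster-separation scores below 0.27 are removed (0.27 itself
passes); samples must have call rates strictly above 97.5%. Calls need
at least 10 consecutive supporting SNPs and face *no* minimal size
restriction — an 800 bp call with 10 SNPs survives. Intervals are
1-based and closed everywhere, matching how array CNVs are reported; a
call ending exactly at a gene's first base overlaps it by one base pair.
Spans are reported in Mb, half-up at one decimal.

Loss calls are scored with the ClinGen section-based rubric, shipped as
an editable table (`inst/extdata/clingen_loss_rubric.csv`). Sections 2,
4 and 5 are evidence-strength judgements, so every assessment may
override a criterion's default points; at most one criterion per section
may be selected, and the summed score maps to the five verdict bands
(≥ 0.99 pathogenic; 0.90–0.98 likely pathogenic; −0.89–0.89 uncertain;
−0.98 to −0.90 likely benign; ≤ −0.99 benign), which partition the line.

The worked example's chromosome-6 deletion
(6:71,561,194–84,303,230, 12.7 Mb, 87 protein-coding genes, overlapping
the panel gene `TENT5A`) is assessed with criteria 1A, 2A, 3C, 4C and 5G
and a total score of 0.9. Note the wrinkle: criterion 2A (complete
overlap of an established haploinsufficiency gene) carries +1.0 by
default, which would push the total to 1.9 — inconsistent with a
reported total of 0.9. The bundled assessment therefore records 2A as
*evaluated but assessed at 0 points*, an explicit override that
reproduces the 0.9 total; the plausible reading is that "criteria
fulfilled" meant "sections evaluated" rather than "points awarded". The
scoring function requires explicit per-assessment points for exactly
this reason. The 87-gene count is an input attribute of the call
(annotation-version-dependent), not recomputed from a bundled gene
model.

## The synthetic-data generator

`generateCohort()` emulates the statistical structure the analysis
assumes: suspicion flags at a configurable proportion (default 25%),
carriers planted per group at configurable rates (defaults 8/15 and
1/45, the worked example's rates), one (likely) pathogenic variant per
carrier with attributes drawn to satisfy the proxy rule, a Poisson
background of VUS per patient (default mean 0.8, chosen to match a
cohort in which roughly half the patients carry at least one rare panel
VUS) with attributes drawn to fail the proxy rule, and sibling pairs
sharing family identifier and carrier status.
`generateControlPopulation()` plants proxy-qualifying carriers at a
background rate (default 1%) to exercise the enrichment comparison at
desk scale. Everything is reproducible from the seed.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: linkage between variants, realistic
allele-frequency spectra (frequencies are either absent or uniform small
numbers), annotation error (consequence, CADD and ClinVar fields are
taken at face value), sequencing artefacts upstream of the QD filter,
population structure, and phasing (compound-heterozygote calls stay
phase-unaware). The generator validates the pipeline's bookkeeping and
its statistical behaviour under the stated model, not the accuracy of
upstream annotation.

Test problem sizes: property tests run cohorts of 60–600 patients;
parameter recovery uses 100 replicates of 60-patient cohorts (95% exact
binomial confidence intervals must cover the planted group rates in at
least 90% of replicates) and 30 replicates of 600-patient cohorts for
mean recovery within three standard errors. These sizes give the
properties sharp expectations while keeping the default suite fast.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere; half-open conversions
  are internal only.
* Strict inequalities sit exactly where the stated rules put them:
  QD ≤ 5 removed, CADD > 15 supports PP3, frequency < cutoff retained,
  cluster separation < 0.27 removed, call rate > 97.5% passes,
  CADD ≥ 20 enters the VUS report.
* TSV is the canonical interchange dialect. The VCF reader is a
  deliberate v4.2 subset — per-sample GT plus INFO keys mapped through a
  configurable dictionary — not a general VCF implementation; it
  delegates parsing to `VariantAnnotation` and reports one record per
  carrier sample (hom-ref and missing genotypes are not observations).
* Chromosome labels are normalized by stripping a leading `chr`, so
  `chr6` and `6` compare equal and normalization is idempotent.
* The combining matrix and the loss rubric are data, not code.
* Verdict conflicts (pathogenic and benign arms both satisfied) resolve
  to uncertain significance rather than erroring: contradictory evidence
  is a legitimate state of knowledge.

## Known limitations

The panel's interval coordinates are approximate GRCh37 gene spans — a
documented reconstruction adequate for CNV overlap screening. The proxy
classifier inherits every bias of ClinVar assertion coverage. The
enrichment test treats the background rate as a known constant rather
than an estimate with its own sampling error; with a reference
population three orders of magnitude larger than the cohort this is a
good approximation. Gain/duplication rubric scoring, mosaicism and
allele-specific copy number are out of scope, as is liftover between
genome builds.
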