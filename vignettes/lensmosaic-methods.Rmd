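---
title: "lensmosaic: methods, parameter choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lensmosaic: methods, parameter choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lensmosaic)
```

# Scope

`lensmosaic` detects somatic variants at allele fractions of a few percent
from per-site, per-strand allele read counts of deep targeted sequencing,
compares a case tissue against one or two matched control tissues from the
same individual, applies a multi-stage quality filter cascade, quantifies
individual variants by droplet digital PCR (ddPCR) Poisson statistics, and
converts allele fractions into clonal patch sizes for an epithelial
monolayer. The package operates on counts, not alignments: read-level
context (mismatches, distance to read ends and indels, base and mapping
qualities) enters as optional per-read *evidence* attached to the counts.

# The calling model

## Genotypes

At a site with depth $d$ and $a$ reads supporting an alternate allele, the
genotype of one sample is decided by thresholds
(`caller_params()`): `LOW_COVERAGE` when $d$ is below the minimum coverage
(50× for both case and control by default); `REF` when $a$ is below the
minimum supporting reads (2), the fraction $a/d$ is below `min_var_freq`
(0.01), or the variant is seen on fewer strands than required (2 in the
control, 1 in the case); `HOM` when $a/d \ge 0.75$; `HET` otherwise. When
per-read evidence is attached and the mean base quality of the supporting
reads falls below `min_avg_qual` (15), the support is disregarded. Purity
parameters are carried at their default 1.0, at which the purity
correction is the identity; no correction is implemented.

## The somatic test

The case/control contrast is a one-sided Fisher exact test on
$[[n^{N}_{ref}, n^{N}_{alt}], [n^{T}_{ref}, n^{T}_{alt}]]$: with all
margins fixed, the p-value is the upper hypergeometric tail
$P(X \ge n^{T}_{alt})$, computed from `stats::phyper`. One-sidedness is a
design choice: the screen looks for variants *enriched* in the case
tissue, and the mirrored tail (control over case) is used for the LOH
direction, so that swapping case and control exactly exchanges SOMATIC and
LOH calls. p-values are clamped to the smallest positive double rather
than underflowing to zero; an all-zero table returns p = 1 with a
`degenerate` flag.

Classification follows presence/absence: present in both samples →
GERMLINE; present in the case only and $p \le 0.05$ → SOMATIC; present in
the control only and $p \le 0.05$ → LOH (reported under the somatic
umbrella downstream); anything else UNKNOWN. "Present" is genotype-level
(HET or HOM): a control with one or two stray error reads still counts as
absent here, and the stricter raw-count absence rule lives in the filter
cascade. With two controls, SOMATIC requires absence from *both* controls
and significance against each (the reported p is the less significant of
the two); presence in any control makes the call GERMLINE; LOH requires
presence in both controls. Sites where any involved sample is below
coverage are skipped and counted.

No genome-wide multiple-testing correction is applied: the operating point
is a per-variant $p \le 0.05$ plus the hard filter cascade, and the
false-positive control is demonstrated empirically on technical-replicate
nulls (below) rather than analytically.

## Unpaired screening

Without a control, each candidate allele is tested against the
expectation under an assumed per-base error rate $e$ (default 0.01,
configurable): observed $[d-a, a]$ versus expected
$[d - \mathrm{round}(de), \mathrm{round}(de)]$, same one-sided test. This
is an explicit *screening* construction — the expected row is a modelling
convenience, not a second observation — and its calls carry status
UNKNOWN until filtered.

# The filter cascade

`run_cascade()` applies, in order: a status gate (paired: keep SOMATIC and
LOH; unpaired: keep $p \le 0.05$), site depth, per-strand support, control
absence (paired), the frequency window (unpaired), cross-sample
recurrence, and read evidence. Thresholds (`filter_config()`):

| filter | default | notes |
|---|---|---|
| depth, 2-way | ≥300 case and control | inclusive ("minimum of") |
| depth, 3-way | ≥250 case, ≥300 each control | inclusive |
| depth, unpaired | >300 | strict, deliberately different |
| strand support | ≥4 alt reads per strand | inclusive |
| control absence | ≤0 alt reads in every control | strict zero |
| frequency window | VAF < 0.40 (screen), < 0.25 (report) | strict |
| recurrence | ≤10% VAF in ≥3 distinct samples | flags all occurrences |
| read evidence | >3 mismatches, ≤10 bp to indel, ≤5 bp to read end | removes reads |

Choices worth explaining:

* **Strict control absence.** "Absence" is read literally (0 alt reads).
  At 1000× with a 0.1% error rate a control shows ≥1 stray read of a given
  allele at a given site with probability ≈ 0.28, so the strict default is
  harsh on real data and the knob `control_absence_max_alt_reads` exists;
  the default stays 0 because the absence rule is the cascade's strongest
  false-positive guard.
* **Two unpaired windows.** Screening uses < 40%; a stricter < 25%
  reporting window is exposed separately (`max_unpaired_freq_report`)
  because the two cutoffs serve different stages of a screen and
  conflating them would silently change which candidates are counted.
* **Recurrence thresholds.** Cross-mapping between near-identical
  paralogues produces the same apparent low-VAF variant in many unrelated
  samples (the extreme case being nearly every sample in a batch). The
  quantitative operating point — ≥3 distinct samples at ≤10% VAF — is this
  package's choice; both knobs are exposed.
* **Read-end and indel margins.** "Near the ends of reads" and "close to
  indels" are quantified as 5 bp and 10 bp respectively; with 101-bp
  reads, the 5-bp margin discards about 12% of uniformly positioned
  supporting reads, which leaves the per-strand minimum intact for any
  variant with ≥8 supporting reads unless support was marginal to begin
  with.
* **Filter order and audit.** Every filter is evaluated for every input
  call (no short-circuiting), so the audit table is complete and any
  order effect is inspectable. The per-call filters (depth, strand,
  absence, window) give an order-independent PASS set; the read-evidence
  filter can change effective strand support and therefore runs last by
  design, after the plain strand filter, with both recorded.

The cascade is monotone (output ⊆ input) and idempotent on its own
output; both properties are enforced by randomized property tests.

# ddPCR quantification

Droplets are classified by two thresholds: variant-positive iff FAM > 4000
and HEX < 3000 fluorescence units; wild-type-positive iff HEX ≥ 3000 with
FAM ≤ 4000; double-positive when both channels are high; empty otherwise.
The wild-type rule is the complement of the variant rule — only the
variant rule is canonical, so the complement is the natural closure. For
Poisson purposes a double-positive droplet counts as positive in *both*
channels (it contains at least one template of each kind; the standard
duplex treatment). Concentrations follow
$\lambda = -\ln(1 - n_{pos}/n_{total})$ and
$CN = \lambda / v_{droplet}$, with
$VAF = CN_{VAR}/(CN_{VAR}+CN_{WT})$.

Numerical details: $\lambda$ uses `log1p` for accuracy at low occupancy; a
fully positive channel is a *saturation* error (λ undefined) rather than a
number; an all-empty reaction gives $CN_{VAR}=CN_{WT}=0$ and VAF is an
explicit undefined-VAF error rather than NaN. The droplet volume defaults
to 0.85 nL (the nominal droplet volume of the common 15,000-droplet
systems); it is a parameter because instruments differ. Confidence
intervals are not computed in this version.

# Clone-size model

A diploid cell carrying one variant allele contributes one alternate and
one reference allele to bulk DNA, so a heterozygous variant at allele
fraction $f$ marks $2f$ of the sampled cells (capped at 1); homozygous
variants mark $f$. The clone's cell count is that fraction of the cells in
the sampled specimen, parameterised as a *sampled area fraction* of a
total epithelium (cells are assumed uniformly distributed over the area,
which is how such specimens are actually described); dividing by the cell
density (default 5500 cells/mm², peripheral lens epithelium; total
epithelium 0.5×10⁶ cells) yields the clone area. Cell counts are rounded
to the nearest cell; the area is reported exactly and also rounded to the
nearest whole mm², because that is the precision at which such an estimate
is honest — e.g. a 5000-cell clone at 5500 cells/mm² is 0.909 mm²,
reported as "~1 mm²".

```{r clone}
estimate_clone(0.01, clone_assumptions(sampled_area_fraction = 0.5))
```

# The synthetic-data generator

`simulate_pileups()` emulates targeted-capture deep sequencing of several
samples from one individual:

* **Depth**: negative binomial with mean 1000× and dispersion 0.05
  (variance $\mu + 0.05\mu^2$, i.e. ~23% coefficient of variation), since
  capture depth is overdispersed in practice; dispersion 0 gives Poisson
  depths.
* **Germline**: heterozygous/homozygous variants at per-site rates
  3×10⁻⁴ / 1.5×10⁻⁴ (roughly the density of a few hundred SNPs and a
  dozen indels over ~0.8 Mb of captured exome), identical in all samples.
* **Somatic plants**: binomial sampling at the planted VAF, only in the
  target samples. Overlapping plants at one (site, allele) with
  conflicting VAFs are rejected; germline draws skip planted sites so
  every signal has one truth class.
* **Error**: substitution-only at rate 10⁻³ per base (a typical post-
  deduplication Illumina operating point), applied to *every* read — so a
  homozygous site observes fraction $1 - e$ — with the erroneous base
  uniform over the three alternatives. An optional strand-asymmetric
  error mode (`error_strand_bias`) produces one-strand artifacts for
  exercising the strand filter.
* **Artifacts**: recurrent low-VAF signals planted in a chosen fraction
  of samples, mimicking cross-mapping between paralogues.
* **Strands**: each read is forward with probability `strand_bias` (0.5).
* **Evidence** (optional): clean per-read draws — Poisson(0.3)
  mismatches, uniform position along a 101-bp read, no nearby indel,
  base quality ~N(35, 3), mapping quality 60 — with strand labels
  consistent with the counts.
* **Indels** are an extra allele symbol at a site, with no sequence
  realignment; this suffices to exercise calling and filtering logic.

`simulate_aliquot_pair()` is the technical-replicate null: two samples,
one genome, independent sampling noise, zero true somatic differences.

`simulate_droplets()` draws per-droplet template occupancies as
independent Poissons and emits baseline (500 ± 200) or positive
(8000 ± 500) channel signals, values chosen to straddle the 4000/3000
thresholds with no overlap, so classification noise is negligible and
estimator properties can be tested in isolation.

What the generator does **not** emulate: capture efficiency and on/off-
target structure, PCR duplicates, alignment context (the recurrence model
is the only alignment artifact), read-sequence level error profiles,
droplet "rain" (intermediate fluorescence). Tests passing on this
generator therefore demonstrate the *logic* of the pipeline — thresholds,
classification, estimator consistency, false-positive suppression under a
realistic error/depth model — not performance on real alignments.

# Validation operating points

The test suite fixes these problem sizes (chosen to give tight sampling
error at desk scale):

* technical-replicate null: 50,000 sites × 2 aliquots at ~1000×, 0.1%
  error, fixed seed — the full paired pipeline must return zero
  survivors;
* Fisher p: exact agreement (10⁻¹²) with an independent
  binomial-coefficient tail enumeration on *all* 2×2 tables with margins
  ≤ 60;
* Poisson estimator: 15,000 droplets, λ ∈ {0.05, 0.2, 1.0}, 500 seeds,
  ≥95% of runs within 10% relative error; a planted 1.3% VAF recovered
  within ±0.004 in ≥95% of 500 runs at wild-type loading λ = 0.6
  (mid-range optimal droplet occupancy);
* detection power: plants at VAF 0.02–0.04 at ~1000× with clean evidence
  survive the cascade in ≥95% of 200 seeded replicates (run with zero
  error rate: under the strict control-absence default, a 0.1% error
  process alone removes ~28% of true variants via stray control reads,
  which is a property of the strict default, not of detection);
* recurrence: an artifact planted in 35 of 39 samples is flagged in
  100% of replicates;
* cascade monotonicity/idempotence on 1000 randomized call sets.

# Known limitations

* Counts in, counts out: no BAM/CRAM ingestion, no realignment, no
  per-read pileup construction.
* The unpaired test's expected-error table is a screening construction;
  its p-values are not calibrated error probabilities.
* No copy-number awareness, tri-allelic genotype models, or base-quality
  recalibration; no purity correction (purities are fixed at 1).
* ddPCR thresholds are inputs (set from controls by the operator);
  automatic threshold selection and rain clustering are out of scope.
* The clone model assumes uniform cell density and a well-mixed specimen;
  it is deliberately linear and makes no statement about clone shape or
  growth dynamics.
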