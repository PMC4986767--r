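# lensmosaic

Detection and quantification of low-frequency somatic variants in paired
deep-sequencing data, with droplet digital PCR (ddPCR) validation support
and clonal patch-size estimation.

## The problem

Somatic mosaicism — sequence variants carried by a subset of an
individual's cells — shows up in bulk DNA as alternate alleles at
fractions far below the 50%/100% of germline heterozygous/homozygous
variants. At variant allele fractions (VAF) of 1–4%, true somatic signal
competes directly with sequencing error, alignment artifacts and strand
bias, so detection requires deep targeted coverage (~1000×), a matched
control tissue from the same individual, and aggressive post-call
filtering. `lensmosaic` implements that whole workflow for per-site allele
count data, as originally applied to human lens epithelium (where a
somatic variant at ~1% VAF implies a millimetre-sized clone of mutant
epithelial cells), but nothing in the package is tissue-specific.

## What the package computes

**Paired somatic calling.** For each site and candidate allele, case and
control samples are genotyped against read-support thresholds (minimum
coverage 50×, ≥2 variant reads, VAF ≥ 0.01, per-strand support, homozygous
at VAF ≥ 0.75) and the allele counts are compared with a one-sided Fisher
exact test on the 2×2 table

```
            ref        alt
control   n_ref,N    n_alt,N
case      n_ref,T    n_alt,T
```

with `p = P(X ≥ n_alt,T)` under the hypergeometric null with all margins
fixed. A variant present in the case only with `p ≤ 0.05` is **somatic**;
present in both samples it is **germline**; present in the control only it
is **LOH** (loss of heterozygosity, counted under the somatic umbrella).
Unpaired samples are screened against an expected-error table at a
configurable per-base error rate.

**Filter cascade.** Surviving calls must pass, in order: site depth
(≥300/≥300 case/control for two-way designs, ≥250/≥300 for three-way;
>300 for unpaired), ≥4 variant reads on *each* strand, strict absence of
the variant allele from every control, a <40% VAF screening window
(unpaired), a cross-sample recurrence filter (the same low-VAF variant in
≥3 samples is an alignment artifact), and a read-evidence filter that
discards supporting reads with >3 mismatches, near indels, or near read
ends. Every decision is recorded in a per-call audit table.

**ddPCR quantification.** Droplets are classified by two-channel
fluorescence thresholds (variant-positive iff FAM > 4000 and HEX < 3000),
and absolute concentrations follow the Poisson law
`λ = −ln(1 − n_pos/n_total)`, `CN = λ / v_droplet`, with
`VAF = CN_VAR / (CN_VAR + CN_WT)`.

**Clone-size model.** A heterozygous variant at VAF `f` marks `2f` of the
sampled cells; applied to the cells in the sampled area and divided by the
cell density, this converts a VAF into a clone area in mm².

**Synthetic data.** A simulator generates multi-sample pileup tables with
known ground truth (germline variants, planted somatic clones at chosen
VAFs, substitution error, strand-imbalanced artifacts, recurrent
cross-sample artifact sites) and simulated droplet reactions, so every
stage is testable without external data.

## Worked example

Simulate a peripheral/central lens epithelium pair with one somatic clone
planted at VAF 1.1%, run the full pipeline, and size the clone:

```r
library(lensmosaic)

sim <- sim_config(
  n_sites = 5000, samples = c("lens_periph", "lens_central"),
  mean_depth = 1000, error_rate = 0.001,
  germline_het_rate = 3e-4, germline_hom_rate = 1.5e-4,
  somatic_plants = list(planted_variant(2500, "C", 0.011,
                                        samples = "lens_periph")),
  seed = 146)
res <- run_pipeline(run_config(case = "lens_periph",
                               controls = "lens_central",
                               sim = sim, out_dir = tempfile(),
                               seed = 146))
#> simulating 5000 sites x 2 samples
#> calling (paired mode, case=lens_periph, controls=lens_central)
#> 4 putative variant call(s)
#> 1 call(s) survive the cascade
res$passed
#> <variant_calls> 1 call(s)
#>   chrom  pos ref alt sample_case depth_case alt_case   vaf_case    p_somatic
#> 1  chr1 2500   G   C lens_periph        923       13 0.01408451 0.0001800142
#>    status filters_failed
#> 1 SOMATIC
```

The planted clone is the only survivor: the germline variants are
classified GERMLINE at the status gate and the error reads never clear the
genotype thresholds. An independent ddPCR measurement of a 1.3% variant:

```r
d <- simulate_droplets(cn_wt = 700, cn_var = 700 * 0.013 / 0.987,
                       n_droplets = 15000, seed = 146)
quantify_droplets(d)
#> <ddpcr_quant>
#>   droplets: 15000 (var+ 60, wt+ 6581, double 53, empty 8306)
#>   CN_VAR 8.896, CN_WT 686.911 copies/uL (lambda 0.007562 / 0.5839)
#>   VAF = 0.0128 (1.28%)
```

And the size of the clone implied by a 1.1% VAF in a specimen covering
half of a 0.5×10⁶-cell epithelium at 5500 cells/mm²:

```r
estimate_clone(0.011, clone_assumptions(sampled_area_fraction = 0.5))
#> <clone_estimate>
#>   VAF 0.011 (heterozygous) -> 2.2% of sampled cells
#>   250,000 cells sampled -> clone of 5,500 cells
#>   clone area 1 mm^2 (~1 mm^2)
```

## Package layout

- `sim_config()`, `simulate_pileups()`, `simulate_aliquot_pair()`,
  `simulate_droplets()` — synthetic data with ground truth
- `read_counts_tsv()` / `write_counts_tsv()`, `read_bed()`,
  `apply_quality_mask()`, `write_vcf()` — I/O and pre-calling masking
- `caller_params()`, `call_genotype()`, `fisher_somatic_p()`,
  `classify_paired()`, `call_unpaired()`, `call_sample_set()` — calling
- `filter_config()`, the individual `*_filter()` functions and
  `run_cascade()` — the filter cascade with audit trail
- `ddpcr_thresholds()`, `classify_droplets()`, `poisson_copies()`,
  `vaf_from_copies()`, `quantify_droplets()` — ddPCR
- `clone_assumptions()`, `cell_fraction()`, `clone_cells()`,
  `clone_area()`, `estimate_clone()` — clone-size model
- `run_config()` / `run_pipeline()` — end-to-end orchestration

See `vignettes/lensmosaic-methods.Rmd` for the modelling assumptions,
parameter choices and known limitations.
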