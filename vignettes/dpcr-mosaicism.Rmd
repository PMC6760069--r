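---
title: "Quantifying low-level GNAS mosaicism by digital PCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying low-level GNAS mosaicism by digital PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicdpcr)
library(dplyr)
```

## The problem

McCune–Albright syndrome and isolated fibrous dysplasia of bone are caused by
postzygotic activating variants of *GNAS* — overwhelmingly c.604C>T
(p.Arg202Cys) and c.605G>A (p.Arg202His). Because the variant arises after
fertilisation, only a fraction of a patient's cells carry it, and in
peripheral blood that fraction is often far below what Sanger sequencing can
resolve. Chip-based digital PCR addresses this by partitioning a reaction
into 20,000 nanolitre wells: a mutant-specific FAM-labelled assay lights up
only the wells that received at least one mutant template, so single
molecules become countable events against an arbitrarily large wild-type
background.

`mosaicdpcr` implements that workflow end to end as composable,
tibble-in/tibble-out functions: chip simulation with known ground truth,
partition classification, Poisson quantification, calibrator-based cutoff and
limit-of-detection inference, and cohort-level detection-rate tabulation
across four detection methods (Sanger, allele-specific PCR, COLD-MAMA PCR,
digital PCR).

## The counting model

Let a chip have $n$ wells of volume $v$ (µl) holding a total reaction volume
$V = nv$. If $M$ mutant copies are loaded, copies land in wells independently,
so the count per well is Poisson with mean $\lambda = M v / V$. A well is
*positive* when it holds at least one copy, so the expected positive fraction
is $1 - e^{-\lambda}$. Inverting, from an observed positive fraction
$\hat p$ among quality-passing wells,

$$\hat\lambda = -\ln(1 - \hat p), \qquad
  \widehat{\mathrm{cpm}} = \hat\lambda / v,$$

where cpm is mutant copies per µl of reaction mix, the instrument's primary
output. At the occupancies relevant here ($\hat p \lesssim 0.2\%$) the
Poisson correction changes the estimate by under 0.1%, so applying it is
statistically right and numerically inconsequential; we apply it always. The
mass concentration follows from the absolute-quantification identity

$$\mathrm{ng/µl} = \mathrm{cpm} \times 0.0033\;\mathrm{ng} \times 3.34,$$

with 0.0033 ng the mass of one haploid human genome and 3.34 the dilution
factor for the 15 µl of sample plus reaction mixture. The 3.34 does not
follow arithmetically from the stated volumes, so it is treated as an opaque
instrument constant, configurable in `quant_constants()` but never
rederived.

```{r}
s <- tibble::tibble(n_valid = 20000, n_positive = 20)
poisson_cpm(s, chip_spec())
absolute_quant(12.11)
```

## What the simulator emulates — and what it does not

`simulate_chip()` generates a chip from ground truth: DNA mass, the fraction
of genomes from heterozygous mutant cells, and a two-component fluorescence
model. The mutant copy number is `mass / 0.0033 × het_cell_fraction / 2` —
the factor ½ because a heterozygous cell carries the mutant on one of its two
alleles. This fixes the semantics of *relative mutation abundance* (RMA)
throughout the package: 100% RMA means pure heterozygous-mutant DNA, i.e. a
mutant allele fraction of 0.5, because the calibrators are dilutions of
heterozygously mutated patient samples.

Defaults are the study conditions where stated and a single realistic choice
where not:

* `n_partitions = 20000`, `loaded_volume = 15` µl — the chip format used.
* `partition_volume = 15/20000` µl — not stated at this precision anywhere;
  taken as the loaded volume spread evenly over the wells, configurable.
* `dna_conc = 5` ng/µl, `dna_volume = 1` µl — the loading protocol.
* fluorescence negative 1000 ± 400 RFU, positive 8000 ± 800 RFU — chosen once
  so that both validated thresholds (3000 and 5000 RFU) fall between the
  components; all four parameters configurable.
* `dropout_rate = 0.05` and `quality_low_fraction = 0.02` — a realistic
  degree of imperfect well filling and QC failure, leaving ≈ 18,600 valid
  wells per chip, comfortably above the 10,000-point reporting floor while
  still exercising the QC path.

Not modelled, deliberately: the reference (VIC) dye channel, optical
crosstalk, spatial well effects, and per-well wild-type occupancy — the
mutant-detection assays report only the FAM mutant signal, so wild-type
template never produces a positive call in this model. Consequently the
simulator's 0% RMA chips are *cleaner* than real wild-type chips, which show
a small background (the reference 0% calibrator points sit at 0.07–0.10 cpm,
one or two wells per chip). Passing simulation tests therefore demonstrate
the estimator's statistical behaviour, not robustness to chemical
false-positive mechanisms; the cutoff machinery handles the latter because it
is anchored to measured 0% controls, not to an assumed-zero background.

One integer seed fully determines a chip; replicate chips use distinct
derived seeds, and the caller's RNG state is restored afterwards.

## Partition calling

`call_partitions()` applies the two validated QC rules literally: a well is
valid when its quality score is strictly over 0.6, a chip is reportable when
at least 10,000 wells are valid, and a valid well is positive when its FAM
signal is strictly above the assay threshold. Values exactly on a threshold
are excluded — the wording of the validated settings is "over", so ties go
to the conservative side. A chip failing QC still yields counts; only the
`reportable` flag changes, mirroring how an analyst reviews rather than
discards such chips.

## Calibration, cutoffs, and the limit of detection

Serial dilutions of heterozygous mutant controls (100% → 3% RMA for
c.604C>T, 100% → 1.5% for c.605G>A, plus a 0% wild-type point, triplicate
chips per dilution) give per-point mean and sample SD of cpm.
`determine_cutoff()` tests every nonzero point against the 0% point with a
two-sided two-sample t-test computed from summary statistics and selects the
lowest-RMA significant point (α = 0.05); its mean cpm becomes the positivity
cutoff.

```{r}
curve <- calibrator_from_summary(
  filter(gnas_calibrators(), target_variant == "c.605G>A"),
  gnas_assay("c.605G>A"))
glance(determine_cutoff(curve))
```

**Design choice — pooled rather than Welch t.** With only printed summaries
(mean, SD, n = 3 per point) both flavours are computable. The reported
p-values for the two selected cutoff points (0.0028 and 0.0004) match the
pooled-variance Student t with 4 degrees of freedom to printed precision,
and are inconsistent with the Welch approximation (≈ 0.017 and 0.006), so
the pooled test is what the original analysis used and is our default;
`var_equal = FALSE` switches to Welch. The selected cutoff points — 0.391 cpm
(3% RMA) for c.604C>T and 0.464 cpm (1.5% RMA) for c.605G>A — are identical
under both flavours. When a dilution point has zero spread across replicates
the test degenerates; we return p = 0 when the means differ and p = 1 when
they do not, which keeps cutoff selection well-defined for noise-free
simulated curves.

`call_sample()` then applies a deterministic point-cutoff rule: MUT iff
cpm ≥ cutoff mean. The original calling procedure included manual review of
2-D scatterplots with non-overlapping error bars; no single threshold rule
can reproduce manual review exactly, and on the packaged cohort this rule
reproduces 157 of 158 recorded per-variant calls. The one discordance is a
borderline ovarian-cyst sample sitting 0.021 cpm above the c.604C>T cutoff
yet recorded wild type — exactly the kind of call manual review resolves
differently. We keep the rule and document the discordance rather than
special-casing it.

The **limit of detection** is the absolute quantification of the cutoff mean,
rounded *up* to two decimals (`compute_lod()`). Ceiling rounding is the only
defensible mode for a detection limit — reporting it below the concentration
actually resolved would overstate sensitivity — and it is also the only mode
under which both assays' cutoffs (0.00431 and 0.00511 ng/µl) yield the single
validated LOD of 0.01 ng/µl. Everywhere else the package rounds half-up (cpm
to 3 decimals, ng/µl to 2), matching the reported tables; base R's
round-half-to-even is never used on reported values.

**RMA labels.** `assign_rma()` anchors a positive sample to the dilution
point nearest in log-cpm, labelling it `=level` within two SDs of the anchor
mean and `>`/`<` otherwise, with anything at or above the top point labelled
100. The original subcluster attribution procedure is not specified tightly
enough to reproduce label-for-label — the two printed dilution series
themselves appear to have their assay assignment swapped relative to the
per-sample labels — so RMA labels are descriptive output here, not validated
calls, and are excluded from the reproduction tests.

## Cohort tabulation

`load_cohort()` reads a per-sample sheet (79 samples, 54 patients packaged as
`cohort_table1.tsv`) with per-variant calls for the four methods. Tabulation
rules, each chosen to reproduce the reference tables:

* a sample is positive for a method iff either variant is MUT (never double
  counted), and tested iff either variant has a non-ND result;
* tissue classes BO, CB/FB, OC/OCL/OT, BL partition all tissue codes, with
  suffixed labels (`BO-LJ`) classed by their leading code;
* a patient is positive iff any of their samples is, tested iff any sample
  is;
* rates are percentages rounded half-up to one decimal; the display-only
  truncation mode (`round_mode = "truncate"`) reproduces the
  repeating-decimal cells shown as 66.6% (10/15) and similar;
* `subcohort_comparison()` restricts to patients tested by all four methods
  (14 in the packaged cohort), giving the only fair head-to-head comparison;
* `false_negative_count()` counts patients positive by digital PCR, tested
  but negative by another method.

```{r}
cohort <- load_cohort()
detection_table(cohort, "DPCR")
subcohort_comparison(cohort)
```

The packaged sheet is a faithful transcription, including its internal
tensions: the per-tissue digital-PCR cells sum to 37 positive samples while
the accompanying headline total reads 36, and the COLD-MAMA blood and
ovarian cells display 2/11 and 7/10 where the sample table supports 3/11 and
8/10. The package reports what the table supports and the test suite records
(rather than hides) the discrepancies.

## Numerical and degenerate-input choices

* Thresholds: strict inequalities everywhere (quality, RFU).
* Saturated chips (all valid wells positive) raise an error instead of
  returning infinity; empty well sets and missing 0% calibrator points are
  errors naming the problem.
* Zero-variance t-tests degenerate to p ∈ {0, 1} as described above.
* Cutoff selection is invariant to the ordering of calibrator points, and a
  curve whose mean cpm is not monotone in RMA warns but proceeds.
* Rounding: half-up for reported values, ceiling for the LOD, no rounding in
  intermediate computation.

## Problem sizes used in the test suite

The statistical properties are verified at sizes chosen to make the checks
decisive at three standard errors while staying quick: Poisson recovery over
200 seeded chips at per-well occupancies of 1e-4, 1e-3 and 1e-2; occupancy
conservation over 40 chips per rate; calibrator-grid simulation over 100
seeds of 21 chips each (7 dilutions × 3 replicates, full 20,000-well chips
throughout). The whole suite runs in well under a minute on one core.

## Known limitations

* The simulator's fluorescence model is Gaussian two-component with no
  chemical false-positive mechanism; background positivity enters only
  through measured 0% calibrator points.
* RMA category labels emulate an under-specified manual procedure and should
  be read as descriptive.
* Confidence intervals on cpm (e.g. by replicate-well bootstrap) are not
  implemented; the workflow quantifies point estimates and validated
  cutoffs.
* The dilution factor 3.34 is trusted, not derived; changing reaction
  volumes requires the caller to supply the matching factor.
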