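# mosaicdpcr

Digital PCR quantification of low-level *GNAS* mosaicism.

McCune–Albright syndrome and fibrous dysplasia of bone are caused by
postzygotic activating *GNAS* variants — c.604C>T (p.Arg202Cys) and c.605G>A
(p.Arg202His) — present in only a fraction of a patient's cells. In blood the
mutant allele fraction is routinely below the resolution of Sanger
sequencing, so molecular diagnoses are missed unless a biopsy is available.
Chip-based digital PCR partitions a reaction into 20,000 nanolitre wells and
counts the wells lit by a mutant-specific FAM assay, turning single mutant
molecules into countable events. `mosaicdpcr` is for laboratory scientists
and methodologists who want that workflow as tested, composable R functions:
simulation with known ground truth, partition calling, Poisson
quantification, calibrator-based cutoffs, and cohort detection-rate
tabulation.

## The model

With $M$ mutant copies loaded over $n$ wells of volume $v$ (total volume
$V = nv$), per-well copy counts are Poisson with mean $\lambda = Mv/V$, so
from the observed positive fraction $\hat p$ among quality-passing wells

$$\hat\lambda = -\ln(1-\hat p), \qquad
\widehat{\mathrm{cpm}} = \hat\lambda / v, \qquad
\mathrm{ng/\mu l} = \mathrm{cpm} \times 0.0033 \times 3.34 .$$

A sample is called mutant when its cpm reaches the assay's positivity
cutoff: the lowest-RMA calibrator dilution whose triplicate cpm differs
significantly (two-sample t-test on summary statistics, α = 0.05) from the
0% wild-type point. The limit of detection is the cutoff's mass
concentration rounded up to two decimals. See the vignette
(`vignettes/dpcr-mosaicism.Rmd`) for the full account, including the RMA
(relative mutation abundance) semantics: 100% RMA = pure heterozygous DNA =
mutant allele fraction 0.5.

## Worked example

Derive the c.605G>A cutoff from the packaged calibrator summaries, simulate
a blood-like chip at 1.5% RMA, quantify it, and call it:

```r
library(mosaicdpcr)
library(dplyr)

curve <- calibrator_from_summary(
  filter(gnas_calibrators(), target_variant == "c.605G>A"),
  gnas_assay("c.605G>A"))
cutoff <- determine_cutoff(curve)
glance(cutoff)
#> # A tibble: 1 × 5
#>   assay_id      cutoff_cpm rma_percent  p_value alpha
#>   <chr>              <dbl>       <dbl>    <dbl> <dbl>
#> 1 GNAS_27895_mu      0.464         1.5 0.000361  0.05

chip <- simulate_chip(
  sim_params(dna_conc = 5, het_cell_fraction = 0.015, seed = 11),
  assay = gnas_assay("c.605G>A"))
res <- quantify_chip(chip)
res
#> # A tibble: 1 × 7
#>   n_total n_valid n_positive qc_pass   cpm abs_ng_per_ul reportable
#>     <int>   <int>      <int> <lgl>   <dbl>         <dbl> <lgl>     
#> 1   20000   18653         11 TRUE    0.787          0.01 TRUE

call_sample(res$cpm, cutoff)
#> [1] "MUT"
```

18,653 of 20,000 wells passed QC (comfortably above the 10,000-point floor),
11 were FAM-positive, giving 0.787 mutant copies/µl ≈ 0.01 ng/µl — above the
0.464 cpm cutoff, so this 1.5%-RMA sample is correctly detected.
`compute_lod(cutoff)` gives the assay's detection limit, 0.01 ng/µl.

Cohort-level, on the packaged 79-sample / 54-patient sheet:

```r
patient_rate(load_cohort(), "DPCR")
#> # A tibble: 1 × 4
#>   method positives tested  rate
#>   <chr>      <int>  <int> <dbl>
#> 1 DPCR          23     54  42.6
```

i.e. digital PCR yields a molecular diagnosis in 23 of 54 patients (42.6%),
versus 7.4% for Sanger on the same cohort (`patient_rate(cohort,
"SANGER")`). `detection_table()`, `subcohort_comparison()` and
`false_negative_count()` break this down by tissue class and method;
`autoplot()` methods draw chips and calibrator curves.

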