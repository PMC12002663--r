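# clocklineage

Stochastic lineage simulations of coupled circadian clock / cell cycle
gene networks, and the statistics by which circadian control of the cell
cycle can be detected from single-cell lineage data.

## The problem

Whether the circadian clock exerts emergent control over cell
proliferation is surprisingly hard to establish. Bulk growth rates barely
move even when molecular clock--cell-cycle couplings are present, while
lineage-resolved intermitotic times (IMTs) carry a distinctive
fingerprint: cousin cells correlate more strongly than mother--daughter
pairs (the *cousin--mother inequality*, CMI = r<sub>cousin</sub> −
r<sub>mother-daughter</sub>), and grandmother correlations turn negative.
`clocklineage` is for computational biologists who want to simulate this
physics mechanistically and design lineage-correlation experiments around
it — including the use of the small-molecule clock inhibitor KL001 as a
causal probe.

## The models

Three coupled gene-network variants (`build_model(1|2|3)`):

* a PER-CRY negative-feedback clock (Hill repression of *Per/Cry*
  transcription by nuclear PER-CRY), extended in Models 2-3 by the
  REV-ERBα/BMAL1 secondary loop with PER-CRY inactivation of BMAL1-CLOCK;
* a cyclin B / MPF relaxation oscillator (Models 1-2) or a reduced
  four-cyclin cascade with p21 (Model 3) for the cell cycle;
* forward coupling `C1`: BMAL1-CLOCK activates *Wee1*; WEE1 inactivates
  MPF. Reverse coupling `C2`: MPF represses *Rev-erb*α.

Equations are integrated as chemical Langevin SDEs (Euler–Maruyama, with
`none`, `constant` or `state_dependent` noise). Each module carries one
time-scale factor, calibrated so the uncoupled clock runs at 24 h and the
uncoupled cell cycle at any requested autonomous period T<sub>CC</sub> in
10–36 h. Lineages grow by MPF-threshold phase transitions (G1 → S/G2 → M
→ division) with symmetric inheritance, recorded as directed binary
trees.

Key statistics: per-run Pearson IMT correlations of
sister/cousin/mother–daughter/grandmother pairs and the CMI;
Fourier-based entrainment spectra of both oscillators; KL001
dose–response of clock period and modulation depth (KL001 is modelled as
division of the PER-CRY degradation rates by a dose factor); log-linear
population growth fits; and cell cycle phase proportions against the
ergodic age-structure prediction 2(e<sup>−λa₁</sup> − e<sup>−λa₂</sup>).

## Worked example

Forward-coupled Model 2 at the HCT116-like calibration point
(C1 = 0.55, autonomous period 15 h, calibrated noise):

```r
library(clocklineage)

m <- build_model(2, C1 = 0.55, C2 = 0, autonomous_TCC = 15)
run <- run_lineage(m, noise_spec("constant", sigma = 0.03),
                   n_ancestors = 4, stop = list(max_population = 128),
                   seed = run_seed(1, 1))
run
#> <lineage_run> 252 cells, 124 divided, 4 lineage(s), stop at 82.85 h

imt_stats(run)
#> # A tibble: 1 × 4
#>       n  mean    sd    cv
#>   <int> <dbl> <dbl> <dbl>
#> 1   124  15.5  2.17 0.140

correlation_summary(run)
#> # A tibble: 3 × 3
#>   relation             r n_pairs
#>   <chr>            <dbl>   <int>
#> 1 sister           0.237      58
#> 2 mother_daughter -0.168     120
#> 3 cousin           0.120     108
```

One run is noisy; the ensemble median over 20 runs shows the inequality
clearly:

```r
runs <- lapply(1:20, function(i)
  run_lineage(m, noise_spec("constant", sigma = 0.03), n_ancestors = 4,
              stop = list(max_population = 128),
              seed = run_seed(1, i))$cells)
s <- cmi(runs)
glance(s)
#> # A tibble: 1 × 5
#>   n_runs median_delta mean_delta sd_delta n_undefined
#>    <int>        <dbl>      <dbl>    <dbl>       <int>
#> 1     20        0.276      0.278    0.186           0
cmi_boot_ci(s)
#>     lower     upper
#> 0.1968410 0.3377926
```

The median cousin-minus-mother-daughter difference is 0.276 with a
bootstrap 95% interval well above zero: cousins correlate more strongly
than mother–daughter pairs, purely as a consequence of clock gating.
Population growth in the same run is cleanly exponential:

```r
fit_growth_rate(population_curve(run))
#> <growth_fit> lambda = 0.04401 1/h, doubling time 15.75 h, R^2 = 0.996
```

`entrainment_curve()`, `kl001_dose_response()`,
`phase_proportion_analysis()` and `run_experiment()` drive the remaining
analyses; each returns a tidy tibble (or an object with `tidy()` /
`glance()` methods) and has an `autoplot()`/`plot_*()` companion.

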