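---
title: "Models and methods: coupled circadian clock / cell cycle lineage simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: coupled circadian clock / cell cycle lineage simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

Single-cell time-lapse experiments on several cell types show a puzzling
lineage correlation pattern in intermitotic times (IMTs): cousin cells are
often more strongly correlated than mother--daughter pairs (the
"cousin--mother inequality", CMI), and grandmother correlations can be
negative.  An oscillatory gating of cell cycle progression -- most
naturally by the circadian clock -- can produce exactly this pattern.
`clocklineage` implements stochastic gene-network models of the coupled
circadian clock / cell cycle system, grows simulated cell lineages from
them, and extracts the statistics by which such clock control can be
detected: lineage IMT correlations, entrainment spectra, the response to
the clock inhibitor KL001, population growth rates, and cell cycle phase
proportions over time.

# The models

Three network variants are provided, selected by `build_model(model_id)`.

**Clock side.**  The core is a PER-CRY negative feedback loop: *Per/Cry*
mRNA is translated into a cytoplasmic PER-CRY complex that translocates to
the nucleus and represses its own transcription (Hill repression,
coefficient 4, as required for robust limit cycles in loops of this
depth).  In Models 2 and 3 a secondary loop is added: BMAL1-CLOCK activates
*Rev-erb*&alpha; transcription, REV-ERB&alpha; represses *Bmal1*
transcription, and nuclear PER-CRY both represses *Rev-erb*&alpha;
transcription and inactivates the BMAL1-CLOCK heterodimer by direct
binding (mass-action term `kbp * B * Pn`).  The secondary loop is a genuine
co-oscillator whose oscillation is permitted by the PER-CRY loop; this
architecture was chosen for three reasons that the tests probe directly:

* BMAL1-CLOCK and nuclear PER-CRY peak in near anti-phase;
* the cell cycle can entrain the clock through the REV-ERB&alpha; branch
  (reverse coupling), because that branch owns a large share of the
  BMAL1-CLOCK dynamics;
* when PER-CRY is frozen at a high level (the KL001 limit) every clock
  species stops oscillating and settles at a nonzero level, with
  BMAL1-CLOCK parked near -- in fact somewhat below -- its free-running
  mean, so the WEE1 drive on the cell cycle is not grossly distorted by
  the drug.

Model 1 carries only the PER-CRY loop with a constitutive (constant)
BMAL1-CLOCK level.

**Cell cycle side.**  Models 1 and 2 drive division with a single
cyclin B / MPF relaxation oscillator: cyclin B accumulates at a constant
rate, activates MPF (with a positive MPF self-activation loop), and MPF
activates an APC-like degradation activity that destroys cyclin and
resets the cycle.  WEE1 enters as an MPF-inactivating rate.  Model 3
replaces the single driver by a reduced four-cyclin cascade
(CycD &rarr; CycE &rarr; CycA &rarr; CycB) with p21 as a shared Cdk
inhibitor; REV-ERB&alpha; represses p21 with a gain scaled by the forward
coupling strength, so that at `C1 = 0` the two modules are exactly
separable (a property the test suite verifies by finite differences).

**Coupling.**  Forward coupling: BMAL1-CLOCK activates *Wee1*
transcription with dimensionless gain `C1`; WEE1 inactivates MPF.  Reverse
coupling (Models 2-3): MPF represses *Rev-erb*&alpha; transcription with
gain `C2`.  `C1` and `C2` multiply the Hill-term maximal rates, and the
kinetic constants around them were fixed so that `C1 = 0.55` sits inside
the forward-entrained regime -- the same absolute number that the
experiments of record treat as meaningful.

# Calibration by time rescaling

Uniformly multiplying every rate constant of an autonomous module by `s`
divides its period by exactly `s` without changing the orbit.  Each module
therefore carries a single time-scale factor (`scl` for the clock, `scc`
for the cell cycle).  `build_model()` measures the uncoupled deterministic
periods, rescales both factors, re-measures, and fails loudly if the
result is off by more than 0.5 h.  `set_autonomous_period()` retunes only
`scc`, so any autonomous cell cycle period (TCC) in 10-36 h is available
while the clock stays at 24 h.

# Stochastic integration

The deterministic equations are converted to chemical Langevin SDEs and
integrated with the Euler--Maruyama scheme (`integrate_model()`).  The
right-hand side is decomposed at definition time into nonnegative
production and degradation fluxes; in `state_dependent` mode the noise
amplitude of species *i* is `sqrt(production_i + degradation_i) / sqrt(omega)`,
in `constant` mode it is a fixed `sigma` per species.  Negative excursions
are clipped to zero after each step -- the simplest deterministic contract
consistent with CLE practice.  The default step is `dt = 0.01` h, about a
thousandth of the fastest period of interest; the suite verifies first-order
endpoint convergence and agreement with an independent stiff solver in the
noise-free limit.  Trajectories are bit-reproducible given the seed;
lineage simulations draw one RNG stream per cell, derived from the run
seed and the cell id, so reproducibility does not depend on scheduling
order.

The default `constant`-mode `sigma` of 0.045 (and 0.03 used by the
headline experiments at 4-ancestor desk scale) is the package's noise
calibration: under `C1 = 0.55` it keeps the pooled IMT coefficient of
variation inside the 0.10-0.20 band reported for HCT116-like cells.

# Lineage growth and phases

`run_lineage()` grows binary trees: each cell integrates its own SDE from
its inherited state, enters M at the upward crossing of `theta_M` by MPF
(latched), and divides at the subsequent downward crossing of
`theta_div`; the two daughters inherit the mother's concentrations
verbatim.  Thresholds default to 60% (`theta_M`) and 20% (`theta_S`,
`theta_div`) of the deterministic uncoupled MPF peak, which lands the
deterministic phase durations at sensible G1 < S/G2 shares and fires
division exactly once per relaxation spike.  Cells alive at the stop rule
are censored and excluded from all IMT statistics.  Phase labels are kept
as first-crossing event times (G1 &rarr; S/G2 &rarr; M taken as monotone
within a cycle), which is what `snapshot_phase_counts()` consumes.

Ancestor populations come from `burn_in_ensemble()`: one long trajectory
past its transient, sampled either at uniform random times
(`synchronize = "none"`, fully asynchronous -- clock phases pass a
Rayleigh uniformity check) or in narrow windows around nuclear PER-CRY
peaks (`synchronize = "clock"`).  The second mode represents a culture
whose clocks have been synchronised (as after a medium change) while cell
cycle positions remain spread, and it is the regime in which
population-level M-phase fraction oscillations are visible; with fully
asynchronous ancestors the family rhythms average out and only a
root-N residue remains.  Because all clock-synchronised runs share their
t = 0 phase, replicate M-fraction series are phase-aligned and are averaged
before spectral analysis in the headline experiments.

# The statistics battery

`extract_pairs()` builds unique related pairs (sister, mother--daughter,
cousin, grandmother, great-grandmother) from uncensored cells; a
brute-force lowest-common-ancestor classifier serves as the test oracle.
`pearson_pairs()` symmetrises sister and cousin pairs by including both
orders, and signals (rather than silently returns) undefined correlations.
Correlations are computed per run, pooling pairs across the run's
ancestors; ensembles are across runs, which mirrors how run-ensemble
boxplots are constructed.  The CMI statistic is
`delta = r_cousin - r_mother_daughter`, summarised by the ensemble median
with a bootstrap confidence interval.

`spectral_summary()` linearly detrends, Hann-tapers and Fourier-transforms
a signal; the dominant frequency comes from a zero-padded spectrum (the
padding interpolates between the coarse bins of short windows) and the
amplitude is measured in the time domain as half the mean peak-to-trough
excursion of the final cycles, which stays meaningful for damped
signals.  For short, noisy fraction series the search band is capped at
twice the circadian period, since slower components cannot be resolved in
the available windows.  `fit_growth_rate()` is ordinary least squares of
log cell number on time.  `ergodic_prediction()` implements the
exponential age-structure law: in a population growing at rate
`lambda`, the fraction of cells with age in `[a1, a2)` is
`2 (exp(-lambda a1) - exp(-lambda a2))`, the factor 2 being the young-cell
enrichment from binary division.

# KL001

KL001 stabilises CRY; with PER-CRY lumped, the drug is a division of the
PER-CRY complex degradation rates (cytoplasmic and nuclear protein, not
mRNA) by a dose factor, 1 being control.  `kl001_dose_response()` reports,
per dose, the period and the modulation depth (oscillation amplitude over
mean level -- the natural readout for reporter-style traces) of nuclear
PER-CRY, the direct target.  In this parameterisation the modulation
decays monotonically with dose and the oscillation collapses over a
narrow factor range (between factors 4 and 5 at default settings), with
clock species settling at nonzero levels.

# Problem sizes

The headline experiments run at a desk scale chosen so the entire suite
finishes in minutes on one core: 20-run ensembles of 128-cell populations
from 4 ancestors for correlation and growth statistics, three
100-ancestor populations over 96-108 h for phase-proportion series, and
deterministic sweeps of about 60 clock periods for entrainment and
dose-response spectra.  A paper-scale profile (100 runs) is one
configuration switch away (`experiment_config(profile = "paper")`).

# Known limitations

These are properties of this reimplementation, verified by its own tests,
and they bound what passing tests can and cannot show.

* Absolute correlation values are not meaningful -- only the qualitative
  structure (which relations are larger, signs, and changes under
  perturbation).  Real lineages inherit many factors this model does not
  represent.
* The CMI window sits at autonomous periods of roughly 12-18 h in this
  parameterisation: it is strong near 12-15 h, marginal by 20 h, and
  absent at 24-30 h.  Reports that place the upper edge nearer the clock
  period itself are reproduced only qualitatively.
* Under KL001 the inequality is erased essentially completely at doses
  that flatten the clock (the drop saturates near -100% rather than
  -50%), because in this model the inequality is purely clock-driven and
  symmetric inheritance contributes no cousin-specific correlation.
* The dose-response period drifts down by ~2 h and then collapses
  abruptly, rather than jumping upward before the collapse; the secondary
  clock loop, which is fast enough to be entrainable by the cell cycle,
  takes over timing as PER-CRY saturates.
* At a 12 h autonomous period the M-phase fraction carries both a 12 h
  division-wave component and the 24 h clock-gated component; the 12 h
  line can dominate a single run's spectrum, and replicate averaging
  recovers the clock-period component on most but not all seeds.
* The Euler-Maruyama/CLE treatment of Michaelis-Menten kinetics is an
  approximation; exact stochastic simulation of elementary reactions is
  out of scope.
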