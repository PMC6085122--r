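---
title: "Cell-cycle phase segmentation and size homeostasis from histone-reporter traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-cycle phase segmentation and size homeostasis from histone-reporter traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclesizer)
```

## The measurement model

In budding yeast carrying a fluorescently tagged histone H2B, the total
nuclear fluorescence of a growing cell traces a characteristic shape over one
cell cycle: a *plateau* during the unbudded period (G1; histone pools are
constant), a *linear ramp* while histones are synthesised in tight coupling
with DNA replication (S), a second *plateau* during the budded period (G2/M),
and a *sudden drop* when the nucleus divides at anaphase and roughly half of
the histones migrate into the bud. Because histone content is proportional to
genome content, the post-S plateau sits at twice the pre-S plateau, and the
ramp boundaries time DNA replication directly — something neither bud-neck
markers nor budding morphology can resolve.

`cyclesizer` implements the complete downstream analysis of such traces:

1. **simulation** of lineages with known ground truth (`simulate_lineage()`),
2. **segmentation** of each cycle into G1/S/G2M/anaphase
   (`detect_anaphase_drops()`, `fit_piecewise()`, `segment_trace()`) with an
   explicit quality-control policy (`qc_policy()`, `qc_filter()`),
3. **cycle statistics**: the 15 per-cycle variables, Pearson correlograms,
   Kolmogorov–Smirnov strain comparisons, and robust size-compensation
   slopes (`compute_variables()`, `correlogram()`, `compensation_slope()`),
4. **noise profiling**: CV and Fano factor along the cycle with bootstrap
   errors and the CV $= \sqrt{F/V}$ power law (`noise_profile()`,
   `fit_fano_scaling()`, `fano_fold_change()`),
5. the **noisy linear map** of daughter birth size (`fit_return_map()`,
   `fano_prediction()`, `fit_intrinsic_noise()`, `convergence_rate()`,
   `convergence_trajectories()`).

## The synthetic world

The generator is *volume-target driven*. For each cycle:

* **G1** ends when the cell volume reaches
  $a_{G1} V_{birth} + (1 - a_{G1}) V^{tgt}_{G1} + \eta$. The retention
  coefficient $a \in [0, 2]$ is the ground truth of size control: the slope
  of $\Delta V$ against initial volume is exactly $s = a - 1$, so $a = 0$ is
  an ideal Sizer, $a = 1$ adds a size-independent increment, and $a = 2$
  yields slope $+1$.
* **S** draws a Gaussian duration (truncated positive); the bud appears at S
  onset and total histone content doubles linearly across S.
* **G2/M** ends when the *bud* reaches the analogous target
  $a_{G2M} V\!b_S + (1 - a_{G2M}) V\!b^{tgt}_{G2M} + \eta$ — size control in
  the budded period acts on the bud compartment.
* **Anaphase** has fixed duration; the signal drop spans anaphase minus the
  fixed 5.6-min anaphase-end-to-cytokinesis offset, and the daughter (the
  bud) inherits a fraction $d/(1+d)$ of the histone pools
  (`dm_fluo_asymmetry` $d$, default 1; the measured partition asymmetry is
  ~0.94).

Default parameters are calibrated so that a wild-type-like daughter shows
G1 ≈ 45 min, S ≈ 36 min, G2/M ≈ 15 min, anaphase ≈ 12 min (division time
≈ 108 min), birth volume ≈ 25 fL, end-of-G1 volume ≈ 40 fL, division
asymmetry $r ≈ 0.386$, compensation slopes $s_{G1} = -0.3$ (daughters) and
$s_{G2M} = -0.4$ — matching published wild-type phenomenology. Frames are
taken every 3 min; fluorescence noise defaults to 2% of the G1 plateau and
volume noise to 0.5 fL. Because a single $(a, V^{tgt})$ pair parameterises
G1 for both lineage classes, simulated *mother* G1 durations are shorter and
less variable than real aging mothers — a deliberate simplification; all
headline analyses are daughter-centric.

Phase-duration noise is Gaussian on the volume targets (homoscedastic, as
the linear-map model assumes) — the duration distribution family itself is
not constrained by the data, and this choice is flagged here rather than in
the data. Draws implying a negative volume increment are resampled (at most
100 times, then clamped with a flag); the retry counts are recorded per
cycle.

**Maturation.** Fluorophores mature with first-order kinetics
$dI/dt = P(t) - I/\tau$, $dM/dt = I/\tau$. Since production is piecewise
constant, the simulator advances $(I, M)$ *exactly* from event to event
(closed-form update) instead of on a fixed sub-frame grid — this removes an
integration step size from the model entirely. The exported
`apply_maturation()` keeps a gridded interface for filtering arbitrary
production series. A short constant ($\tau = 5$ min, sfGFP-like) reproduces
the plateau–ramp–plateau shape almost undistorted; a long one ($\tau = 45$
min, mCherry-like) low-pass-filters it into a featureless rise (see below).

**What a green test does not establish.** The generator emulates the
*signal structure* of the reporter, not microscopy: there is no image
segmentation error model beyond additive Gaussian volume noise, no
photobleaching, no tracking failures, no age-dependent physiology. Passing
tests certify the trace-level pipeline, not the upstream vision stages.

## Segmentation and its numerical choices

Drops are detected where fluorescence falls by more than 25% of its local
3-frame median within at most two frames; the onset is refined to the last
frame not yet significantly declining and the end is the last frame of
significant decline (2% of the local median per frame), which keeps
measurement noise from stretching events. Between consecutive drop ends the
continuous plateau–ramp–plateau model is fitted by *exhaustive* search over
breakpoint pairs on the frame grid (closed-form least squares per pair, ties
broken by the earliest pair). Sub-frame breakpoint interpolation is refused
as false precision at 3-min sampling.

Because every boundary estimate is quantised to the frame grid, a duration
(the difference of two boundaries) carries up to *two* frames of
discretisation error even on noiseless data; the medians are within one
frame. The anaphase duration additionally absorbs the onset convention (the
last pre-drop frame) and is systematically long by roughly one frame. Tests
assert exactly these bounds rather than an unattainable single-frame
guarantee.

Quality control is an explicit policy (the source study reports only that
63% of cycles passed, not its criteria): minimum fit $R^2$ (0.85), positive
ramp slope, plateau ratio in $[1.5, 2.7]$, each phase at least one frame,
cycle length in $[30, 400]$ min, a known previous cytokinesis, and — beyond
the obvious gates — a minimum fractional depth of the terminating drop
(40%). The depth gate encodes that a true nuclear division halves the
signal; without it, a square artifact whose trailing edge mimics a drop can
carve out a spurious "cycle" whose plateau ratio lands inside the accepted
band. It assumes near-even histone partition and should be relaxed for
strongly asymmetric partition mutants.

**The mCherry degeneration.** With $\tau = 45$ min, steady-state cells are
born with a large immature pool, so the G1 signal *rises* as inherited
fluorophore matures and the fitted "pre-S plateau" is not flat; the plateau
ratio collapses to ~1.55 and S timing becomes unrecoverable. The fitted
breakpoint does not literally collapse to the window start — the blur
produces a slowly-rising early segment rather than a steeper one — but the
scientific content (no resolvable pre-S plateau, ramp-only appearance) is
exactly reproduced and asserted in the tests.

## Size-compensation statistics

All robust slopes use iteratively reweighted least squares with Tukey's
bisquare weight, tuning constant 4.685 (95% Gaussian efficiency), MAD scale
re-estimated each iteration, convergence $10^{-8}$, at most 200 iterations;
confidence intervals are normal-theory ($z = 1.96$) from the M-estimator
sandwich variance. This pins down the "robust linear regression" that the
source methods name without specifying. G2/M compensation is computed on
the *bud* compartment by default (`compensation_table(g2m_whole_cell =
TRUE)` reproduces the strongly attenuated whole-cell version). Pearson (not
rank) correlations populate the correlogram, mothers in the upper triangle,
daughters in the lower, with pairwise-complete deletion and no
multiple-testing correction (raw coefficients, as conventionally reported).

Strain comparisons use the two-sample Kolmogorov–Smirnov test with *exact*
p-values whenever there are no ties: at typical per-strain sample sizes the
asymptotic null is conservative. Note that even the exact non-randomised
test has attained size ≈ 0.0396 at $n = m = 200$ and nominal 0.05, because
the KS statistic is discrete; the calibration test asserts agreement with
this exactly computed attained size.

## Noise and the linear map

The Fano factor $F = \mathrm{Var}(V)/\langle V \rangle$ is computed on raw
volumes; under the central-limit scaling of growth noise,
$\mathrm{CV} = \sqrt{F/V}$ with $F$ approximately constant along the cycle,
so $F$ is the size-independent noise strength. Bootstrap errors resample
cells, never frames, preserving within-cell coupling.

Daughter birth sizes follow the noisy linear map
$V_{n+1} = p V_n + (1 - p) V_{eq} + \eta$, with
$F = \frac{\langle\eta^2\rangle / V_{eq}}{(1 - p)(1 + p)}$ at stationarity
and convergence rate $\lambda = -\ln(p)/\langle T_{div}\rangle$. The map
couples to the compensation analysis through $p = r\,a$, $a = s_{tot} + 1$.
Two caveats decided here:

* $\langle\eta^2\rangle$ is estimated as the variance of the robust-fit
  residuals (configurable to OLS residuals) — the estimation route is not
  specified by the model itself.
* The bridge $p = r (s_{tot} + 1)$ presumes the daughter receives an
  (approximately) constant fraction $r$ of the divided volume. Under the
  mechanistic `"bud"` division rule with linear growth, bud size is
  decoupled from mother birth size and the marginal split differs from the
  average split, so the bridge fails *by construction* — not by bug. The
  generator therefore offers `division_rule = "fraction"`, which divides
  volume exactly as the model assumes; the bridge test runs in that world.
  The 99% confidence interval on the intrinsic noise $c = \eta^2/V_{eq}$ is
  profiled from the residual sum of squares (F test), matching the
  dashed-band convention for that fit.
* Return maps use daughter-of-daughter chains (each generation's first
  daughter), the reading most consistent with the recursion; convergence
  trajectories select founders deviating by more than +50% or below 70% of
  $V_{eq}$ and follow six generations.

## Acceptance anchors

`scripts/acceptance.R` recomputes, from scratch at a caller-supplied seed:
the Timer calibration slope (+1; 5,000 cells, exponential growth, mean
doubling, 5% multiplicative noise), the Adder calibration slope (0; ΔV ~
N(40, 8) fL independent of initial volume), and the plateau ratio of the
piecewise fit on one noiseless cycle (2.0). For the plateau ratio the
simulated phase boundaries are placed *on* the 3-min frame grid: the ratio
is structurally 2 (histone doubling), and grid alignment removes the only
nuisance — boundary-frame discretisation — so the fitted value is exact
rather than merely close. The remaining acceptance criteria (Sizer slope,
linear-map limit, round-trip, Monte-Carlo Fano, CI coverage, KS
calibration, Fano-fold-change monotonicity, mCherry degeneration) run as
`tests/testthat/test-acceptance.R`.

## Known limitations

* Mother-cell G1 durations are compressed relative to real replicative
  aging (single-target parameterisation; see above).
* The drop detector assumes division roughly halves the nuclear signal;
  extreme partition-asymmetry settings require relaxing
  `qc_policy(min_drop_frac = )`.
* Absolute Fano levels of real strains are not reproduced — they depend on
  biological noise sources the generator does not model; only structure and
  trends (contraction under compensation, Eq.-(2) consistency, monotone
  fold-change) are in scope.
* `division_rule = "fraction"` re-partitions volume but not the trace's bud
  channel; it is intended for ground-truth-level model studies.
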