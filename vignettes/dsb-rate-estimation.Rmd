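---
title: "Estimating spontaneous DNA break rates from fluorescent focus data"
author: "DSBrate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating spontaneous DNA break rates from fluorescent focus data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DSBrate)
```

## The measurement problem

Double-strand breaks (DSBs) are rare in unperturbed cells — far below the
sensitivity of bulk physical assays — so the only practical route to a true
*rate* is single-cell imaging: a fluorescent fusion of a double-strand-end
binding protein (phage Mu Gam fused to GFP) forms a visible focus at each
break. Turning focus counts into break rates requires three quantitative
ingredients, and this package implements all of them with a synthetic-data
generator that makes every step testable against known ground truth:

1. **Detection efficiency** `p`: not every break yields a scoreable focus.
   Gamma irradiation produces a known number of breaks per cell per gray
   (`y` = 0.031 DSBs/cell/Gy for *E. coli*, from sedimentation
   measurements), so the slope of mean foci per cell against dose, divided
   by `y`, estimates `p`.
2. **Foci per division** `f`: time-lapse imaging of microcolonies growing
   from single founders counts divisions and spontaneous focus appearances.
   Because a focus-bearing cell stops dividing (the fusion protein traps
   the broken end and blocks repair), the colony is a branching process
   with an absorbing state.
3. **The correction** `r = f / p`: the spontaneous DSB rate per cell
   division.

## The generative model

`simulateMicrocolony()` implements a continuous-time branching process.
Interdivision times are exponential with a regime-dependent mean
(`tauSchedule`), i.e. a piecewise-constant division hazard. The memoryless
choice is deliberate: it keeps the process Markovian and every downstream
expectation analytically checkable, at the cost of a broader colony-size
distribution than real, fairly synchronous bacterial microcolonies show.
For analyses that need the observed "follow each founder to ~100 cells"
design, the `stopAtCells` argument ends observation at a target colony
size instead of a fixed time.

Each division event carries one independent Bernoulli trial with success
`q = r * p`: with probability `q` the division produces a *detected* break,
assigned to one of the two daughters at random, and (by default) that cell
never divides again. One trial per division — rather than one per daughter
— is what makes the foci-per-division statistic estimate `q` directly, and
is the reading consistent with breakage arising from a replication event
completed at division. Whether focus appearance is really synchronous with
division is not resolvable from endpoint counts; tying it to divisions is
the model commitment that encodes the generation-dependence conclusion,
and the clock-like alternative is available as an explicit alternative
generator (`focusModel = "time"`, a per-cell-hour Poisson process) for
power analyses.

Defaults are the calibrated study conditions: `r = 0.021` breaks per
division, `p = 0.71`, background `b = 0.043` foci per cell (the minimal-
medium zero-dose level), `y = 0.031` DSBs/cell/Gy, and a schedule of
`tau = 1.95 h` for 9 h followed by `tau = 26 h`. The 1.95 h mean is chosen
so that a founder reaches ~100 cells after 9 h of growth (the branching
process grows as `exp(t/tau)`); 26 h represents the near-halt of divisions
after glucose withdrawal. The background is modelled Bernoulli rather than
Poisson because `b < 1` in every calibrated regime and the difference is
second order (`P(2+ background foci)` ~ `b^2/2` ≈ 0.001).

The dose-response generator draws true breaks per cell as Poisson(`y D`),
thins them binomially with `p` (a thinned Poisson is again Poisson, which
the moment tests exploit), and adds the Bernoulli background.

## Calibration

`fitDoseResponse()` is ordinary least squares of per-dose mean foci on
dose — unweighted by default, since the historical calibration treats the
per-dose means as equally informative; an inverse-variance weighted option
exists. The intercept is fitted, not forced through the zero-dose mean;
the separate published-style subtraction is `netInducedFoci()`. With
exactly two dose points the slope is the difference quotient and `r2` is
reported as `NA`. Two calibration routes coexist deliberately: the
two-point arithmetic on the printed anchor values (0.043 foci/cell at
0 Gy, 3.12 at 140 Gy → 0.022 foci/cell/Gy → efficiency 0.71) and the full
regression on a many-dose table; the package makes both available because
the provenance of the printed 0.022 slope is ambiguous, and uses the
two-point route as the anchor for the printed-arithmetic chain.

`bootstrapEfficiencyCI()` is a percentile bootstrap over refits. The
summary table carries only per-dose `(mean, sd, n)`, not per-cell counts,
so each replicate redraws every per-dose mean from its estimated sampling
distribution (`mean + sd/sqrt(n) * N(0,1)`) — a moment-based stand-in for
resampling cells that is exact in the large-`n` limit the tables live in
(thousands of cells per dose). A zero-variance table collapses to a
zero-width interval, and the whole interval scales as `1/yield`.

## Rate inference

`fociPerDivision()` uses the colony-level estimator: per colony
`f_i = foci_i / divisions_i`, then mean and SEM across colonies. That
matches the "mean ± SEM over microcolonies" reporting convention of the
source experiments; the pooled estimator `sum(foci)/sum(divisions)` with a
Wilson 95% interval is reported alongside (Wilson rather than Wald because
focus counts are small). Colonies whose founder never divided are excluded
with a warning — they carry no per-division information.

`correctRate()` applies `r = f/p` with, by default,
`rSem = fSem / p`: the efficiency's own uncertainty is *excluded*, which
reproduces the published ±0.008 (= 0.006/0.71); full delta-method
propagation including an efficiency SE is behind
`propagateEfficiency = TRUE`. The published 0.021 itself is 0.0145/0.71 =
0.0204 before rounding, which is why downstream checks use a 5% relative
tolerance.

`frequencyToRate()` converts the older flow-cytometric estimate — a rate
`F` of cells acquiring at least one break per generation — by multiplying
with the mean break multiplicity of focus-carrying cells
(`108/98 ≈ 1.1` under matched growth conditions): `0.01 × 108/98 = 0.011`
DSBs per division, independent of and consistent with the microfluidic
route.

`generationDependence()` is the formal version of the "foci track
divisions, not hours" argument: per regime (e.g. before/after glucose
withdrawal) it computes foci per division and foci per hour, then
contrasts regimes by a binomial ratio interval (per division) and a
Poisson ratio interval (per hour). Support requires the per-division ratio
to be compatible with 1 while the per-hour ratio is not. Regimes with no
divisions are flagged rather than silently dropped.

## Co-localization geometry

`matchFoci()` pairs green (break) and red (chromosome-marker) foci within
each cell by **minimum-total-distance assignment** — exact branch-and-bound
up to 8 foci per channel, greedy global-nearest beyond. Exact assignment,
rather than iterated mutual nearest neighbours, was chosen because greedy
matching provably differs from the optimum on some configurations and the
optimum is the reproducible, order-free definition. Ties are resolved
deterministically by sorting calls on (x, y) first. Cells are classed 1:1,
1:2 (one green, two red — the replicating-chromosome case, yielding a near
and a far distance) or other; only 1:1 and 1:2 enter distance summaries,
but everything is counted.

The overlap criterion for a "yellow" (co-localized) pair is a configurable
threshold, default 0.2 µm ≈ the diffraction limit, because the original
scoring criterion is not stated numerically; every reported fraction
carries its threshold. `categoryCounts()` implements per-focus two-marker
classification with two documented denominators (matched pairs counted
once, or per-focus counting), since both conventions appear in published
figures of this kind.

`simulateFocusPairs()` draws the green-red displacement magnitude as a
Rayleigh variable whose mean follows a saturating exponential of genomic
distance, `mean(d) = 0.57 µm × (1 - exp(-d / 35 kb))`. The measured
anchor points fix the plateau at 0.57 µm (the 2.4 Mb value) and the 35 kb
scale reproduces the 55 kb (~0.45 µm) and 80 kb (~0.51 µm) means; the
functional form itself is a modelling choice — four measured points
determine no curve — constrained to be monotone, zero at zero and
saturating.

## Copy number and multi-focus fractions

`relativeCopyNumber()` implements the delta-Ct method with a single
amplification efficiency for both loci (default `E = 2`): per sample
`deltaCt = mean Ct(ter) - mean Ct(ori)`, normalized to a stationary-phase
reference assumed 1:1, then `ratio = E^ddCt`. Replicates are averaged on
the Ct scale before exponentiation, the standard convention.
`expectedMultifocusFraction()` is the exact forward model
(copies → binomial cutting → binomial detection); it is deliberately *not*
fitted to observed multi-focus percentages because the per-site cleavage
efficiency is unknown — the package exposes the forward direction and the
monotone ori-vs-ter ordering only.

## Spot calling

`detectFoci()` replaces unspecified original counting software with a
standard, tested operator: difference-of-Gaussians band-pass at the PSF
scale (second sigma 1.6× the first), robust threshold at
`median + kSigma × 1.4826 MAD` of the filtered image (`kSigma = 5`,
chosen for stability on sparse-spot images where the field is almost all
background), 8-neighbourhood local maxima with ties broken toward the
lowest (row, col) index, and 3×3 intensity-weighted sub-pixel centroids.
The band-pass and robust statistics make detection invariant under a
constant added to the whole image. Coordinates are 0-based, physical
position at the pixel centre, x along columns. No attempt is made to
reproduce the original software numerically — only to satisfy measurable
quality bounds (≥95% recall and precision at SNR 10 and ≥5σ separation)
on synthetic images with known truth.

## What the synthetic data does and does not show

The generators reproduce the *stochastic structure* the analyses assume:
Bernoulli breakage per division with binomial detection thinning, Poisson
dose-delivered breaks, arrest-on-focus, copy-number-dependent cutting,
distance-dependent two-channel geometry and Poisson shot noise on Gaussian
spots. They deliberately omit: cell shape and segmentation (masks are
inputs), chromatic aberration, photobleaching/phototoxicity (the
fluorescence-exposure question is handled as a two-sample rate comparison,
`exposureControlCompare()`), 3-D nucleoid structure, and any sequence-level
biology. Passing tests therefore demonstrate that the *estimators are
correct under the stated model*, not that the model is a complete account
of real images; in particular the efficiency calibration inherits whatever
systematic error the literature yield `y` carries, which is why the
published efficiency is itself called a rough estimate.

## Numerical choices and problem sizes

Tolerances in the test-suite are three standard errors of the quantity
under test (Monte-Carlo or analytic), never ad hoc percentages, except
where a published rounding step imposes one (the 5% relative tolerance on
0.021). Simulation sizes are chosen to make those standard errors small
relative to the effects tested: 20 microcolonies of ~100 cells
(~2,000 divisions) for end-to-end rate recovery — the design of the source
experiment, whose binomial noise floor (SD ≈ 0.003 on r) is the honest
uncertainty of that design; 5,000 cells per dose over six doses for
calibration; 2,000 bootstrap replicates; 10,000-50,000 cells for moment
checks; 200 rendered images for spot-caller operating characteristics.
All randomness flows from one seed through labelled streams
(`seedStream()`), so adding a stage never shifts existing draws and every
pipeline output is byte-reproducible (`runPipeline()` demonstrates this
end to end).

## Known limitations

* The branching simulation records focus events only at divisions under
  the default model; sub-division timing of focus appearance is not
  modelled (and is not identifiable from endpoint counts).
* The bootstrap treats per-dose means as Gaussian; at very small `n` per
  dose a per-cell resample would differ.
* The greedy assignment fallback above 8 foci per channel is not
  guaranteed optimal; cells that crowded are outside the regimes studied.
* `exposureControlCompare()` is a plain Welch comparison; it does not
  model dose accumulation across exposures.
* Efficiency estimates above 1 are flagged, not clamped — they indicate an
  inconsistent yield assumption rather than a computable probability.
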