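# DSBrate

Spontaneous DNA double-strand breaks (DSBs) drive mutation, genome
rearrangement and evolution, but they are far too rare for bulk physical
assays: in growing *E. coli* only on the order of 1% of cells carry one.
Fluorescent fusions of double-strand-end binding proteins (phage Mu Gam
fused to GFP) make single breaks visible as foci in living cells — and
because the fusion traps the broken end, a focus-bearing cell stops
dividing, turning a growing microcolony into a branching process with an
absorbing state. **DSBrate** is an R package for turning such focus data
into true break rates, for microscopists and quantitative biologists
working with focus-reporter systems.

The core quantities:

* **Detection efficiency** — foci per cell is linear in gamma-ray dose
  *D*; with a known radiation yield *y* (DSBs cell⁻¹ Gy⁻¹), the fitted
  slope *s* gives the probability a true break is scored as a focus,
  *p = s / y*.
* **Break rate per division** — in time-lapse microcolonies, each division
  is a Bernoulli trial: per colony *f·ᵢ = foci / divisions*, summarised as
  mean ± SEM across colonies, and corrected to the true rate
  *r = f / p*.
* **Legacy conversion** — older assays measured the rate *F* of cells
  acquiring ≥1 break per generation; multiplying by the mean multiplicity
  *m* of focus-carrying cells gives *r = F·m*.

Companion modules cover the generation-dependence test (per-division vs
per-hour focus rates across division-rate regimes), two-channel focus
co-localization geometry (minimum-distance matching, overlap fractions,
near/far interfocal distances, two-marker category counts), ΔCt relative
ori:ter copy number, a difference-of-Gaussians spot caller, and
synthetic-data generators for every input, so the whole pipeline is
testable against known ground truth.

## Worked example

```r
library(DSBrate)

## 1. calibrate detection efficiency from a dose-response
params <- SimParams()   # r = 0.021, p = 0.71, b = 0.043, y = 0.031
tab <- simulateDoseResponse(params, doses = c(0, 20, 40, 70, 100, 140),
                            nCells = 5000, seed = 7)
cal <- fitDoseResponse(tab, yield = 0.031)
cal
#> CalibrationResult
#>   slope     : 0.0222 foci/cell/Gy (se 0.000135)
#>   intercept : 0.0413 foci/cell
#>   r2        : 1
#>   yield     : 0.031 DSB/cell/Gy
#>   efficiency: 0.716

## 2. count foci per division in 20 simulated microcolonies (~100 cells)
traces <- lapply(1:20, function(i)
  simulateMicrocolony(params, tEnd = 60, stopAtCells = 100,
                      seed = seedStream(42, paste0("trace", i))))
fp <- fociPerDivision(traces)

## 3. efficiency-correct into a DSB rate per division
correctRate(fp$f, fp$fSem, p = efficiency(cal), nColonies = fp$nColonies,
            totalFoci = fp$totalFoci, totalDivisions = fp$totalDivisions)
#> RateEstimate
#>   foci/division f : 0.0177 +/- 0.00292 (SEM, 20 colonies)
#>   efficiency p    : 0.716
#>   DSB/division r  : 0.0247 +/- 0.00408
#>   pooled q        : 0.0181 (Wilson 95% 0.0131-0.0251)
```

The fitted slope (~0.022 foci cell⁻¹ Gy⁻¹) over the yield 0.031 recovers
the detection efficiency ~0.71; dividing the observed foci-per-division
mean by it recovers the simulation's true rate of 0.021 DSBs per division
to within the binomial noise of ~2,000 divisions (SD ≈ 0.003 — a single
20-colony experiment is intrinsically that uncertain, and this seed's
draw lands at 0.0247 with the truth inside the pooled interval). The printed
arithmetic anchors behave the same way:

```r
twoPoint <- data.frame(dose_Gy = c(0, 140), mean_foci = c(0.043, 3.12))
slope(fitDoseResponse(twoPoint))        # 0.02198  -> 0.022
netInducedFoci(twoPoint, 140)           # 3.077    -> 3.07
estimateEfficiency(0.022, 0.031)        # 0.7097   -> 0.71
dsbRate(correctRate(0.0145, 0.006, p = 0.71))   # 0.0204  -> 0.021
frequencyToRate(0.01, 108, 98)          # 0.01102  -> 0.011
```

`runPipeline(pipelineConfig(seed = 1), "out/")` runs the whole chain —
traces, dose-response, calibration, rate, co-localization — writing TSV
tables, JSON results and a human-readable report, byte-identical under a
fixed seed.

See `vignettes/dsb-rate-estimation.Rmd` for the model, its assumptions
and the numerical design choices.

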