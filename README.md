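# noda2d

Generalized two-dimensional correlation spectroscopy (2D-COS) for
perturbation-indexed series of vibrational spectra — for spectroscopists who
measure a stack of 1D spectra along a temperature (or other perturbation)
trajectory and want to know not just *which* bands respond, but *in what
order*.

## What it computes

Given spectra I(ν, T) at k perturbation values, a reference spectrum Ī(ν)
(by default the spectrum at T_min) defines the dynamic spectra
Ĩ(ν, T) = I(ν, T) − Ī(ν). Two maps follow:

- synchronous: Θ(ν₁, ν₂) = 1/(k−1) · Σᵢ Ĩ(ν₁, Tᵢ) Ĩ(ν₂, Tᵢ) — symmetric;
  diagonal auto-peaks measure each band's susceptibility to the
  perturbation, off-diagonal cross-peaks mark bands that change together;
- asynchronous: Ω(ν₁, ν₂) = 1/(k−1) · Σᵢ Ĩ(ν₁, Tᵢ) Σⱼ Mᵢⱼ Ĩ(ν₂, Tⱼ) with
  the Hilbert–Noda matrix Mᵢⱼ = 0 (i = j), 1/(π(j−i)) otherwise —
  antisymmetric with zero diagonal; non-zero cross-peaks mark sequential
  (out-of-phase) responses.

Noda's sign rules turn each cross-peak's (sign Θ, sign Ω) pair into a
verdict: Θ>0, Ω>0 means the band at ν₁ responds *prior to* the band at ν₂;
Ω<0 flips it; Θ<0 reverses the rule; Ω≈0 means the bands respond in phase.
`applyNodaRules()` applies the table, attempts a transitive closure, and
reports (never resolves) inconsistent cycles.

The package also ships the surrounding workflow: wide-CSV spectral I/O with
an exact round-trip guarantee, region selection, linear-endpoint baseline
correction, internal-standard band-area (or vector) normalization, linear
resampling of unevenly spaced series, auto/cross-peak detection,
asynchronous slices, contour plots, a YAML-configured end-to-end pipeline
with a replayable run log, and a synthetic band-model generator with known
ground-truth response ordering so every stage is testable without any
instrument data.

## Worked example

Three Gaussian bands (HWHM 10 cm⁻¹) at 1000/1060/1120 cm⁻¹ with sigmoid
intensity responses switching on at 270/290/310 K, sampled like a typical
temperature-series FTIR-ATR acquisition (k = 10 spectra, 250–340 K in 10 K
steps, 4 cm⁻¹ grid):

```r
library(noda2d)
sim <- generateSeries(syntheticSpec(list(
  bandSpec(1000, 10, onsetT = 270),
  bandSpec(1060, 10, onsetT = 290),
  bandSpec(1120, 10, onsetT = 310)
)))
maps <- correlate2d(sim$series, reference = "first")
maps
#> CorrelationMaps: 76 x 76 (from k = 10 spectra)
#>   sync  range [1.86e-62, 0.0299]
#>   async range [-0.00608, 0.00608]

cps <- detectCrosspeaks(maps)
print(cps, digits = 4)
#>    nu1  nu2  kind sync_sign async_sign sync_value async_value prominence
#> 1 1060 1000 cross         +          -    0.02383   -0.004664     0.7963
#> 3 1120 1000 cross         +          -    0.01527   -0.006076     0.5104
#> 2 1120 1060 cross         +          -    0.01539   -0.003735     0.5142

ord <- applyNodaRules(cps)
ord
#> SequentialOrder: 3 pairwise relation(s), 0 cycle(s)
#>   nu1  nu2   verdict                                           rule
#>  1060 1000 nu2_first sync > 0, async < 0: nu2 responds prior to nu1
#>  1120 1000 nu2_first sync > 0, async < 0: nu2 responds prior to nu1
#>  1120 1060 nu2_first sync > 0, async < 0: nu2 responds prior to nu1

recoverOrder(ord, sim$truth)$fraction
#> [1] 1
```

Reading the output: every cross-peak sits on the ν₁ > ν₂ triangle with a
positive synchronous sign (all bands grow on heating) and a negative
asynchronous sign, so in each pair the *lower*-wavenumber band — the one
with the earlier onset — responds first: 1000 before 1060 before 1120 cm⁻¹.
That matches the generator's ground truth exactly (recovery fraction 1).

The same analysis runs end to end from a YAML configuration:

```r
res <- runPipeline(demoConfig("cns-low"), outputDir = "demo-out")
```

which writes maps, peak tables (labelled with a packaged band-assignment
dictionary for TEMPO-oxidized cellulose / bPEI materials), the order report,
asynchronous slices, contour figures and a replayable `run_log.json`. The
shell interface wraps the same functions:

```sh
Rscript inst/scripts/noda2d.R demo --name cns-low --outdir demo-out
Rscript inst/scripts/noda2d.R run --config my-config.yaml --outdir out
```

See the vignette (`vignettes/two-dimensional-correlation.Rmd`) for the
model, the preprocessing contracts, the synthetic generator's assumptions
and every numerical choice.

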