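# pcdexr

Simulation and evaluation of **moving-blocker scatter correction for
photon-counting dual-energy chest radiography**, at desk scale, in R.

Dual-energy chest radiography forms two weighted log-subtraction images —
soft-tissue (PMMA-enhanced) and bone (Al-enhanced) — from the low- and
high-energy bins of a photon-counting detector (PCD). Scatter contaminates
both bins, predominantly at low energies, and biases the subtraction. The
moving-blocker method steps a thin tungsten rod across the beam over a
sequence of low-dose frames: pixels in the rod shadow receive (almost) only
scatter, so the shadows sample the scatter field directly, per energy bin,
with no added dose. This package simulates the whole chain and quantifies
the benefit with IEC 62220-2-1-style metrics:

* **Phantom** — LucAl-style chest phantom (PMMA + 4.1 mm Al + 190 mm air
  gap) in three sizes (247.1 / 267.1 / 287.1 mm background), with ten
  25 mm cylindrical inserts (PMMA 2–10 mm, Al 0.5–2.5 mm).
* **Beam** — analytic 120 kVp tungsten spectrum with 4 mm Al filtration,
  normalized to 1 mGy entrance air kerma (or any target); user spectra via
  a two-column text file.
* **Transport** — analytic Beer–Lambert primary projection; Monte Carlo
  Compton scatter (Klein–Nishina) with next-event estimation onto the
  detector, validated against an independent single-scatter quadrature.
* **Detector** — 0.75 mm CdTe PCD, 1.6 keV energy blur, thresholds at
  30/70 keV, 100 µm pixels binned to 1 mm, Poisson counting noise.
* **Estimator** — 25 blocker frames at 1/25 dose; shadow-center sampling
  (3 central columns), cubic interpolation across the 25 shadow positions,
  Gaussian smoothing (σ = 5 mm), per-bin subtraction.
* **Metrics** — per-insert dual-energy contrast from two noise realizations,

  DEC = [(F̄₁−B̄₁) + (F̄₂−B̄₂)] / (2 √(varF₁+varB₁+varF₂+varB₂)),

  and the kerma-normalized dual-energy subtraction efficiency
  DSE = DEC / Ka (equal to DEC at Ka = 1 mGy).

## Worked example

A reduced, single-size run (30 cm detector, 3×10⁴ photon histories) takes a
few seconds and exercises the full pipeline:

```r
library(pcdexr)
cfg <- run_config(sizes = "standard", detector_cm = 30,
                  n_photons = 3e4, coarse_n = 11, seed = 77)
ex <- run_experiment(cfg)
ex
#> <experiment> sizes: standard; seed 77
#>   standard: scatter-map error mean 0.141% max 1.008%
rep <- dec_report(ex)
subset(rep, target & state == "corrected" & image == "b",
       select = c(material, thickness, dec, rel_change_pct))
#>    material thickness        dec rel_change_pct
#> 42       al       0.5  -4.218177     -2.2695062
#> 44       al       1.0  -8.714989      0.9251107
#> 46       al       1.5 -12.403852      0.4626859
#> 48       al       2.0 -16.401061      1.2413078
#> 50       al       2.5 -19.835693     -0.5299909
```

The scatter-map error compares the moving-blocker estimate against the
simulation's expected-scatter truth inside the phantom-covered field of
view. DEC is signed; its magnitude grows roughly linearly with insert
thickness, and `rel_change_pct` is the DEC gain of scatter correction over
the uncorrected acquisition — at this reduced photon budget the per-insert
gains are within the run-to-run noise, which is expected at a standard-size
phantom's moderate scatter fraction. At the full reference configuration
(`run_config()` defaults: 40 cm detector, 2×10⁶ histories, three sizes) the
scatter-map error is ≈0.13% mean / ≈0.85% max per bin, and the
thickness-averaged DEC gain per size and image type ranges from ≈2% to
≈27%, largest for the large phantom where scatter is highest.

Other entry points: `validate_scatter()` (per-bin error metrics and 1-D row
profiles), `plot_dec()` (DEC-vs-thickness curves), `write_phantom_description()`
and `run_experiment(..., out_dir=)` for provenance exports,
`read_run_config()` for YAML configs.

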