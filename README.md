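# biliscreen

Screening analysis for neonatal hyperbilirubinemia from smartphone skin
images.

About half of term newborns develop visible jaundice; a small fraction
progress to bilirubin levels that threaten kernicterus. The gold-standard
measurement — total plasma bilirubin (TsB, µmol/L) from a heel-stick blood
sample — is invasive and unavailable at home, which is exactly where bilirubin
peaks (days 3–5, after discharge). A candidate low-cost screen is a smartphone
photograph of blanched glabella skin taken through a dermatoscope: bilirubin
is a yellow chromophore absorbing in the blue (peak ≈ 460 nm), so the
red/green/blue channel intensities of such an image carry a TsB-dependent
signal.

`biliscreen` implements the full analysis chain that evaluates this idea, for
researchers developing image-based jaundice screens:

- **Synthetic cohort and image generator** — seeded, reproducible cohorts of
  n ≈ 51 newborns (TsB ~ truncated log-normal, median 155, range 28–289
  µmol/L, plus gestational age, postnatal age, birth weight, haemoglobin,
  sex) and 8-bit RGB glabella patches whose channel means follow
  `alpha_c + beta_c·TsB + covariate terms + subject noise + pixel noise`.
  The default profile is calibrated in closed form so the extracted
  channel/TsB Pearson correlations are r ≈ 0.59 (green), 0.46 (blue), 0.21
  (red). Hair-streak and specular artifacts can be stamped on for QC testing.
- **Spectral forward model** — Gaussian chromophore bands (bilirubin,
  haemoglobin, melanin), a two-pass Beer–Lambert reflectance
  `R(λ) = exp(−2L Σ cᵢ εᵢ(λ))`, a yellow-green band-pass filter
  (half-maximum 483/589 nm, peak 516 nm), and trapezoid-integrated camera
  RGB rendering.
- **Image pipeline** — minimum-variance uniform-region selection, saturation
  / artifact / uniformity QC, exact per-channel mean/median/quartile
  extraction, and 2×2–4×4 block-aggregated re-analysis.
- **Screening statistics** — Pearson correlation with the t-transform
  p-value, single-pass 3-SD population outlier exclusion, discrimination-limit
  classification (test-positive iff intensity > limit; condition-positive iff
  TsB > 205 µmol/L) with sensitivity = 100·tp/(tp+fn) and
  specificity = 100·tn/(tn+fp), full threshold scans, and stepwise forward
  OLS regression with partial-F entry at p < 0.05.
- **Pipeline entry points** — `simulate_study()` / `screen_study()` write
  cohort CSVs, PNG images, correlation/scan/regression reports and a
  provenance manifest; a thin CLI wrapper ships in `inst/cli/biliscreen`.

## Worked example

```r
library(biliscreen)

# the printed green-channel worked example: 26 subjects above limit 212
# (11 of them with TsB > 205 umol/L), 25 below, none condition-positive
ints <- c(rep(230, 26), rep(190, 25))
tsb  <- c(rep(250, 11), rep(150, 15), rep(150, 25))
classify_and_score(ints, tsb, limit = 212, clinical_threshold = 205)
#> <screening_result> limit 212, TsB threshold 205 umol/L
#>   tp=11 fp=15 tn=25 fn=0
#>   sensitivity 100%  specificity 62.5%

# one simulated cohort through the full image pipeline
cfg <- pipeline_config(seed = 1)
res <- run_cohort_correlation(cfg)
res$correlations
#>   channel         r      p_value  n
#> 1     red 0.2047823 1.494407e-01 51
#> 2   green 0.4652360 5.819304e-04 51
#> 3    blue 0.5357048 5.100109e-05 51
```

A single simulated cohort of 51 newborns shows significant green and blue
channel correlations (here r = 0.47 and 0.54, both p < 0.001) and a weak,
non-significant red one (r = 0.20, p = 0.15) — the qualitative pattern the
screening analysis rests on; any one cohort scatters around the calibration
targets (0.59/0.46/0.21), which the 200-replicate acceptance run recovers. `threshold_scan()` then identifies the largest discrimination limit
retaining 100% sensitivity, and `screen_study()` writes the complete report
set for a cohort directory.

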