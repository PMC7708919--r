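# pawtherm

Infrared-thermography (IRT) scoring of arthritis activity in mouse models.

Inflamed joints are warmer than healthy ones. In preclinical rheumatoid-
arthritis studies — most commonly the collagen-induced arthritis (CIA)
model — that temperature rise can be read out contactlessly with a small
radiometric infrared camera, replacing or complementing the two invasive
gold standards (caliper paw-thickness measurement and subjective clinical
scoring). `pawtherm` is for researchers running such studies: it turns
thermograms into quantitative disease scores and carries those scores
through severity classification, cohort selection and longitudinal
treatment-efficacy statistics.

## The score at the core

Seven elliptical regions of interest (ROIs) are placed on each frame:
four over the wrist/ankle joints of the paws and three on the upper back.
With `T_p` the mean ROI temperature of paw `p` and `T_back` the mean of
the three back ROI means, the per-paw **temperature index** and its
four-paw total are

    TI_p      = T_p / T_back            (p in {FL, FR, HL, HR})
    TI_total  = TI_FL + TI_FR + TI_HL + TI_HR

Healthy paws sit near TI 0.83–0.85; a fully inflamed joint approaches the
back temperature (TI → 1), so TI_total runs from ≈3.3 to a nominal maximum
of 4. Severity bins (absent / mild / moderate / severe at TI 0.85, 0.90,
0.95, with analogous thickness and clinical-score bins) and the
trial-inclusion rule (all four joints at TI ≥ 0.9) are built in. Around
the score, the package provides:

* emissivity / reflected-temperature correction (band-integrated
  fourth-power radiance model; skin ε 0.98, fur ε 0.94) and blackbody
  calibration QC with an OLS fit and accuracy verdict;
* elliptical-ROI masks and pixel statistics with fixed, documented
  discretization conventions;
* a synthetic-data generator (phantom thermograms and full longitudinal
  CIA/control cohorts with a shared latent-severity measurement model) so
  the whole chain is testable without animal data;
* trapezoid-AUC treatment-efficacy analysis with normality-gated
  two-group tests (Shapiro–Wilk → Student t or Mann–Whitney) and
  Pearson/Kendall correlation.

See the vignette (`vignettes/thermal-scoring.Rmd`) for the models,
conventions and design decisions.

## Worked example

```r
library(pawtherm)

cohort <- generate_cohort(cohort_config(seed = 2))   # 14 CIA + 4 control mice
scores <- score_cohort(cohort)

s <- interval_summary(scores, "ti_total")
s[s$day %in% c(0, 28), ]
#>      group day  mean      sd   min   max  n
#> 1      CIA   0 3.373 0.03952 3.319 3.444 14
#> 9      CIA  28 3.693 0.13539 3.357 3.798 14
#> 2  control   0 3.289 0.01220 3.277 3.303  4
#> 10 control  28 3.293 0.01790 3.278 3.318  4
```

The CIA group starts at the healthy baseline (TI_total ≈ 3.37 vs 3.29 in
controls) and flares to ≈3.69 at day 28 while controls stay flat.
Classification and cohort selection at the flare:

```r
hm <- severity_heatmap(scores, day = 28, modality = "TI", group = "CIA")
hm$n_moderate_severe
#> 12          # of 14 mice: all four joints at TI >= 0.9
sum(scores$included[scores$day == 28 & scores$group == "CIA"])
#> 12          # the same 12 animals pass the trial-inclusion rule
```

The two non-responders are excluded exactly as an experimenter would
exclude them. Agreement with the conventional endpoint:

```r
cia28 <- subset(scores, day == 28 & group == "CIA")
median(cia28$total_clinical)                      # 10 (of max 16)
correlate(cia28$ti_total, cia28$total_thickness)
#> Pearson r = 0.610 (p = 0.0204)
```

Camera QC against a simulated blackbody series (35–40 °C, triplicates,
0.1 °C sensor noise):

```r
fit <- fit_calibration(generate_calibration_series(35:40, reps = 3,
                                                   noise_sd = 0.1, seed = 2))
fit
#> Calibration fit (6 reference points)
#>   slope 0.9921  intercept 0.3090 degC
#>   R-squared 0.9994  max |deviation| 0.082 degC
accuracy_check(fit, tolerance = 0.2)$message
#> "max |deviation| 0.082 degC <= tolerance 0.200 degC: PASS"
```

A thin CLI over the same functions lives in `inst/scripts/pawtherm.R`
(subcommands `simulate`, `calibrate`, `score`, `classify`, `analyze`,
`report`).

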