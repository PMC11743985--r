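# painattn

Pain is salient: it pulls attention, and it interferes with attention-demanding
tasks. Two behavioral phenotypes summarise how an individual resolves this
competition, and both have been linked to resting-state brain activity within
the **dynamic pain connectome (DPC)** — a 16-node system spanning the ascending
nociceptive pathway, the descending antinociceptive pathway, the salience
network, and the default mode network.

`painattn` is an R package for analysts working with such data
(MEG/EEG source-space ROI time series plus behavioral task records). It
implements the full analysis pipeline:

1. **Behavioral phenotyping**
   - The *intrinsic attention to pain* (IAP) score from a 20-trial
     experience-sampling task with four thought-probe responses:

     ```
     IAP = (2·n_onlypain + n_mostlypain − 2·n_onlyelse − n_mostlyelse) / n_total
     ```

     ranging from −2 (consistently mind-wanders away from pain) to +2
     (consistently attends to pain); negative scores define the low-IAP
     group, positive scores the high-IAP group.
   - The *A/P type* from a numeric-interference (NI) task performed with and
     without concurrent painful stimulation: after dropping the two practice
     blocks and trials with RT < 200 ms or > 2500 ms,
     `ΔRT_mean = RT_mean(pain) − RT_mean(no-pain)`; ΔRT < 0 is A type
     (attention to task dominates), ΔRT > 0 is P type (pain dominates).

2. **Spectral metrics per ROI** — z-score normalization, Welch power spectral
   density (1000-sample Hamming windows, 50 % overlap, 10000-point FFT ⇒
   0.1 Hz grid at fs = 1000 Hz), then total alpha power (AUC 8–13 Hz,
   left-point Riemann sum), total theta power (AUC 4–8 Hz), and the peak
   alpha frequency (PAF) speed and power (in-band argmax).

3. **Group statistics** — per-ROI two-sided Mann–Whitney U tests between
   phenotype subgroups with Benjamini–Hochberg FDR correction across the
   16-ROI family (per metric, per contrast), pooled-SD Cohen's d effect
   sizes, Spearman brain–behavior correlations, and pooled-variance t tests
   for behavioral summary contrasts.

4. **Synthetic cohort generator** — since such MEG datasets are typically
   not public, a first-class simulator produces behavioral tables and ROI
   series with known ground truth: a `1/f^χ` aperiodic background plus a
   Gaussian alpha bump and a flat theta-band elevation, synthesized by
   shaping the amplitude spectrum and randomizing phases; the between-group
   theta contrast is calibrated to a target Cohen's d (default 0.93 in the
   default-mode nodes PCC and precuneus).

## Worked example

```r
library(painattn)

cfg    <- cohort_config(duration_s = 60, seed = 2026)  # 26 low / 24 high IAP
cohort <- simulate_cohort(cfg)

phen <- phenotype_table(cohort$experience, cohort$ni_trials)
head(phen[, c("subject_id", "iap_score", "iap_group", "delta_rt_mean", "ap_type")], 4)
#>   subject_id iap_score iap_group delta_rt_mean ap_type
#> 1    sub-001     -1.05       low        -54.76       A
#> 2    sub-002     -1.20       low        -52.20       A
#> 3    sub-003     -1.50       low        -89.01       A
#> 4    sub-004     -1.05       low        -25.02       A

metrics <- compute_cohort_metrics(cohort)
cmp <- run_group_comparison(metrics, phen, contrast = "iap",
                            metric = "total_theta_power")
subset(cmp, roi %in% c("PCC", "mPFC", "precuneus"))
#>          roi      network u_statistic p_uncorrected    p_fdr cohen_d significant
#>          PCC default_mode         388      1.43e-01 5.80e-01   0.528       FALSE
#>         mPFC default_mode         326      7.93e-01 8.23e-01   0.122       FALSE
#>    precuneus default_mode         566      8.54e-07 1.37e-05   1.775        TRUE
```

The IAP scores and ΔRT values are per-subject phenotypes; `cmp` holds one row
per ROI with the U statistic, the raw and BH-adjusted p value across the
16-ROI family, and the effect-size magnitude. In this cohort the theta
elevation was simulated in PCC and precuneus with a generative d of 0.93:
the precuneus contrast survives FDR while the PCC draw happens to land at an
observed d of 0.53 and does not — single-cohort effect estimates scatter
widely around the generative effect at n = 50, which is exactly what the
simulator is for.

A whole run (simulate → phenotype → spectra → compare, with a deterministic
manifest) is:

```r
cfg <- run_config(out_dir = "out", cohort = cohort_config(seed = 1))
run_all(cfg)
```

or from a shell, `Rscript inst/cli/painattn.R run-all --config run.yaml
--out out --seed 1` (subcommands `simulate`, `phenotype`, `spectra`,
`compare`, `run-all` run single stages from on-disk tables).

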