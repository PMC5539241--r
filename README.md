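# ceusvv

Quantification of adventitial **vasa vasorum** (VV) from contrast-enhanced
ultrasound (CEUS), for imaging scientists validating perfusion-based
markers of early atherosclerosis.

The VV is the microvessel network in the adventitia of large arteries;
its proliferation marks — and partly precedes — atherosclerotic disease.
After intravenous microbubble contrast, video intensity rises wherever
perfused vessels exist, so the enhancement of an adventitial region of
interest tracks VV density. This package implements the full
quantification chain and a synthetic data generator that makes every
stage verifiable by parameter recovery.

## The statistic

For an ROI's time–intensity curve (TIC) $I(t)$, the **maximal
video-intensity enhancement** is

$$\mathrm{MVE} = \max_t I(t) - I_{bg},$$

with $I_{bg}$ the mean intensity over the pre-destruction (background)
frames. The headline quantity is the **normalized MVE**

$$\mathrm{nMVE} = \frac{\mathrm{MVE}_{\text{adventitia}}}{\mathrm{MVE}_{\text{lumen}}},$$

using a luminal reference ROI proximal to the lesion, which cancels gain
and dose effects. Groups with graded disease are compared by one-way
ANOVA and Dunnett's T3 (Welch statistics referred to the studentized
maximum modulus distribution, computed here by quadrature with a
Monte-Carlo oracle), and nMVE is correlated with CD31/VEGF
microvessel counts via Pearson's r. Two-sample t tests accept either raw
samples or published (n, mean, SD) summaries.

The synthetic generator renders long-axis vessel-phantom cine loops with
mono-exponential destruction–replenishment kinetics
$I(t) = I_0 + A(1 - e^{-\beta(t - t_0)})$, a latent per-group VV density
driving adventitial amplitude and Poisson two-observer histology counts,
and additive clipped Gaussian noise. See the vignette
(`vignettes/ceus-vasa-vasorum.Rmd`) for the model, calibration and
limitations.

## Worked example

```r
library(ceusvv)
cfg <- cohort_config(groups = default_group_specs(10), seed = 1)
sim <- simulate_cohort(cfg)                    # 60 animals, 6 groups
report <- group_comparison_report(sim$cohort, control_group = 0)
print(report)
```

```
Cohort comparison report

Per-group summaries:
 group_id  n nmve_n nmve_mean nmve_sd cd31_mean cd31_sd vegf_mean vegf_sd
        0 10     10    0.1619 0.06333      1.40  0.6992      1.05  0.4972
        1 10     10    0.3032 0.10469      4.05  0.5986      1.85  0.7835
        2 10     10    0.5360 0.43738      6.65  1.4347      3.40  1.4491
        3 10     10    0.6486 0.20544      9.40  2.6854      5.20  1.7353
        4 10     10    0.6568 0.15455     10.50  2.5820      5.85  1.7488
        5 10      0        NA      NA     15.55  2.5216      9.45  1.5537

Omnibus one_way_anova: statistic 8.87995, df  4, 45, p = 2.254e-05

Dunnett T3 (control vs group rows):
 group_i group_j mean_diff statistic     df   p_welch p_adjusted vs_control
       0       1   -0.1413     3.653 14.809 2.400e-03  2.195e-02       TRUE
       0       2   -0.3741     2.677  9.377 2.447e-02  1.784e-01       TRUE
       0       3   -0.4867     7.159 10.695 2.149e-05  2.010e-04       TRUE
       0       4   -0.4949     9.370 11.940 7.493e-07  7.211e-06       TRUE

Normalized MVE vs microvessel counts:
 marker     r  n t_statistic   p_value ci_lower ci_upper
   vegf 0.455 50       3.540 0.0009019   0.2022   0.6509
   cd31 0.519 50       4.207 0.0001127   0.2813   0.6967
```

Reading it: estimated group means of normalized MVE rise from ≈0.16
(controls) to ≈0.66 (advanced disease), tracking the configured latent
densities (0.146 … 0.660); the omnibus ANOVA rejects equality; the T3
contrasts separate later groups from the control after family adjustment;
and normalized MVE correlates positively with both microvessel counts.
Group 5 (near-occlusive plaque) is histology-only by design — it carries
counts but no normalized MVE.

A thin command-line front end over the same functions is at
`inst/cli/ceusvv.R` (subcommands `simulate`, `extract`, `quantify`,
`stats`, `run`, `fixtures`).

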