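---
title: "Quantifying adventitial vasa vasorum from contrast-enhanced ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adventitial vasa vasorum from contrast-enhanced ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceusvv)
```

## The measurement problem

The vasa vasorum (VV) is the microvessel network in the adventitia — the
outer layer — of large arteries. Its proliferation accompanies, and in part
precedes, atherosclerosis, which makes VV density an attractive imaging
marker of early disease. Contrast-enhanced ultrasound (CEUS) can read it
out non-invasively: intravenous microbubbles act as red-cell tracers, so
video intensity rises wherever perfused vessels exist, including the
adventitia of a diseased carotid.

The quantification chain this package implements is:

1. draw polygonal regions of interest (ROIs) on a cine loop — one in the
   adventitia, one in the lumen proximal to the lesion;
2. average video intensity over each ROI per frame, giving a
   time–intensity curve (TIC);
3. reduce each TIC to its **maximal video-intensity enhancement (MVE)** —
   the curve's peak minus the background intensity measured before
   enhancement;
4. form the **normalized MVE**, the adventitial MVE divided by the luminal
   MVE. The luminal reference cancels gain, attenuation and injection-dose
   effects, leaving a dimensionless proxy for adventitial VV density;
5. compare groups of animals with graded atherosclerosis, and correlate
   normalized MVE with CD31- and VEGF-positive microvessel counts from
   immunohistochemistry.

Because no imaging data accompany this design, the package ships a
first-class synthetic generator so that every stage is testable by
parameter recovery against known ground truth.

## The kinetic model

After a high-energy destruction pulse clears microbubbles from the imaging
plane, intensity in a perfused compartment recovers towards a plateau. We
use the standard mono-exponential destruction–replenishment model

$$I(t) = I_0 + A\,\bigl(1 - e^{-\beta (t - t_0)}\bigr)_+,$$

with baseline $I_0$, plateau enhancement $A$ (video-intensity units on the
8-bit 0–255 scale), replenishment rate $\beta$ (s$^{-1}$) and
destruction-pulse time $t_0$. This choice is a modeling decision: TIC
acquisition protocols vary between post-destruction replenishment and
bolus wash-in, and the functional form of real curves is rarely reported.
The mono-exponential form is the field's standard replenishment kinetics
and makes the peak analytically checkable: for an acquisition lasting
$T$ seconds past onset, the TIC maximum is $I_0 + A(1-e^{-\beta T})$, so
MVE estimates $A$ with relative error $e^{-\beta T}$ — below $10^{-6}$
once $T \ge 20/\beta$, the duration used in the exactness tests.
`onset_time` is exposed so either a replenishment or a wash-in reading can
be emulated; the package makes no claim about which applies to any given
acquisition.

Two practical consequences:

- the normalized MVE of a noiseless acquisition equals the ratio of the
  two compartments' amplitudes, exactly when the rates match (the
  saturation factors cancel) and to $O(e^{-\beta T})$ otherwise;
- MVE is invariant under a global affine gain applied to both TICs when
  backgrounds are recomputed, which the tests assert to $10^{-9}$.

## The phantom and its noise

The synthetic cine loop idealizes a 2D long-axis carotid view as
horizontal bands: an echolucent lumen flanked by two adventitial bands,
an optional plaque polygon protruding into the lumen (groups 4 and 5),
and surrounding tissue at a constant grayscale level (default 20). Default
frame geometry is 48×64 pixels at 5 frames/s for 22 s with the destruction
pulse at $t_0 = 2$ s, so ten pre-destruction frames define the background
window.

Noise is additive Gaussian per pixel and frame (default SD 4 intensity
units), clipped to $[0, 255]$. Multiplicative speckle is deliberately out
of scope: the statistic under test averages hundreds of pixels per ROI,
so only the mean and variance of the noise reach the TIC, and an ROI mean
of iid noise is Gaussian with SD $\sigma/\sqrt{n_{px}}$ either way. This
equivalence is also why `cache_tics = TRUE` may skip pixel rendering and
draw TIC-level noise directly; the two routes are asserted to estimate
the same quantity. Clipping can bias compartments whose plateau approaches
255; with the default calibration this affects less than 0.1% of animals
in the densest imaged group and is ignored.

Pixel membership of an ROI uses the even–odd rule at pixel centers: the
pixel at 0-based (row $i$, col $j$) covers $[j, j+1)\times[i, i+1)$ and is
tested at $(j+0.5,\, i+0.5)$, with the half-open edge convention resolving
on-edge points deterministically. The test suite checks this against a
brute-force scalar enumeration and under whole-pixel translations.

## The cohort generator

Six groups mirror a graded-atherosclerosis rabbit design: controls
(group 0), high-fat diet of increasing duration (1–3), accelerated
diet-plus-injury with small plaque (4), and a near-occlusive plaque group
(5). A latent VV density $d_g$ drives everything:

- **Enhancement.** The adventitial amplitude of animal $i$ in group $g$ is
  $A_i = \gamma\, d_g\, L_i$ with gain $\gamma$ equal to the luminal
  amplitude (120) by default, so the expected amplitude ratio — hence the
  expected normalized MVE — equals $d_g$. $L_i$ is a lognormal biological
  multiplier with $E[L] = 1$ (meanlog $= -s^2/2$, log-SD $s = 0.35$ by
  default, a ~36% biological CV). The default densities
  $(0.146, 0.278, 0.435, 0.660, 0.660, 1.2)$ place the first five group
  means at the published working values for graded carotid disease; they
  are non-decreasing by construction.
- **Histology.** Each of two independent observers counts
  $\mathrm{Poisson}(a + b\,d_g)$ marker-positive microvessels per
  cross-section; the analysis value is their mean. Defaults solve the
  linkage through two observable points (control counts at $d = 0.146$;
  pooled early-atherosclerosis counts at $d \approx 0.458$): VEGF
  $a = 0.232$, $b = 7.315$; CD31 $a = 0$ (the two-point solve is slightly
  negative and intercepts must be non-negative), $b = 13.57$.
- **Group 5** is simulated and counted but flagged histology-only: no
  normalized MVE is computed for it, and the cohort-table validator
  rejects any group-5 row that carries one.

Attrition is not simulated; group size is a configuration knob. A single
integer seed makes the whole cohort bit-reproducible; stage-level child
seeds are derived by hashing the stage label into the global seed
(`child_seed()`), so stages can be re-run in isolation.

### What the generator does not emulate

No point-spread function, attenuation, nonlinear bubble oscillation,
speckle texture, motion, or 3D geometry. Passing recovery tests therefore
demonstrates that the *quantification chain* is correct and calibrated —
not that the chain is robust to acquisition physics it never sees. On real
loops, ROI placement, motion and speckle will add variance that these
tests cannot bound.

## The statistical layer

All statistics are computed from their defining formulas and
cross-checked in the tests against base R and brute-force evaluation:

- `t_test()` — Student (pooled) or Welch, raw samples or published
  (n, mean, SD) summaries; both input routes share one code path and are
  bit-consistent.
- `one_way_anova()` — classical fixed-effects F test.
- `friedman_test()` — within-block midranks with the general tie-corrected
  chi-square. ("Friedman one-way ANOVA" is a contradiction in terms for
  independent groups, so the package offers both tests under separate
  names and the cohort report uses classical ANOVA; nothing is silently
  substituted.)
- `dunnett_t3()` — all-pairs T3 for unequal variances: Welch statistic per
  pair, adjusted p from the studentized maximum modulus (SMM) with
  $m = k(k-1)/2$ parameters. The SMM CDF
  $P(M \le q) = \int_0^\infty (2\Phi(qu) - 1)^m f_U(u;\nu)\,du$
  (with $U = \chi_\nu/\sqrt{\nu}$) is evaluated by adaptive quadrature;
  a seeded Monte-Carlo sampler (`rsmm()`, fallback seed 20170801) is the
  independent oracle, and agreement within 0.005 is asserted at $10^6$
  draws. For $m = 1$ the SMM reduces exactly to two-sided $|t_\nu|$, a
  reduction the tests assert to $10^{-6}$.
- `pearson_correlation()` — product–moment r, t-based p, Fisher-z 95% CI.

Degenerate-input conventions: zero pooled variance with equal means gives
$t = 0, p = 1$; with unequal means, the $p = 0$ limit plus a degenerate
flag; constant Friedman blocks give statistic 0, $p = 1$; negative MVE is
reported with a warning, never clamped; TIC peak ties resolve to the
earliest frame.

### Null calibration

The suite re-derives type-I error under exchangeable normal nulls at
10,000 replicates: two-sample t at $n = 8$, five-group ANOVA at $n = 8$,
and Friedman at 20 blocks × 4 treatments. The Friedman dimensions were
chosen so the chi-square reference is adequate: at small block counts the
rank statistic is discrete and the asymptotic test runs conservative — a
property of the test itself, not an implementation defect — so the
calibration check uses a block count large enough for the nominal level
to be meaningful.

## Calibrating the enhancement–count correlation

For coverage tests one needs the *true* correlation between the pipeline's
normalized MVE and a count. Under the generative model it has a closed
form. With $D$ the latent density across the cohort (discrete over group
values, equal weights), $R = DL$ the true ratio, and $N$ the mean of
$n_{obs}$ Poisson($a + bD$) counts:

$$\mathrm{cov}(R, N) = b\,\mathrm{Var}(D), \qquad
  \mathrm{Var}(R) = E[D^2]e^{s^2} - E[D]^2, \qquad
  \mathrm{Var}(N) = b^2 \mathrm{Var}(D) + \frac{a + b E[D]}{n_{obs}}.$$

`model_mve_count_correlation()` implements this (validated against a
200,000-draw simulation), and `calibrate_count_linkage()` solves for the
slope $b$ achieving a target correlation — the correlation is increasing
in $b$ with supremum $\sqrt{\mathrm{Var}(D)/\mathrm{Var}(DL)}$, so targets
above that biological-scatter bound are rejected rather than silently
approximated. The coverage test sets the truth to 0.60, runs 100 seeded
cohorts of 50 animals per imaged group, and requires the Fisher-z 95% CI
to cover the truth at least 93 times. Estimation noise from the imaging
chain slightly attenuates the realized correlation relative to this truth;
at the default noise level the attenuation is well inside the CI width at
$n = 250$.

## Worked example

```{r example, eval = FALSE}
cfg <- cohort_config(groups = default_group_specs(10), seed = 1)
sim <- simulate_cohort(cfg)
report <- group_comparison_report(sim$cohort, control_group = 0)
print(report)
```

The report prints per-group mean ± SD of normalized MVE and counts, the
omnibus ANOVA, the T3 control contrasts and both correlations. With the
default calibration the group means rise from ≈0.15 (controls) to ≈0.66
(advanced disease), later groups separate from the control after SMM
adjustment, and both correlations are positive.

## Numerical and design choices

- **Problem sizes.** Recovery runs use 50 animals per imaged group
  (rendered pixels) and 100 replicates for coverage (cached TICs); the
  oracle-equivalence sweeps use 100 random loops up to 32×32×50 and 1,000
  random small samples. These sizes make standard errors small relative
  to the asserted tolerances while keeping the whole suite fast.
- **Background window.** "Background video-intensity" is taken as the mean
  over frames strictly before the destruction pulse; when no pulse time is
  recorded, frames before first enhancement onset (10% of dynamic range
  above the minimum) are used. Both are overridable by an explicit window.
- **Normalization variant.** The ratio divides background-subtracted MVEs
  by default — raw maxima would re-introduce the tissue baseline the
  statistic exists to cancel — but `variant = "raw_max"` is available for
  sensitivity analysis, and results record which was used.
- **Smoothing** defaults to off (window 1); when applied, the moving
  average truncates at the edges and the TIC carries its smoothing
  descriptor so peak statistics stay auditable.
- **Output stability.** All tabular outputs use fixed column order and 9
  significant digits; identical config + seed reproduce byte-identical
  CSV/JSON, which the pipeline tests assert.

## Known limitations

- The latent density enters enhancement and histology through the same
  scalar; real VV beds are spatially heterogeneous and 2D long-axis
  imaging undersamples them, so real imaging–histology correlations run
  lower than the model's ceiling.
- A single lognormal multiplier cannot reproduce heterogeneous per-group
  CVs (published group SDs imply CVs from ~20% to ~95%); the geometric SD
  is exposed per configuration instead.
- The occlusive-plaque group's loop is rendered for completeness, but its
  enhancement is unvalidated by construction — it exists to exercise the
  histology-only bookkeeping path.
- p-values from the SMM quadrature inherit `stats::integrate` tolerances
  (~$10^{-10}$); the Monte-Carlo fallback is only accurate to
  $O(n^{-1/2})$ and is used when quadrature fails to converge.
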