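---
title: "Methods: models, assumptions and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, assumptions and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoscreen)
```

This vignette documents the statistical models implemented by
chronoscreen, the assumptions each makes, the default parameters and
why they were chosen, what the synthetic-data generators emulate (and
deliberately do not), and the numerical conventions pinned by the test
suite. No empirical result is claimed here beyond what the tests and
the acceptance script actually compute on synthetic data.

## 1. Rhythm screening (JTK)

### Model

A feature is tested for 24-h rhythmicity by rank concordance with a
cosine reference. For observations $x_i$ at zeitgeber times $t_i$ and
reference $r_i = \cos(2\pi (t_i - \phi)/24)$, the statistic is
Kendall's $S = \sum_{i<j} \operatorname{sgn}(x_j - x_i)
\operatorname{sgn}(r_j - r_i)$. Being rank-based, the test is invariant
to any monotone transformation of the data and makes no distributional
assumption; its null is the uniform distribution over orderings.

### Exact null

Under the null, $S$ over all orderings of distinct values against a
tied reference decomposes as $S = 2J - M$, where $J$ is a sum of
independent Mann–Whitney inversion counts between consecutive
reference tie-groups and $M$ is the number of reference-untied pairs.
Each count's probability generating function is a Gaussian binomial,
computed exactly by polynomial multiplication followed by exact long
division; the convolution of the group pmfs gives the full null in
milliseconds for the design sizes used here (30 observations, tie
pattern 5/10/10/5). The implementation is verified against
full-permutation enumeration (all 720 orderings of 6 values) in the
test suite.

Tied *data* values break the distinct-values assumption, so tied
features fall back to a seeded Monte-Carlo permutation null
(`n_perm = 1e5` by default); constant features receive $p = 1$.

### Lag scan and multiplicity

The reference phase $\phi$ is scanned over the sampling grid (six lags
for the default 4-h grid) and the minimum one-sided $p$ is taken.
Because lags half a period apart produce sign-flipped references, the
six one-sided tests are exactly three two-sided tests, so the minimum
is anti-conservative by a factor approaching the number of lags. The
reported per-feature `p_value` is therefore the Bonferroni bound
$\min(1, n_{\text{lags}} \cdot p_{\min})$ (the raw minimum is kept as
`p_lag_min`). This correction is load-bearing: without it, the BH
step-up at $q < 0.2$ cascades on pure-noise matrices (measured ~30% of
null features called), destroying FDR control; with it, measured
empirical FDR on the simulation suite is below the nominal bound while
sensitivity on amplitude-0.5 cyclers remains 1.0.

### FDR and defaults

$q$-values are Benjamini–Hochberg (`stats::p.adjust`, verified against
the direct step-up formula) across the features of one group, and the
significant set is $q < 0.2$ (strict), the conventional threshold for
metabolite screens; lipid-style screens pass `q_threshold = 0.05`. The
period is fixed at 24 h: with six timepoints over one cycle, shorter
periods are unidentifiable.

## 2. OPLS time-of-day modeling

### Model

Single-response OPLS (Trygg–Wold): predictive weight
$w \propto X^\top y$, orthogonal components
$w_o \propto p - (w^\top p) w$ with deflation
$X \leftarrow X - t_o p_o^\top$, final predictive component on the
deflated matrix. Predictive scores are orthogonal to all orthogonal
scores by construction (pinned at $10^{-8}$), and with zero orthogonal
components the model is exactly one-component PLS1 (verified against
`mixOmics::pls` to $4\times10^{-16}$). $X$ is unit-variance scaled and
mean-centered (sample SD); the response defaults to the numeric ZT
hour, with an optional circular $(\sin, \cos)$ encoding since ZT is
periodic — in that mode PRESS and SS are pooled across the two
response columns before the F-test.

### Cross-validation and significance

7-fold cross-validation with deterministic venetian-blind assignment
(every 7th sample in group/ZT/replicate order), chosen over random
folds so results are exactly reproducible and every fold spans the
full time course. Scaling is re-estimated inside each training fold;
nothing is learned from held-out samples.
$Q^2_{cum} = 1 - \prod_a \mathrm{PRESS}_a/\mathrm{SS}$ over component
counts $a = 0..n_{\text{ortho}}$, the product convention of the
chemometrics literature. Orthogonal components are accepted while they
improve $Q^2_{cum}$ by more than `q2_tol = 0.01`, capped at
`max_ortho = 3` (beyond which, at $n \le 30$, components chase noise).

CV-ANOVA: $F = \frac{(\mathrm{SS}_y - \mathrm{PRESS})/d_1}
{\mathrm{PRESS}/d_2}$ with $d_1 = 1 + n_{\text{ortho}}$ and
$d_2 = n - 1 - d_1$. Degrees-of-freedom conventions differ across
software; this one is pinned here and verified against direct numeric
integration of the F density. $\mathrm{PRESS} \ge \mathrm{SS}_y$ maps
to $F = 0$, $p = 1$ (no model). A model is "significant" at
$p < 0.05$.

PCA (`fit_pca`, a `prcomp` wrapper) is provided as the standard
outlier/quality look before modeling.

## 3. Behavioral analysis

### DAM2 parsing

`read_dam` parses the 42-field tab-separated monitor dialect (index,
date, time, status, six reserved fields, 32 channel counts); any line
with a different field count or non-integer count is a hard error
naming the line. Non-OK status rows are kept but flagged; gaps in the
minute sequence are reported as an attribute rather than silently
interpolated.

### Artifact filter

Monitor spikes are minutes whose counts are at least 6 SD above the
mean of the *pooled non-zero* counts across all flies of the
experiment. Pooling non-zero counts makes the baseline a property of
real activity rather than of sleep amount; six SD keeps the false-call
rate effectively zero on clean Poisson-like data (measured 0 on the
simulation suite) while catching all injected spikes (recall 1.0).
Each artifact is replaced by the mean of the nearest non-outlier
neighbor on each side (single neighbor at edges); replacements stay
real-valued.

### Sleep scoring

The field-standard 5-minute rule: every maximal run of $\ge 5$
zero-count minutes is sleep in its entirety. `summarize_sleep`
produces per fly-day totals, day/night splits (day = 12 h from
lights-on; under DD the prior entrainment's lights-on is carried
forward as subjective day), bout counts and mean bout length (bouts
attributed to their start day), total activity, and waking activity
(counts per awake minute, `NA` for an all-sleep day). Flies with zero
counts over the final 24 h of the window are presumed dead and
excluded, listed in an attribute.

### Rhythm power

The minute series is mean-subtracted and the discrete-Fourier power at
the bin nearest 24 h is normalized by the total positive-frequency
power, so the value is the fraction of variance at the circadian
frequency; a record is rhythmic at $\ge 0.01$. The peak within the
18–30 h band is also reported. A noiseless 24-h sinusoid gives
normalized power 1 at exactly 24 h; a 12-h sinusoid leaves nothing in
the band.

### Group comparisons

`compare_groups` gates each group with Shapiro–Wilk at $\alpha = 0.05$
(zero-variance groups fail the gate with a warning): all-normal
$\to$ t-test / ANOVA + Tukey; otherwise Mann–Whitney / Kruskal–Wallis
+ Dunn (implemented directly — z from pooled ranks with tie
correction, Bonferroni-adjusted — since no installed package provides
it). The `timepoints` design compares all timepoint pairs with
Bonferroni. With two control genotypes supplied, a phenotype is called
only when the experimental group differs from **both** controls
(adjusted $p < 0.05$ each) — the standard guard against genetic
background effects.

## 4. Imaging quantification

Per-cell calcium-reporter signal:
$(\mathrm{GFP}/\mathrm{bg}_G)/(\mathrm{RFP}/\mathrm{bg}_R)$, i.e.
background-corrected GFP normalized to the constitutive RFP.
`calexa_brain_summary` averages within (brain, cell class); the l-LNv
and s-LNv classes are never pooled because their calcium rhythms
differ in phase and magnitude.

Redox stacks: per-slice Otsu threshold on the 488-nm channel
(`EBImage::otsu` on the 0–1 rescaled slice, 256 levels) combined with
an upper cap (default 250 of 255) that excludes saturating structures
such as trachea. The brain's raw ratio is the mean 405-nm intensity
over the mask divided by the mean 488-nm intensity over the same mask
— means are taken before the quotient (a ratio of means, not a mean of
per-pixel ratios, which would be noise-amplifying at dim pixels). Raw
ratios are normalized per imaging run by the pooled mean of that run's
control brains, so runs are never mixed and the normalized control
mean is exactly 1.

## 5. Synthetic-data generators

All four generators are seeded, deterministic, restore the caller's
RNG state, and return ground truth alongside the data. Defaults are
the study conditions, not tuned values.

**Omics** (`simulate_omics`): 159 features, ZT {0,4,8,12,16,20},
5 young / 4 old replicates; 17 rhythmic features per group with 4
shared; value $= b_f\,(1 + a\cos(2\pi(t-\phi_f)/24))\,\varepsilon$ with
baselines $b_f = 1000\,e^{N(0,0.5)}$ (right-skewed, peak-height-like),
relative amplitude 0.5 (young) / 0.25 (old), mean-1 lognormal noise
with CV 0.1 (young) / 0.3 (old) — aging damps amplitude and inflates
variance. Phases rotate through the sampling grid. *Not emulated*:
missing values, batch effects, correlated features, heteroscedastic
detector noise, annotation ambiguity.

**Activity** (`simulate_activity`): per minute, a fly is active with
probability 0.5 (day) or 1/20 (night; geometric zero-runs with mean
20 min, matching the sleep-bout scale), and an active minute registers
$1 + \mathrm{Pois}(1)$ crossings. Spikes of $30\times$ the count rate
are injected at isolated known minutes. *Not emulated*: circadian
waveform shape (morning/evening peaks), inter-fly variability,
position effects, gradual death.

**Imaging** (`simulate_roi_table`, `simulate_rogfp_stack`): ROI tables
with multiplicative lognormal noise around configured per-condition
ratios; stacks with disk-shaped foreground at a 10% target fraction,
bright 488 foreground (180 of 255) and 405 set to the configured redox
ratio times the noiseless 488 level. The redox ratios are kept below 1
so the 405 channel cannot clip at 8 bits. *Not emulated*: optical
blur, z-attenuation, bleed-through, photobleaching.

## 6. Numerical conventions and open decisions

- **Two SD conventions on purpose**: heatmap-style display scaling
  (`zscale_features`) uses the population SD (divide by root mean
  squared deviation), while OPLS feature scaling uses the sample SD —
  each matching the convention of its downstream consumer.
- Cosine references are rounded to 9 decimal digits so grid symmetries
  (e.g. ZT4/ZT20 about a ZT0 peak) tie exactly rather than by
  floating-point accident.
- Exact-null cache: one Harding distribution per reference tie
  pattern, shared across lags and features.
- The lag-scan Bonferroni correction (Section 1) is a deliberate
  deviation from reporting the raw min-p: the uncorrected screen
  violates its own FDR contract. Both values are reported.
- Pipeline outputs format numbers to 9 significant digits
  (`formatC %g`) before writing, so reruns are byte-identical and
  manifests (md5 per file) can assert determinism.
- CV-ANOVA degrees of freedom: $d_1 = 1 + n_{\text{ortho}}$,
  $d_2 = n - 1 - d_1$; circular-response models pool PRESS/SS across
  the sine and cosine columns with
  $d_2 = 2n - 2 - 2 d_1$.
- Problem sizes exercised by the tests and acceptance script: 159
  features × 30 samples (screen and OPLS, 20 seeds per condition),
  16–32 flies × 3–5 days of minute data, 3 × 64 × 64 stacks.

## 7. Limitations

- The exact JTK null assumes exchangeability across all samples;
  replicate autocorrelation would violate it (replicates here are
  independent animals, so the assumption is appropriate).
- With six timepoints the lag grid is coarse: true phases between grid
  points lose power, and period estimation is impossible (24 h is
  assumed, not inferred).
- The Bonferroni lag bound is mildly conservative (antipodal lags are
  fully dependent), trading a little sensitivity for a valid FDR
  contract.
- OPLS significance is asymptotic in the CV-ANOVA F approximation;
  at $n = 30$ the test is conservative rather than exact.
- The FFT rhythmicity threshold (1% of variance at the 24-h bin) is a
  convention, not an estimated operating point; very noisy rhythmic
  records near the threshold will flip between calls.
- The sleep summaries assume complete minute coverage of the analysis
  window; recordings with gaps should be truncated to full days first
  (gaps are surfaced by `read_dam` but not imputed).
- Generators sample independent features/minutes/pixels; none of the
  analyses are validated here against correlated-noise regimes.
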