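---
title: "Methods: simulating and analyzing a cash-transfer infant-EEG trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing a cash-transfer infant-EEG trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegitt)
```

## Overview

`eegitt` implements the analysis pipeline of a multi-site randomized
unconditional cash-transfer trial with infant resting EEG as the endpoint,
together with a synthetic-data generator calibrated to that trial's design.
The pipeline has five stages: cohort simulation, raw-EEG synthesis,
preprocessing (re-reference, filter, epoch, reject), spectral band-power
extraction, and intent-to-treat (ITT) inference with family-wise error
control. Every stage is exercised by the test suite without any external
data.

## The statistical model

For each analyzed outcome $y_i$ (absolute or relative band power of child
$i$), the ITT regression is

$$y_i = \alpha + \beta\,T_i + \sum_s \gamma_s \mathbb{1}[\text{site}_i = s]
        + X_i'\delta + \varepsilon_i,$$

where $T_i$ is the randomized high-cash assignment indicator and $X_i$ the
baseline covariate vector (mother's age, schooling, household income, net
worth, general and mental health, race/ethnicity, marital status, adults in
household, other children, smoking and alcohol during pregnancy, father in
household, child sex, birth weight, gestational age, child age at visit,
and usable epoch count). Because assignment is randomized, $\beta$ is
unbiased for the ITT effect with or without covariates; covariates only
improve precision. Standard errors are heteroskedasticity-consistent (HC1
by default, `HC0`–`HC3` available via `sandwich::vcovHC()`), and the
default p-value uses the normal approximation to the robust $t$ (a
$t$-distribution with residual degrees of freedom is available via
`df_method = "t"`; at $n = 435$ the two are nearly identical). The
standardized effect size divides $\beta$ by the outcome's SD in the
low-cash analytic arm, the trial's convention for expressing effects in
control-group SD units.

Missing covariate cells are mean-imputed using the *analytic* (EEG) sample,
not the full cohort — these differ whenever attrition is
covariate-dependent — and categorical covariates receive an explicit
`"(missing)"` level. Outcomes are never imputed.

### Westfall–Young free stepdown

Absolute and relative power form two four-member outcome families.
`westfall_young()` draws permutations of the treatment labels *within site
strata* — valid under randomization and preserving the site structure that
the fixed effects absorb — holding covariates and outcomes fixed, which
tests the null of no treatment effect conditional on covariates. The
alternative engine choice (residual bootstrap) was considered and rejected:
label permutation requires no model assumptions beyond randomization
itself. For observed statistics $|t_{(1)}| \ge \dots \ge |t_{(m)}|$ and
permuted statistics $|t^{*b}_j|$, the adjusted p-value of the $k$-th
ordered member is the proportion of resamples in which
$\max_{j \ge k} |t^{*b}_{(j)}|$ reaches $|t_{(k)}|$, followed by a
cumulative-maximum pass that enforces monotonicity. Adjusted p-values are
reported as raw resample proportions (`count/B`), so a member can obtain
$p = 0$ at finite $B$; the production default is $B = 10{,}000$ and the
seed is a mandatory argument.

The resampling loop evaluates all members and permutations with a
Frisch–Waugh decomposition: outcomes and treatment are residualized against
the non-treatment design once, after which each permutation's robust $t$ is
a closed-form expression in elementwise products. The identity with the
full-model `sandwich` computation is exact for HC0/HC1 and is asserted in
the tests to $10^{-10}$.

## The synthetic cohort

`generate_cohort()` draws 1,000 dyads: Bernoulli(0.40) assignment,
near-uniform sites, and baseline covariates from
normal/log-normal/categorical families anchored at the trial's published
marginals (e.g., maternal schooling $\mathcal{N}(12, 3.1)$ years, household
income log-normal with mean \$21.5k). The trial publishes only marginals,
so the joint distribution is a package choice: covariates are drawn
mutually independently and independently of assignment. Attrition flags
exactly 251 low-cash and 184 high-cash children as the EEG analytic sample,
drawn at random within arm — the real pandemic-driven attrition mechanism
is explicitly not modeled. Baseline maternal covariates receive missing
cells at `missing_covariate_rate` (default 3%).

Latent absolute band powers are log-normal, moment-matched to the published
low-cash means/SDs (theta 40.268/23.317, alpha 7.441/4.213, beta
1.874/1.592, gamma 0.986/0.947 uV^2); the high-cash arm's target mean is
shifted by `effect_size` $\times$ SD per band (defaults 0.02/0.17/0.26/0.23).
Log-normality keeps powers positive and right-skewed, as band power always
is. Across bands the Gaussian scores share a common factor with loading
$\sqrt{\rho}$, $\rho$ = `band_cor` = 0.5 — band powers within a child are
strongly positively correlated in real EEG, and the trial does not publish
the correlation, so this is a documented package default, not a claim about
the study.

## The synthetic EEG signal

`generate_recording()` synthesizes 19 scalp channels (10–20 labels; the
20th hardware channel is the online reference) at 500 Hz as

* a scalp-wide $1/f$ background with one-sided PSD
  `floor_scale`$/f$ (default 0.02 uV^2/Hz at 1 Hz), and
* per band, a Gaussian process realized by zero-phase brickwall filtering
  of white noise in the frequency domain — flat PSD strictly inside the
  band, zero outside — rescaled so its *realized* variance equals the
  child's latent band power exactly.

Brickwall synthesis replaces time-domain Butterworth shaping because IIR
skirts leak several percent of a large band's power into its neighbors,
which would confound the spectral-recovery oracle with a synthesis
artifact.

Each channel mixes a scalp-wide common realization (variance share
`channel_mix`, default 0.5) with an independent per-channel realization of
the same band power, plus white sensor noise (`channel_noise_sd`, 0.2 uV).
A purely common signal would be annihilated exactly by the T7/T8-average
re-reference; with mixing, re-referencing multiplies every band power by
the same montage factor $\tfrac{3}{2}(1-\text{channel\_mix})$ in
expectation, leaving relative power and standardized effect sizes — the
trial's inferential quantities — unchanged. `floor_scale` and
`channel_noise_sd` are set so the background contributes at most a few
percent of any band's measured power, consistent with the model's premise
that the band processes carry the band power.

`inject_artifacts()` adds blink-like 0.3-s, ~400-uV raised-sine transients
on frontal channels and 0.5-s broadband ~150-uV bursts on all channels at
Poisson rates (defaults 2 and 0.5 per minute), returning a per-sample
ground-truth mask against which rejection sensitivity is scored.

All generators are pure functions of `(config, seed)`: per-subject streams
derive from a stable integer hash of (master seed, id, stream), so any
child's recording can be regenerated in isolation, bit-identically.

## Preprocessing

Defaults: T7/T8-average re-reference (T7/T8 excluded from scalp averages
afterwards), zero-phase band-pass 0.3–50 Hz implemented as a 2nd-order
Butterworth high-pass cascaded with a 4th-order low-pass (the cascade keeps
the very small normalized high-pass corner numerically stable in transfer-
function form; forward–backward filtering applies each magnitude response
twice), then 1-s epochs with 50% overlap rejected when any channel exceeds
±100 uV. Sub-epoch recordings yield an empty epoch set rather than an
error; trailing partial epochs are dropped. Rejection is per-epoch,
all-channels — one bad channel discards the epoch — which is conservative
and keeps the usable-epoch count invariant to channel order. These three
parameters (epoch length, overlap, threshold) are configuration with
documented defaults; they are this package's choices, not the study's
unpublished preprocessing constants.

## Spectral estimation

`bin_spectrum()` computes a Welch-style PSD: per epoch and channel, a
periodic-Hann-windowed FFT periodogram (DC removed per epoch, one-sided
scaling by $2/(f_s \sum w^2)$, Nyquist not doubled), averaged over epochs
and channels, then integrated into 48 one-hertz bins with lower edges
2..49 Hz. Whole-scalp power averages PSDs across channels (power
averaging), so it equals the channel-average oracle exactly and is *not*
the mean of unequal-sized region means. Default band boundaries are
theta [2,6), alpha [6,10), beta [10,20), gamma [20,50) — integers that tile
the 48 bins, with the mid-to-high range starting at 6 Hz; boundaries are
configuration and validated for disjointness and tiling.

Two numerical facts matter for interpretation:

* **Resolution/leakage trade-off.** At 1-s epochs the grid step is 1 Hz
  and the Hann mainlobe smears each spectral step across its neighboring
  bin. Where the spectrum drops steeply (theta→alpha, a ~5× step), a few
  percent of the larger band's power is attributed to the smaller band.
  Band-power estimates are therefore a *fixed, near-identity linear mixing*
  of the latent powers — identical for every child — so arm contrasts and
  standardized effect sizes pass through undistorted even though individual
  absolute levels shift by a few percent. Oracle tests that need sharper
  resolution (the 10.5-Hz sinusoid, isolated-band recovery) use 4-s epochs,
  where the mainlobe fits inside a 1-Hz bin.
* **Standardization.** `standardize_bins()` z-scores each bin with the
  pooled-sample mean/SD, which forces the arm-mean curves to satisfy
  $n_{lo}\bar z_{lo} + n_{hi}\bar z_{hi} = 0$ per bin exactly (the
  mirror-image identity); a zero-SD bin is an error naming the bin.

## Composite index

`build_index()` aggregates absolute alpha/beta/gamma into a single
mid-to-high-frequency outcome. The default `"zmean"` averages the three
powers after z-scoring over the analytic sample (an Anderson/Kling-style
summary index: mean zero, invariant to rescaling any component); `"rawsum"`
sums raw powers in uV^2. The index is analyzed by `fit_itt()` like any
band. No attempt is made to reproduce any particular published composite
coefficient, because the published value is not reconstructible from the
published band summaries; the method is configuration with documented
behavior.

## Problem sizes and test design

The acceptance-level checks use sizes chosen to bound Monte-Carlo error
while staying practical on a single CPU: 200 simulated cohorts at the full
1,000-dyad / 251+184-analytic design for effect-size recovery (Monte-Carlo
SE ≈ 0.008 per band); 1,000 null datasets × 500 permutations for the
family-wise error rate (binomial 95% half-width ≈ 0.013 around 0.05);
60-s single-channel recordings for the spectral oracles; and 15–60 s
EEG synthesis for end-to-end runs. The production recommendation for real
inference remains 10,000 permutations.

## What passing tests do and do not show

The generator reproduces the trial's design (sample sizes, assignment
ratio, attrition counts, marginal covariate anchors, band-power moments,
injected effects) but not real data's joint structure: covariates are
mutually independent, attrition is random within arm, band powers are
exactly log-normal, and the EEG has no spatial topography beyond the
common/independent mixing, no line noise, no non-stationarity, and only
stereotyped artifacts. Passing tests therefore demonstrate that the
*estimators and algorithms* are correct under the stated design — unbiased
effect recovery, exact mirror and normalization identities, family-wise
error control — not that any particular scientific conclusion transfers to
real recordings. Regional analyses use a standard 10–20 grouping
(frontal/central/parietal/occipital) as configuration; the temporal pair
serves as reference and belongs to no region. EDF serialization quantizes
to 16-bit with a per-channel symmetric physical range, bounding round-trip
error at range$/2^{16}$ per sample.
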