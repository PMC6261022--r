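---
title: "Estimating individualized optimal stopping times for task fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating individualized optimal stopping times for task fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Task-fMRI protocols fix the number of trials in advance, for every subject.
But subjects differ — sometimes dramatically — in how quickly their
estimated neural responses stabilise as trials accumulate. A subject whose
trial-to-trial response is steady yields a stable general linear model (GLM)
beta weight after a modest number of trials; a subject whose responses
fluctuate needs far more. `ostfmri` implements a principled way to measure
that convergence per subject and per trial type, and to derive an
*optimal stopping time* (OST): the volume at which the experiment could have
ended without degrading the neural-pattern information the task was run to
collect.

Because the original clinical imaging data behind this method are not
publicly deposited, the package pairs the estimator with a fully synthetic
stop-signal-task (SST) study — a behavioral simulator, a BOLD
timecourse generator, and a cohort builder — so every claim the package
makes is demonstrated end-to-end on data it can generate itself.

## The model

### Volume-wise GLM

For a subject with $T$ acquired volumes, independent-component (IC)
timecourses $Y \in \mathbb{R}^{T \times C}$, and a design matrix $X$
(six HRF-convolved trial-type regressors — instruction, GG, GfSS, GfFS, SS,
FS — a motor regressor, 24 motion regressors, intercept and cosine drift),
the volume-wise GLM refits ordinary least squares on volumes $1..t$ for
every $t$ from a burn-in start (the 50th volume, or later if some trial
type has not yet occurred) up to $T$, saving the trial-type betas
$\beta_t$ at each step. Volumes with framewise displacement above 0.5 mm
are deleted identically at every refit.

### SoAD and exponential decay

Convergence is monitored by the sum of absolute differences of betas
between consecutive refits, per trial type, summed over components:

$$\mathrm{SoAD}(t) = \sum_{c=1}^{C} |\beta_{t,c} - \beta_{t-1,c}|.$$

The series is modelled as exponential decay
$N(t) = N_0 e^{-\lambda t}$; taking logs turns this into a straight line,
so $\lambda$ and $N_0$ come from a robust linear regression of
$\ln \mathrm{SoAD}$ on $t$ (Tukey bisquare, tuning constant 4.685,
leverage-adjusted residuals, MAD-based scale — the conventional IRLS
defaults). The half-life is

$$t_{1/2} = \ln 2 / \lambda,$$

and the k-half-life stopping volume is $t_\mathrm{start} + \mathrm{round}(k\,t_{1/2})$
for $k = 1..4$, clipped at $T$ when the estimate exceeds the acquisition.
After $k$ half-lives the SoAD has declined by $100(1-2^{-k})$ percent:
50, 75, 87.5, 93.75%. A subject-level stopping time across trial types is
the maximum of the four per-type OSTs.

### Validation by classification

Neural features are the concatenated betas of the four stop-related trial
types (GfSS, GfFS, SS, FS) at a stopping volume — $4 \times 22 = 88$
dimensions with the default 22 components. OST-truncated features are
compared against full-task features by balanced leave-one-out
cross-validation: for each left-out subject the majority group is
subsampled to the minority size (with 40 CD / 27 controls: 27+27 = 54
training subjects for a CD test subject, 26+26 = 52 for a control), a
linear soft-margin SVM (cost 1) is trained on each of many independently
drawn training sets, and the subject's score is the fraction of those
classifiers predicting its true label. Accuracy-vs-chance uses a
one-sided one-sample Wilcoxon signed-rank test against 0.5; conditions are
compared to the full task by paired one-sided signed-rank tests with
Bonferroni adjustment (family of 16 = 4 trial types x 4 half-lives).
Sex can be regressed out of every feature dimension first.
Behavioral validity is checked by correlating mean reaction times in the
truncated window against the full task, excluding subjects whose window
already spans every trial (their correlation is forced to 1 and would
bias the estimate); successful-stop trials have no reaction times and are
excluded by construction.

## What the synthetic generator emulates

* **Task**: 300 go/stop trials (75 stops, never adjacent), 2,000 ms
  inter-trial interval, three 20 s rests, one 4 s instruction block,
  502 volumes at TR = 2 s. The printed task parameters do not pin down
  per-trial stimulus time; the default 1,100 ms stimulus window spreads
  the 300 trials over 497 of the 502 volumes (the remainder is a rest
  tail) and is exposed as `trial_dur_ms`.
* **Behavior**: an independent horse-race model. Go finishing times are
  ex-Gaussian (mu 450 ms, sigma 80 ms, tau 60 ms), stops succeed when
  SSD + SSRT (250 ms) beats the go process; the SSD staircase (start
  250 ms, steps of 50 ms, floor 0) then holds stop success near 50%,
  which the acceptance suite verifies. Go omissions occur at rate 0.02.
  Mean go RT varies across subjects (SD 40 ms), which is what makes
  truncated- and full-task mean RTs correlate strongly across a cohort.
* **BOLD**: per trial and component, an impulse of amplitude
  `amp_mean[type, component] + jitter` at trial onset, convolved with a
  canonical double-gamma HRF (peak near 5 s, undershoot near 15 s,
  unit peak); motor impulses at button presses; AR(1) observation noise
  (lag-1 correlation 0.3, unit marginal SD, percent-signal-change units);
  random slow cosine drift. Motion is a Gaussian random walk with
  occasional spikes that push framewise displacement past the 0.5 mm
  censoring threshold at ~2% of volumes.
* **The convergence mechanism**: the trial-by-trial amplitude jitter is a
  stationary AR(1) *across successive trials of the same type* (lag-1
  correlation `amp_ar = 0.95`, marginal SD `amp_sd`). This models slow
  attentional/arousal drift rather than white trial noise, and it is a
  deliberate design choice: independent jitter merely rescales the SoAD
  series — the fitted decay constant is invariant to scale — whereas a
  drifting amplitude makes the beta estimate chase a moving target, so
  subjects with larger `amp_sd` genuinely converge more slowly. Setting
  `amp_ar = 0` recovers the white-jitter model.
* **Cohort**: 40 cocaine-dependent (CD) / 27 control subjects, male
  proportions 30/40 and 14/27. CD subjects carry an amplitude offset
  (default 0.5) on selected trial-type-by-component cells; subject-level
  jitter SD 0.2; per-subject `amp_sd` is log-normal
  (meanlog $\log 0.4$, sdlog 0.5) so convergence rates spread across the
  cohort.

What the generator does **not** emulate: voxel-space data and spatial ICA
(component timecourses are generated directly), scanner site effects,
physiological noise beyond AR(1) + drift, and non-stationary motion
artifacts beyond FD spikes. Passing tests therefore demonstrate that the
estimator behaves correctly when its modelling assumptions hold and
degrade gracefully under the perturbations we simulate — not that real
acquisitions obey those assumptions.

## Numerical choices

* **OLS, not prewhitened GLS.** The decay-of-change statistic is
  estimator-agnostic, and OLS is deterministic and directly checkable
  against a normal-equations oracle. Columns are equilibrated to unit
  norm before solving so that regressors of wildly different magnitudes
  (squared motion differences vs the intercept) cannot corrupt the rank
  decision; genuinely rank-deficient refits (common shortly after the
  burn-in, where drift and motion columns are nearly collinear over few
  rows) are solved minimum-norm and flagged per volume.
* **Censoring by deletion**, identically at every refit, rather than
  zero-weighting.
* **Drift inside the GLM** via a cosine basis up to the conventional
  1/128 Hz high-pass edge, keeping the pipeline self-contained instead of
  assuming pre-filtered inputs.
* **Non-positive SoAD values are excluded** before the log transform, and
  their count recorded — flooring them would inject an arbitrary constant
  into the slope.
* **Decay clock anchoring.** The regression predictor is the absolute
  volume index, and the OST anchors at the first fitted volume
  (`t_start + k t_half`), because no SoAD exists before it; counting from
  volume zero is available via `anchor = "zero"` and recorded in outputs.
* **Rounding** of fractional stopping volumes is half-up;
  non-decaying subjects ($\lambda \le 0$) are a flagged first-class
  outcome whose OST is the full task, not an error.
* **Fractional LOOCV scores.** Each left-out subject keeps the fraction
  of resampled classifiers voting its true label; headline accuracy is
  the mean fractional score (majority-vote accuracy is also reported).
  The fractional reading makes the signed-rank test well defined on 67
  continuous values.
* **Wilcoxon variants**: exact distributions up to n = 25 (rank-sum:
  both groups, no ties), normal approximation with continuity correction
  above.
* **Seeding**: one global seed is split into per-stage, per-subject
  streams by a multiplicative hash (`child_seed()`), so adding a subject
  never perturbs another subject's data.

## Problem sizes used in the tests

The unit suite exercises everything on miniature studies (40-70 trials,
100-160 volumes, 2-3 components), which preserve every structural
property at a fraction of the cost. The acceptance suite runs the default
502-volume study: one full 67-subject cohort for the classification
checks with 100 training resamples per left-out subject (the protocol's
1000 resamples only narrow the per-subject score granularity; 100 keeps
the demonstration affordable), a 20-session staircase calibration, a
20-seed null calibration of the chance test at the classification layer,
and two 30-subject arms for the variance-vs-convergence contrast.

## Known limitations

* The exponential-decay model is a convenient summary, not a generative
  truth: the SoAD of an OLS trajectory under stationary noise decays
  roughly like a power law, and the fitted half-life should be read as a
  descriptive convergence scale. The robust fit absorbs the resulting
  curvature in log space.
* Half-life estimates for subjects with strong amplitude drift are
  long-tailed; clipped stopping times (beyond the acquisition) are
  reported as the last volume and flagged, so 3- and 4-half-life
  conditions largely reproduce full-task features.
* Per-subject LOOCV scores are not independent (every pair of folds
  shares almost all training data), so the signed-rank test against
  chance is mildly anti-conservative; on null cohorts its empirical
  rejection rate runs somewhat above the nominal level. The pairwise
  condition comparisons inherit the same caveat, which the Bonferroni
  adjustment partly offsets.
* The SVM uses a fixed cost of 1 with no feature scaling, matching the
  reference protocol; no hyperparameter search is performed by design.
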