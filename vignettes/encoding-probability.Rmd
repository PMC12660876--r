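---
title: "Encoding and decoding probability and confidence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding and decoding probability and confidence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probencode)
```

`probencode` implements a complete analysis chain for asking how neural
time series (fMRI voxels or any other units) encode the hidden probability
of events in a changing environment, and the confidence attached to that
probability estimate. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic-data machinery
does and does not establish about real data.

## The task process and its ideal observer

The experimental paradigm is a binary sequence task. On trial $t$ a
stimulus $s_t \in \{A, B\}$ is drawn from a Bernoulli distribution with
hidden parameter $h_t = p(A)$. The parameter follows a change-point
process: at each step it stays put or, with hazard $1/75$, is resampled
uniformly on $[0.1, 0.9]$, subject to two constraints — the odds
$h/(1-h)$ must change by a factor of at least 4 at every change point, and
a change is forced if 300 trials elapse without one. Sessions contain 420
stimuli at a 1.3 s stimulus-onset asynchrony, with report periods (two
5 s response screens) inserted on average every 22 stimuli with a uniform
jitter of $\pm 3$. `generate_sequence()` draws sessions from exactly this
process; with the 10 s report periods a session lasts a little over 12
minutes, slightly longer than the scanned sessions it emulates, because
the report-period duration is a fixed design default here rather than a
measured quantity.

The normative observer of this process is implemented by
`run_ideal_observer()` as grid filtering. The posterior over $h$ is held
on a grid (default 100 equally spaced points spanning the support) and
updated per observation:

$$p(h_{t} \mid s_{1:t}) \propto p(s_{t} \mid h_{t})
  \left[(1 - \gamma)\, p(h_{t-1} \mid s_{1:t-1}) + \gamma\, \pi(h)\right],$$

where $\gamma$ is the hazard and $\pi$ the resampling prior. Two modeling
choices deserve mention:

* **Prior support.** The observer's prior and resampling distribution are
  uniform over the generative support $[0.1, 0.9]$, not over $[0, 1]$.
  This matches the process the observer is normative for; both the grid
  and the prior are configurable in `observer_config()`.
* **Transition kernel.** The observer's kernel is the plain
  stay-or-resample mixture above. It deliberately ignores the odds-factor
  and maximum-run constraints of the generator: those constraints make
  the exact transition kernel depend on the current value and the run
  length, a complication with negligible effect on the estimates at
  hazard $1/75$.

Per trial the observer reports the probability estimate (posterior mean),
confidence ($-\log$ posterior standard deviation, i.e. log precision up
to a factor of two), Shannon surprise $-\log p(s_t)$ and the outcome
entropy. By default these are computed from the distribution held
*before* observing $s_t$ (the transition-propagated prior predictive):
the task asks for a prediction about the upcoming stimulus, and surprise
is only well defined from the pre-update prediction. The post-update
convention is available via `timing = "posterior"`. All logarithms are
natural (nats).

The iterative filter is checked against `enumerate_posterior()`, an
exact-by-enumeration computation that sums over all change-point
configurations of a short prefix. The two agree to $10^{-8}$ for every
binary sequence up to length 8 in the test suite.

## Encoding models

A unit's tuning curve maps the encoded estimate $x$ (probability or
confidence) to expected activity. Two model classes are implemented
(`encoding_spec()`):

* **linear**: $\hat y = w x$ — the classical parametric modulation;
* **versatile**: $\hat y = \sum_{i=1}^{K} w_i f_i(x)$ with Gaussian (or
  sigmoid) basis functions — a linearizing model able to approximate any
  smooth tuning curve.

Basis centers obey the equal-gap rule ($\mu_i = a + i(b-a)/(K+1)$).
Defaults follow the study design: $K = 10$, $\sigma = 0.04$ on $[0, 1]$
for probability and $\sigma = 0.06$ on $[1.1, 2.6]$ for confidence —
widths chosen so the basis sum is nearly constant over the domain
(translation invariance). For other $K$ the width defaults to 0.44 times
the center spacing, which preserves that ratio. The basis amplitude is 1;
ridge regression absorbs overall scale. Confidence estimates occasionally
leave $[1.1, 2.6]$; they are clamped to the boundary and the count is
recorded on the design object (and surfaced as a warning).

A third class, `posterior_expectation`, replaces $f_i(x_t)$ by its
expectation under the trial's full posterior, $\sum_g f_i(\text{grid}_g)
p_t(\text{grid}_g)$, implementing the hypothesis that activity reflects
the distribution rather than a point estimate.

`build_design()` places the per-trial modulators as impulses at stimulus
onsets and convolves them with a canonical double-gamma HRF (peak 6 s,
undershoot 16 s, dispersions 1, ratio 1/6, 32 s support, peak-normalized
to 1 — `hrf_spec()` exposes all parameters). The convolution is computed
by evaluating the kernel directly at scan-minus-onset lags, the exact
limit of an oversampled impulse-grid convolution. Regressors of
no-interest are appended: a stimulus-onset constant, surprise, outcome
entropy (omitted when entropy itself is the estimate of interest), a
report-screen constant, the normative estimate at each report screen, the
reported estimate, and optional motion confounds (for synthetic data,
`simulate_motion()` provides smooth random walks; off by default).

Temporal preprocessing (`preprocess_sessions()`) is applied **identically
to data and regressors**: per-session linear detrending and high-pass
filtering at 1/128 Hz — realized as removal of a discrete-cosine drift
basis, the standard drift model — then z-scoring over the concatenation
of all sessions per column, then per-session demeaning. Data are not
z-scored per session on purpose: under a versatile code the signal
variance legitimately differs between sessions. Columns the filter
annihilates (constants, pure drifts) are set to zero rather than left as
amplified round-off.

## Fitting and the z-R² score

`fit_encoding()` solves ridge regression in closed form,
$w = (X^\top X + \lambda I)^{-1} X^\top y$, without an intercept (all
series are session-demeaned). The penalty is shared across units and
across models with equal regressor counts; the default $\lambda = 1$ on
z-scored regressors can be recalibrated with `tune_ridge_lambda()`, a
simulation-based grid search mirroring how such penalties are set in
practice.

`evaluate_encoding()` scores a model by leave-one-session-out
cross-validation. On the held-out session, predictions use the interest
regressors only (equivalent to fixing no-interest regressors at their
session mean of zero), scored by the sums-of-squares $R^2$, which may be
negative. Because even meaningless regressors can fit autocorrelated
noise, the $R^2$ is standardized against a *sequence null*: the interest
regressors are rebuilt from 100 freshly generated task sequences (same
generative process, same report timeline, fitted weights kept) and scored
against the same held-out data. The score is
$z\text{-}R^2 = (R^2 - \mu_0)/\sigma_0$, averaged over folds. Null
sequences are drawn once per evaluation and shared across units and
folds; units with a zero-variance null are flagged and excluded with a
warning.

## The synthetic experiment and model recovery

`simulate_experiment()` generates the full study at configurable scale:
sessions from the task process, normative estimates, simulated reports
(normative value plus Gaussian noise of sd 0.1, discretized to the
3/5-range probability scales and the 5-level confidence scale — reports
exist only to populate the no-interest regressors and can be switched
off), and voxel time series $y = X_{\text{int}} w + \varepsilon$ with
interest weights drawn uniformly in $[-0.5, 0.5]$ and white noise of
power `noise_ratio` times the signal power (default 9, i.e. 10% signal).

`model_recovery()` crosses generative and fitted models — by default the
2 × 2 set {linear, versatile} × {probability, confidence}; an
entropy-linear model can be added — and reports the mean z-R² matrix and
the fraction of experiments each fitted model wins. The desk-scale
default is 10 experiments × 20 voxels (the full-scale simulation it
emulates used 100 × 100); weights are drawn per voxel per experiment and
held constant across sessions. At this scale the generative model wins
essentially every experiment and matched versatile fits are strongly
positive.

Two quantitative caveats, established with the test suite rather than
asserted:

* Fitting a *linear* model to versatile-generated data does not give
  exactly zero z-R²: a random weighted sum of bumps retains a linear
  component on average, so the linear fit recovers part of the signal
  (well under half the matched score). The qualitative claim — linear
  models explain the data well only when the generative model is linear —
  survives.
* *Cross-estimate* cells (probability model fitted to confidence-coded
  data and vice versa) are small but not exactly zero: probability and
  confidence estimates are correlated through the task statistics, so a
  slight positive bias (an order of magnitude below matched scores)
  remains. The acceptance checks therefore bound the magnitude of these
  cells rather than testing them against zero within sampling error.

What the generator does **not** emulate: spatial structure between
voxels, physiological and scanner noise spectra (noise is white),
participant-specific learning (only the normative observer is
implemented), report-behavior idiosyncrasies, and any surface geometry.
Passing recovery at desk scale therefore demonstrates that the pipeline's
inferences are internally consistent and identifiable under the stated
noise model — not that real cortical data meet those assumptions.

## Tuning-curve characterization

`tuning_curve()` reconstructs a unit's curve as the weighted basis sum on
a 201-point grid (resolution is a free choice; results are insensitive to
it at these widths). `characterize_curve()` computes:

* **argmax** (ties broken toward lower $x$) and whether it is
  *non-extreme*, i.e. at least 20% of the span away from both bounds;
* **non-monotonicity** $n(f) = 1 - |f(b) - f(a)| / (f_{max} - f_{min})$,
  with $m(f) = 1 - n(f)$; $m(f) = 1$ is necessary but not sufficient for
  monotonicity;
* **nonlinearity** $\nu(f) = 1 - R^2_{\text{lin}}$ of an ordinary
  least-squares line fitted to the curve;
* **peak count** on the min-max-normalized curve, counting interior local
  maxima with height ≥ 0.7 and topographic prominence ≥ 0.125 (prominence
  = drop to the higher of the two saddles separating the peak from higher
  ground; endpoints never count). No installed R routine computes
  prominence, so the implementation is in-package and is tested against
  an exhaustive traversal oracle on 1,000 random curves.

Constant curves are flagged degenerate with $n = \nu = 0$ by convention
and excluded from group summaries. Units of interest are selected by
converting cross-validated $R^2$ into empirical p-values against a
white-noise null (`empirical_null_r2()`, default 10,000 samples; the
full-scale analysis used $10^6$) with Benjamini–Hochberg FDR at 0.05.
Reliability is verified by refitting weights on two independent halves of
the data (sessions {1,2} vs {3,4} by default) and correlating them;
selection on one noise dataset yields chance reliability on an
independent one, guarding against selection-induced bias.

## Multivariate decoding and RDM geometry

`estimate_bin_patterns()` refits the versatile model with 5 basis
functions, jointly on the three training sessions and separately on the
held-out session; the interest weights are the per-bin response patterns.
Units are ranked by z-R² estimated *within the training sessions only*
(inner leave-one-session-out among the three) and the top 100 kept; when
fewer units exist, all are used. `decode_bins()` assigns each valid test
bin $j$ the training bin $k$ minimizing the correlation distance
$D(j,k) = 1 - r(\text{test}_j, \text{train}_k)$ (ties toward the lowest
bin). A bin is valid in a fold when at least 5% of that session's stimuli
fall in it, a stimulus counting for a bin when its estimate exceeds 10%
of the bin's basis maximum. Accuracy is the fraction of valid bins
decoded correctly, averaged over folds; chance is 1/5.

Because train and test patterns come from different data, the RDM is
asymmetric with a nonzero diagonal. `average_rdm()` averages folds while
ignoring invalid rows, and `regress_rdm()` regresses all valid cells
(diagonal included, intercept included, predictors z-scored) on the
identity model (0 diagonal / 1 off-diagonal — the signature of a highly
non-monotonic code) and the graded model ($|j-k|$ by default,
$(j-k)^2$ optionally — the signature of a monotonic code); the winner is
the larger coefficient. On synthetic cohorts at 10% signal, bump-coded
units are classified identity and monotone-coded units graded in
essentially all simulated participants. `group_decoding_stats()` supplies
the group layer: per-region t-tests of accuracy against chance with
BH-FDR across regions, and graded-fraction tests against 0.5.

## Reproducibility and scale

Every stochastic step flows through explicit integer seeds; identical
seeds give bit-identical sequences, experiments and pipeline outputs
(`run_pipeline()` writes a JSON manifest with the command, configuration
and seed alongside every output set). The test-suite problem sizes — 10
experiments × 20 voxels for recovery, cohorts of 10–20 simulated
participants for decoding and RDM geometry, 100-sequence nulls — are the
package's desk-scale defaults, chosen to make the full suite convenient
to run routinely; all of them scale up by configuration.

## Known limitations

* The observer assumes the true hazard; subjective or leaky inference is
  out of scope.
* The high-pass filter is a DCT drift projection; a recursive filter
  would differ slightly near the cutoff.
* Real-data entry points accept plain matrices or NIfTI volumes plus
  events tables, but spatial preprocessing, surface projection and
  cluster-level inference are outside the package.
* The sequence null shares the report schedule with the true session; if
  report timing itself carried signal, the null would absorb it.
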