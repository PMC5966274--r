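---
title: "The Bayesian observer model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Bayesian observer model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(visprior)
```

This vignette is the package's own account of the model it implements,
the choices that were genuinely open, and what the synthetic-data tests
do and do not establish about real data.

## The task and its statistics

Observers estimate the direction of coherently moving dots presented at
one of four contrast levels within a single 567-trial session: 167 trials
with no stimulus, 243 at a contrast driven by a 4-down/1-up detection
staircase, 90 at a 2-down/1-up staircase, and 67 at high contrast. Low
contrast directions come from nine design angles (0°, ±16°, ±32°, ±48°,
±64° around a per-session reference); ±32° appear in roughly 70% of
4/1-staircase trials, so observers implicitly acquire a bimodal
expectation peaked there. Estimates are analyzed only on staircased
trials after trial 170 (where the staircases have converged) on which the
observer validated an estimate and reported detecting the stimulus.

## Generative model

One trial of the Bayesian observer chains four stages:

1. **Sensory corruption.** The true direction $\theta_{act}$ is perturbed
   twice with the same von Mises concentration $\kappa_{sens}$: a
   trial-varying direction $\theta_t \sim V(\theta_{act}, \kappa_{sens})$
   and a measurement $\theta_{sens} \sim V(\theta_t, \kappa_{sens})$.
2. **Inference.** The observer multiplies the learned prior
   $p_{exp}(\theta) = \tfrac12[V(\theta;-\theta_{exp},\kappa_{exp}) +
   V(\theta;+\theta_{exp},\kappa_{exp})]$ with the single-stage likelihood
   $V(\theta_{sens};\theta,\kappa_{sens})$ and reads out the **circular
   mean** of the posterior as the percept $\theta_{perc}$.
3. **Motor stage.** The report adds motor noise:
   $V(\theta_{est};\theta_{perc},\kappa_m)$.
4. **Lapses.** With probability $\alpha$ the estimate is uniform on the
   circle.

The response distribution used for fitting marginalizes stage 1
numerically, maps every possible measurement through stage 2, and
convolves with the motor kernel — so simulation and likelihood are two
views of exactly the same chain (the test suite verifies their agreement
against a $10^6$-draw Monte-Carlo histogram at 3-standard-error
resolution).

Two points in stage 1–2 were open to interpretation:

* **Two-stage vs single-stage corruption.** We implement the literal
  two-stage cascade as the default and keep a `stages = 1` switch. The
  two stages double the measurement variance while the observer's
  likelihood keeps width $\sigma_{sens}$; at the group-mean parameters
  this predicts an off-mode estimation SD of about 13.9°, close to the
  observed group value near 13.8°, whereas the single-stage variant
  predicts about 12.1°.
* **Posterior-mean tie-break.** A symmetric posterior (measurement at
  exactly 0° or 180° under a bimodal prior) has an undefined circular
  mean; the percept is then defined as the measurement itself.

The `ADD` response-strategy families are an explicit reconstruction: with
probability $w$ (free, in $[0,1]$) the response is drawn from the
expectation distribution — the full prior (`ADD1`), the prior truncated
to the stimulus side and renormalized (`ADD2`, a direction of exactly 0°
counting as positive), or the prior mode(s) blurred only by motor noise
(`ADD1_m`/`ADD2_m`, the $1/\kappa_{exp}\to 0$ limits) — otherwise it is
an unbiased sensory estimate with sensory-plus-motor noise and lapse.
`ADD1_m` keeps half the expectation mass at each mode; side-conditioning
is what distinguishes `ADD2_m`.

## Parameters

| Parameter | Units | Meaning | Typical value |
|---|---|---|---|
| $\theta_{exp}$ | deg | prior mode location (modes at $\pm\theta_{exp}$) | 40 |
| $\sigma_{exp}$ | deg | prior width | 15 |
| $\sigma_{sens}$ | deg | sensory noise (scalar, or per direction) | 10 |
| $\alpha$ | — | lapse probability | 0.06 |
| $\sigma_m$ | deg | motor noise (pre-fit, then fixed) | 10 |
| $w$ | — | ADD-family expectation weight | free |

Concentrations and dispersions convert by $\sigma = \sqrt{1/\kappa}$
(radians to degrees). The alternative circular-SD convention differs by
under 3% for $\sigma \le 30°$ and is available via
`kappa_to_sigma(..., method = "circular-sd")`.

## Numerical machinery

All densities live on a regular grid over $(-180°, 180°]$ with 0.5°
spacing (720 points; configurable). The spacing divides every design
angle, so rotations are integer index shifts and all convolutions
(measurement cascade, motor blur, sensory-plus-motor combination) use the
FFT. The posterior-mean map is itself a circular convolution of the
complex phase-weighted prior with the likelihood kernel, which makes a
full likelihood evaluation across nine stimulus angles run in about two
milliseconds. Likelihood values at observed estimates are linear
interpolations on the grid; densities are renormalized after convolution
and floored at $10^{-300}$ inside logs. The test suite checks the 0.5°
pipeline against 0.01° quadrature (posterior means agree to better than
0.05°) and trapezoid normalization to $10^{-6}$.

## Fitting

Motor precision and a high-contrast lapse rate are first fit by maximum
likelihood on validated high-contrast trials (at least 20 required),
assuming negligible sensory noise there. Model parameters are then
estimated on the filtered staircased trials by Nelder–Mead simplex search
under a sine-based bound transform, started from a grid of log-spaced
dispersions ($\sigma_{exp} \in \{4,8,16,24\}$,
$\sigma_{sens} \in \{4,8,16,32,64\}$, $\theta_{exp}$ at 32°, $\alpha$ at
0.05); the objective is evaluated at every start and the best three are
polished. BIC is $-2\log L + k\log n$ with $n$ the number of trials in
the likelihood. Across-subject comparison uses two-sided Wilcoxon
signed-rank tests on paired BIC differences (zero differences dropped;
exact distribution up to $n = 25$, normal approximation with continuity
correction beyond).

**Search bounds.** $\theta_{exp} \in [1°, 70°]$,
$\sigma_{exp} \in [1°, 30°]$, $\sigma_{sens} \in [0.5°, 80°]$,
$\alpha, w \in [0, 1]$. The $\theta_{exp}$ and $\sigma_{exp}$ bounds are
identification constraints, not conveniences: as $\theta_{exp}$
approaches 180° the bimodal prior degenerates to a single mode whose
outward push on estimates mimics a genuine prior just beyond the probed
range, and a prior wider than ~30° is behaviorally indistinguishable
from no prior at a single session's trial counts. Without these bounds
the maximum-likelihood estimate occasionally (a few percent of synthetic
subjects) jumps onto those degenerate ridges with likelihood advantages
of a few nats, which says more about the flatness of the likelihood than
about the observer.

## The synthetic-data generator

`make_schedule()` reproduces the session's condition counts exactly.
`run_staircases()` implements the 4/1 and 2/1 rules in log-contrast steps
(0.1 log units, halved at each reversal down to 0.02, rails at $10^{-4}$
and $10^0$); with a logistic detection model the converged runs hold
detection near the theoretical $0.5^{1/4} \approx 84\%$ and
$0.5^{1/2} \approx 71\%$ targets. Step sizes, start values, and the
detection model are simulation conveniences (they are not fit to
anything): the task's original adaptive parameters are not part of the
analysis. No-stimulus trials have no generative branch in the estimation
model, so hallucinations are simulated by drawing the measurement from
the observer's own prior and passing it through the usual
posterior/motor/lapse chain, with a configurable per-trial hallucination
probability (default 0.12, giving on the order of 20 hallucinations per
167 no-stimulus trials — a typical in-task rate); undetected no-stimulus
trials respond uniformly. Reaction times are pass-through lognormal
filler: nothing in the pipeline models them.

What passing tests on this generator shows: the estimator recovers the
parameters of data that truly come from the model, the analysis code
computes what it claims, and the model's qualitative signatures
(attractive bias, variability dip at the modes, mode-clustered
hallucinations) emerge at realistic parameter values. What it cannot
show: that real observers are Bayesian, that the inclusion criteria
behave sensibly under real artifacts (fatigue, drift), or that trait
correlations in real cohorts are causal — the generator's trait link is a
plain linear latent model.

## The recovery experiment and its sampling population

Parameter recovery samples 80 synthetic subjects, simulates 200
staircased trials each (the post-exclusion trial count of a session,
taken from the session's own angle mix), refits with $\sigma_m$ fixed at
its true per-subject value — mirroring its estimation from separate
high-contrast trials — and reports the Pearson correlation per parameter
on the degree scale.

The sampling means are the group means (40°, 15°, 10°, 0.06, 10°). The
spreads and truncations are this package's choice and deserve a candid
paragraph. We use SDs (10°, 6°, 3°, 0.08, 3°), truncated to
$\theta_{exp} \in [20°, 64°]$, $\sigma_{exp} \in [6°, 26°]$,
$\sigma_{sens} \in [5°, 20°]$, $\alpha \in [0, 0.25]$,
$\sigma_m \in [5°, 20°]$. Two considerations fix them. First, an
information bound: at 200 trials the Fisher information of the response
distribution caps the precision of $\hat\alpha$ at about 0.02, so a
population spread of $\alpha$ much below ~0.05 cannot yield a high
actual-vs-recovered correlation for any estimator; lapse rates in
estimation tasks plausibly span 0 to 0.25, and the chosen spread reflects
that. Second, identifiability: subjects whose prior is very wide relative
to their sensory noise leave essentially no prior footprint in 200
trials, so their prior parameters are unrecoverable in principle; the
truncation keeps the population inside the regime the recovery question
is about. Under these conditions, recovery correlations land around
0.85–0.95 per parameter at desk scale (the acceptance suite computes the
exact values at its fixed seed), and rise above 0.98 for all parameters
at 2000 trials per subject — the estimator is consistent; a single
session is simply a 200-trial instrument.

## Behavioral statistics

The per-angle description of estimation behavior fits
$(1-\alpha)V(\theta;\mu,\kappa) + \alpha/360$ per design angle by EM with
the lapse fraction shared within subject; bias is $\mu$ minus the true
angle (wrapped) and variability is the dispersion of $\kappa$. Group
curves carry Cousineau–Morey within-subject standard errors
(subject-mean-centered, bias-corrected). The no-stimulus clustering ratio
is the probability of estimating within 8° of either mode divided by the
measure of those windows ($2 \times 16/360$), so uniform responding
scores exactly 1 and full concentration scores 11.25. A literal
fixed-bin-count reading of the ratio would imply a 720° support, which is
not circular; the implemented convention keeps the uniform-scores-1
calibration, which is the property the statistic is used for.

Trait analyses use iteratively reweighted least squares with the Huber
loss (tuning constant 1.345, MAD scale) on z-scored variables; the
reported robust "r" is the standardized slope, which equals Pearson's r
exactly when nothing is downweighted. Kendall's $\tau_b$ is tie-corrected,
with an exact small-sample null (inversion-count enumeration) when there
are no ties and $n \le 12$. Bonferroni correction multiplies by 4 — the
four primary hypotheses (two trait spectra × prior precision / sensory
precision) — and is reported only for those rows.

## Problem sizes in the shipped tests

The test suite exercises the pipeline at the scales the analyses
prescribe where that is the point (80 subjects × 200 trials for recovery;
50 subjects for model comparison and the behavioral signatures) and at
reduced scales elsewhere (unit tests use $10^4$–$10^5$ draws for
distributional checks, $10^6$ for the Monte-Carlo oracle). These sizes
are the package's validation design; they keep the default suite to a few
minutes on one core.

## Known limitations

* The joint estimation-plus-detection observer (which would give
  no-stimulus trials a principled generative branch) is out of scope;
  hallucination simulation is a modelling convenience.
* Point maximum-likelihood only: no uncertainty intervals on fitted
  parameters, no hierarchical pooling across subjects.
* Model comparison is signed-rank-on-BIC; exceedance-probability
  random-effects selection is not implemented.
* The robust "r" convention (standardized IRLS slope) reproduces sign and
  approximate magnitude of published robust-regression correlations, but
  exact numerical equality with other implementations is not guaranteed.
* $\theta_{exp}$ beyond ~70° and $\sigma_{exp}$ beyond ~30° are outside
  the fit's search region by design; data truly generated there will be
  clamped to the boundary.
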