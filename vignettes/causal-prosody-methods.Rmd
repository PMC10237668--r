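---
title: "Methods: prosodic restyling and the Bayesian choice model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prosodic restyling and the Bayesian choice model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific setting

English *so* is a general causal connective: it marks a causal relation
without saying whether that relation is **objective** (a cause and its
real-world consequence — "Jim got his nose pierced, so he bled a little") or
**subjective** (an argument and a speaker's claim — "…, so he wants
attention"). Production work has shown that speakers nevertheless pronounce
*so* differently in the two cases: it is about 50 ms longer under subjective
causality, and its f0 contour is more concave with a lower onset. The
perception question is whether listeners can exploit those prosodic cues. The
experimental logic is a forced-choice discourse-completion task: listeners
hear an event clause followed by a prosodically manipulated *so* and pick one
of two printed continuations (subjective vs objective).

This package implements the full computational chain of that study:

1. **f0 contour modelling and restyling** by functional principal component
   analysis (FPCA),
2. **stimulus assembly** — duration scaling, gap removal, and export of
   restyling specifications in Praat text formats,
3. **synthetic data generation** for both contours and listener responses,
4. the **Bayesian hierarchical logistic model ladder** with prior predictive
   checks, bridge-sampling Bayes factors, and posterior summaries.

The study's raw listener responses are not publicly deposited, so the
package's empirical claims are about *recovery*: data are simulated from the
generative model at the study's reported posterior means, and the analysis
chain is required to recover those values.

# Contour model

A contour is a sampled f0 trajectory in semitones. Semitones are computed
relative to a reference frequency, by default the speaker's median f0
(`hz_to_semitones()`); the reference is configurable because the convention
is not universal. Each contour is duration-normalized onto a common grid of
`G = 101` equally spaced points on [0, 1] by linear interpolation
(`normalize_time()`), which makes tokens of different durations pointwise
comparable.

FPCA then approximates each normalized contour as

$$F0(t) \approx \mu(t) + s_1\,\mathrm{FPC}_1(t) + s_2\,\mathrm{FPC}_2(t) +
  s_3\,\mathrm{FPC}_3(t),$$

with a shared mean curve, up to three orthonormal component curves, and
per-token scores. The estimator (`fit_fpca()`) is the eigendecomposition of
the sample covariance of the centered contours on the grid — the simplest
estimator consistent with the model, with no roughness penalty. Smoothness in
this setting comes from the data (f0 tracks are already smooth on a 101-point
grid); if needed, a smoother can be applied to contours before fitting.
Numerical choices worth noting:

* **Sign convention.** Eigenvectors are sign-ambiguous. Each component is
  flipped so its grid integral is non-negative (ties broken by making the
  first nonzero value positive), which makes results deterministic across
  platforms and runs.
* **Inner product.** Orthonormality is defined under the plain grid dot
  product; scores are inner products of centered contours with the
  components, which coincides with the least-squares projection.
* **Interpolation.** Linear throughout (normalization and reconstruction).
  Linear interpolation is exactly reversible on its own grid, so
  `project()` after `reconstruct()` returns the input scores to machine
  precision.
* **Reconstruction grid.** `reconstruct()` evaluates the model curve every
  5 ms from 0 up to the target duration; the endpoint is included only when
  the duration is an exact multiple of the step (285 ms / 5 ms gives 58
  samples). No terminal point is extrapolated.

**Restyling** (`restyle_scores()`) imposes a prosodic category by replacing
s2 and s3 with per-condition targets while keeping the token's own s1 (its
overall level/tilt). The default targets are the production-study values:

| condition  | s2     | s3     | duration |
|------------|--------|--------|----------|
| subjective | +0.335 | −0.065 | 285 ms   |
| objective  | −0.515 | +0.025 | 235 ms   |

so the subjective-minus-objective contrasts are +0.85 (s2), −0.09 (s3) and
50 ms, exactly.

# Stimulus assembly

`build_stimulus()` composes the manipulation chain for one clip: project the
connective contour, restyle, reconstruct at the condition's target duration,
rescale the segment durations by a single factor (preserving the /s/ : /əʊ/
ratio exactly), and remove the silent gap between the event clause and the
connective. The event-clause contour is never touched. The duration targets
are applied as exact per-token totals; the source presentation is compatible
with either exact totals or means across tokens, and exact totals are the
reproducible choice. Durations are kept real-valued internally and rounded
half-up to 0.1 ms only at export, so repeated scaling cannot accumulate
rounding drift.

The package does not synthesize audio. The published manipulation used a
PSOLA resynthesizer; what that external step needs — the restyled pitch
points and the segment boundaries — is exactly what `export_praat()` writes
(a PitchTier and a TextGrid in Praat's text formats, both dialects readable
back losslessly). Waveform synthesis and perceptual naturalness evaluation
are out of scope.

# Synthetic data

## Contours

`gen_contours()` draws contours from a low-rank model: a falling mean curve
plus three orthonormalized shapes — level/tilt, a concave mid-span bulge,
and an end-point tilt — with condition-specific means for s2 and s3 (the
restyling targets above) and durations near 285/235 ms. Defaults the source
does not determine were fixed once, on identifiability grounds:

* within-condition score SDs `(1, 0.25, 0.2)`: eigenvalue separation between
  the three structural directions and the white-noise floor is what makes
  the component estimator stable, so the SDs are ordered and well separated;
* measurement noise 0.1 st per sample: small relative to the weakest
  component, as for smoothed f0 tracks;
* duration SD 10 ms around the condition means.

Two honest limitations follow. First, the true component *shapes* of the
source data exist only as published figures, so the generator guarantees the
estimator's properties (oracle equivalence, contrast recovery) rather than
numerically reproducing those figures. Second, the s3 condition contrast
(−0.09) is largely absorbed by the eigen-rotation toward the much larger s2
contrast (+0.85) and is not recoverable from fitted scores — a genuine
property of PCA on such data, not an implementation defect; recovery tests
therefore assert the s2 contrast only.

## Listener responses

`gen_responses()` is the generative twin of the fullest analysis model: for
participant $p$, pair $q$ and prosody $x \in \{0, 1\}$,

$$\Pr(\text{choice}=1) = \mathrm{logit}^{-1}\!\big(\beta_0 + a_p + b_q +
  (\beta_{\text{pros}} + u_p + w_q)\,x\big),$$

with all random effects independent normals. Defaults are the study's
reported posterior means: $\beta_0 = -1.06$, $\beta_{\text{pros}} = 0.39$,
$\mathrm{sd}(u) = 0.51$, $\mathrm{sd}(w) = 0.42$. The random-intercept SDs
are not reported and default to 0.5 for both grouping factors — the same
order as the reported slope SDs — and are prominently configurable.
`generative_params_m0()` is the intercept-only twin (no prosody effect, no
slope variation), used for intercept-recovery runs: fitting the intercept
model to data that contain a prosody effect would fold half that effect into
the intercept, so recovery of −1.06 is only well-posed against the
intercept-only twin. Trials are conditionally independent given the random
effects (no order or fatigue effects), and every table is a complete
participant × pair × prosody crossing. Each generator takes one root seed
with documented per-operation stream splitting, so fixtures are
bit-reproducible.

`gen_filler_accuracies()` reproduces the printed filler-accuracy
distribution exactly (38 of 55 at 100%, 2 above 90%, 3 at 70–89%, 8 at
50–69%, 4 below 50%), randomizing within bands on the 20-filler lattice.

# Participant filtering

`filter_participants()` excludes participants whose incorrect fraction on
the fillers is **at or above** 10%. The two published phrasings ("10% or
more incorrect fail" vs "below 90% accuracy excluded") disagree at exactly
90% accuracy; the strict reading of the failure rule is used, the boundary
case fails, and the comparison is done on integer counts so lattice values
are exact. On the printed distribution both readings retain 40 of 55.

# The model ladder

Four nested Bernoulli-logit models are fitted (`fit_choice_model()`):

| model | formula |
|-------|---------|
| m0 | `~ 1 + (1|participant) + (1|pair)` |
| m1 | `~ prosody + (1|participant) + (1|pair)` |
| m2 | `~ prosody + (1+prosody|participant) + (1|pair)` |
| m3 | `~ prosody + (1+prosody|participant) + (1+prosody|pair)` |

Priors: the population coefficients (intercept and prosody) carry the
normal(0, SD) prior under study, with SD ∈ {1.5, 1, 0.5} for reported fits
and Bayes factors (screened against {10, 0.25} in prior predictive checks);
every random-effect SD carries a half-normal(0, 1) prior; intercept/slope
pairs are independent (no correlation parameter). The choice to put the
varying-SD prior outside the screened family follows from the prior
predictive design: the screening model is the intercept model, whose
predictive distribution is driven by the intercept prior, so that is where
the screened prior belongs; everything else is a documented default.

Sampling is by Gibbs/slice MCMC (JAGS) with a **non-centered**
parameterization — random effects are expressed as `sd * z` with standard
normal `z` — which removes the funnel geometry that otherwise traps the
sampler at small SDs (centered runs showed split-chain Rhat up to 1.66 on
slope SDs; non-centered runs stay within 1.01). The default configuration is
four chains of 10,000 iterations with 2,000 warm-up, as in the study;
`reduced_settings()` (four chains, 2,000 iterations, 500 warm-up) is used
for replicate simulation runs and testing, where the posterior mean — not
tail resolution — is the quantity of interest.

**Convergence contract.** Every fit computes split-chain Rhat and bulk and
tail effective sample sizes for the reported coefficients and evaluates the
contract: no divergences, Rhat within 0.01 of 1, bulk ESS above 90% of the
kept draws. Violations raise a warning (or error in strict mode) carrying
the full report. Two qualifications are documented rather than hidden: the
slice sampler has no divergence diagnostic, so the divergence count is 0 by
construction; and the 90% ESS level is a property of well-adapted
Hamiltonian samplers — a Gibbs sampler at the reduced settings typically
sits below it for the intercept, which the report will honestly flag while
posterior means remain accurate (Monte-Carlo SE of the mean at ESS ≈ 250 is
about 0.01 on the log-odds scale, an order of magnitude below the replicate
noise).

# Prior predictive checks

`prior_predictive()` simulates full datasets from the priors and returns the
per-draw proportion of subjective choices. Zero-mean priors give predictive
proportions centered at 0.5 for any SD; normal(0, 10) piles roughly
three-quarters of the mass outside (0.05, 0.95) — the inverse-logit of a
wide prior concentrates near 0 and 1 — while SDs of 1.5 and below keep the
bulk of the mass in the interior. A useful closed-form anchor: with the
intercept alone, the fraction outside (0.05, 0.95) is
$2\,(1 - \Phi(\mathrm{logit}(0.95)/\mathrm{SD}))$, which is 0.77 at SD = 10;
random-effect variation only shrinks it further. No prior concentrates more
than ~77% of dataset-level proportions outside that band, which is worth
knowing when comparing against verbal descriptions like "never or always".

# Bayes factors

`bayes_factor()` estimates BF10 as a ratio of marginal likelihoods, each
obtained by iterative bridge sampling (`marginal_likelihood()`): a
moment-matched multivariate normal proposal is fitted on half of the
posterior draws (SDs log-transformed so the space is unconstrained, with the
Jacobian in the target), and the optimal-bridge fixed point is iterated
entirely in log space. The estimator is validated against conjugate models
with closed-form marginal likelihoods. Each estimate is repeated with fresh
proposal draws; if the coefficient of variation of the implied Bayes factor
reaches 10%, the result is rejected with an instability error rather than
returned. Bands follow the usual reporting convention (>10 strong, 3–10
weak, 1–3 very weak, <0.1 favors the null). Because each model's marginal
likelihood is estimated separately, Bayes factors are coherent across the
nested ladder (BF(m3, m0) equals the product of the stepwise factors up to
estimator noise).

The by-pair slope term is evaluated as m3 vs m2 and the by-participant slope
as m2 vs m1, following the ladder exactly as published — including the
detail that pairs keep intercept-only structure in m2 even though by-pair
slopes are supported later.

# Posterior summaries

`summarize_effects()` reports posterior means, 95% and 50% credible
intervals (percentile-based), and exponentiated quantities under **both**
conventions: the mean of exponentiated draws (headline; Jensen's inequality
makes it the larger) and the exponential of the posterior mean. Reporting
both reconciles odds-ratio figures that differ in the second decimal
depending on convention (1.47 vs 1.48 style). The intercept row also carries
the reciprocal odds (odds of the objective continuation). For m2/m3, a
per-participant slope table flags participants whose 95% CrI excludes zero.

# Pipeline and problem sizes

`run_pipeline()` chains the stages — contour simulation, FPCA, 30-stimulus
build, response simulation, filtering (55 → 40), ladder fits, the 3 × 3
Bayes-factor table, and summaries — writing every artifact with a config
hash and seed, plus a structured per-stage log; `report_run()` renders the
text report and forest-style figures. The numbered scripts under `analysis/`
are thin drivers over these functions.

Simulation sizes used by the shipped tests and the acceptance script are
desk-scale by design: recovery runs use 40 participants × 15 pairs × 2
conditions per replicate with 5–10 replicates under `reduced_settings()`, and
contour-recovery runs use 200 contours per set. These sizes put Monte-Carlo
error comfortably inside the stated recovery tolerances (±0.15 on the
log-odds coefficients, ±0.20 on the odds ratio) without requiring the full
10,000-iteration configuration, which remains available via
`sampler_settings()`.

# Known limitations

* Contour shapes are synthetic stand-ins with guaranteed estimator
  properties, not numerical reproductions of the published component
  figures.
* The s3 condition contrast is unidentifiable from fitted scores in the
  presence of the dominant s2 contrast (see above).
* No audio is synthesized or analyzed; pitch tracking is out of scope and
  contours are inputs.
* The real listener data are not deposited, so the published Bayes-factor
  values on real data are not reproducible; the package checks BF
  *properties* (self-comparison, null behavior, ladder coherence, prior
  ordering) on synthetic data instead.
* Passing recovery tests show the chain is consistent at the generative
  model's assumptions (independent normal random effects, conditional
  independence, balanced design); they cannot show robustness to
  misspecification present in real listener data (order effects, non-normal
  participant variation, item confounds).
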