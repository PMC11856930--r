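---
title: "Observer models of audiovisual temporal recalibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observer models of audiovisual temporal recalibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avrecal)
```

## The problem

Repeated exposure to audiovisual stimuli with a constant stimulus-onset
asynchrony (SOA) shifts the point of subjective simultaneity (PSS): stimuli
first perceived as asynchronous come to feel synchronous.  Two robust
features of this *temporal recalibration* constrain any mechanistic account:
the effect grows with the adapter SOA only up to roughly 100–300 ms and then
plateaus (nonlinearity), and it differs between auditory-leading and
visual-leading adapters (asymmetry).  `avrecal` implements a family of six
trial-level observer models that compete to explain these features, a joint
maximum-likelihood pipeline that fits them to ternary temporal-order-judgment
(TOJ) data from a pre-test / exposure / post-test design, a model-agnostic
PSS analysis, and a synthetic-experiment generator so that every stage can
be exercised and validated without any empirical data.

Throughout, SOA is `s = t_A - t_V` in seconds: negative values mean the
auditory stimulus led.

## The measurement model

The arrival latency of each signal at the comparison stage is a fixed delay
plus an exponentially distributed random delay with time constant `tau_a`
(auditory) or `tau_v` (visual).  The measured SOA `m` is the difference of
arrival times, so given the physical SOA `s` and the observer's current
audiovisual bias `beta`,

$$p(m \mid s, \beta) = \frac{1}{\tau_A + \tau_V}
  \begin{cases}
  \exp[(m - (s+\beta))/\tau_V], & m \le s + \beta,\\[2pt]
  \exp[-(m - (s+\beta))/\tau_A], & m > s + \beta,
  \end{cases}$$

an asymmetric double-exponential peaking at `s + beta` with value
`1/(tau_a + tau_v)`.  `measurement_density()`, `measurement_cdf()`,
`measurement_quantile()` and `sample_measurements()` expose the density, its
closed-form CDF and inverse, and exact sampling (`m = s + beta + E_A - E_V`).
Modality-independent precision is the constraint `tau_a = tau_v`, under which
the distribution is symmetric.

The bias is dynamic: `beta_i = beta_pre + Delta_i`, where `Delta_i` is the
cumulative recalibration shift after exposure trial `i`; `beta_pre` is
restored at the start of every session's pre-test.

## Three bias-update rules

* **Causal inference** (`ci_*`).  On each exposure trial the observer
  entertains a common-cause scenario (`C = 1`, SOA prior `N(0, sigma_c1^2)`)
  and a separate-causes scenario (`C = 2`, `N(0, sigma_c2^2)`,
  `sigma_c2 > sigma_c1`).  Scenario-conditioned MAP estimates are combined by
  model averaging with the posterior probability of a common cause
  (`infer_soa()`), and the bias shifts toward reconciling measurement and
  percept: `Delta <- Delta + alpha * (s_hat - m)` (`ci_bias_update()`).
  Because the common-cause scenario retains influence at any measured SOA,
  this rule predicts non-zero recalibration even for clearly asynchronous
  adapters.
* **Asynchrony-contingent** (`ac_*`).  No Bayesian inference: the update
  compensates the raw measurement, scaled by the likelihood that the pair
  was physically simultaneous, `Delta <- Delta - p(m | SOA=0) * alpha * m`
  (`contingent_bias_update()`).  The likelihood is the double-exponential
  density at `s = 0` under the current bias, so updates die off
  exponentially with `|m|`: nonlinearity without inference, but no
  recalibration at large adapter SOAs.
* **Asynchrony-correction** (`corr_*`).  Recalibrate only when the
  measurement registers as asynchronous: `Delta <- Delta - alpha * m` when
  `|m| > c`, else unchanged (`correction_bias_update()`).  Updates *grow*
  with the adapter SOA — the qualitative opposite of the observed plateau —
  which is why this family serves as the comparison baseline.

Crossing the three rules with modality-specific versus modality-independent
latency precision yields the six models (`recal_model()`).  Free parameters
(Table: `model_parameters()`): `beta_pre`, `tau_a`/`tau_v` (or a common
`tau`), the causal-prior parameters `sigma_c1`, `sigma_c2`, `p_common`
(causal-inference models only), the simultaneity criterion `criterion`, the
lapse rate `lambda`, and the learning rate `alpha`.  A single criterion
parameter serves both the TOJ decision and the asynchrony-correction
exposure rule.

## The ternary TOJ task

The observer reports "auditory first", "simultaneous" or "visual first" by
comparing the SOA estimate to symmetric criteria at `±c`, with a lapse rate
`lambda` spread uniformly over the three responses.  For the two readout
families the estimate *is* the measurement, and the response probabilities
are closed-form in the measurement CDF (`toj_probs_readout()`).  Ties at the
criteria count as "simultaneous"; they have probability zero under the
continuous measurement distribution, so the convention only fixes
determinism.

For the causal-inference observer the estimate distribution has no closed
form.  `toj_probs_causal_inference()` implements the simulation estimator:
10,000 measurements per test SOA (by inverse-CDF transform of uniform
deviates, so that under a fixed seed the output is a smooth function of the
parameters — common random numbers), each mapped through the inference to an
estimate.  `toj_probs_ci_exact()` computes the same probabilities
deterministically: the estimate mapping `s_hat = f(m)` is tabulated, the
measurement-space decision regions `{f(m) > c}` and `{f(m) < -c}` are
located by sign-change detection with root refinement, and the response
probabilities are exact interval masses under the closed-form measurement
CDF.  This is the infinite-sample limit of the simulation estimator; the
test suite verifies that the two routes agree within Monte-Carlo error.  The
likelihood machinery uses the deterministic route, which removes simulation
noise from the objective and is orders of magnitude faster.

### What the observer knows about its own bias

The measurements are generated under the observer's current bias, but the
inference (and the readout) takes the measurement at face value: the
observer does not subtract its own bias.  This is what makes recalibration
observable — after the exposure phase the whole estimate distribution, and
with it the psychometric functions, is displaced by the accumulated shift.
An observer that corrected for its own bias would produce pre- and post-test
curves that never move, and `beta_pre` would be unidentifiable.  The
exception is the asynchrony-contingent *exposure* rule, whose simultaneity
likelihood is evaluated under the current bias (the rule is explicitly a
comparison of the measurement against what simultaneity would produce,
delays included).  The `observer_bias` argument of the causal-inference
functions exposes the assumed bias for exploration.

## Exposure phase and the post-test likelihood

`simulate_exposure()` runs one 250-trial exposure phase trial by trial under
any rule (a pure-R reference implementation with the exact estimate
mapping).  The likelihood needs the *distribution* of the cumulative shift,
so `approximate_shift_distribution()` simulates the phase `n_reps` times
(default 1000; C++ kernel, with the causal-inference estimate mapping
tabulated on a uniform grid over ±5 s and linearly interpolated — the
mapping saturates analytically, so clamping at the grid ends is exact),
fits a Gaussian by the sample mean and standard deviation, and discretises
it into 100 equal bins spanning triple the sample range
(`min - range` to `max + range`).  Bin weights are Gaussian densities at the
bin centres; the post-test likelihood integrates the per-session product of
response probabilities against them as a Riemann sum (density × bin width),
evaluated in log space with a log-sum-exp over bins
(`posttest_loglik()`).  A degenerate sample (zero spread, e.g. `alpha = 0`)
collapses to a point mass, under which the post-test term reduces exactly to
the pre-test likelihood of the post-test records — a limit the tests assert
to 1e-9.

The pre-test likelihood (`pretest_loglik()`) uses one shared curve at
`beta_pre` for all sessions.  `joint_loglik()` is their sum, with the
exposure noise drawn once from the seed (common random numbers), so it is
deterministic given `(params, seed)` and smooth in the parameters.

Synthetic experiments (`simulate_experiment()`) deliberately break the
symmetry with the likelihood: each session's post-test is generated at a
*single realised* trajectory's final shift — what one participant actually
experiences — while the likelihood integrates over the shift distribution.

## Fitting

`fit_recalibration()` maximises the joint log-likelihood under box
constraints with multiple starts.  Each search is staged: first the
parameters that shape the pre-test curve (everything except `alpha`) are
refined against the cheap closed-form pre-test likelihood; then the learning
rate is initialised on a coarse grid; then all parameters are polished
jointly.  Searches use the PORT quasi-Newton routines (`nlminb`) with
forward-difference gradients; pieces of the objective that are invariant to
the perturbed parameter (the estimate table, the decision regions, the
exposure simulation) are memoized, which makes gradient evaluation cheap.
Starting points are one data-driven moment start (plus, for the
causal-inference models, a second start on the other side of the
criterion/prior trade-off described below) and Latin-hypercube draws within
the bounds.  The `sigma_c1 < sigma_c2` ordering is enforced by optimising
the spread gap rather than `sigma_c2`.  Refitting with the same seed
reproduces the result exactly.

Fitting bounds (see `model_parameters()`) are plausibility ranges for human
audiovisual timing — e.g. `tau` in 5–500 ms, `criterion` in 1–500 ms,
`lambda` in 1e-4–0.2 (the positive lower bound keeps the likelihood finite),
`alpha` in 0–0.1 for the causal-inference and correction rules and 0–2 for
the contingent rule, whose rate multiplies a density (units 1/s) and so
absorbs a `1/(tau_a+tau_v)` scale.

`compare_recal_fits()` ranks fits of the same dataset by penalized
likelihood (AIC/BIC), reporting differences relative to the weakest model on
the half-deviance scale.  This is a deliberate simplification: a full
model-evidence comparison requires priors over parameters that are not part
of this package's scope; BIC differences are the standard large-sample
surrogate, and the documentation never presents them as marginal
likelihoods.

## Descriptive analysis

`fit_descriptive()` is the model-agnostic characterisation: the ternary
readout psychometric functions are fitted jointly to one session's pre- and
post-test with a shared shape (`tau_a`, `tau_v`, `criterion`, `lambda`) and
separate biases, so the curves may shift but not deform.  The PSS (`pss()`)
is the SOA maximising the probability of reporting "simultaneous", located
by a 1-ms grid over ±0.6 s with golden-section refinement; for
`tau_a = tau_v` it equals `-beta` exactly, and the lapse rate cannot move
it.  `analyze_recalibration()` assembles per-session PSS shifts
(recalibration effects) and their sum over sessions, the asymmetry index
(positive: more recalibration for visual-leading adapters).  Uncertainty
comes from a nonparametric bootstrap that resamples responses within each
(session, phase, test SOA) cell — preserving the design — with percentile
intervals; 1000 resamples by default.

## The synthetic-experiment generator

`experiment_design()` defaults to the study conditions this package
emulates: nine sessions at adapter SOAs 0, ±0.1, ±0.2, ±0.3, ±0.7 s; 15 test
SOAs (±0.5 s and −0.3 to 0.3 s in 0.05-s steps) × 20 repetitions per phase
(300 TOJs per phase); 250 exposure trials.  `generate_observer()` draws
ground-truth parameters uniformly within plausible ranges chosen to mirror
the between-participant spread reported for audiovisual ternary TOJ:
biases ±120 ms, time constants 20–120 ms, criteria 40–300 ms, lapse rates
0.5–6%, `p_common` 0.3–0.9, learning rates 0.003–0.02 (0.05–0.6 for the
density-scaled contingent rule).  These ranges are the generator's
definition of a realistic observer population; recovery results are
conditional on them.

What the generator does *not* emulate: session-order or fatigue effects,
dissipation of recalibration between top-up trials, criterion drift, and
the oddball-detection task itself.  Green recovery tests therefore show that
the pipeline is self-consistent at realistic signal-to-noise, not that real
data are this well-behaved.

## Numerical choices

* The scenario likelihoods `P(m | C)` (double-exponential likelihood
  integrated against a zero-mean Gaussian) are computed in closed form as
  two exponentially-modified-Gaussian terms via `pnorm`, in log space; the
  tests check them against adaptive quadrature to better than 1e-6 relative
  error.
* The scenario-conditioned MAP has an exact three-candidate solution
  (`-sigma^2/tau_v`, `sigma^2/tau_a`, or the likelihood peak `m - beta`,
  exactly one of which is admissible); a dense-grid search is kept as the
  test oracle.
* The estimate mapping is tabulated on 8001 points over ±5 s for the public
  decision-region function (4001 inside the fitting loop); region boundaries
  are always refined by `uniroot` on the exact mapping to 1e-11.
* The kink of the measurement density belongs to the left branch; both
  branches agree there, so this only fixes determinism.
* Estimates exactly at `±c` count as "simultaneous" (measure-zero).
* Dynamically unstable learning rates (possible for the contingent rule,
  whose effective per-trial gain is `alpha` times a density) are assigned
  log-likelihood `-Inf` rather than propagating non-finite simulations.

## Problem sizes used by the validation suite

The test suite runs the recovery studies at reduced scale: parameter
recovery uses 20 synthetic causal-inference observers, the full nine-session
design, five starts per fit, 200 exposure simulations per session inside the
likelihood, and capped optimizer iterations; model recovery uses five
observers per generating model with a single staged data-driven search per
candidate model, 60 exposure simulations and tighter caps.  The
Monte-Carlo psychometric operation is validated against its deterministic
limit separately, so the likelihood's accuracy inside these studies does not
depend on a per-evaluation simulation size.  These sizes are the package's
chosen trade-off between statistical resolution and a test suite that runs
in minutes; `recover_parameters()` and `recover_models()` accept larger
sizes for stand-alone studies.

## Known limitations

* **A criterion/prior identifiability ridge.**  At this design's data scale,
  widening the simultaneity criterion while weakening the common-cause prior
  (and raising the learning rate) produces nearly identical pre-test curves
  and recalibration patterns.  Maximum-likelihood estimates therefore wander
  along this ridge by a few tens of milliseconds in `criterion`, with
  compensating drifts in `p_common`, `sigma_c2` and `alpha`; `sigma_c2` is
  essentially unidentified once `sigma_c2^2/tau` exceeds the measurement
  range.  `beta_pre`, the time constants and the lapse rate recover well.
  The bracketed double start mitigates, but cannot remove, the ridge.
* Recalibration is assumed stable from the end of exposure through the
  post-test; dissipation is not modelled.
* The descriptive model is the shared-shape/shifted-bias account; a
  criterion-shift alternative is not implemented.
* Model comparison is penalized likelihood, not marginal likelihood.

## A minimal session

```{r example, eval = FALSE}
obs <- generate_observer("ci_ms", rng_seed = 1)
dat <- simulate_experiment(obs, rng_seed = 2)

fit <- fit_recalibration(dat, "ci_ms", n_starts = 5, rng_seed = 3,
                         control = list(n_reps = 200, maxit = 70))
summary(fit)
plot(fit)

alt <- fit_recalibration(dat, "ac_ms", n_starts = 5, rng_seed = 3,
                         control = list(n_reps = 200, maxit = 70))
compare_recal_fits(fit, alt)

analyze_recalibration(dat, n_boot = 200, rng_seed = 4)
```
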