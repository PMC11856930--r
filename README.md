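# avrecal — observer models of audiovisual temporal recalibration

`avrecal` fits and simulates trial-level observer models of cross-modal
temporal recalibration measured with ternary temporal-order judgments
(TOJ: "auditory first" / "simultaneous" / "visual first").  It is aimed at
computational psychophysicists studying how exposure to a constant
audiovisual asynchrony shifts the point of subjective simultaneity (PSS),
and why that shift is nonlinear in the adapter SOA and asymmetric between
auditory-leading and visual-leading adapters.

## The models

Arrival latencies of the auditory and visual signals are shifted
exponentials with time constants τ_A, τ_V, so the measured SOA
`m` (with `s = t_A − t_V`; negative = auditory lead) follows an asymmetric
double-exponential density peaking at `s + β`, where β is the audiovisual
temporal bias:

    p(m | s, β) = 1/(τ_A + τ_V) · exp[ (m − (s+β))/τ_V ]   for m ≤ s + β
                  1/(τ_A + τ_V) · exp[ −(m − (s+β))/τ_A ]  for m > s + β

Recalibration is the trial-by-trial accumulation of updates to β during a
250-trial exposure phase.  Three update rules are implemented:

* **causal inference** — Δ ← Δ + α(ŝ − m), where ŝ is the model-averaged
  Bayesian estimate combining a common-cause scenario (SOA prior
  N(0, σ²_C1)) and a separate-causes scenario (N(0, σ²_C2)), weighted by the
  posterior probability of a common cause (prior p_common);
* **asynchrony-contingent** — Δ ← Δ − p(m | SOA = 0) · α · m, the update
  scaled by the likelihood that the pair was physically simultaneous;
* **asynchrony-correction** — Δ ← Δ − α·m only when |m| exceeds the
  simultaneity criterion c.

Each rule comes with modality-specific (τ_A ≠ τ_V) or modality-independent
(τ_A = τ_V) latency precision, giving six models: `ci_ms`, `ci_mi`,
`ac_ms`, `ac_mi`, `corr_ms`, `corr_mi`.  TOJ responses compare the SOA
estimate to criteria ±c with lapse rate λ.  Models are fitted jointly to
pre- and post-test judgments of all sessions by maximum likelihood, with the
post-test likelihood integrating over the Monte-Carlo-simulated distribution
of the cumulative shift (Gaussian fit, 100-bin Riemann sum).

## Worked example

Simulate a nine-session experiment (15 test SOAs × 20 repetitions in each of
pre- and post-test, adapters 0, ±0.1, ±0.2, ±0.3, ±0.7 s) from a known
causal-inference observer, refit it, and compare against the
asynchrony-correction baseline:

```r
library(avrecal)
obs <- generate_observer("ci_ms", rng_seed = 11)
dat <- simulate_experiment(obs, rng_seed = 12)     # 5400 TOJ trials

fit <- fit_recalibration(dat, "ci_ms", n_starts = 3, rng_seed = 13,
                         control = list(n_reps = 150, maxit = 50))
summary(fit)
#> Model ci_ms: logLik -1929.03, AIC 3876.1, BIC 3935.4 (5400 trials)
#>   estimates:
#>  beta_pre     tau_a     tau_v  sigma_c1  sigma_c2  p_common criterion    lambda
#>   -0.0359    0.0222    0.0730    0.0287    0.3561    0.7089    0.1125    0.0211
#>     alpha
#>    0.0310
```

(The generating observer had `beta_pre = -0.054`, `tau_a = 0.020`,
`tau_v = 0.071`, `lambda = 0.021`: the bias, time constants and lapse rate
recover closely; the criterion/prior parameters sit on a known shallow
trade-off, discussed in the vignette.)

```r
alt <- fit_recalibration(dat, "corr_ms", n_starts = 2, rng_seed = 13,
                         control = list(n_reps = 150, maxit = 50))
compare_recal_fits(fit, alt)
#> Observer-model comparison (penalized likelihood; strongest first)
#>     model n_par   loglik     aic     bic d_loglik log_lr_vs_worst
#> 1   ci_ms     9 -1929.03 3876.05 3935.40  1157.83         1144.94
#> 2 corr_ms     6 -3086.85 6185.71 6225.27     0.00            0.00
```

The correction model cannot reproduce this observer's recalibration plateau,
and loses by over 1100 half-deviance units.  The model-agnostic analysis
shows the signature pattern — PSS shifts tracking the adapter SOA for small
asynchronies, collapsing at ±0.7 s, with a lateral offset set by the bias:

```r
analyze_recalibration(dat, n_boot = 100, rng_seed = 14)
#> Recalibration summary (descriptive shifted-curve fits)
#>   session adapter_soa_s pss_pre pss_post  effect ci_lower ci_upper
#> 1       1          -0.7  0.0736   0.0544 -0.0193  -0.0349  -0.0018
#> 2       2          -0.3  0.1116  -0.2722 -0.3838  -0.4017  -0.3591
#> 3       3          -0.2  0.0995  -0.2292 -0.3287  -0.3493  -0.3070
#> 4       4          -0.1  0.0984  -0.1047 -0.2031  -0.2241  -0.1844
#> 5       5           0.0  0.0916  -0.0313 -0.1229  -0.1427  -0.1074
#> 6       6           0.1  0.1044   0.0786 -0.0258  -0.0522  -0.0067
#> 7       7           0.2  0.0639   0.1292  0.0654   0.0419   0.0881
#> 8       8           0.3  0.0946   0.1100  0.0154  -0.0056   0.0365
#> 9       9           0.7  0.1227   0.1227  0.0000  -0.0238   0.0104
#> Asymmetry index: -1.0027 s [-1.0728, -0.9478] (95% bootstrap, 100 resamples)
```

Negative effects mean the PSS moved toward auditory lead.  The negative
asymmetry index reflects this observer's much greater recalibration for
auditory-leading adapters, as expected from its precise auditory / imprecise
visual latencies.

See `vignette("recalibration-models", package = "avrecal")` for the model
derivations, fitting machinery, numerical choices and known limitations.

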