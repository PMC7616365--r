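# gcdf

Gated cascade diffusion models of decision making, motor preparation,
and motor execution, for researchers who analyse choice reaction-time
tasks with electromyographic (EMG) decomposition of the response.

EMG lets a reaction time be split at the onset of the response-muscle
burst into a premotor time (PMT) and a motor time (MT), and reveals
*partial bursts* — subthreshold muscle activations that do not produce
the response. `gcdf` implements a model family that explains all three
at the single-trial level:

* a decision stage accumulating evidence as a diffusion,
  `dx = v dt + sigma dW`;
* a motor-preparation stage smoothing the decision variable with a
  leaky filter `dy = lambda (x - y) dt` — the steady-state
  approximation of a Kalman–Bucy filter with gain
  `lambda' tanh(lambda' t)` recovering the decision variable from
  transmission noise (`lambda = Inf` turns the filter off, giving the
  unfiltered gated cascade as an exactly nested special case);
* a motor-execution stage in which tonic gating inhibition `g` is
  subtracted from the prepared signal (`zL = max(-y - g, 0)`,
  `zR = max(y - g, 0)`) and the response fires when a neural drive
  reaches the threshold `r`.

PMT = `Te + t_g` (with `t_g` the last time the winning drive becomes
positive before threshold) and MT = `(t_hit - t_g) + Tr`. The package
simulates trials and whole experiment-shaped datasets with between-trial
parameter variability, summarizes observed and simulated tables
identically (six trial types, quantile probability functions, burst
statistics, PMT–MT correlations, time-locked mean neural drive), and
fits models by minimizing the quantile-binned likelihood-ratio
statistic

    G2 = 2 sum_ijkl n_ijkl log[ (n_ijkl / n_i) / (n'_ijkl / n'_i) ]

with differential evolution under common random numbers, followed by
AIC/BIC comparison (`AIC = G2 + 2m`, `BIC = G2 + m ln N`) and exact
binomial model-selection tallies across subjects.

## Worked example

```r
library(gcdf)

# the motion-discrimination template: 6 coherence levels x 192 trials
design <- make_design("exp1")
preset <- preset_params("exp1", "GCDF", "full")
tab <- simulate_dataset(preset$params, preset$map, design, seed = 42)

correct <- tab[!tab$omitted & tab$accuracy, ]
round(tapply(correct$pmt, correct$condition, mean)[design$condition], 3)
#>     0  0.05  0.08  0.12   0.2   0.4
#> 1.123 1.022 0.992 0.935 0.769 0.507
round(burst_stats(tab)$prop_burst, 3)
#> [1] 0.287 0.263 0.216 0.219 0.119 0.016
```

Mean premotor time and the proportion of correct trials containing at
least one partial burst both fall as motion coherence rises — the
difficulty signatures the model family was built to capture. A single
noise-free trial shows the closed-form event chain (drift 0.2, gate
0.05, threshold 0.02, residuals 0.3/0.1 s):

```r
ramp <- gcdf_params("GCD", g = 0.05, r = 0.02, Te = 0.3, Tr = 0.1,
                    sigma = 0, sigma_free = TRUE)
rec <- simulate_trial(ramp, drift_linear(1), 0.2, correct_channel = "upper")
c(pmt = rec$pmt, mt = rec$mt, rt = rec$rt)
#>   pmt    mt    rt
#> 0.550 0.201 0.751
```

(`t_g = g/v = 0.25` s, threshold at `(g+r)/v = 0.35` s, on a 1 ms
grid.) Fitting recovers generating parameters from synthetic data:

```r
truth <- preset_params("exp1", "GCDF", "raw")
obs <- generate_observed_dataset(truth$params, truth$map, design,
                                 seed = 101)$table
spec <- tighten_bounds_from_data(spec_linear_coherence("GCDF", raw = TRUE),
                                 obs)
fit <- fit_model(obs, spec, design, n_sim = 5000, n_pop = 12, n_gen = 12,
                 F_range = c(0.35, 0.7),
                 explore = list(n_sim = 1000, n_gen = 18), seed = 102)
fit$par
```

A thin command-line front end (`inst/cli/gcdf`) exposes `simulate`,
`summarize`, `fit`, `recover`, `compare` and `fixtures` subcommands
over the same functions; see `?gcdf_cli`.

## Scope

The package starts from trial-level PMT/MT/burst events: raw EMG
voltage processing (filtering, onset detection, artifact rejection) is
out of scope, as are EEG signals, urgency/collapsing-bound extensions,
and continuous movement kinematics. See the methods vignette
(`vignettes/gcdf-models.Rmd`) for the model's assumptions, numerical
conventions, and the design decisions behind the fitting procedure.
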