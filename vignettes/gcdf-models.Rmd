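---
title: "Gated cascade diffusion models: simulation and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gated cascade diffusion models: simulation and fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`gcdf` simulates and fits a cascade architecture for two-choice reaction
time in which decision making, motor preparation, and motor execution are
distinct but continuously coupled stages.

1. **Decision.** Evidence accumulates as a drift diffusion
   $dx = v\,dt + \sigma\,dW$, $x(0) = x_0$, with drift $v$ set per
   experimental condition by a *drift map* (see below) and diffusion
   coefficient $\sigma$ fixed at 0.1: the model is invariant under a
   common rescaling of all evidence-unit parameters, so $\sigma$ only
   fixes the measurement scale.
2. **Motor preparation.** The decision variable is transmitted
   continuously to a preparation stage that smooths it with a leaky
   first-order filter $dy = \lambda (x - y)\,dt$, $y(0) = x_0$. The
   filter output is an exponentially weighted average of the recent past
   of $x$; its mean lags the mean of $x$ by $1/\lambda$ seconds. The
   filter is the steady-state form of a Kalman–Bucy filter recovering a
   drifting diffusion from white transmission noise, whose exact
   time-varying gain is $\lambda' \tanh(\lambda' t)$
   (`kalman_gain()`); the `GCDF_KB` variant simulates that exact form
   with observation noise of scale $\xi$. As $\lambda \to \infty$ the
   filter disappears and the model reduces to the unfiltered gated
   cascade (`GCD`).
3. **Motor execution.** Tonic gating inhibition $g$ is subtracted from
   the prepared signal before it can excite the muscles: the *neural
   drive* to the two response channels is
   $z_L = \max(-y - g, 0)$, $z_R = \max(y - g, 0)$. The overt response
   occurs when a drive first reaches the response threshold $r$.

Muscular excitation (EMG) begins whenever a drive becomes positive, so
the model partitions reaction time the way EMG recordings do. The
*premotor time* is $\mathrm{PMT} = T_e + t_g$, where $t_g$ is the last
time the winning drive becomes positive before reaching threshold and
$T_e$ is a residual pre-motor latency (stimulus encoding and related
processes). The *motor time* is $\mathrm{MT} = (t_{hit} - t_g) + T_r$,
with $T_r$ the electromechanical residual. $\mathrm{RT} =
\mathrm{PMT} + \mathrm{MT}$ holds exactly for every simulated trial.
Positive drive excursions that die out before threshold are *partial
bursts* — subthreshold muscle activations. The filter is what keeps
their number realistic: an unfiltered cascade transmits all the
diffusion noise to the muscles and produces far too many of them.

## Parameters

| Parameter | Units | Meaning |
|---|---|---|
| `v` / drift map | evidence/s | condition-specific mean drift |
| `sigma` | evidence/√s | diffusion coefficient, fixed 0.1 |
| `x0` | evidence | starting point (signed) |
| `g` | evidence | gating inhibition |
| `r` | evidence | response threshold on the neural drive |
| `Te`, `Tr` | s | residual latencies added to PMT and MT |
| `lambda` | 1/s | filter leak; `Inf` = unfiltered |
| `xi` | evidence/√s | transmission-noise scale (`GCDF_KB`) |
| `sv` | evidence/s | SD of Normal between-trial drift variability |
| `sx0`, `sTe`, `sTr`, `slambda` | as base | ranges of Uniform between-trial variability |

All parameters except `x0` and the drift criterion `dc` are constrained
nonnegative, and the Uniform ranges may not exceed 180% of `g`, `Te`,
`Tr`, `lambda` respectively — which also guarantees that realized
residual latencies and leaks stay positive, so the sampler asserts
rather than clamps.

Drift maps (`drift_linear()`, `drift_criterion()`,
`drift_conditions()`) encode the three condition-to-drift rules used
across the four experiment templates: linear in motion coherence
($v = k \cdot \mathrm{coh}$), numerosity against a criterion of 50
dots, and free per-condition drifts. Two genuinely open conventions are
resolved as follows and exposed as options:

* **Drift criterion `dc`.** In the numerosity form the signed constant
  is applied additively to the drift, $v = v_1(\mathrm{count} - 50) +
  dc$, the standard drift-criterion convention.
* **Numerosity drift variability.** When drift variability varies with
  count, the default rule is $sv(\mathrm{count}) = \sqrt{\eta_0^2 +
  (\sigma_1 \mathrm{count})^2}$ (`sv_rule_numerosity()`), reflecting
  approximate-number representations whose spread grows with magnitude;
  any function of the count can be plugged in instead.

## Numerics

The simulator (`simulate_trial()`, `simulate_dataset()`) uses explicit
Euler–Maruyama integration at `dt = 0.001` s, matching the 1 ms
granularity of the behavioural and EMG data the model is meant for.
Choices embedded in that scheme:

* **Filter stability.** The per-step filter gain `lambda * dt` (and the
  Kalman–Bucy gain) is capped at 1. Below the cap the update is exactly
  the explicit Euler step; above it, `y` tracks `x` with a one-step
  delay, so arbitrarily large finite leaks degrade gracefully into the
  unfiltered model instead of becoming unstable. `lambda = Inf`
  bypasses the filter entirely, making the nesting of the unfiltered
  model exact (bit-identical trials under matched seeds).
* **Events on the grid.** Threshold attainment is the first grid point
  with $z \ge r$ (no sub-step interpolation). $t_g$ and burst onsets
  use the last grid point with zero drive before the excursion, which
  makes the aligned drive exactly zero at lag 0 in
  `mean_neural_drive()`. Every positive excursion of at least
  `min_burst_duration` (default one step) counts as a partial burst;
  larger values emulate artifact rejection.
* **Observation-noise discretization** (`GCDF_KB`): the per-step
  observation is $\tilde x_n = x_n + (\xi/\sqrt{dt})\,\mathcal N(0,1)$,
  the standard continuous-white-noise convention.
* **Seeds.** Every trial has its own seed derived from the master seed,
  so single trials are regenerable in isolation and matched-seed
  comparisons across parameter settings (scaling, nesting, filter
  on/off) reuse identical noise streams per trial index. Draws with zero
  scale consume no random numbers, keeping streams aligned between raw
  and degenerate settings.
* **Deadline.** Trials not finished by the design deadline (5 s for the
  motion template, 4 s otherwise, configurable) are omissions: excluded
  from every downstream statistic, with the rate logged per condition.

## Summaries

Observed and simulated tables are summarized identically
(`trial_type_proportions()`, `quantile_summary()`, `burst_stats()`,
`pmt_mt_correlation()`). Trials are classified into six types by
response accuracy and first-burst channel (`pureC`, `CC`, `IC`,
`pureI`, `II`, `CI`); bursts in both channels are retained but only the
first burst's channel feeds classification. Quantiles use linear
interpolation between closest ranks (sorted value $x_{(k)}$ at
probability $(k-1)/(n-1)$); the rule is fixed and documented because
several conventions exist. Incorrect-response quantiles are reported
only when every condition has at least 10 errors (configurable),
mirroring the usual display rule. Partial-burst latencies are
referenced to stimulus onset ($T_e$ plus the excursion onset); the
per-condition mean is available both trial-weighted and as a mean of
subject means. The PMT–MT correlation uses correct trials by default.
`mean_neural_drive()` extends the winning channel's drive past
threshold with a linear decay of 0.15 evidence/s (floored at zero),
aligns trials at $t_g$ and averages; its rising slope over the first
50 ms tracks task difficulty.

## Fitting

`fit_model()` minimizes the likelihood-ratio statistic
$$G^2 = 2 \sum_{ijkl} n_{ijkl}
  \log\frac{n_{ijkl}/n_i}{n'_{ijkl}/n'_i}$$
over condition $i$, trial type $j$, and six PMT and MT bins $k, l$
bounded by the observed quantiles (.1, .3, .5, .7, .9), computed per
condition and response class. Implementation decisions where the
construction is genuinely open:

* Boundaries come from the observed data only, per condition and
  response class; cells with fewer than 5 trials collapse to a single
  bin and cells below 20 trials to a median split only.
* A trial exactly on a boundary goes to the lower bin.
* A cell with observed mass but zero simulated mass has its simulated
  proportion floored at $1/(2 n'_i)$ (half a trial), keeping $G^2$
  finite without touching populated cells.
* Candidates are evaluated with *common random numbers*: one evaluation
  seed fixes the per-trial-index noise streams for every candidate, so
  the objective is a deterministic function of the parameters and the
  whole fit is reproducible from its master seed.
* Constraint violations (caps, nonnegativity) incur a large additive
  penalty rather than a reparameterization, keeping the bounds
  interpretable.

Minimization is by differential evolution with binomial crossover.
The default strategy is `rand-to-best/1/bin` with `CR = 0.6` and
`F = 0.6`: mutants are pulled toward the incumbent best while retaining
population diversity, and the moderate crossover rate lets single
coordinates improve inside the curved trade-off valleys this objective
has (residual latency against filter delay against gate). Pure
`best/1/bin` collapses the population prematurely here, and
`rand/1/bin` needs several times more evaluations; both remain
available. An optional exploration phase runs the same DE with a
smaller simulation budget first and seeds the full-budget phase with
its final population; small-budget landscapes are slightly distorted
(the zero-cell floor is more forgiving when $n'_i$ is small), which is
exactly why the reported parameters and $G^2$ always come from the
full-budget objective. Two exact accelerations exploit the objective's
structure: per-condition *racing* (the statistic is a sum of
nonnegative per-condition divergences, so a challenger is abandoned the
moment its partial sum exceeds the fitness it must beat — no
approximation, since such a challenger is rejected either way), and a
deterministic compass-search *polish* after DE (coordinate probes with
shrinking relative steps, pattern moves along successful sweep
directions, and step-cycle restarts while probes keep paying off),
which removes residual optimizer variance at the basin bottom. For specs without residual-latency variability,
`tighten_bounds_from_data()` shrinks the `Te` and `Tr` upper bounds to
the observed minima of PMT and MT — valid bounds by construction, since
every premotor time contains `Te` and every motor time contains `Tr`. $G^2$ converts to $\mathrm{AIC} = G^2 + 2m$ and
$\mathrm{BIC} = G^2 + m \ln N$ with $m$ the number of free parameters
and $N$ the observations entering $G^2$. Across subjects,
`model_selection_tally()` applies the exact two-sided binomial test at
$\alpha = .05$ (for 18 subjects, 14 or more must favour a model;
`min_significant_count()`).

## What the synthetic data do and do not show

`make_design()` and `generate_observed_dataset()` emulate the four
study layouts (six coherence levels × 192 trials; eight numerosity
bins; three memory strengths plus new items; four word-frequency levels
plus pseudowords) with the stated between-trial variability
distributions, and `preset_params()` carries the published group-average
full-model parameters. Per-condition trial counts for the non-motion
templates are not part of the published descriptions and default to 192
to parallel the motion task. Synthetic cohorts jitter a truth parameter
set with a lognormal coefficient of variation of about 0.1 — a chosen,
not estimated, between-subject spread. Synthetic tables contain none of
the nuisance structure of real EMG: no artifactual bursts, no onset
detection noise, no trial rejection. Passing recovery tests therefore
demonstrates that the fitting machinery identifies the model from data
the model itself generated — a necessary condition, not evidence about
real recordings.

## Problem sizes used by the test suite

The packaged tests run parameter recovery on a synthetic truth built
from the motion-template filtered-model preset with variability zeroed:
6 conditions × 192 observed trials, fitted with 5,000 simulated trials
per condition per evaluation, a 12-member population, an 18-generation
exploration phase at 1,000 trials per condition, 12 full-budget
generations with the mutation factor dithered in [0.35, 0.7], and a
350-probe compass polish, repeated over three master seeds. Ordering checks
(difficulty effects on PMT, MT and burst statistics; filter effects on
burst rates and latencies) use 50,000 trials per condition; correlation
and nesting checks use 10^4–10^5 trials. These sizes are the package's
choices for a desk-scale validation; reference fits in the literature
of this model class use 20,000 simulated trials per condition and far
larger optimization budgets.

## Limitations

* Raw EMG signal processing (filtering, onset detection, artifact
  rejection) is out of scope: the package starts from trial-level PMT,
  MT and burst events.
* No urgency signals or collapsing bounds; no refractory period after a
  partial burst; no continuous force or kinematics.
* Between-trial variability in the leak uses a Uniform range purely by
  convention, as no theory constrains its shape.
* The fit objective treats trials as exchangeable within condition;
  sequential effects are not modeled.
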