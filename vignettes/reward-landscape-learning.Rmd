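---
title: "Modelling reinforcement-based sensorimotor learning on reward landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reinforcement-based sensorimotor learning on reward landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewardscape)
```

## The problem

When a reaching movement earns only binary feedback — reward or nothing —
the learner has no error vector to follow. What it does have is a
*reinforcement landscape*: the mapping from motor action (here, reach
angle) to the probability of reward. `rewardscape` implements a minimal
model of how the sensorimotor system climbs such a landscape using nothing
but movement variability and the most recent success, together with the
analysis tools needed to compare that model with trial-by-trial reaching
data.

Reach angles are expressed as z-scores relative to each individual's
baseline behaviour: 0 is the mean baseline reach angle, 1 is one baseline
standard deviation clockwise. Defining landscapes on this axis equates the
experienced gradient across individuals with different intrinsic motor
variability.

## The landscapes

Two families of piecewise-linear landscapes are built in.

**Single-gradient landscapes** (`exp1_landscape()`) rise linearly from an
x-intercept through the baseline point (probability 1/3 at z = 0) to a
plateau between 3 and 6 z-scores, and are zero elsewhere. The steep
variant has slope 2/9 per z-score and plateau 1; the shallow variant has
slope 1/9 and plateau 2/3. The rising segment is
$(m/3 - 1/9)\,\theta + 1/3$ with peak rate $m$, so the x-intercept
$-3/(3m-1)$ is forced to $-1.5$ (steep) and $-3$ (shallow).
Counterclockwise variants are exact mirror images about 0.

**Valley landscapes** (`exp2_landscape()`) place the learner between a
steep slope rising in one direction and a shallow slope rising in the
other, with plateaus 1 and 2/3 respectively, again spanning 3–6 z-scores
on each side.

```{r}
L <- exp1_landscape("steep", "CW")
reward_probability(L, c(-1.5, 0, 1.5, 4.5, 7))
```

At jump discontinuities (the outer plateau edges) the boundary point takes
the larger one-sided value, i.e. plateau intervals are closed toward the
rewarded region. This matches the defining inequalities of both the
clockwise and counterclockwise forms and keeps the mirror identity
$R_{\mathrm{mirror}}(\theta) = R(-\theta)$ exact at every point, which the
test suite asserts.

## The learning model

Three parameters: an update proportion $\alpha$, motor noise SD
$\sigma_m$, exploration noise SD $\sigma_e$. On trial $n$ the executed
angle is

$$\theta_n \sim \mathcal N\!\left(\bar\theta^{aim}_n,\; \sigma_n^2\right),
\qquad
\sigma_n^2 = \begin{cases}
\sigma_m^2 & \text{previous reach rewarded}\\
\sigma_m^2 + \sigma_e^2 & \text{previous reach unrewarded,}
\end{cases}$$

and the intended aim moves only after a rewarded reach:
$\bar\theta^{aim}_{n+1} = \bar\theta^{aim}_n +
\alpha(\theta_n - \bar\theta^{aim}_n)$; after a failure the aim is
unchanged. Gradient ascent is implicit: exploration samples the
neighbourhood, and successes — which are more frequent uphill — drag the
aim uphill.

Sessions follow a 50/350/50 schedule (baseline / reinforced / washout).
Feedback-free trials are treated as *successes for the variance gate but
never update the aim*: the absence of feedback is not a failure signal, so
baseline and washout reaches carry motor variance only. This choice also
produces the retention of the adapted aim through washout that the
no-update rule implies. The first reinforced trial therefore starts with
variance $\sigma_m^2$.

### Canonical parameter values

The package defaults are $\alpha = 0.40$, motor **variance** 0.81 and
exploration **variance** 0.90 in baseline-SD units, i.e.
$\sigma_m = 0.9$ and $\sigma_e = \sqrt{0.90} \approx 0.949$. The variance
parameterization is deliberate: it is the unique reading under which the
package's expected-reward optima (3.95 / 3.76 / ±3.95, below) and cohort
learning-rate constants ($\lambda \approx 27$ steep, $\approx 46$
shallow) jointly land on the reference values this model class is known
to produce (3.96 / 3.8 / ±3.96 and 28.0 / 49.6). Reading the same
numerals as SDs misses all four: the optima come out 3.84 / 3.78 and the
time constants 32 / 54. `model_params()` takes SDs, so supply
`sigma_m = sqrt(v)` to specify a variance `v`.

```{r}
model_params()
```

### Simulation engine

`simulate_cohort()` advances all individuals in lockstep, one vectorized
draw per trial, so a 100,000-individual session costs seconds;
`keep = "mean"` drops the per-individual matrices for large cohorts. The
run is bit-reproducible under its master seed. Individuals within a
cohort share the per-trial draw stream and are therefore not separately
re-runnable; `simulate_participant(seed = )` gives a standalone
reproducible series.

```{r}
co <- simulate_cohort(landscape = L, n = 200, seed = 1)
co
fit_exponential(co)
```

## Expected reward and the optimal aim

For an intended aim $\bar\theta^{aim}$ the probability of reward is the
integral of the Normal reach density against the landscape,

$$E[U](\bar\theta^{aim}) = \int p(\theta \mid \bar\theta^{aim}, \sigma^2)\,
R(\theta)\, d\theta,
\qquad
\sigma^2 = \sigma_m^2 + \bigl(1 - R(\cdot)\bigr)\sigma_e^2 .$$

Where the variance formula is evaluated is a genuine design fork. The
package default evaluates $R(\cdot)$ at the *intended aim*: $\sigma^2$ is
then a single number per aim, the kernel is a proper density, and the
integral is a true convolution — consistent with $\sigma^2$ entering
$E[U](\bar\theta^{aim}, \sigma^2)$ as a scalar argument, and the only
variant that reproduces the reference optima. The alternative — variance
varying with the integration point, which makes the kernel unnormalized
(no renormalization is applied) — is kept behind
`variance_at = "integrand"` for comparison; it shifts the steep optimum
to ≈ 3.84.

Numerics: trapezoidal integration on a grid of spacing 0.005 over
[−12, 12] (the support ±6 plus a ≥4-SD margin, which `check_grid()`
enforces; coarser than 0.05 is rejected). The argmax over a 0.005-spaced
aim grid is refined by golden-section search, and halving the spacing
moves the optimum by < 0.01 (asserted in the tests). A maximum that is
flat over more than 0.25 z-score, or split across disjoint plateaus, is
reported as non-unique via a warning and broken toward the smallest
|aim|.

```{r}
optimal_aim(exp1_landscape("steep", "CW"))
optimal_aim(exp1_landscape("shallow", "CW"))
optimal_aim(exp2_landscape("CCW"))
```

## Analyses

**Learning rate.** `fit_exponential()` fits
$\theta_i = a(1 - e^{-i/\lambda})$ to the mean curve over reinforced
trials by nonlinear least squares (Levenberg–Marquardt), multi-started
over $\lambda \in \{5, 20, 50, 100, 200\}$. The index starts at $i = 1$
on the first reinforced trial, so $\lambda$ is in units of reinforced
trials. A flat curve leaves $\lambda$ meaningless; the fit is then
flagged unidentifiable rather than failing.

**Bootstrap inference.** `bootstrap_lambda()` resamples *participants*
(not trials) with replacement — the standard unit for between-subject
inference — averages each resample, refits, and reports the posterior
spread of $\lambda$; with two groups, the one-tailed probability that
group A did not learn faster is the mass of the
$\lambda_B - \lambda_A$ difference distribution at or below zero.
Resamples whose fit fails are retried from the multi-start, else dropped
and counted.

**Classification.** `classify_final()` averages the last 100 reinforced
trials. On single-gradient landscapes, means at or above the 1.0 z-score
cutoff mark learners (the cutoff that separates the bimodal final-angle
distribution; 0.5 and 1.5 serve as robustness checks). On valley
landscapes the sign distinguishes steep from shallow learners after
sign-flip pooling (`pool_sign_flip()` negates angles of
counterclockwise-rising landscapes so the steep slope is always at
positive z).

**Early exploration.** `nth_success_prediction()` conditions final
classification on whether an individual's Nth success lay on the steep
(z > 0) or shallow (z < 0) slope; a success at exactly 0 belongs to
neither and is skipped. Empty conditioning sets yield `NA`, not 0.

**Variability by history.** `variability_by_history()` bins consecutive
angle changes by the preceding outcome. Under a frozen aim
($\alpha = 0$) the closed forms $\sqrt2\,\sigma_m$ (after success) and
$\sqrt2\sqrt{\sigma_m^2+\sigma_e^2}$ (after failure) hold and anchor the
tests. The baseline bin uses the last 26 baseline trials (trials 25–50
of the reference protocol), so per-participant estimates are noisy by
construction; average over participants before interpreting.

**Contingency tables.** `contingency_test()` is the two-sided Fisher
exact test (delegated to `stats::fisher.test`); the test suite checks it
against a brute-force hypergeometric enumeration.

## Calibration

`initial_guess_sigmas()` inverts the closed forms above to seed the
fitter; mixed reinforcement histories bias the motor guess upward (the
after-success bin then mixes variance regimes), which is why these are
starting values only. `fit_parameters()` minimizes the summed squared
error between simulated and target mean curves — both single-gradient
conditions jointly — using a coarse grid followed by Nelder–Mead. Every
objective evaluation reuses the same seed (common random numbers), which
removes resampling jitter between candidate parameter sets; the residual
objective noise at the default 2,000 simulated individuals per evaluation
is small enough for the simplex to recover generating parameters within
±0.1 (asserted in the acceptance tests at 1,500 per evaluation against
targets from 4,000-individual cohorts). Flat targets are flagged:
$\alpha$ is unidentifiable when nothing is learned. Parameter spread is
available by refitting on participant-resampled targets
(`n_boot`, `target_matrices`).

## Replication scenarios

The scenario runners exercise the same learner outside the core protocol,
in native units (degrees or mm), with schedules as explicit configuration
— their defaults are plausible round numbers, not reproductions of any
specific published schedule, and the properties asserted about them are
qualitative:

- `run_gradual_rotation()`: a reward window stepped away from the
  displayed target; the cohort tracks the ramp approximately linearly.
- `run_shifted_cursor()`: a skewed random cursor shift (shifted gamma;
  mean `shift_location`, skewness $2/\sqrt{\mathrm{shape}}$); the greedy
  learner compensates but settles short of the hit-maximizing position.
- `run_rect_target_2d()`: a long, thin target; successes anywhere along
  the length update the aim there, so the aim random-walks along the
  task-irrelevant axis (positive lag-1 autocorrelation) while staying
  pinned across the task-relevant one. Noise is isotropic with the same
  scalar $\alpha$ per axis — the minimal assumption, since nothing here
  constrains a 2-D noise covariance.
- `run_variability_sweep()` and `run_initial_reward_sweep()`: $\lambda$
  falls as either noise SD grows (more exploration, faster ascent), and
  the baseline reward probability of the shallow landscape moves
  $\lambda$ only marginally next to the steep-vs-shallow gap.

## What the synthetic data does and does not show

The generator *is* the model: simulated cohorts exhibit exponential
learning curves, learner/non-learner splits, history-dependent
variability, and steep-slope preference because the success-gated update
produces them. Passing tests therefore validate the implementation and
the internal consistency of the analyses, not the model's adequacy for
any particular behavioural dataset: real reaching data add drifts,
fatigue, strategy shifts, lapses and non-Normal noise that the generator
deliberately omits. Analyses accept recorded trial tables in the same
format (`read_trials()`) precisely so that the identical pipeline can be
applied to real data.

## Problem sizes and numerical choices

Simulation sizes used by the checks: 100,000 individuals per condition
for the headline time constants in `scripts/acceptance.R` (matching the
cohort size at which those constants were defined), 10,000 in the test
suite's learning-rate check, 3,000–4,000 per cell for sweeps and
classification frequencies, and 60 replicate 40+40 cohort pairs for the
steep-faster-than-shallow comparison. These sizes put Monte-Carlo error
well inside the asserted tolerances (the fitted $\lambda$ of a
10,000-individual cohort varies by a few tenths of a trial across
seeds). Degenerate inputs are handled explicitly: zero-width targets,
empty history bins, flat curves and empty trial files raise errors,
`NA`s or flags rather than silent numbers.

## Known limitations

- The learner is phenomenological: no error-based term, no savings, no
  use-dependent plasticity, no reaction/movement-time structure.
- Landscapes are piecewise-linear in z-space; graded (non-binary) rewards
  and nonlinear reward gradations are out of scope.
- The exploration gate is binary (last outcome only), while the
  expected-reward integral lets exploration scale continuously with
  reward probability; the two are consistent only in the regimes where
  reward probability is locally flat.
- Cohort members share one draw stream (see above); per-individual
  reproducibility requires `simulate_participant()`.
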