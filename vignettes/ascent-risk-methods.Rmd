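---
title: "Methods: personality-informed barrier-ascent risk assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personality-informed barrier-ascent risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gobypass)
```

## The model

`gobypass` predicts whether an individual benthic fish ascends an in-stream
barrier by combining a deterministic decision matrix with a statistical
layer that explains the matrix's output.

For a fish with total length $TL$ (cm) and trait indices
$(B, A, S)$ — boldness, activity, asociability — assessed against a barrier
with maximum near-bottom flow velocity $v_{\max}$ (m/s) and worst
pool-to-pool gap $g_{\max}$ (m):

* **Decision 1 (swimming)**: critical swimming speed
  $U_{crit} = a + b \cdot TL$ must strictly exceed $v_{\max}$. $U_{crit}$ is
  the maximum *sustained* speed, so this is a conservative criterion for
  holding position against the flow.
* **Decision 2 (endurance)**: endurance at the limiting flow follows the
  published round-goby relationship
  $\log_{10} E = c_v\, v + c_L\, TL + c_0$ with $E$ in minutes and $v$ in
  cm/s. Treating $U_{crit}$ as ground speed, the traversable distance
  $d = 60 \cdot U_{crit} \cdot E$ must strictly exceed $g_{\max}$: the fish
  must be able to reach the next resting pool before exhausting itself.
* **Decision 3 (personality)**: each trait is compared against its
  invasion-front population mean; the fish "intends" to ascend iff at least
  $k$ of the 3 traits strictly exceed their thresholds ($k = 2$ by default).
  The rule is compensatory and unweighted — it is deliberately blind to
  *which* traits are above average.

The overall outcome is the conjunction of the three decisions. All
comparisons are strict: a value exactly at its threshold fails, consistent
with the thresholds being defined as "higher values than the mean".

### Assumptions

* $U_{crit}$ increases linearly with body length across the sizes of
  interest (juvenile-to-adult range). This is well supported for small
  benthic fish but breaks down near a species' maximum size.
* The endurance relationship is extrapolated to the assessed cohort's
  length range; its published calibration covers roughly 9–15 cm.
* The invasion-front trait means are meaningful thresholds, i.e. the mean
  is a representative center for each trait distribution. `moment_check()`
  exists precisely to audit this: it flags $|$skewness$| > 1$ as "mean may
  not represent center".
* Decisions 1 and 2 are evaluated against global maxima of the profile
  (worst station, worst gap), the conservative reading; a per-station
  evaluation would be laxer.

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `speed_slope` | (m/s)/cm | 0.05 | With intercept 0, reproduces the single published anchor: 12.2 cm → 0.61 m/s. The underlying cross-species regression is not numerically published, so the line is explicit configuration. |
| `speed_intercept` | m/s | 0 | See above; a zero intercept also keeps $U_{crit}$ positive for all lengths. |
| `endurance_coeff_velocity` | per (cm/s) | −0.027 | Published endurance formula. |
| `endurance_coeff_length` | per cm | 0.007 | Published endurance formula. |
| `endurance_intercept` | log10 min | 0.516 | Published endurance formula. |
| trait thresholds | index | 1.13 / 1.17 / 0.95 | Printed invasion-front means for boldness / activity / asociability. |
| `min_traits_above` | count | 2 | The compensatory 2-of-3 rule. |
| `flow_limit_m_s` | m/s | 0.5 | Only used when a profile is not supplied; with a profile the computed near-bottom maximum is authoritative. |
| `distance_limit_m` | m | 4.54 | Worst pool gap of the worked-example bypass. |
| boldness `log_base` | — | ten | The transform is stated without a base; printed index values (1.13–1.76) are consistent with either. Base ten is the package default and is recorded in scored output. |
| `min_move_cm` | cm | 1.0 | Activity counts displacements *strictly* greater than 1 cm ("longer than one centimeter"). |
| exclusion `window_s` | s | 1800 | Fish that do not move in the first 30 min of the sociability video are excluded. |
| IRLS `coef_cap` | — | 25 | See "Separation" below. |
| `n_groups` | count | 10 | Deciles of risk for Hosmer–Lemeshow; df = groups − 2. |

## Trait scoring choices

* **Boldness** is $\log(t_{max}) - \log(\text{latency})$, a bijection from
  $(0, t_{max}]$ onto $[0, \infty)$: zero for a fish that never resumes
  movement, one decade of latency per index unit in base ten.
* **Asociability** is the mean Euclidean distance (converted px → cm) from
  the fish to a *single* stimulus point — the midpoint of the compartment
  wall the conspecific pair sits behind — not to the individual stimulus
  fish. Scoring starts at the movement-onset frame (the frame from which
  the first nonzero displacement occurs), mirroring a protocol that
  extracts frames "starting when the fish began to swim"; a never-moving
  fish is an exclusion, not an error. The px→cm scale is an explicit input
  per recording: the assay tank has two plausible reference widths (80 cm
  and 26.5 cm), so calibration is never inferred. Because the raw-cm and
  dimensionless forms are both defensible, `asociability_index()` can
  return the index normalized by any supplied length scale alongside the
  raw cm value.
* **Activity** counts inter-frame displacements strictly greater than 1 cm;
  the percent form (count / intervals × 100) makes recordings of different
  durations comparable, and `count = percent × intervals / 100` exactly.
* The 30-minute exclusion rule assigns a displacement over $(t_{i-1},
  t_i]$ to the window iff $t_i \le 1800$ s, so movement first visible at
  1801 s still excludes the fish.

## The statistical layer

The logit layer is written in the package rather than delegated, because
its behavior under separation must be defined, not accidental.

**Separation.** The decision-matrix outcome is a deterministic function of
the predictors, so quasi-complete separation is the *expected* regime: the
Bernoulli likelihood has no finite maximizer and IRLS estimates diverge
along a fixed direction. The fitter therefore (i) step-halves so the
deviance never increases, and (ii) when the coefficient vector exceeds the
cap (default 25 on the linear-predictor scale), rescales the entire vector
— intercept included — onto the cap. Rescaling preserves the decision
boundary exactly, so the capped solution classifies identically to the
diverging one while keeping all reported quantities finite. The fit carries
`separation_warning = TRUE` and still reports deviance, AIC, and percent
correct at the capped solution. A one-class outcome returns a flagged
degenerate fit instead of an error.

**Conventions forced by arithmetic.** The reported `deviance` is
$-2\,\ell$; `aic = deviance + 2(k+1)` with the intercept counted in the
parameter count. These two conventions are the only pair under which an
all-subset AIC table is internally consistent with a deviance-style
"2 × logLikelihood" figure (e.g. a 4-predictor deviance of 33.896 gives AIC
43.896 = 33.896 + 2·5), and the package's subset tables satisfy the
identity on every row by construction (and by test). Classification
accuracy uses a fixed 0.5 probability cutoff.

**Hosmer–Lemeshow.** Deciles of risk are equal-count groups by sorted
fitted probability; the statistic is
$\sum_g (O_g - E_g)^2 / (E_g(1 - E_g/n_g))$ on $g - 2$ df. Groups with zero
expected variance (all fitted probabilities 0 or 1 — common under
separation) are merged into a neighbor, with a message, rather than
producing NaN. Different software draws group boundaries differently at
ties; the standard deciles-of-risk definition implemented here is the
documented choice.

**Spearman correlations** are the Pearson correlation of average ranks
(midranks at ties), computed directly; constant columns yield flagged `NA`
entries instead of silent NaN propagation.

## The synthetic-data generator

The generator produces data *with the statistical structure the analysis
assumes*, so that every downstream stage is testable:

* **Lengths**: truncated normal, mean 9.9 cm, SD 1.5 cm, bounds
  7.3–15.3 cm — the documented size structure of the assayed cohort (the
  SD is not printed; 1.5 cm puts the printed bounds near ±2σ and is the
  package's fixed choice).
* **Traits**: correlated multivariate normal truncated at 0 (the indices
  are nonnegative by construction), sampled by row rejection; marginal
  normality mirrors the skew/kurtosis audit that justified using means as
  thresholds. Default front means are the printed thresholds
  (1.13, 1.17, 0.95); default SDs are 0.35 index units, a fixed choice
  placing the printed worked-example values (1.71, 1.76, 0.47) within
  roughly ±1.7σ of their means; default correlations use the reported
  intracorrelations (boldness–activity 0.366, boldness–asociability
  −0.093, activity–asociability 0.261). Invasion-center means are not
  numerically published; the default of front − 1 SD is an assumption and
  labelled as such.
* **Recordings**: a stay-or-jump random walk (move probability per frame,
  Gaussian step reflected at the arena walls) at one frame per 6 s, with a
  lognormal latency capped at $t_{max}$.
* **Flow profiles**: uniform station velocities within configured ranges
  with the physical ordering near_shore ≤ near_bottom ≤ center enforced.

A single master seed fans out to fixed per-generator substreams, so adding
a generator call does not perturb the draws of another.

What the generator does **not** emulate: temporal autocorrelation of real
trajectories beyond the random walk, assay-protocol differences between
populations (the cross-protocol percent normalization of activity is
implemented only as the stated percent-of-observations form), measurement
error in the pixel coordinates, and any size–trait dependence beyond the
configured correlations. Passing tests on synthetic cohorts therefore
demonstrate the pipeline's internal correctness and calibration, not the
field validity of the thresholds.

The worked-example barrier profile is likewise synthetic: only the summary
values were published (11 stations at 6 m, bottom maximum 0.50 m/s,
shoreline 0.16 m/s, center 1.4 m/s, worst pool gap 4.54 m), so
`example_flow_profile()` ships smooth station series constructed to hit
exactly those maxima, and the CSV copy is named
`rhine_bypass_flow_synthetic.csv` to say so.

## Numerical choices and degenerate inputs

* Truncated-normal lengths use inverse-CDF sampling (no rejection); trait
  truncation at 0 uses row rejection with a hard iteration limit and an
  informative error if the configured means/SDs make truncation heavy.
* Zero trait SDs short-circuit to exact means (and, combined with strict
  threshold comparisons, yield a 0% ascent cohort when means equal
  thresholds — ties fail).
* IRLS: at most 100 iterations, convergence when the deviance change drops
  below 1e−8, 30 step-halvings maximum.
* The known discrepancy in the worked example: plugging $v = 50$ cm/s and
  $TL = 12.2$ cm into the printed endurance formula gives
  $E = 10^{-0.7486} \approx 0.178$ min and hence $d \approx 6.53$ m, not
  the 13 m quoted alongside it. No documented choice of $v$ reproduces
  13 m. The package records its own computed distance in the trace; the
  qualitative decision is unaffected (6.53 m > 4.54 m), so the worked
  example's decisions all reproduce.
* The two printed bottom-flow maxima (0.52 m/s in the measurement summary,
  0.5 m/s in the worked example) are reconciled by always using the
  supplied profile's computed maximum; the shipped fixture sets it to 0.50
  so the worked-example comparison reproduces exactly.
* Which flow velocity enters the endurance formula is configurable in
  spirit via `distance_sensitivity_table()`; the pipeline default is the
  profile's near-bottom maximum, the worst case a bottom-dwelling fish
  must beat. The non-ground-speed variant ($U_{crit} - v$) is available
  via `subtract_flow` for sensitivity analysis and is substantially more
  conservative.

## Test problem sizes

The suite exercises distributional recovery at $n = 10^4$ cohorts,
decision-matrix monotonicity over $10^4$ random individuals, IRLS-vs-direct
likelihood maximization at $n \le 50$, null calibration of the LR statistic
(200 replicates of $n = 500$) and of Hosmer–Lemeshow p-values (200
replicates of $n = 1000$), all under fixed seeds. These sizes give
comfortable Monte-Carlo resolution for 3-standard-error and
Kolmogorov-distance checks while keeping the whole suite fast.

## Known limitations

* The decision matrix is binary by design; it does not propagate
  uncertainty in the thresholds or swim coefficients (no probabilistic
  softening of the gates).
* No temperature correction of $U_{crit}$, no re-fitting of the
  length–speed regression from literature data, no hydraulic modeling of
  the flow field — profiles are measurements, not simulations.
* The logit layer offers no penalized (Firth) alternative; under
  separation its coefficient *magnitudes* are a reporting convention (the
  cap), and only the boundary direction and fit statistics are
  interpretable.
* Cohort-level field results depend on trait data that were never
  deposited; the package reproduces the printed worked example and the
  method's structure, not the original cohort statistics.

## A minimal run

```{r example, eval = FALSE}
fish <- data.frame(fish_id = "worked_example", tl_cm = 12.2,
                   boldness = 1.71, activity = 1.76, asociability = 0.47)
run_decision_matrix(fish, example_flow_profile())

res <- run_pipeline(pipeline_config(
  cohort = list(synthetic = list(n_individuals = 50)), seed = 42))
res
```
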