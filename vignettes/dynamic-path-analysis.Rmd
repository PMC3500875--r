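---
title: "Dynamic path analysis: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic path analysis: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynpath)
```

# Overview

`dynpath` treats causality and mediation as properties of *processes evolving
in time* rather than of static variables. Four pieces fit together:

1. **Linear dynamic systems** (`linear_sde`): mechanistic models
   $dX_t = A X_t\,dt + dB(t) + dW_t$ in which influence is carried by the
   drift matrix $A$, and path-specific effects have closed forms.
2. **Local independence graphs** (`li_graph`): directed graphs, cycles
   allowed, encoding which processes' histories enter which processes' local
   characteristics, with the $\delta$-separation criterion
   (`delta_separated`) for reading off conditional local independence.
3. **Dynamic path analysis** (`fit_dynamic_path`): per-event-time path
   analysis for counting-process data, combining an additive hazard fit with
   ordinary mediator regressions into cumulative direct, indirect and total
   effect curves.
4. **Linear increment models** (`fit_increment_series`,
   `test_local_dependence`): per-time regressions of panel increments on
   lagged levels, the discrete-time counterpart used for longitudinal
   biomarker series.

A synthetic-data module (`gen_mediation_survival`, `gen_coupled_panel`,
`gen_sde_panel`) generates data with exactly the statistical structure each
estimator assumes, so every claim in the test suite is checked against a
known mechanism.

# Path-specific effects in linear systems

For a linear system with drift $A$ and zero deterministic input, the
conditional expectation is $E(X_t \mid X_0) = \exp(At) X_0$, so shifting the
initial level of a source process by $\Delta$ moves the expected level of a
target process at horizon $t$ by $(\exp(At))_{\text{target},\text{source}}
\,\Delta$ — the *total effect* (`total_effect`), defined for any drift,
cyclic or not.

To attribute this flow to individual pathways, `split_paths` rebuilds the
system as a tree: the target is replaced by one copy per directed
source-to-target path, each copy receiving only the final edge of its path,
with shared intermediate prefixes duplicated so each root-to-leaf route is a
unique path. By linearity the copies' responses sum back to the original
target response. `path_effects` reads each path's contribution off the split
system's matrix-exponential solution. For an acyclic system with zero drift
diagonal, a path with $k$ edges and weight product $\pi$ carries
$\pi\,t^k/k!\,\Delta$: a direct edge of weight $c$ contributes $c\,t\,\Delta$
and a two-edge path with weights $a,b$ contributes $ab\,t^2/2\,\Delta$.

```{r fig2}
A <- matrix(0, 3, 3, dimnames = list(1:3, 1:3))
A[2, 1] <- 1; A[3, 1] <- 1; A[3, 2] <- 1
m <- linear_sde(A)
path_effects(m, "1", "3", t = 1)
```

**Design choices.** Path decomposition is restricted to acyclic influence
structures with zero self-dynamics along the relevant paths: there the path
set is finite and the closed form holds. Systems with feedback raise a
descriptive error and retain `total_effect`, which needs no such structure.
Self-dynamics (nonzero diagonal) on off-path nodes are harmless and allowed.
The path registry is ordered lexicographically by label sequence so output is
reproducible. Node references are accepted by label or 1-based position and
stored by label. The matrix exponential is computed by the scaling-and-
squaring routine in the Matrix package; the test suite checks it against an
independent truncated power series and against the $\pi t^k/k!$ enumeration
formula on randomly generated acyclic systems.

**Simulation.** `simulate()` uses the Euler–Maruyama scheme with step equal
to the grid spacing, so the user controls accuracy through the grid; the
noise covariance is factorized by a symmetric PSD square root (eigenvalue
tolerance $10^{-10}$). With a zero noise covariance the scheme is the Euler
ODE solver; at step $10^{-3}$ it tracks $\exp(At)x_0$ to a relative error
below $10^{-3}$ over $t \in [0,2]$ for the three-process example, and this
is asserted in the tests.

# Local independence graphs and $\delta$-separation

An edge $l \to k$ states that process $k$'s local characteristic (drift, or
intensity for counting processes) depends on the history of $l$. For a
linear system this is simply the off-diagonal pattern of $A$
(`drift_to_graph`); diagonal entries are self-dynamics, not edges. Unlike
classical DAGs, these graphs may contain cycles: mutual influence between
processes is meaningful.

`delta_separated(g, A, B, C)` decides whether every influence route from $A$
into $B$ is blocked by $C$:

1. restrict to the ancestral subgraph generated by $A \cup B \cup C$
   (reachability-based, hence well-defined on cyclic graphs — no acyclicity
   check is imposed);
2. delete directed edges leaving $B$ (this makes the criterion asymmetric in
   $(A, B)$, matching the direction-specific nature of local independence);
3. moralize (join all co-parents, drop directions);
4. test undirected separation of $A$ from $B$ by $C$.

Step 4 uses breadth-first reachability with $C$ removed; the package also
ships `separation_oracle`, an exponential-time simple-path enumerator
(guarded to small graphs) used to cross-validate the reachability check on
randomized inputs. Independent censoring has a graphical reading here:
censoring is independent exactly when all other processes are locally
independent of the censoring process, and the packaged worked examples
(`scenario_graph`, the `censoring_graph` fixture in the tests) show the
separated and non-separated censoring configurations side by side.

Node roles (treatment/mediator/outcome/censoring/unobserved) can be attached
to graphs but are documentation only; no algorithm consults them.

# Dynamic path analysis for event-history data

The data model is counting-process (start/stop) format: intervals
$(\text{start}, \text{stop}]$ per subject with covariates constant on each
interval. Conventions the package fixes explicitly (the field's literature
often leaves them implicit):

* **At-risk rule**: interval $(s_0, s_1]$ covers $t$ iff $s_0 < t \le s_1$;
  an event is attributed to its interval's stop time.
* **Covariates are step functions**: intermittently measured covariates are
  carried forward (LOCF) between updates — declared rather than assumed,
  since real cohort data are measured irregularly.
* **Ties** are processed as a single event time with a multi-event indicator
  vector; least squares handles the multiplicity.
* **Singular designs** at an event time are skipped and logged, never
  pseudo-inverted: a generalized inverse would silently change the estimand
  and break the decomposition identity below. The skipped times are
  reported, and any skip flags the fit as approximate.

`fit_additive_hazard` solves, at each event time $t_k$, the least-squares
problem of the event indicator on the at-risk design, and accumulates the
increments $d\hat B(t_k)$ into cumulative regression functions $\hat B(t)$.
The intercept-only special case collapses to the classical
occurrence/exposure estimator with increments $d_k/r_k$ — asserted exactly
in the tests, alongside a cross-check of the general fit against
`survival::aareg`.

`fit_dynamic_path` adds the per-event-time mediator regressions
$\hat\theta(t_k)$ (mediator on intercept, treatment, extras, over the
at-risk set) and forms

* direct$(t)$: cumulative treatment coefficient of the full additive fit,
* indirect$(t) = \sum_{t_k \le t} \hat\theta_1(t_k)\, d\hat B_Z(t_k)$,
* total$(t)$: cumulative treatment coefficient of the marginal additive fit
  (mediator omitted).

Because all three regressions share the at-risk sample at each event time,
the nested least-squares identity (marginal slope = direct slope +
mediator-on-treatment slope × mediator slope) holds per event time, making
**total = direct + indirect exact at machine precision** whenever no time
was skipped. The suite asserts a maximum absolute gap below $10^{-10}$ on
every simulated dataset; the reported `identity_gap` column makes any
approximation visible.

**Uncertainty.** Pointwise percentile bootstrap bands (`bootstrap_bands`)
resample subjects with replacement, re-fit, evaluate curves at the original
event times by last-value-carried-forward, and take percentile intervals.
This is a package design choice — simultaneous bands and analytic band
constructions are out of scope. Replicates without events are dropped and
counted.

# Linear increment models for panels

For panel data on a common grid, `fit_increment_series` regresses, at each
time $t_j$, the response increment $Y(t_j)-Y(t_{j-1})$ across subjects on an
intercept plus predictors' values at $t_{j-\text{lag}}$. Increments are
always one-step differences of the response; the lag applies to predictors
and is counted in grid steps. Missingness is handled complete-case per time
(no imputation): the simplest defensible default given the per-time
regression structure, with per-time complete-case counts reported and
checked against an independent recount in the tests.
`cumulative_coefficients` accumulates the per-time coefficients into step
curves, with variances summed across times under a working independence
assumption.

`test_local_dependence` aggregates the per-time standardized coefficients of
a candidate influencing variable into $Q=\sum_t z_t^2$. The aggregate
statistic is this package's construction (per-time estimates with bands are
what the field usually displays). Two reference distributions are offered:

* `chi2`: $Q \sim \chi^2_{df}$ with one degree of freedom per fitted time.
  Approximate, because per-time fits share subjects; with increments whose
  noise is independent across times the approximation is good, and the
  calibration suite measures the actual type-I error.
* `permutation`: whole trajectories of the candidate variable are permuted
  across subjects (each subject's own history stays intact, destroying
  cross-subject alignment while preserving marginal dynamics); included
  precisely because the chi-squared reference is approximate.

Direction-specificity comes from the regression structure: testing
RNA $\to$ dCD4 and CD4 $\to$ dRNA are different regressions, mirroring
one-way coupling between a viral-load-like process and an immune-marker-like
process. On panels generated with one-way coupling, the suite requires
empirical type-I error within binomial error of 5% in the null direction
(500 panels) and power above 95% in the coupled direction.

# The synthetic-data generators

`gen_mediation_survival` draws a binary treatment $X$
($P(X{=}1)=0.5$), a mediator $Z(t) = \theta_0 + \theta_1 X + b_i + e_i(t)$
updated every 0.1 time units ($b_i$ a persistent subject shift, $e_i(t)$
fresh noise), and an event intensity $\beta_0+\beta_1 X+\beta_2 Z(t)$.
Events are simulated by fine-grid Bernoulli thinning (default step 0.01)
rather than inversion, so time-varying and covariate-dependent intensities
are handled uniformly; negative intensities are clipped at zero *with
accounting* (the clip fraction is reported, and the calibrated defaults keep
it below 1%, asserted in the suite). Default parameters — $n=500$,
$\beta=(0.1, 0.3, 0.5)$, $\theta_0=1$, $\theta_1=1$, subject SD 0.1, within
SD 0.3, horizon 2 — are the package's standing study conditions: a linear
hazard comfortably positive, roughly half the subjects treated, and event
fractions high enough that cumulative curves are well resolved by $t=1$.

Censoring options mirror the graphical censoring story: `"independent"`
(constant rate; every process locally independent of censoring; estimates
remain unbiased — asserted) and `"mediator"` (rate increasing in the current
mediator; the mediator-ignoring analysis is then biased). The latter is kept
in the suite as a *negative control*: the test demonstrates the bias rather
than claiming to correct it — weighting estimators are out of scope. Each
generated dataset carries its implied local independence graph so
graph-level verdicts and data-level estimates are cross-checked
automatically.

`gen_coupled_panel` evolves variables by increment = coupling × lagged
levels + noise. The default scenario — two variables, one-way coupling 0.5,
unit initial SD and unit increment noise for the driven variable, $n=200$,
15 monthly times — gives a standardized cross-effect of about 0.5 at the
first transition, which is what the calibration properties quote.
Missingness is completely at random only; informative missingness is out of
scope. `gen_sde_panel` bridges the continuous and discrete views: panels
sampled from a linear SDE, with the discretized coupling $A\,\Delta t$
matching the continuous flow to discretization accuracy (a cross-module
consistency check in the suite).

# What the tests do and do not show

Everything asserted above is computed by the suite itself on synthetic data:
closed-form path effects, decomposition completeness against the $t^k/k!$
oracle, $\delta$-separation against brute-force path enumeration, the exact
decomposition identity, parameter recovery (slopes of cumulative curves at
$t=1$ recover $(\beta_1, \beta_2, \theta_1\beta_2)$ within three Monte-Carlo
standard errors at 200 replicates; bias does not grow from $n=200$ to
$n=800$ at Monte-Carlo resolution), and test calibration. Problem sizes in
the suite (up to 200 replicates of $n=500$; 500 random graphs; 700 panels)
were chosen as the smallest giving stable Monte-Carlo verdicts.

Synthetic data are not cohort data. The generators produce linear hazards,
Gaussian mediators, MCAR missingness and common observation grids; real
event-history data bring informative observation times, measurement error
correlated with risk, non-linear intensities and competing risks. Passing
this suite shows the estimators implement their definitions and recover
parameters under the assumed mechanism — not that the assumptions hold in
any particular cohort. In particular the dependent-censoring negative
control is a warning, not a fix: under mediator-driven censoring the
marginal analysis is biased by design, and re-weighting corrections are
deliberately not implemented.

# Known limitations

* Constant drift only; time-varying $A(t)$ and nonlinear systems are future
  work, as is estimating $A$ from data.
* Path decomposition requires acyclicity along the relevant paths; feedback
  systems get total effects only.
* Single-event survival (no recurrent events, no frailty, no competing
  risks); proportional-hazards modelling is intentionally absent.
* Bootstrap bands are pointwise percentile bands; no simultaneous coverage.
* Per-time OLS standard errors in the increment model ignore within-subject
  correlation across times; the permutation test is the guard against
  over-trusting the chi-squared reference.
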