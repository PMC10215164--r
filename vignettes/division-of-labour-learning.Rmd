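---
title: "Division of labour under social and individual learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Division of labour under social and individual learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dolgame)
```

## The game

A population of `N` agents repeatedly plays an n-player task-selection game.
Each agent is a point $(x, y, z)$ of the unit simplex: the fractions of
effort it invests in task X (a homeostatic task with a concave collective
benefit, such as thermoregulation in an ant colony), task Y (a thresholded
task with a sigmoidal collective benefit, such as brood care), and
inactivity Z, which produces nothing and costs nothing. Every time step the
population is shuffled uniformly into $K = N/n$ games of $n = 5$ players.
A group with collective efforts $X_k = \sum_i x_i$ and $Y_k = \sum_i y_i$
produces the shared benefit

$$B(X_k, Y_k) = \tfrac{1}{n}\, B_X(X_k)\, B_Y(Y_k),
\qquad
B_X(E) = b_1 E + b_2 E^2,
\qquad
B_Y(E) = \frac{1}{1 + e^{-\beta\,(E - 1/w)}},$$

which every member receives in full — the multiplicative coupling means
*both* tasks have to be staffed before anyone profits. Costs are private and
additive, $C(x, y) = c_x x^{e_x} + c_y y^{e_y}$, and an agent's payoff is
$\Pi = B - C$. The inactivity share never appears in the cost: laziness is
free, it just forgoes benefit production.

The same game is then iterated under two unrelated behavioural update
rules:

* **Social learning** (`run_social()`): discrete generations of
  payoff-biased imitation. After payoffs are assigned, every agent copies
  the trait pair of a role model sampled from the whole population with
  Boltzmann probability $e^{\zeta \Pi_l} / \sum_m e^{\zeta \Pi_m}$ (self-
  imitation allowed), and with probability $\mu$ additionally perturbs both
  traits with Gaussian noise of spread $\sigma$, clipped to the trait box
  and rescaled onto the simplex when needed.
* **Individual learning** (`run_individual()`): no agent ever observes
  another. The trait square is discretised into half-open bins of side
  $h$ (210 bins at $h = 0.05$; `build_bin_grid()`), each agent holds a
  probability vector over bins, realizes its action by Gaussian jitter
  around the sampled bin's centre, and reinforces the bin its realized
  action fell into with the cross rule
  $\pi_l \leftarrow \pi_l + \alpha\,\hat\Pi\,(1 - \pi_l)$ (others decay by
  $1 - \alpha \hat\Pi$), where $\hat\Pi$ is the payoff mapped affinely into
  $[0,1]$.

A third, non-simulational layer (`ad_regime()`, `find_singular_points()`)
applies adaptive dynamics to the same payoff structure: the invasion
fitness of a rare mutant among $n - 1$ residents, its selection gradient,
and the second-order classification of singular strategies into ESS,
branching point, or repeller.

## Parameters

| parameter | meaning | default |
|---|---|---|
| `b1`, `b2` | linear / quadratic benefit coefficients of task X | preset |
| `beta` | sigmoid slope of the task-Y benefit (per unit collective effort) | 3 |
| `w` | $1/w$ = collective effort at the task-Y sigmoid midpoint | preset |
| `n` | group size | 5 |
| `zeta` | imitation selection intensity | 2 |
| `mu`, `sigma` | exploration probability / spread (social) | 0.01, 0.005 |
| `alpha` | cross-learning rate | 0.01 |
| `h`, `jitter_sigma` | bin side, realization spread (individual) | 0.05, `h/4` |
| `cost_coeff_x`, `cost_exp_x` | task-X cost scale and exponent | 2.1, 0.8 |
| `cost_coeff_y`, `cost_exp_y` | task-Y cost scale and exponent | 1.5, 0.5 |

Three environment presets span the qualitative regimes
(`dol_env_preset()`): *specialised* (`b1 = 16, b2 = -6, w = 0.2`),
*branching* (`b1 = 20, b2 = -4, w = 0.3`) and *uniform*
(`b1 = 28, b2 = -6, w = 0.5`).

### How the cost constants were fixed

The benefit coefficients, group size and learning parameters above are
externally given; the cost constants and the initial trait are free, and
the regime taxonomy only materialises for suitable combinations. They were
calibrated **once**, with the adaptive-dynamics layer alone (no simulation
in the loop), against three requirements: the specialised environment's
gradient flow must collapse to full inactivity; the branching environment
must have a convergence-stable interior singular point that is *not* an
ESS; the uniform environment must have an interior ESS with a strictly
positive inactivity share. A grid scan over
$e_x, e_y \in [0.3, 1]$ and $c_x, c_y \in [0.6, 3]$ left a compact feasible
region; the defaults $c_x = 2.1, e_x = 0.8, c_y = 1.5, e_y = 0.5$ sit in
its interior, giving a branching point at $(0.143, 0.792)$ with leading
mutant curvature $+2.3$ and a uniform-environment ESS at $(0.272, 0.578)$
with $z^\ast = 0.150$. The shared initial trait $(x_0, y_0) = (0.3, 0.6)$
was chosen inside all three basins: for $w = 0.3$ the task-Y sigmoid is
essentially flat below collective effort $\approx 2.5$, so starts with
small $y_0$ cannot bootstrap the threshold task in any calibration and
collapse to inactivity regardless of the environment's regime.

```{r presets}
for (p in c("specialised", "branching", "uniform"))
  cat(sprintf("%-12s -> %s\n", p, ad_regime(dol_env_preset(p))$label))
```

## Time scales of the two learning modes

The two paradigms do not share a clock. Imitation moves the population mean
at rate $\zeta\,\mathrm{Var}(\text{trait})\,\|\nabla f\|$ per generation
and reaches its attractor within a few thousand generations at
$N = 200,\ \sigma = 0.005$; social runs default to $T = 10^4$. The
cross-learner's policy can move at most $\alpha = 0.01$ per generation, its
normalised payoff differences between neighbouring bins are of order
$10^{-2}$–$10^{-1}$, and exploration is local (the jitter $h/4$ rarely
leaves the chosen bin), so crossing the ~12-bin distance from the initial
condition to an attractor is a reaction–diffusion wave that needs order
$10^5$ generations. Individual runs therefore default to $T = 10^5$; at
$T = 10^4$ the cross-learner is still in transit in every environment and
any regime label would describe the transient, not the steady state. With
the compiled kernels a full $10^5$-generation run takes tens of seconds.

## Reading regimes off finished runs

`classify_regime()` implements the three-way taxonomy with auditable
thresholds, evaluated on the final 10 % of stored generations:

* `fully_specialised` if tail-mean inactivity $\bar z \ge 0.9$. The
  threshold is 0.9 rather than something closer to 1 because the binned
  action space cannot express $z > 1 - h$ (0.95 at $h = 0.05$) and the
  Gaussian realization shaves off roughly another $h/4$; 0.9 keeps one
  threshold meaningful for both paradigms.
* `branching` if `detect_clusters()` finds $\ge 2$ coexisting clusters in
  at least 80 % of the tail snapshots. A cluster set is accepted only if
  every cluster holds $\ge 15\,\%$ of the agents, centroids are
  $\ge 0.1$ apart, **and** each pairwise centroid distance exceeds twice
  the summed within-cluster RMS radii. The last condition demands an
  actual density gap: k-means will happily cut a broad unimodal cloud in
  two, and binned cross-learners hovering on the flat payoff plateau
  around an ESS form exactly such clouds.
* `uniform` otherwise.

For individual-learning runs the classifier works on each agent's *modal*
bin centre (the policy argmax) rather than the single-generation realized
traits or the policy-expected traits: realizations carry jitter of order
$h/4$ that is not trait differentiation, and expected traits of a fully
converged corner population still read $\bar z \approx 0.87$ because of
residual exploration mass. The modal bin is the agent's committed
behavioural type. Realized and expected traits remain stored for
diagnostics.

## What the three regimes look like

```{r regimes, eval = FALSE}
env <- dol_env_preset("uniform")
soc <- run_social(social_config(N = 200, T = 10000), env, seed = 1)
ind <- run_individual(cross_config(N = 200, T = 100000, thin = 100),
                      env, seed = 1)
classify_regime(soc)
classify_regime(ind)
```

In the *specialised* environment the task-Y threshold ($1/w = 5$) is out
of reach for any group of five, benefits never cover costs, and both
learning modes converge on full inactivity — the population starves by
collapse of the collective tasks. In the *uniform* environment both modes
settle on one shared interior trait combination with a sizeable inactive
share ($\bar z \approx 0.15$): inactivity emerges at the steady state even
though it is never directly rewarded, because the marginally decreasing
returns of the two tasks stop paying for full engagement. This is the
focal phenomenon: a lazy fraction of effort arises as a by-product of
payoff-driven adjustment in a joint environment, under either learning
paradigm.

## The branching environment at small population scale

Adaptive dynamics predicts, for the branching preset, convergence to
$(0.143, 0.792)$ followed by disruptive diversification (leading mutant
curvature $+2.3$). The simulated dynamics at the package's default desk
scale ($N = 200$) reproduce the convergence but **not** a persistent
two-cluster split, and the package makes no attempt to hide this:

* Under imitation, nascent branches are eroded by drift. The imitation
  resampling with shared group benefits has a small effective population
  size, and the variance injected by exploration
  ($\mu \sigma^2 = 2.5 \times 10^{-7}$ per generation) cannot outrun
  branch-loss at $N = 200$ within $10^4$ generations. Worse, the concave
  power cost has divergent curvature at zero effort, so the small-$x$
  region around the branching point is itself disruptively unstable: runs
  that linger there eventually nucleate task-X free-riders, lose the
  taxed trait entirely, and then slide to full inactivity. Larger
  populations postpone this; no parameterisation of the power-cost family
  we scanned removes it while keeping the other two regimes intact.
* Under cross-learning, the same payoff logic drives a slow decay of the
  task-X policies with the same eventual collapse, and the transient
  multi-bin spread is a travelling wave rather than stable coexistence.

The three layers therefore agree fully on the specialised and uniform
environments, while in the branching environment the adaptive-dynamics
layer retains the branching prediction and the finite-population
simulations document its fragility at this scale. Seeding the predicted
dimorphism directly shows frequency-dependent restoring forces holding it
for thousands of generations before drift removes one branch, which locates
the discrepancy in nucleation and maintenance at small $N$, not in the
selection structure.

## Numerical choices

* All adaptive-dynamics derivatives are finite differences (step $10^{-6}$
  for gradients, $10^{-4}$ for curvatures, one-sided at the simplex
  boundary where the power cost is not differentiable), each verified
  against an independent step size; classification labels are checked to
  be invariant under step halving.
* The gradient flow uses projected explicit Euler with step
  $\min(0.02, 0.002/\|g\|)$; roots are polished by multi-start L-BFGS-B on
  $\|g\|^2$ and deduplicated within $10^{-6}$.
* Cross-learning payoffs are normalised by `payoff_bounds()`, an analytic
  envelope (parabola vertex and endpoints for $B_X$, monotone $B_Y$, cost
  maximum on the simplex hypotenuse) that provably contains every
  achievable payoff; the tests verify it against brute-force evaluation
  over all monomorphic and single-deviant compositions on the
  $h = 0.05$ grid.
* Mutation and jitter repair: per-trait clipping to $[0, 1]$ followed, if
  $x + y > 1$, by radial rescaling onto the hypotenuse — the minimal
  repair that preserves the direction of the proposal.
* Hypotenuse bin membership: realized points whose half-open floor indices
  would leave the simplex are assigned the outermost bin still inside it;
  traits exactly at 1 fall to the last bin of their axis.

## What the simulations do and do not show

The generator reproduces the *structure* of the study system — random
re-partition into groups every step, multiplicative benefit coupling,
cost-free inactivity, the two update rules — under one fixed, documented
calibration of the cost functions. It does not model heterogeneous agent
ability, spatial or network structure in who meets whom, task switching
costs, or environmental fluctuation, and its regime labels at
$N = 200$ speak to that population scale only: branching in particular is
a large-population prediction whose finite-$N$ realisation is
drift-limited. Conclusions about real colonies should lean on the
qualitative agreement of the two learning modes, not on any quantitative
value of the calibrated constants.
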