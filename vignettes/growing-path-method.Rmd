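---
title: "Growing and optimizing minimum free energy paths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing and optimizing minimum free energy paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growpath)
```

## The model

A transition path lives in an n-dimensional collective-variable (CV)
space. Snapshots are points $\chi \in \mathbb{R}^n$; dihedral components
are periodic with period $2\pi$ and every difference is taken along the
shortest arc. The CV-space norm is plain Euclidean on the wrapped
displacement, mixing radians and Angstrom without rescaling; an optional
per-CV weight vector is accepted by `cv_displacement()` but defaults
to 1. This unscaled mixture is deliberate: step sizes such as
$s_g = 0.102$ or $s_{op} = 0.002$ are quoted in these mixed units, and
rescaling would silently change what those numbers mean.

A **gradient field** is anything that returns $\nabla F(\chi)$: an
analytic surface, an interpolated grid, or the constrained-dynamics
estimator. The path machinery only ever sees this contract, so the same
optimizer runs on a closed-form test surface in microseconds or on a
simulated mean force in hours.

### Growth

From the bare reactant, snapshots are appended with arc step $s_g$ along
the normalized blend of the downhill direction and the pull toward the
product,
$$P_g \propto -\nabla F(\chi^{(end)}) + w\,
  \frac{\chi^{(p)} - \chi^{(end)}}{|\chi^{(p)} - \chi^{(end)}|},$$
terminating by appending the product once the end is within $s_g$ of it.
As printed in the string-method literature the blend is sometimes used
unnormalized; we normalize it so that $s_g$ is a geometric arc step,
which keeps the termination test and the expected snapshot count
consistent when the gradient is large. `grow_config(raw_direction =
TRUE)` restores the literal unnormalized rule. If the gradient exactly
cancels the pull (resultant norm below $10^{-12}$) the step aborts with
a diagnostic rather than applying a random kick — reproducibility is
worth more here than robustness to a measure-zero configuration.

After each growth step the path is reparametrized and swept twice
(`sweeps = 2`) by fixed-step steepest descent at $s_{op}$, including the
newest snapshot; the budget arithmetic $k \sum_{i=1}^{m} i$ only
balances if the newest snapshot is included, and whether those
growth-phase sweeps use the final optimizer is genuinely open — we
default to fixed-step descent as the simplest choice.

### Optimization

Every optimizer moves snapshots by (a multiple of) the perpendicular
gradient component $P_{op} = -\nabla F + (\nabla F \cdot s)s$ with unit
tangent $s$ from central differences (one-sided at the ends), then
reparametrizes. The metric tensor between Cartesian and CV space is
taken as the identity; the `gradient_field` contract is the hook where a
non-diagonal metric would enter, but none is implemented.

* `sd_fixed`: $\chi \leftarrow \chi + s_{op} P_{op}$.
* `sd_variable`: the step is halved when the free-energy sum over
  snapshots *decreased* and reset to its initial value otherwise. That
  orientation is as printed in the source literature and is unusual
  (it shrinks the step while things go well); because the intent cannot
  be guessed from the text we implement it verbatim and provide
  `inverted_variable_rule = TRUE` for the conventional reading.
* `quasi_newton`: all snapshots are stacked into one $nm$-vector and a
  limited-memory BFGS proposal (two-loop recursion, memory depth 5 — a
  standard default, the depth is not prescribed) is formed on the
  objective whose gradient is $-P_{op}$. The full proposal overshoots
  badly on string problems, so the path moves only the fraction
  $s_{step} \in (0, 1]$ toward it, is then smoothed and reparametrized.
  A non-descent or non-finite proposal falls back to one steepest
  descent sweep.

Smoothing minimizes the bending objective
$f = \sum_i (\theta_i - \pi)^2$ over interior snapshots by steepest
descent, 1000 steps of size $10^{-4}$ by default. The angle gradient
uses the factor $(\theta - \pi)/\sin\theta$, which is finite (limit
$-1$) at straight configurations; triples with a zero-length arm are
skipped. A step that would increase $f$ is retried at half size, so $f$
never increases.

Convergence is tracked by
$\sigma_\perp = \sqrt{\sum_i |P_{op}^{(i)}|^2 / (nm)}$ — an RMS
per-dimension gradient magnitude. The defining sum is typographically
ambiguous in its source; the alternative no-root reading is available
via `sigma_perp(..., mean_square = TRUE)`. Optimization stops at
$\sigma_\perp \le$ `tol_factor` $\times$ its initial value, or at
`max_iter`.

### Paths, arc length, reparametrization

The interpolating curve through the snapshots is a cubic spline per CV
against the snapshot index (piecewise linear below four snapshots), and
each segment's length is a composite Simpson integral of $|d\chi/dt|$
with a fixed 16-subinterval subdivision — converged at the snapshot
densities used here. We use Forsythe–Malcolm–Moler end conditions
(exact cubics through the four end points) rather than natural ends:
natural end conditions deform under on-curve refinement and cost about
five digits of arc-length stability at the path ends. Reparametrization
resamples the same curve at equal arc-length fractions
$\xi_i = (i-1)/(m-1)$, iterating the redivision until per-segment
lengths agree with their mean to 0.1%; endpoints never move. The
reaction coordinate $\xi$ is the arc-length fraction, which coincides
with the snapshot-index fraction exactly when profiles are reported
(i.e. after reparametrization).

### Constrained dynamics and the mean force

The toy engine integrates point particles with Beeman's algorithm
(1 fs default timestep), a Berendsen thermostat (coupling time 100 fs —
unstated in the method literature, this is a conventional value), and
coupled ("matrix") SHAKE: the multipliers of all constraints are solved
simultaneously by Newton iteration each step, rather than Gauss–Seidel
cycling, because per-CV attribution of $\langle\lambda\rangle$ is
otherwise ill-defined when CV gradients share atoms. The multiplier
enters the Beeman position update with coefficient
$\tfrac{2}{3}\Delta t^2/m$ (the $4/6$ weight of the current force), so
$\lambda$ is solved directly in force units and
$\langle\lambda\rangle = +\partial F/\partial\chi$ without unit
conversion — the sign convention is fixed by the harmonic closed form
$\langle\lambda_x\rangle = k(c - x_0)$. Velocities are kept on the
constraint manifold by projection, and a velocity-Verlet integrator sits
behind `md_config(integrator = "velocity_verlet")` as a cross-check;
equilibrium averages agree between the two.

Two numerical choices deserve emphasis:

* **Thermostat pathology.** Berendsen weak coupling alone is unsafe on
  systems with a handful of degrees of freedom: energy migrates into a
  quasi-static drift mode, the kinetic temperature collapses, and
  position means can bias. The engine therefore redraws velocities from
  the Maxwell distribution every `collision_interval` steps (default
  50) and re-projects them. All-atom systems would not need this; our
  toys do.
* **Block-averaged errors.** Successive multiplier samples are serially
  correlated, so `lambda_se` is computed from ~50 block means, not the
  naive per-sample standard error.

Equilibration defaults to 20% of the production length and is discarded.
A preparatory damped gradient descent on $\sum(\sigma - \text{target})^2$
lands the system on the constraint manifold before dynamics begin.

The free energy along a path is the trapezoid-rule integral of the
tangential mean force over arc length (the snapshots are the quadrature
nodes; the source does not state its quadrature), anchored at
$F(0) = 0$, plus the correction $-k_B T \ln\langle|Z|^{-1/2}\rangle$
evaluated as an endpoint difference by default (per-snapshot attribution
is applied when a correction is supplied at every snapshot). The two
terms are kept in separate columns (`ti_term`, `correction_term`) so
their relative size can be judged; on the bundled toys the correction is
orders of magnitude below the integral term. Only the multiplier term is
used as the *gradient* during optimization; both terms enter the
*profile*.

Package-wide units: kcal/mol, Angstrom, radians, femtoseconds, Kelvin,
amu; $k_B = 0.0019872041$ kcal/(mol K).

## What the synthetic fixtures emulate

`fixture_set()` bundles:

* **ala_like_2d** — two Gaussian wells of unequal depth (6 and
  4 kcal/mol, width 0.85), a 5 kcal/mol Gaussian barrier whose center is
  displaced off the straight line between the wells, and a weak
  quadratic confinement. This reproduces the qualitative geometry of a
  dipeptide backbone-dihedral surface: the straight interpolated path
  crosses the barrier (max 2.28 kcal/mol) while the optimal path curves
  through the valley on the far side (the grown path tops out at
  0.34 kcal/mol). The stored minima are Newton-refined so gradients
  vanish there to machine precision. Nothing about the parameters is
  fitted to any real molecular surface; the well-depth difference of
  2 kcal/mol was chosen as a typical conformational free-energy gap so
  that the state-function checks run at a realistic magnitude.
* **toy_harmonic_2d** — the mean force is exactly $k(\chi - \chi_0)$
  and temperature-independent; the multipliers are noiseless, which
  validates extraction and sign but not statistics.
* **toy_coupled_system** — constrained $x, y$ linearly coupled to a
  thermal $z$; the multiplier fluctuates while its mean retains a closed
  form. This is the statistically honest estimator test.
* **toy_distance / saddle_quadratic / harmonic_nd** — Z-matrix,
  SHAKE, and symmetry edge cases.

Passing on these fixtures shows the machinery is correct: geometry,
estimator statistics, convergence behavior, bookkeeping. It does not
show that any particular molecule's free energy is reproduced — real
CV choices, force fields, solvent, and sampling adequacy are outside
what a desk-scale surface can exercise, and hidden barriers orthogonal
to the constrained CVs would bias any constrained-dynamics estimate.

## Demonstration problem sizes

The bundled validation runs use m = 40 snapshots on the 2-D fixture,
steepest descent run to $\sigma_\perp \le 0.02\,\sigma_\perp^{(0)}$
(at most 600 iterations), quasi-Newton with $s_{step} = 0.2$ to
$0.03\,\sigma_\perp^{(0)}$ from the straight start (the grown start is
already near-converged, so its relative threshold is kept at 0.05), and
the dense descent oracle integrated with RK4 at arc step 0.002 from the
lowest-energy index-1 saddle found by a scanned Newton search. The
mean-force recovery uses 10 constrained points at 30 ps each (1 fs
timestep). These sizes were chosen so every check runs comfortably on a
single CPU while leaving clear numerical margins.

## Known limitations

* Quasi-Newton on the string objective plateaus: the perpendicular
  force is not the gradient of a scalar objective, so curvature
  information is heuristic. It converges far faster than steepest
  descent early (reaching the steepest-descent 200-iteration
  $\sigma_\perp$ level within a handful of iterations on the fixture)
  but stalls around $\sigma_\perp \approx 0.04$–0.05 there; the
  smoothing term also biases slightly against curvature.
* Single-ended growth only; the double-ended two-fragment variant is
  intentionally not implemented.
* Grid surfaces refuse to extrapolate beyond their bounds (failing
  loudly is safer than optimizing into unsampled territory).
* The deterministic growth/optimization pipeline finds one path; it
  will not enumerate multiple competing channels. On the bundled
  fixture both the straight and the grown starts happen to converge to
  the same (lower) channel, which is what makes the state-function and
  oracle checks sharp.
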