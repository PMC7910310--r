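---
title: "A bulk-surface model of Cdc42-driven cell polarisation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bulk-surface model of Cdc42-driven cell polarisation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdc42sim)
```

## The model

During polarisation the GTPase Cdc42 accumulates at a single membrane site,
the pole, from which a yeast bud (or more generally a new growth axis)
emerges. `cdc42sim` implements a dimensionless bulk-surface
reaction-diffusion description of this process. The cell is the unit ball
$\Omega$, its membrane the unit sphere $\Gamma$. Three forms of Cdc42 are
tracked: the active, GTP-bound membrane form $u$, the inactive, GDP-bound
membrane form $v$, and the GDI-sequestered cytosolic form $V$. On the
membrane,

$$
\partial_\tau u = \Delta_\Gamma u + \gamma f(u, v), \qquad
\partial_\tau v = d\,\Delta_\Gamma v + \gamma\bigl(-f(u, v) + q(u, v, V)\bigr),
$$

with the activation kinetics $f(u,v) = c_2 v - u + u^2 v$ (GEF/GAP-driven
activation, first-order inactivation, quadratic PAK/scaffold positive
feedback) and the membrane flux
$q(u,v,V) = c_1 V\,(c_{\max} - (u+v)) - c_{-1} v$ (GDI-mediated delivery
onto free membrane capacity, and dissociation back into the cytosol).

Because the cytosolic form diffuses orders of magnitude faster than the
membrane-bound forms, the cytosol is taken well mixed (the fast-cytosol
limit): $V$ is a single scalar slaved to the membrane load through the
nonlocal mass-conservation functional

$$
V[u+v] = V_0 - \frac{1}{|\Omega|}\int_\Gamma (u+v)\,\mathrm{d}s ,
$$

so the total amount $|\Omega| V + \int_\Gamma (u+v)$ is a constant
$|\Omega| V_0$. This reduced two-state surface system is what the package
simulates and analyses; the full three-dimensional bulk problem with a
finite cytosolic diffusivity is outside its scope, and the quantitative
simulation outputs should be read with that reduction in mind.

A note on signs: the spatially averaged (homogeneous) system is
$\dot{\bar u} = \gamma f$, $\dot{\bar v} = \gamma(-f + q_0)$ with
$q_0(\bar u,\bar v) = c_1 a (c_{\max}-s)(m-s) - c_{-1}\bar v$, $s = \bar u +
\bar v$, $m = V_0/a$. The sign $\gamma(-f + q_0)$ is the only one
consistent with the surface system and with mass conservation
($\dot{\bar V} = -a\gamma q_0$); the package uses it throughout.

### Parameters

| name | meaning | reference value |
|------|---------|-----------------|
| `c1` | relative influx of inactive Cdc42 from the cytosol | 0.05 |
| `c_minus1` | relative dissociation from the membrane | 0.01–0.05 |
| `c2` | relative activation (GEF/GAP module) | 0.15–0.45 |
| `c_max` | maximum membrane-bound concentration | 3 |
| `V0` | total average concentration of all forms | 6 |
| `gamma` | reaction strength, proportional to membrane area | 25 |
| `d` | relative diffusivity of the inactive membrane form | 10 |
| `a` | surface/volume ratio, $|\Gamma|/|\Omega| = 3$ for the unit ball | 3 |

All are dimensionless; `nondimensionalise()` maps dimensional rate
constants onto them (concentration scale $\sqrt{k_{-2}/k_3}$, time scale
$R^2/D_A$). `a` is stored as a parameter rather than hard-coded so that the
kinetics can be reused on non-spherical geometries, for which the theory
still guarantees well-posedness; the derived capacity `m = V0/a` is always
recomputed, never set.

## Steady states and the trapping region

Setting $f = 0$ forces $v^\ast = u^\ast/(c_2 + u^{\ast2})$; substituting
into $q_0 = 0$ and clearing the denominator yields a degree-6 polynomial
whose positive real roots are the positive steady states
(`find_steady_states()`). The polynomial is positive at $u = 0$ and as
$u \to \infty$, so simple positive roots come in pairs: the count is 0, 2,
4 or 6. Root finding is global (companion-matrix roots, then a Newton
polish); `newton_refine()` offers the local Newton path from the
prescribed start guess $u_0 \in (\sqrt{c_2}, \min\{c_{\max}, m\})$,
$v_0 = u_0/(c_2+u_0^2)$, falling back to bracketed bisection when the
Jacobian degenerates, so a diverging iteration is never reported as a
root. Near-multiple roots are flagged `degenerate` rather than silently
dropped, because the parity statement only holds for simple roots.

Physically admissible states live in
$\mathcal{A} = \{u, v \ge 0,\; u + v \le \min(c_{\max}, m)\}$: the
membrane saturates at $c_{\max}$ and the cytosol cannot hold negative
amounts ($u + v \le m$ keeps $V \ge 0$). For the homogeneous dynamics
$\mathcal{A}$ is a trapping region — on each boundary segment the flow
points inward — and the suite verifies this on batches of seeded
trajectories. The trapping statement applies to the homogeneous system
only; the surface simulator therefore reports pointwise excursions of
fields outside $\mathcal{A}$ as warnings instead of enforcing the region.

A steady state can only seed patterns if $\sqrt{c_2} < \min\{c_{\max},m\}$
and $u^\ast \in (\sqrt{c_2}, \min\{c_{\max}, m\})$ (open interval,
`necessary_condition()`). Where several roots lie in the bracket the
smallest is selected (`select_steady_state()`), mirroring the start-guess
rule.

## Linear stability and the two instability routes

Linearising around the selected steady state gives, for a spatial mode
with Laplace–Beltrami eigenvalue $k^2$ (on the unit sphere $k^2 = l(l+1)$,
$l \in \mathbb{N}$),

$$
\gamma J_{\mathrm{loc}} - \mathrm{diag}(k^2, d\,k^2), \qquad
J_{\mathrm{loc}} = \begin{pmatrix} f_u & f_v \\ -f_u + q_u & -f_v + q_v
\end{pmatrix},
$$

where $q_u = -c_1 V^\ast$ and $q_v = -c_1 V^\ast - c_{-1}$ are taken at
*fixed* $V = V^\ast$: a non-constant mode integrates to zero over the
sphere, so the nonlocal functional does not respond to it. The
spatially uniform mode ($l = 0$) is different — a uniform perturbation
changes the total membrane load and the cytosol responds — and uses the
mass-coupled Jacobian of the homogeneous system
(`homogeneous_jacobian()`). The difference between these two Jacobians is
exactly what opens the *non-classic* instability route.

`classify()` labels a parameter set by the algebraic Turing conditions on
$J_{\mathrm{loc}}$, with the homogeneous (mass-coupled) mode required
stable in every case:

* **nonclassic** — $\det J_{\mathrm{loc}} < 0$: the uniform-cytosol state
  is a saddle against inhomogeneous perturbations. Some band
  $k^2 \in (0, k_+^2)$ always grows, for any $d \ge 1$ and any
  $\gamma > 0$, so the label is independent of both.
* **classic** — $J_{\mathrm{loc}}$ is a stable node/spiral
  ($\operatorname{tr} < 0$, $\det > 0$) destabilised by unequal surface
  diffusion: $d f_u + g_v > 0$ and $(d f_u + g_v)^2 \ge 4 d \det
  J_{\mathrm{loc}}$, writing $g_v = -f_v + q_v$. At $d = 1$ the first
  condition is the negation of stability, so the classic route is closed —
  and the unstable set is a ray $d \ge d_c$, which is why classic regions
  are nested across $d$ in the parameter maps.
* **none** — no admissible steady state, an unstable homogeneous mode, or
  no wavenumber that can grow.

These conditions are deliberately free of $\gamma$: they say whether the
reaction system can break symmetry at all, which is the quantity the
parameter-plane maps display. Whether an *admissible* spherical harmonic
on the unit sphere actually falls inside the unstable band for a given
$\gamma$ is a separate, quantised question answered by `dispersion()`,
which tabulates the largest eigenvalue real part at $k^2 = l(l+1)$ for
$l \le l_{\max}$ (default 50, far above the unstable bands arising for
$\gamma \lesssim 200$). The two views disagree precisely when the unstable
band lies below $k^2 = 2$ — e.g. the non-classic reference kinetics at
$d = 1$, $\gamma = 25$, which `classify()` calls nonclassic but on which no
integer mode grows, so no pattern forms on the unit sphere at that size.
Points within tolerance $10^{-10}$ of $\det J_{\mathrm{loc}} = 0$ are
labelled `indeterminate` and excluded from region-area statistics, with a
logged count.

`map_parameter_plane()` sweeps two of (`c1`, `c_minus1`, `c2`) over a grid
(default 200×200; ranges config-overridable, defaults
$c_{-1} \in (0, 0.1]$, $c_2 \in (0, 1]$ and $c_1 \in (0, 10]$) and labels
each point per entry of `d_list`. The steady state and $J_{\mathrm{loc}}$
are $d$-independent, so they are computed once per grid point.

## The surface simulator

`build_icosphere()` subdivides the icosahedron and projects onto the
sphere ($10 \cdot 4^L + 2$ vertices at level $L$), then assembles the
standard linear-FEM cotangent stiffness matrix (rows sum to zero exactly;
symmetric positive semi-definite) and the barycentrically lumped mass
matrix. At level 4 (2562 vertices) the generalised eigenvalues reproduce
$l(l+1)$ with multiplicities $2l+1$ to better than 0.4% for $l \le 3$, and
the discrete area is within 0.12% of $4\pi$. Level 4 is the default for
tests and the acceptance computations; level 5 (10242 vertices) roughly
quadruples the cost and, in spot checks of the classic reference run,
reproduces the same pole count and peak amplitude to three figures.

Time stepping is IMEX backward Euler: diffusion implicit (one sparse
Cholesky solve per field per step, unconditionally stable), reactions
explicit, and $V$ recomputed from the nonlocal functional after each
update — which makes the discrete total mass *exactly* conserved (the
observed relative drift is at rounding level, and the suite bounds it by
$10^{-8}$ over full runs). The step size lives on a geometric ladder
$\Delta\tau = 10^{-4} \cdot 1.2^k$ capped at $10^{-2}$: it climbs one rung
when the relative field change per step is below 1% and drops four rungs
(≈ halving) when the change exceeds 10% or the step produces non-finite
values. The explicit reactions impose an effective stability ceiling
$\Delta\tau \lesssim (\gamma \| \partial f\|)^{-1}$; the change-based
controller finds it automatically, and the ladder keeps the set of
factorised operators finite. Crank–Nicolson weighting for diffusion was
considered and rejected: backward Euler's damping of the highest mesh
modes is preferable here because those modes are under-resolved anyway and
the quantities of interest (final pattern statistics) are insensitive to
first-order-in-time error at these step sizes.

Initial conditions perturb the selected steady state multiplicatively,
$u_i = u^\ast(1 + \sigma\xi_i)$, $v_i = v^\ast(1 + \sigma\xi_i')$ with
$\xi \sim U(-1,1)$ i.i.d. from a seeded RNG, and default $\sigma = 0.05$:
large enough that symmetry breaking does not wait on rounding noise,
small enough to stay in the linear regime. The reference study states
random perturbations around the steady state without an amplitude, so
$\sigma$ is this package's choice, fixed once. Simulations are bitwise
reproducible given the same options, and sweep runs derive their seeds
deterministically from a base seed, the swept value and the replicate
index (`derive_seed()`).

## Pole recognition and termination

`detect_poles()` thresholds the active field at the midrange,
$u \ge u_{\min} + \theta\,(u_{\max} - u_{\min})$ with $\theta = 0.5$, takes
connected components under mesh adjacency, and discards components below
1% of the surface. Midrange thresholding is the simplest rule consistent
with "a pole is a single circular spot": it is invariant under affine
rescaling of the field, and for a saturated cap profile it recovers the
cap area to mesh resolution. Relative pole area is reported as a fraction
(or percentage) of the total membrane area. A constant field has no poles
by definition.

A run terminates as `polarised` when, across a trailing window of width
$\Delta\tau = 0.2$: the pole count is at least one and unchanged, the
relative pole area moves by at most 0.01, the pattern contrast
$(u_{\max}-u_{\min})/\bar u$ exceeds 0.5, and the maximal relative field
change is below $10^{-3}$. The contrast guard matters: early in a run the
initial noise has decayed but the unstable mode has not yet emerged, and
without it the near-uniform transient would be declared stationary.
Multi-pole configurations at large $\gamma$ drift (coarsen) on very slow
time scales; if the horizon $\tau_{\max} = 50$ is reached with poles
present the run reports `max_tau`, and `no_pattern` only when no pole
exists at the horizon.

## What the generator emulates — and what it does not

The seeded fixtures (`generate_fixture()`) and defaults reproduce the
reference study's conditions: $V_0 = 6$, $c_{\max} = 3$, $a = 3$,
$\gamma = 25$, $d = 10$, classic kinetics $(0.05, 0.02, 0.45)$ or
$(0.05, 0.04, 0.45)$ and non-classic $(0.05, 0.01, 0.20)$ or
$(0.05, 0.03, 0.15)$. Passing tests on these fixtures show that the
reduced surface model with noisy near-uniform starts reproduces the
reported pattern statistics; they do not validate the finite-cytosol
(3D bulk) corrections, membrane deformation, or any biological noise
structure beyond i.i.d. initial perturbations — real initial conditions
are neither uniform nor uncorrelated.

## Problem sizes and reproduction

The packaged computations use mesh level 4, five seeds for per-parameter
amplitude estimates, and γ-sweeps over $\{10, 20, 40\}$ at five seeds plus
$\{80, 160\}$ at three seeds (the reference study used 20 realisations per
point; the smaller replication keeps the full reproduction in the
minutes range on one core and is the package's chosen trade-off).
`scripts/acceptance.R` reruns all of them from scratch from a single base
seed. With those sizes the classic reference run yields a single pole
with peak amplitude within a fraction of a percent of the reported value,
and the γ-threshold for multiple poles (40) and the ≈25% median pole size
are recovered; run-to-run spread across seeds is at the few-percent level
for amplitudes and one unit for pole counts near regime transitions.

## Known limitations

* The fast-cytosol reduction replaces the bulk diffusion problem; at
  moderate cytosolic diffusivities the coupling it drops is not entirely
  negligible, and amplitude-type outputs inherit that approximation.
* The homogeneous trapping region is not enforced pointwise on fields —
  transient pointwise excursions (e.g. from the initial noise at
  parameter sets close to the capacity bound) are possible and surfaced
  as warnings.
* Pole statistics at regime boundaries (e.g. γ near 40) are sensitive to
  the initial noise; medians across seeds are the robust summaries.
* The classification tolerance near $\det J_{\mathrm{loc}} = 0$ labels a
  measure-zero boundary `indeterminate`; area statistics exclude it.
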