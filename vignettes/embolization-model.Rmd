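---
title: "Modeling and optimizing multi-stage AVM embolization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and optimizing multi-stage AVM embolization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avmemb)
```

## The physical model

A racemic arteriovenous malformation (AVM) compartment is a tangle of thin
vessels that behaves, on the scale of the whole compartment, like a porous
medium.  Endovascular embolization injects a viscous agent (ONYX18, 18 cP)
at the arterial inlet to displace the blood (4 cP) and occlude the
compartment.  `avmemb` models this as one-dimensional two-phase filtration of
two incompressible, immiscible Newtonian fluids.

Let `S(t, x)` be the blood fraction of the pore volume ("saturation"),
`A(x)` the cross-section open to flow, `m(x)` the porosity and `Q(t)` the
total mixture flow.  Conservation of blood volume gives the scalar law

    d(m A S)/dt + d(Q f(S))/dx = 0,

where `f(S)` is the Buckley-Leverett fractional flow of blood: S-shaped,
with `f(0) = 0`, `f(1) = 1`, `f' > 0`, and a single inflection.  The package
builds `f` from power-law relative permeabilities and the mobility ratio:

    f(S) = (k_b(S)/eta_b) / (k_b(S)/eta_b + k_e(1-S)/eta_e),
    k_b(S) = S^alpha_b,   k_e(x) = x^alpha_e.

`alpha_b` is a per-patient quantity; the agent exponent `alpha_e` is not
identifiable from the available clinical data and defaults to 2 (a classical
quadratic permeability; any value >= 1 keeps the S-shape with these
viscosities).

Two features distinguish the problem from a textbook displacement:

* **Blood redistribution.**  Blood that does not enter the AVM takes the
  healthy vascular bed.  The inflow of blood is a given increasing, strictly
  positive function `qbar_b(Sbar)` of the mean blood fraction
  `Sbar = (1/L) \int S dx`, so the total flow is `Q(t) = q_e(t) +
  qbar_b(Sbar(t))` and the inlet saturation obeys the *integral* boundary
  condition `f(S(t, 0)) = qbar_b(Sbar) / (q_e + qbar_b(Sbar))`.
* **Pressure monitoring.**  The inlet pressure follows from Darcy's law,
  `p1 = p2(Sbar) + Q \int eta_b f(S) / (A K k_b(S)) dx`, with `p2` the
  outlet (venous-side) pressure response.  Pressures are kept in mmHg
  (1 mmHg = 1333.22 dyn/cm^2, applied inside the quadrature); everything
  else is CGS.

The ratio `f(S)/k_b(S)` in the pressure integrand has a finite limit
`eta_e/eta_b` as `S -> 0` for the mobility-ratio flux; it is evaluated with
a saturation floor of `1e-12` so fully embolized cells never produce `0/0`.

## Controls and the multi-stage structure

Each stage injects `q_e(t) = gamma * Q(stage start) * E(t)` with a trapezoid
profile `E`: linear ramp-up over `theta1` seconds, plateau at 1 for `theta2`
seconds, and a fixed ramp-down of `epsilon = 0.1` s — the quick stop of
agent supply at each stage end.  `epsilon` is never optimized.  When
`theta1` falls below `1e-8` s the profile degenerates to the discontinuous
"bang" variant (`E = 0` exactly at the stage start, 1 immediately after),
which is the limit of the trapezoid as `theta1 -> 0`.

Between stages the agent solidifies where it stands, shrinking the lumen:

    A_i(x) = A_{i-1}(x) * S_{i-1}(T_{i-1}, x),

and each new stage starts from pure blood (`S_i = 1`) on the reduced lumen.
The quantity that is conserved across the break is `Psi_i = S_i A_i / A_1`,
the blood fraction of the *original* cross-section; its spatial mean is
continuous across stage boundaries by construction, and the objective of an
N-stage plan is the terminal mean `J_N = mean(Psi_N)`.

Two safety constraints encode the clinical risks: `S_i(t, L) = 1` (no agent
breakthrough into the draining vein) and `max_t p1(t) <= p_star` (no
overpressure at the feeder).  Violations switch 0/1 indicators that enter
the penalized objective `J_hat = J_N + R * sum(I1 + I2)` with `R = 1000`.

## The scheme

The conservation law is advanced by a monotone modification of the CABARET
scheme: a two-layer staggered method carrying flux variables `u_j` on the
integer nodes and conservative variables `U_{j+1/2}` on cell centers, with
second-order accuracy on smooth solutions and exact transport of linear
advection at Courant numbers 0.5 and 1.  One step comprises seven
sub-stages (each an exported, individually tested function): CFL time step;
flow and pressure evaluation; a half-time conservative predictor; inlet and
interior numerical fluxes; the full conservative update; and the
flux-variable update with two-sided limiting.

Numerical choices that were genuinely open, and how they were resolved:

* **Monotonicity cap.**  Beyond the conventional two-sided limiter, the
  scheme caps fluxes where the local four-point flux sequence is monotone:
  on nondecreasing data `f_k^{n+1/2} <= f(u_{k-1}^n) + phi_{k-1}^n` with
  `phi = A m (U_{k-1/2}^n - u_{k-1}^n) / ((tau/h) Q)`, and symmetrically
  from below on nonincreasing data.  This enforces the local bound
  `U_{k-1/2}^{n+1} >= u_{k-1}^n` (resp. `<=`), reduces to equality for
  linear advection at `r = 1` (so node-exactness survives), and leaves
  constant states untouched.  Ties in the monotonicity test take the
  nondecreasing branch.  The stencil needs `k >= 2`; the first and last
  flux nodes receive only the two-sided limiter.
* **Outflow boundary.**  All characteristics leave the domain at `x = L`,
  so no condition is imposed there; the extrapolated flux variable at the
  outlet is limited one-sidedly into `[min, max](U_{J-1/2}^{n+1}, u_J^n)`,
  which is exact on affine profiles and monotonicity-safe.
* **Breakpoint-exact stepping.**  Time steps are clipped so that the ramp
  kinks (`theta1`, start of ramp-down, stage end) are hit exactly;
  otherwise the constraint functionals sample the control profile with an
  O(tau) smear.
* **Inlet-wave CFL term.**  The CFL formula evaluates speeds at the current
  conservative values, which at each stage start are uniformly `S = 1`
  where `f'(1) = 0` for agent exponents above 1.  While injection is
  active, the largest incoming wave speed `Q max(f') / (m(0) A_i(0))` is
  included in the CFL maximum so the first steps resolve the arriving
  front.
* **Occluded cells and the resolution budget.**  The stage lumen is floored
  at `1e-6 A_1`; since characteristic speeds scale as `1/A_i`, cells that
  have effectively closed (below `1%` of `A_1`) would otherwise drive the
  step count without limit while contributing less than `1e-2` to every
  functional.  Such cells no longer bind the CFL step, and the engines
  additionally floor the step at `duration / 200000` per stage.  Physically
  resolved regimes run two orders of magnitude below both guards; the
  guards only matter for pathological (heavily penalized) control vectors
  explored by the optimizer.
* **Inverse flux.**  `f^{-1}` is a safeguarded bisection on `[0, 1]` to
  `1e-12` — robustness over speed, as it is called O(J) per step.  The
  compiled engine seeds a guarded Newton iteration from a 4097-point table
  to the same accuracy.

The per-step boundary flux uses `q_e(t^n)` with the half-layer mean `Vbar`,
reproducing the reference discretization exactly (the mixed time indexing is
an O(tau) effect).

Two interchangeable engines implement the identical scheme: a pure-R path
composed of the exported sub-stage operations (the canonical definition,
used by all scheme-verification tests), and a compiled path for the
closed-form model family (power-law mobility ratio plus the bed-curve
family) used by the optimization loops.  Tests assert their agreement to
`1e-10` on identical stages.

## The optimizer

The control vector of an N-stage plan is `(gamma_i, theta1_i, theta2_i)`,
stage-major, in the nonnegative orthant.  The modified particle swarm
method: the initialization box `[0, b_1] x ... x [0, b_{3N}]` is sliced
into M disjoint slabs along the first coordinate, one particle drawn
uniformly per slab; velocities start at zero; each iteration applies the
inertia-weighted update `w^k = w1 - w2 k / I` with cognitive/social terms,
clips negative coordinates to zero (recomputing the velocity as the
realized displacement), updates personal bests only on strict improvement,
and then reinitializes each particle with probability `P` into its own
original slab with zero velocity.  The random factors `r1, r2` are drawn
per coordinate by default (`per_coordinate = FALSE` gives the per-particle
scalar reading; the published description admits both).

Reference constants: `P = 0.15`, `w1 = 0.9`, `w2 = 0.5`, `c1 = c2 = 1.49`,
`I = 300` iterations, `M = 16` particles for two-stage plans and 32 for
three stages, penalty weight `R = 1000`, grid `J = 100`, CFL `r = 0.5`,
`epsilon = 0.1` s.  These are locked by `default_run_config()` and a
regression test.  The default box bounds (`gamma <= 30`, `theta <= 10` s)
are configuration, not constraints — positions may leave the box, only
negativity is forbidden.

## Synthetic patients

Three clinical fixtures (`patient_fixture("K" | "S" | "P")`) carry measured
geometry and filtration characteristics: length, mean cross-section,
absolute permeability, the blood relative-permeability exponent and the
critical pressure.  What cannot be shipped is each patient's measured
healthy-bed response; the generator stands in with a smooth two-parameter
family

    qbar_b(Sbar) = q_base (q_floor_frac + (1 - q_floor_frac) Sbar^q_shape),
    p2(Sbar)     = p_out_base - p_out_drop (1 - Sbar),

which is increasing, strictly positive, and bounded, as the physiology
requires.  Defaults — `q_base = 0.35` cm^3/s, `q_floor_frac = 0.15`,
`q_shape = 2`, `p_out_base = 20` mmHg, `p_out_drop = 8` mmHg — were chosen
once so that the no-injection state of every fixture sits well below its
critical pressure and a nontrivial band of injection intensities remains
pressure-feasible (the resting Darcy drop of fixture K is ~43 mmHg per
cm^3/s of flow, so inflows near 1 cm^3/s would make *any* injection unsafe
and the control problem vacuous).  `random_patient()` draws geometry
bracketing the fixtures, optionally with smoothly varying `A(x)` and
`m(x)`, and rescales `q_base` with the lumen area.

What the synthetic patients do *not* emulate: measured response curves of
real patients (only their qualitative shape), cardiac-cycle pulsatility
(the operation is much longer than a heartbeat), agent hardening during a
stage, multi-compartment AVMs.  Tests passing on synthetic patients
therefore validate the solver, the constraint machinery and the optimizer —
not the clinical calibration of any particular patient.

## Verification problems and sizes

The test suite checks, among others: node-exact linear advection at
`r = 1` over 200 steps (`J = 100`); first-order L1 convergence and a
shock-position error below 2% against an independently implemented Welge
tangent construction for the Buckley-Leverett Riemann problem
(`J = 100` vs `200`); range preservation and non-increasing total variation
on Riemann data; exact penalty bookkeeping; sphere-function recovery of the
swarm in six dimensions; and a scaled end-to-end optimization (two stages,
`M = 8`, `I = 40`, `J = 50`, search box `gamma <= 10`, `theta <= 5` s) that
must return a feasible plan strictly better than both no injection and a
fixed moderate reference plan.  The scaled sizes are the package's chosen
verification problem sizes; the reference configuration for actual studies
remains `J = 100`, `I = 300`, `M = 16/32`.

## Known limitations

* The agent viscosity is constant; ONYX hardening within a stage is not
  modeled (only between stages, via the lumen reduction).
* One spatial compartment; no network coupling beyond the scalar
  `qbar_b`/`p2` response.
* The inverse problem — recovering `f`, `k_b`, `qbar_b`, `p2` from
  intraoperative recordings — is out of scope; fixtures ship with synthetic
  response curves.
* Constraint indicators are evaluated on the recorded time layers; with
  breakpoint-exact stepping every control kink is sampled, but
  sub-step excursions of `p1` between layers are not interpolated.
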