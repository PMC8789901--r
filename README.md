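# avmemb

Simulation and optimal control of **multi-stage endovascular embolization of
cerebral arteriovenous malformations (AVMs)**.

An AVM is a congenital tangle of vessels shorting the arterial and venous
pools.  The preferred treatment fills the abnormal compartment with a viscous
embolic agent (ONYX18) injected at the arterial feeder — but pushing too hard
risks agent breakthrough into the draining vein or a dangerous pressure rise,
both associated with perioperative hemorrhage.  `avmemb` is for researchers
in computational hemodynamics and biomedical optimal control who want to
study *how hard and how long to inject, over how many stages*.

## The model in brief

Blood (saturation `S`, viscosity 4 cP) is displaced by the agent (18 cP) in a
one-dimensional porous-medium description of the compartment:

```
∂(m A S)/∂t + ∂(Q f(S))/∂x = 0,          f(S) = (k_b(S)/η_b) / (k_b(S)/η_b + k_e(1−S)/η_e)
Q(t)  = q_e(t) + q̄_b(S̄(t))              (healthy-bed redistribution)
f(S(t,0)) = q̄_b(S̄) / (q_e + q̄_b(S̄))    (integral inlet condition)
p1(t) = p2(S̄) + Q ∫ η_b f(S)/(A K k_b(S)) dx   (Darcy inlet pressure, mmHg)
```

The nonconvex conservation law is solved with a **monotone CABARET scheme**
(staggered flux/conservative variables, two-sided limiter plus a
monotonicity flux cap; exact for linear advection at Courant numbers 0.5 and
1).  Stages are chained by the solidified agent shrinking the lumen,
`A_i = A_{i−1} S_{i−1}(T_{i−1})`.  A stage injects
`q_e(t) = γ_i Q_i(T_{i−1}) E_i(t)` with a trapezoid profile
`(θ₁ᵢ ramp-up, θ₂ᵢ plateau, fixed 0.1 s ramp-down)`.  The control problem
minimizes the terminal mean blood fraction `J_N` of the original
cross-section subject to `S_i(t, L) = 1` (no breakthrough) and
`max p1 ≤ p*`, handled as a penalty `Ĵ_N = J_N + 1000 Σ(I₁ + I₂)` and
minimized by a **modified particle swarm** (disjoint-slab initialization,
decaying inertia, nonnegativity clipping, probabilistic reinitialization).

## Worked example

```r
library(avmemb)

K  <- patient_fixture("K")          # reconstructed clinical geometry
ff <- build_fractional_flow(K)
plan <- control_plan(list(stage_control(1.2, 1, 2),
                          stage_control(1.2, 1, 2)), epsilon = 0.1)
ev <- simulate_plan(K, ff, plan, grid = grid1d(K$L, 100))
print(K)
print(ev)
#> <patient_model 'K' >
#>   L = 2.4 cm, K = 7.35e-07 cm^2, k_b(S) = S^1.178, p* = 80.7 mmHg
#>   A1(0) = 2.275 cm^2, m(0) = 1, eta_b = 0.04 P, eta_e = 0.18 P
#>   qbar_b(1) = 0.35 cm^3/s, p2(1) = 20 mmHg
#> <plan_evaluation: 2 stage(s)>
#>   J_N = 0.666865, J_hat = 0.666865
#>   stage 1: I1 = 0, I2 = 0, max p1 = 64.91 mmHg, min S(L) = 1.000000
#>   stage 2: I1 = 0, I2 = 0, max p1 = 61.40 mmHg, min S(L) = 1.000000
```

Two moderate stages (intensity 1.2× the inflow, 1 s ramp, 2 s plateau)
displace a third of the blood (`J_N` falls from 1 to 0.667): the inlet
pressure peaks at 64.9 mmHg, safely under the critical 80.7 mmHg, and no
agent reaches the outlet (`min S(L) = 1`), so no penalties apply
(`Ĵ_N = J_N`).  To search for an optimal plan instead, hand
`simulate_plan ∘ unpack_plan` to `pso_optimize()`, or use the config-driven
CLI (`inst/cli/avmemb simulate|optimize|make-patient`).

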