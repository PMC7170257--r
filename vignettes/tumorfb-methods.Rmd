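---
title: "tumorfb: model, numerics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tumorfb: model, numerics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`tumorfb` simulates a radially symmetric melanoma occupying the ball
$0 \le r \le R(t)$ with a free boundary.  Three cell populations share the
tissue -- cancer cells $C$, activated dendritic cells $D$ and cytotoxic
lymphocytes $T$ (all in g/cm$^3$) -- under the incompressibility closure

$$D + T + C = \rho_{tot} = 0.4014 \ \mathrm{g/cm^3},$$

so net cell production creates a radial velocity $u(r,t)$,

$$\frac{1}{r^2}\frac{\partial}{\partial r}\!\left(r^2 u\right)
  = \frac{F_D + F_T + F_C}{\rho_{tot}},
  \qquad \dot R = u(R, t),$$

where $F_X$ are the reaction terms (cell diffusion cancels in the sum
because the three populations share one diffusivity).  Five more fields
diffuse on the same domain: the cytokines IL-12 ($I_{12}$, secreted by
DCs, activates T cells) and TNF-$\alpha$ ($T_\alpha$, secreted by T cells
and by an implicit macrophage source $A_{T\alpha}$), the checkpoint
receptor PD-1 ($P$, riding on T cells), and the two antibodies: anti-PD-1
($A$) and anti-TNF-$\alpha$ ($B$), injected as spatially uniform
pulse-decay sources $\gamma \sum_{t_i < t} e^{-\beta (t - t_i)}$.

T-cell activation is throttled by two quasi-steady checkpoint complexes:

* PD-1--PD-L1, with PD-L1
  $L = \rho_L (T + \varepsilon_C C)(1 + \alpha_L \,
  T_\alpha/(K_{T\alpha} + T_\alpha))$ upregulated by TNF-$\alpha$;
* TIM-3--Gal-9, with TIM-3
  $T_M = \rho_M T\,[1 + \alpha_T\,
  \tfrac{T_\alpha}{K_{T\alpha} + T_\alpha}
  (1 + \alpha_{MA} \tfrac{A}{K_A + A})]$ -- the $\alpha_{MA}$ factor is
  the modelled *resistance to anti-PD-1*: the drug itself upregulates
  TIM-3, TNF-$\alpha$-dependently, and Gal-9 $G = \rho_G C$.

Activation is multiplied by
$f_{Q1} f_{Q2} = \frac{1}{1 + PL/K_{TQ1}} \cdot \frac{1}{1 + T_M G/K_{TQ2}}$.
Anti-TNF-$\alpha$ suppresses $T_\alpha$ and thereby both ligand
upregulations, which is why the combination is expected to beat anti-PD-1
monotherapy.

Boundary conditions at $r = R(t)$: Robin influx for $T$ and $P$
($\partial_r T + \sigma_T(I_{12})(T - \hat T) = 0$ with
$\sigma_T = \sigma_0 I_{12}/(K_{I12} + I_{12})$ -- naive T cells enter
only where IL-12 signals), homogeneous Neumann for $D$, $I_{12}$,
$T_\alpha$, $A$, $B$, and $C = \rho_{tot} - D - T$ from the constraint.
PD-1 starts on and, without drug, stays on the exact manifold
$P = \rho_P T$.

## Parameters

All constants live in a `tfb_params` object (`default_parameters()`),
keyed by ASCII transliterations (`delta_D`, `lambda_C_mouse`, `K_TQ1`,
...), in g/cm$^3$, cm and day units.  Most were derived by three rules,
re-implemented and tested here:

* **Half-saturation rule** $K_X = X^0$: each Michaelis constant equals
  the species' assumed steady state.
* **Cube-root diffusivity scaling** (`young_diffusion()`):
  $D_p = D_V (M_V/M_p)^{1/3}$ anchored at VEGF (24 kDa,
  $8.64\times10^{-2}$ cm$^2$/day).  This reproduces the published
  anti-PD-1 ($4.76\times10^{-2}$) and TNF-$\alpha$ ($8.46\times10^{-2}$)
  values; the published IL-12 value ($7.17\times10^{-2}$) does *not*
  follow from the formula (it yields $7.47\times10^{-2}$) and is kept as
  printed.
* **Steady-state closures** (`derive_closure_rates()`): each production
  rate solves its equation's steady state with every species at its
  target and activation factors at $1/2$; blocking rates assume 10% of
  each drug is consumed by target binding.

Three published values are internally inconsistent; the package makes the
following choices (all selectable by config):

* `lambda_TaT` (TNF-$\alpha$ production by T cells): the sources print
  $1.08\times10^{-6}$ (text) and $6.48\times10^{-4}$ (table) while the
  closure gives $(d_{T\alpha} K_{T\alpha} - A_{T\alpha})/K_T =
  5.36\times10^{-6}$/day.  The closure value is the default -- it is the
  only one under which $T_\alpha$ actually settles at $K_{T\alpha}$, as
  the half-saturation rule requires.
* `mu_PA`: the closure $d_A/(9 P^0)$ gives $2.05\times10^{7}$; the table
  prints $1.03\times10^{7}$ (a factor-2 arithmetic slip in the source).
  The table value is the default because it is the declared simulation
  input; the deviation is recorded in the validation log.
* `d_T`: 0.197/day in simulations (table), 0.18/day inside closures
  (estimation text); `eta` similarly 328.55 vs 328.
* `K_A` (anti-PD-1 half-saturation in the TIM-3 upregulation) is absent
  from the published table; the default $10^{-10}$ g/cm$^3$ is the order
  of the quasi-steady drug level at the mouse dose
  ($\gamma_A/(\beta + d_A) \approx 6\times10^{-11}$).  It is genuinely
  unconstrained and configurable.
* `beta` is printed with a concentration unit but multiplies time in an
  exponential; it is treated as 1.55/day.

A further inconsistency is worth knowing about: at the published
$\rho_P, \rho_L, \varepsilon_C, K_{TQ1}, K_{TQ2}$ and the stated steady
densities, the emergent inhibition $f_{Q1} f_{Q2} \approx 0.09$, not the
$1/1.8$ the closure for `lambda_TI12_T0` assumes (the cancer term
$\varepsilon_C C \approx 0.04$ dominates $T \approx 10^{-3}$ in $L$).
The package uses the mechanistic $f_Q$ formulas in simulation and the
printed $1/1.8$ only inside that closure, as the source does.
Consequences are discussed under *Limitations*.

## Numerics

The solver (`simulate()`, compiled core with a pure-R reference
implementation of every piece) is the moving-mesh explicit Euler scheme:

* **Lagrangian form.** Cell fields obey
  $dX/dt = \delta_X \nabla^2 X + F_X - X \,\mathrm{div}\,u$ along node
  trajectories $\dot r_i = u_i$; advection is absorbed by the node
  motion.  $\mathrm{div}\,u$ equals the velocity source exactly, so a
  state on the constraint manifold $D+T+C=\rho_{tot}$ stays on it to
  machine rounding -- conservation is a genuine diagnostic, not an
  enforced renormalization (a control run holds it to $\sim10^{-15}$).
* **Cytokines/drugs** have diffusivities $\sim10^5$ larger than cells;
  their advection is neglected: they are updated on the frozen mesh and
  linearly re-interpolated to the moved nodes each step.
* **Stencils.** First/second derivatives use the three-point nonuniform
  formulas; at $r=0$ the symmetry limit $3\,\partial_{rr}$ with a
  mirrored ghost gives $6(X_1 - X_0)/h^2$.  The printed first-derivative
  formula carries a sign error on the $X_i$ coefficient (as printed it is
  not exact even for constants off uniform meshes, and it seeds an
  exponentially amplified conservation violation); the implementation
  uses the sign that makes the stencil polynomial-exact, which reduces to
  the same central difference on uniform meshes.
* **Time step.** $\tau = s\,\min_i h_i^2/(2 D_{max})$ with safety
  $s = 0.9$ and $D_{max} \approx 8.46\times10^{-2}$ cm$^2$/day, further
  capped by the fastest reaction rate (TNF-$\alpha$ turnover,
  $d_{T\alpha} = 216$/day, plus drug blocking) so the explicit update
  stays stable when the tumor -- and hence $h$ -- grows large.  Steps land
  exactly on output times.
* **Velocity quadrature** integrates $S r^2$ exactly for piecewise-linear
  $S$, so a constant source reproduces $u = S r / 3$ to rounding.
* **Regrid.** Nodes are re-laid uniformly on $[0, R]$ (linear
  interpolation) when the spacing ratio exceeds 1.5 or the boundary has
  moved 10% since the last regrid.  Linear interpolation preserves the
  conservation constraint and the $P = \rho_P T$ manifold exactly.
* **Guards.** Negative undershoots (the cytokine fields sit near the CFL
  limit and can undershoot by $\sim10^{-16}$ of their scale) are clipped
  to zero and counted; the clip count is reported.  $P/T$ uses a
  $10^{-12}$ floor.  A radius below `r_min` (default 0.01 cm) is treated
  as tumor elimination and the state frozen.  Non-finite values or a
  conservation deviation beyond 1% of $\rho_{tot}$ abort the run.

Default resolution is $N = 100$ mesh intervals with 0.5-day output
cadence; a 30-day mouse control run takes a few seconds.  Dose-map and
sensitivity sweeps in the test suite use $N = 50$ (a desk-scale choice
fixed a priori; halving $N$ changes the 30-day control radius by well
under 1%).

## Experiments

* `run_control()`: untreated mouse baseline.
* `efficacy_map()`: one human-parameter simulation per
  $(\gamma_A, \gamma_B)$ grid point under 3-week cycles S1 (both drugs on
  day 0), S2 (anti-PD-1 day 0, anti-TNF-$\alpha$ day 7) or S3 (the
  reverse), scored by the tumor volume reduction rate
  $\mathrm{TVRR} = (V(0) - V(t_e))/V(0) \times 100\%$.  "First day of
  week $k$" maps to cycle day $7(k-1)$ with the course starting at
  simulation day 0.
* `sensitivity_analysis()`: Latin hypercube sampling
  (`lhs_sample()`, one draw per stratum, independently permuted margins)
  of the nine production/blocking/kill parameters in $\pm50\%$ ranges
  around the mouse baseline (the ranges are unstated in the source;
  $\pm50\%$ is the conventional PRCC choice and is configurable),
  followed by partial rank correlation (`prcc()`) of the tumor radius at
  day 30.  The mouse treatment protocol (both drugs at days 6/10/13) is
  applied so the blocking rates `mu_PA` and `mu_TaB` are exercised at
  all -- an interpretation, flagged as such.  `prcc()` is regression-based
  and is cross-checked against a correlation-matrix-inversion oracle to
  $10^{-10}$.

## What the simulations do and do not establish

The package reproduces every closed-form published quantity it targets
(closure rates, diffusivities, clearance rates), holds the conservation
law to machine precision, keeps PD-1 on its exact no-drug manifold, and
converges under mesh refinement.  The dominant PRCC signs (growth rate
strongly positive; kill rate, DC/T-cell/IL-12 production negative)
reproduce the published sensitivity pattern.

Several headline *qualitative* claims of the source do **not** emerge
from the printed parameter set, and the corresponding acceptance
expectations are deliberately left failing rather than tuned:

* With the published checkpoint constants the steady T-cell density stays
  near $10^{-4}$ g/cm$^3$ (inhibition $\approx 0.09$ and dilution by
  growth, see above), so the maximum drug-induced kill rate
  ($\eta T \lesssim 0.1$/day) never overcomes net tumor growth
  ($\approx 0.25$/day for humans).  TVRR is therefore large and negative
  at every dose in the published ranges instead of the reported
  75--99%.
* At the published `mu_PA` and doses $\gamma_A \le 10^{-11}$
  g/cm$^3$/day, anti-PD-1 depletes under 2% of PD-1 over a full course --
  it is pharmacologically inert except for its TIM-3 (resistance) side
  effect, which makes TVRR slightly *decreasing* in $\gamma_A$ and makes
  S2 (a week of uncovered anti-PD-1) slightly *worse* than S1/S3,
  inverting the published schedule ranking.  TVRR remains monotone in the
  anti-TNF-$\alpha$ dose, which carries essentially all of the efficacy.
* In the control run the averaged $T$ and $I_{12}$ rise as published,
  but averaged $D$ and $T_\alpha$ fall (their sources cannot keep up with
  the dilution $-X\,\mathrm{div}\,u$ at the simulated growth rate).

A green test here therefore establishes internal correctness of the
implementation against the stated equations and constants -- not that
those constants reproduce the source's figures.  The synthetic world is
exactly the printed parameter set; no generator default, tolerance or
seed was adjusted after observing an outcome.

## Known limitations

Radial symmetry only; no macrophage population (folded into
$A_{T\alpha}$); explicit checkpoint complexes replaced by their
quasi-steady products; fully explicit time stepping (no implicit
variant); pulse-decay pharmacokinetics without compartments; model doses
are correlated with, not equal to, clinical doses.
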