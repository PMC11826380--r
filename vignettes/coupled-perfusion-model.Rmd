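---
title: "Coupling poroelastic tissue to a lumped hydraulic circuit: models, schemes, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling poroelastic tissue to a lumped hydraulic circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`porocirc` simulates perfusion of a soft tissue block. Blood in the
microvasculature is treated as pore fluid in a deformable porous solid
(Biot poroelasticity), while the feeding circulation is compressed into a
lumped hydraulic network, the hydraulic analogue of an electrical RCL
circuit. The two subsystems exchange a pressure and a flow rate across one
face of the tissue domain.

**Tissue.** On the box $\Omega = (0,c)\times(-a/2,a/2)\times(-b/2,b/2)$ the
unknowns are the solid displacement $u$ and the pore pressure $p$. Because
soft tissue has nearly the density of water, inertia is dropped
(quasi-static balance) and both constituents are treated as incompressible,
which fixes the storage coefficient to zero and the Biot--Willis coefficient
to one:

$$-\mu_e\Delta u - (\lambda_e+\mu_e)\nabla(\nabla\!\cdot\!u) + \nabla p = F,
\qquad
\partial_t(\nabla\!\cdot\!u) + \nabla\!\cdot\!v = S,
\qquad v = -k\nabla p .$$

The total stress is $T = 2\mu_e E(u) + \lambda_e(\nabla\!\cdot\!u)I - pI$
with $E(u)$ the symmetric gradient, $v$ is the Darcy discharge velocity and
$k$ the permeability. The aggregate modulus $H_A = \lambda_e + 2\mu_e$ is
the 1D confined-compression stiffness.

**Circuit.** The network state
$y = (\pi, \Pi_1, \dots, \Pi_{n_C}, Q_1, \dots, Q_{n_L})$ (connecting-node
pressure, capacitor pressure drops, inductor flow rates) obeys

$$\frac{dy}{dt} = A y + s(t) + \frac{Q(t)}{C}e_1 ,$$

where $s$ collects pressure/flow sources and $Q$ is the inflow from the
tissue. The energy matrix $U = \mathrm{diag}(C, C_1, \dots, L_1, \dots)$
defines the stored energy $\tfrac12 y^\top U y$, and $B = -UA$ the
dissipation form $y^\top B y$. For a passive network the symmetric part of
$B$ is positive semidefinite; the bundled three-state example (source
resistor $\bar R$, capacitor $C_1$, inductor $L_1$ in series with $R_1$,
connecting node $C$) has
$y^\top B y = \Pi_1^2/\bar R + R_1 Q_1^2$, which vanishes on pure
connecting-node states, so the package validates *semi*definiteness rather
than strict definiteness.

**Connection and interface variants.** The circuit meets the tissue across
the face $\Sigma$ (area $m_\Sigma$) through a resistor $R$ and a grounded
capacitor $C$, with the hydraulic Ohm law $Q = (P - \pi)/R$ linking the two
resistor-end pressures. The elastic phase is clamped on $\Sigma$ ($u=0$).
Two treatments of pressure continuity are implemented:

* **PPC** (pointwise): $p \equiv P(t)$ on $\Sigma$ and
  $Q = \int_\Sigma v\cdot n$. The trace pressure is spatially constant by
  construction; the velocity condition is nonlocal.
* **IPC** (integral): $K\,v\cdot n = p - \pi$ pointwise with
  $K = R\,m_\Sigma$, and $P = \tfrac{1}{m_\Sigma}\int_\Sigma p$. Only the
  mean pressure is matched; the trace may vary in space.

Both variants dissipate energy in the connection: $D_\Lambda = RQ^2$ for
PPC and $D_\Lambda = \tfrac1K\int_\Sigma (p-\pi)^2$ for IPC, and the coupled
system satisfies an energy identity
$\tfrac{d}{dt}(E_\Omega + E_\Upsilon) + D_\Omega + D_\Upsilon + D_\Lambda
= \mathcal F$ where $E_\Omega$ is the strain energy, $D_\Omega =
\|k^{1/2}\nabla p\|^2$ the Darcy dissipation, and $\mathcal F$ the forcing
work. On problems whose data depend on $x$ only, the two variants coincide
exactly (the mean of a constant trace is that constant), which is the basis
of several package tests.

## Discretization

**Space.** Conforming Galerkin finite elements on structured box meshes:
trilinear (Q1) hexahedra by default, with the 6-tetrahedra Kuhn split (P1)
as an alternative, and linear elements on the 1D column. Displacement and
pressure use equal-order continuous spaces. No inf-sup pairing or pressure
stabilization is required here: after Backward Euler discretization the
pressure block carries the Darcy stiffness $k\,\Delta t\,(\nabla p,\nabla
q)$, which is elliptic on the pressure space, so the coupled step matrix is
nonsingular in the targeted regimes ($k\,\Delta t$ far from the
incompressible-Stokes limit; the reference configuration has $k = 1$,
$\Delta t = 0.02\,$s). Quadrature is exact for every polynomial integrand
used ($2^3$ Gauss points per hexahedron, a degree-2 rule per tetrahedron,
matching rules on boundary facets).

A deliberate property of the hexahedral default: the trilinear basis is a
tensor product, so on data that depend on $x$ only the discrete solution is
*exactly* one-dimensional (transverse displacement components and in-plane
pressure variation at rounding level, not merely at discretization error).
This mirrors the invariance of the continuous problem and makes the
"1D-conducive" benchmark a sharp machine-precision test rather than a
mesh-convergence statement. The 1D column solver scales all integrals by
the cross-section $ab$, so its energies and flow rates are directly
comparable with 3D runs; with matching axial resolution the two solvers
produce identical profiles to solver precision.

**Time: Backward Euler with the eliminated interface condition.** Each step
solves the Biot system implicitly. For IPC the connecting-node update
$\pi^{n+1} = (RC\,\pi^n + \Delta t\,P^{n+1})/(RC+\Delta t)$ is substituted
into the interface law, producing a Robin-type boundary condition with a
rank-one nonlocal mean term,

$$K v^{n+1}\!\cdot n - p^{n+1}
 + \frac{\Delta t}{RC+\Delta t}\,\frac{1}{m_\Sigma}\!\int_\Sigma p^{n+1}
 = -\frac{RC}{RC+\Delta t}\,\pi^n ,$$

implemented as a bordered sparse system with the single extra unknown
$P^{n+1}$ and the defining row $m_\Sigma P = \int_\Sigma p$. For PPC the
trace pressure unknowns are condensed into the single scalar $P$ (an exact
constraint -- no penalty parameter), and the condensed row receives
$Q = C(P-\pi^n)/(RC+\Delta t)$. In both variants the recovered triple
$(P, \pi^{n+1}, Q)$ satisfies the Ohm law identically, which the package
checks as an a posteriori residual. The step matrix does not depend on
time, so it is factorized once (sparse LU) per run.

## Operator splitting and why it is unconditionally stable

Each time step has two substeps that communicate only through initial
conditions, with no sub-iterations:

1. **Step 1** -- Biot + connection: the tissue system and the scalar ODE
   $C\,d\pi/dt = Q$ are advanced together by Backward Euler with the
   variant's interface treatment. Internal circuit states are frozen.
2. **Step 2** -- internal circuit: $dy/dt = Ay + s(t)$ is advanced by
   Backward Euler from the half-updated state (no $Q$ input). $(u,p)$ are
   frozen.

Testing Step 1 with the displacement increment and the new pressure, and
Step 2 with $Uy^{n+1}$, yields a *discrete* energy identity in which every
physical dissipation appears with its correct sign plus nonnegative
increment-quadratic defect terms ($\tfrac12 a(\delta u,\delta u)$,
$\tfrac12 C\,\delta\pi^2$, $\tfrac12 \delta y^\top U \delta y$). Because
nothing in the derivation constrains $\Delta t$, the unforced total energy
is non-increasing for *every* step size -- the package asserts this over
step sizes spanning $10^{-4}$ to $10\,$s. `audit_energy()` reports both the
defect-free balance (which equals the splitting defect, first order in
$\Delta t$) and the sharp identity (which closes to solver precision, near
$10^{-14}$ relative in practice). The substep order may be reversed
(`order = "circuit_first"`); stability is unaffected and the two orderings
agree to $O(\Delta t)$.

## The PQP fixed-point alternative and its failure mode

The partitioned iteration decouples the models inside each step: solve the
tissue with Dirichlet data $p|_\Sigma = P_j$, extract the variationally
consistent interface flow $Q_{j+1}$, drive a circuit Backward Euler update
with it, and set $P_{j+1} = \pi_{j+1} + R\,Q_{j+1}$. The map
$P_j \mapsto P_{j+1}$ is affine (the problem is linear); convergence
requires its slope magnitude $\hat\gamma_2 < 1$. The slope is essentially
$R\,\partial Q/\partial P$, and the instantaneous flux response to a
boundary-pressure change grows like the inverse diffusion-layer width
$\sim \sqrt{H_A k/\Delta t}$, so $\hat\gamma_2$ *increases* as the step
shrinks and as $R$ grows -- refining the time step eventually destroys
convergence, with geometric iterate blow-up. `run_pqp()` records per-step
iteration counts and the empirical $\hat\gamma_2$, guards against overflow
(default $10^{12}$), and reports divergence as diagnostics rather than an
error; defaults are tolerance $10^{-10}$ and 100 inner iterations. In the
reference configuration with $R = 10$ the recorded factor rises through 1
between $\Delta t = 10^{-2}$ and $10^{-3}\,$s, while the operator-splitting
integrator on the identical problem remains bounded -- the package's
acceptance checks reproduce exactly this contrast. The inner Dirichlet
solve uses the full-trace condition for both variants; applying it under
IPC input data should be considered experimental.

## Parameters, presets and the synthetic configurations

Reference values (SI units throughout):

| parameter | meaning | default | notes |
|---|---|---|---|
| $k$ | permeability (m$^4$N$^{-1}$s$^{-1}$) | 1 | reference configuration |
| $H_A$ | aggregate modulus (Pa) | 1 | split as $\lambda_e=0.5$, $\mu_e=0.25$ |
| $\bar R, R_1, R$ | resistances (N s m$^{-5}$) | 1 | connection $R$ separately settable |
| $C, C_1$ | capacitances (m$^5$N$^{-1}$) | 0.1 | $C$ is the connection capacitance |
| $L_1$ | inductance (N s$^2$m$^{-5}$) | 1 | |
| box | $c\times a\times b$ (m) | $0.5\times0.1\times0.1$ | $m_\Sigma = 10^{-2}$ m$^2$ |
| $\Delta t$ | time step (s) | 0.02 | final time 10 s |

Only $H_A$ is physically determined in 1D; the $\lambda_e/\mu_e$ split is a
free choice in 3D and is fixed once at $0.5/0.25$.

Two preset drives emulate the regimes of interest:

* `preset_oned_conducive()` -- *1D-conducive*: all forcing enters through the
  circuit source $\bar p(t) = A\sin(2\pi t/5)$ (period 5 s chosen to give a
  few cycles over the 10 s window). The amplitude is auto-scaled by
  linearity so the peak interface pressure equals the 0.1 Pa target: a
  cheap 1D run with unit amplitude measures the peak and the amplitude is
  divided out. Under both variants the interface trace is flat -- exactly
  for PPC, at rounding level for IPC on the hexahedral mesh.
* `preset_infiltration()` -- *genuinely 3D*: oscillatory infiltration
  $v\cdot n$ on two clamped faces (a standing cosine pattern on $x=0$, a
  Gaussian spot on $y=-0.05$, periods 10 s and 20/3 s), everything else as
  above. Here the IPC trace develops a finite spatial spread while PPC
  remains flat by construction, and the two variants genuinely differ.

What these synthetic configurations do *not* emulate: irregular anatomy
(the domain is a box), heterogeneous or anisotropic permeability and
stiffness, nonlinear or viscoelastic tissue response, multiple coupling
interfaces, and physiological pressure magnitudes (values are
order-unity reference units, not mmHg). Passing tests therefore certify
the numerical structure -- energy stability, interface treatment,
convergence orders -- not predictive accuracy for a specific tissue.

## Numerical choices and degenerate inputs

* **Circuit oracle.** The variation-of-constants solution
  $y(t) = e^{At}y_0 + \int_0^t e^{A(t-\tau)}(s+bQ)\,d\tau$ is evaluated
  with piecewise-constant sources on a uniform micro-grid (default $10^4$
  intervals) sampled at interval midpoints and propagated exactly through
  an augmented-matrix exponential; the augmented form handles singular $A$
  (e.g., the pure-integrator test circuit $A=0$). Midpoint sampling makes
  the oracle second order in the micro step, far below the first-order
  Backward Euler errors it referees.
* **Passivity tolerance.** The symmetric part of $B$ must have eigenvalues
  $\ge -10^{-12}\|B\|$; exact semidefiniteness is accepted.
* **Solvability.** $(I-\Delta t A)$ is nonsingular for passive circuits and
  every $\Delta t>0$; a singular system raises an error identifying the
  solver. The coupled step matrix is validated implicitly by the sparse LU
  factorization.
* **Constraints.** All essential conditions are homogeneous ($u=0$, $p=0$,
  $u\cdot n=0$) and imposed by degree-of-freedom elimination -- no penalty
  parameters anywhere. Initial displacements are projected onto the
  constrained space.
* **Configuration safety.** Forcing expressions in YAML configs are parsed
  against a whitelist grammar (`sin`, `cos`, `tan`, `exp`, `sqrt`, `abs`,
  `log`, arithmetic, coordinates and `t`), so configuration files cannot
  execute arbitrary code. Unknown keys are rejected with the field path.
* **Outputs.** Time series are written at full double precision (17
  significant digits); identical configurations reproduce bitwise-identical
  CSV files. Field snapshots use legacy ASCII VTK.

## Problem sizes used by the test suite

The shipped tests and the acceptance script use problem sizes chosen to
exercise every claim while keeping a full run in the tens of seconds on one
CPU: the 3D benchmarks run on $12\times5\times5$ and $10\times5\times5$
hexahedral grids (axially equivalent to the 1.5--2k-element simplicial
meshes one would use at the same resolution) for 500 steps of 0.02 s;
mesh-convergence checks use $3^3$ and $6^3$ cells; the 1D column uses
40--50 intervals. All of these are configurable, and nothing in the
implementation is specific to these sizes.

## Known limitations

* Quasi-static, incompressible-constituent Biot only; the fully dynamic or
  compressible-storage variants are out of scope.
* One coupling interface; the clamped condition $u=0$ on $\Sigma$ is the
  only elastic interface option.
* Structured box meshes only; no import of external unstructured meshes.
* First-order time accuracy (Backward Euler splitting); no adaptivity.
* The closed-form contraction coefficients of the PQP map are not
  computed -- only the empirical factor $\hat\gamma_2$ is estimated, so the
  divergence threshold is demonstrated qualitatively, not pinned to a
  universal step size.
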