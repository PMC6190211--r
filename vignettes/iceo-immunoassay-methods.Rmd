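---
title: "Methods: simulating ICEO-enhanced immunoassay binding"
author: "iceobind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating ICEO-enhanced immunoassay binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The physical problem

A heterogeneous immunoassay immobilizes antibodies on a patch of a
microchannel wall and waits for freely suspended antigen to find them. At
nanomolar concentrations and nanometer-scale analytes (diffusivity
$D \sim 10^{-11}\,\mathrm{m^2/s}$) the binding reaction is much faster than
diffusion can feed it: a depletion boundary layer grows over the
functionalized patch and throttles the assay. `iceobind` simulates one remedy:
a *floating gate electrode* — an electrically isolated metal strip on the
channel bottom — polarized by an AC field applied between the channel end
walls. The field acting on the ionic charge it itself induces in the gate's
double layer drives induced-charge electroosmosis (ICEO): a pair of
counter-rotating vortices over the gate that stir fresh antigen toward the
antibodies.

The simulator reproduces, in 2D, the full chain

1. **Electrostatics.** Quasi-static complex-phasor Laplace problem
   $\nabla^2\tilde\phi = 0$ with $\tilde\phi = V_0$ / $0$ on the left/right
   end walls and the thin-double-layer RC charging condition on the gate,
   $-\sigma_f(n\cdot\nabla\tilde\phi) = \tfrac{j\omega C_D}{1+\delta}
   (\tilde V_0 - \tilde\phi)$, where $n$ points from the electrode into the
   bulk, $C_D = \varepsilon_f/\lambda_D$ is the Debye capacitance and
   $\delta = C_D/C_S$ the Stern-layer capacitance ratio. The floating gate
   potential $\tilde V_0$ is an extra unknown closed by charge conservation
   (zero net charging current over the gate).
2. **ICEO slip.** Induced zeta
   $\tilde\zeta = (\tilde V_0 - \tilde\phi)/(1+\delta)$ and the
   time-averaged generalized Helmholtz–Smoluchowski slip
   $\langle u_{s}\rangle = -\tfrac{\varepsilon_f}{2\eta}
   \mathrm{Re}(\tilde\zeta \tilde E_t^{*})$ on the gate. Both factors scale
   linearly with $V_0$, so the slip is exactly quadratic in the drive.
3. **Stokes flow.** Steady incompressible Stokes flow with the slip as
   tangential Dirichlet data on the gate, no slip elsewhere, and (for
   flow-through runs) a parabolic inlet and zero-traction outlet.
4. **Transport–reaction.** Transient advection–diffusion of the antigen
   coupled, on the functionalized half of the gate, to first-order Langmuir
   kinetics $\partial_t B = k_{on} C_w (R_T - B) - k_{off} B$ through the
   flux-exchange condition: the diffusive flux into the wall equals the
   local $\partial_t B$, applied along the local wall normal.

The figure of merit is the binding enhancement factor
$Be = B/B_0$ at $t = 100\,$s: bound antigen with the drive on over bound
antigen with the drive off, both surface-averaged over the functionalized
segment and computed on the same mesh with the same time step.

# Study conditions and the scenario generator

No external data exist; every input is a physical or geometric parameter.
`make_scenario()` encodes the two study conditions:

* `static_chamber`: closed $1000 \times 200\,\mu$m chamber, $50\,\mu$m wide
  and $200\,$nm tall gate centered on the bottom, no through-flow,
  integrated to $100\,$s;
* `continuous_flow`: $1000 \times 50\,\mu$m channel, parabolic inlet of
  mean $50\,\mu$m/s, integrated to $17\,$s.

Shared defaults: $\sigma_f = 1\,$mS/m, $R_T = 3.3\times10^{-8}\,$mol/m$^2$,
$C_0 = 10^{-7}\,$mol/m$^3$, $k_{off} = 10^{-3}\,$s$^{-1}$,
$D = 10^{-11}\,$m$^2$/s, drive $4\,$V at $10\,$Hz. Dimensionless sweeps are
mapped onto physical knobs: the Damkohler number $Da = k_{on} R_T h / D$ by
rescaling $k_{on}$ (with $k_{off}$ fixed), the Peclet number $Pe = u h / D$
by rescaling the inlet velocity.

Parameter decisions that the source material leaves open:

* **$k_{on}$ units.** The printed association constant
  ($10^{-6}\,\mathrm{M^{-1}s^{-1}}$) is dimensionally inconsistent with the
  printed $Da = 660$ for the same parameter set; $Da = k_{on}R_T h/D$ forces
  $k_{on} = 10^{6}\,\mathrm{M^{-1}s^{-1}} = 10^{3}\,\mathrm{m^3/(mol\,s)}$.
  We adopt the latter and treat the printed exponent as a typo; `damkohler()`
  then returns 660 exactly.
* **$\lambda_D$ and $\delta$.** Only the conductivity is stated. The Debye
  length follows from the symmetric-electrolyte relation
  $\lambda_D = \sqrt{\varepsilon_f D_{ion}/\sigma_f} \approx 37.6\,$nm
  (small-ion $D_{ion} = 2\times10^{-9}\,$m$^2$/s), and $\delta$ defaults to 0
  (no Stern layer); both are exposed as knobs. At the headline drive
  frequency (10 Hz, far below the RC relaxation) the slip is insensitive to
  both, which is why the headline $Be$ is robust to this gap.
* **Water properties.** $\varepsilon_f = 7.08\times10^{-10}\,$F/m,
  $\eta = 10^{-3}\,$Pa·s — standard aqueous values.
* **Functionalized span.** "Left side of the gate surface": we take the left
  half ($25\,\mu$m).
* **Gate position.** Centered at $x = 500\,\mu$m (read from the device
  sketch; not printed).

# Discretization

All solvers share one linear (P1) triangular finite-element kernel built on
sparse `Matrix` algebra.

**Mesh.** A tensor-product graded grid, split into triangles whose diagonals
mirror about the gate centerline, so the mesh is exactly symmetric and
discrete solutions inherit the continuous symmetries (the computed slip
profile is odd about the gate center to machine precision). Cell sizes grade
from $2\,\mu$m at the gate corners and the bottom wall to $5\,\mu$m in the
bulk at `resolution = 1`, with the local $dx\!:\!dy$ ratio capped near 3 so
every triangle's minimum angle stays above $15^\circ$ at any resolution.
That anisotropy cap is also why the corner cells are $w_g/25$ at
`resolution = 1` (a $w_g/50$ corner column against $5\,\mu$m rows would
break the angle floor); $w_g/50$ is reached from `resolution ≈ 2.5`.
Gates shorter than $1\,\mu$m collapse to a flat boundary segment (a 200 nm
feature under a 200 $\mu$m channel would force extreme aspect ratios for no
visible change in the fields); taller gates are meshed as raised blocks
whose top *and sidewalls* carry the charging condition and the slip.
`grid_independence()` re-runs any scalar quantity across resolutions and
flags changes above 2%.

**Electrostatics.** The complex Robin problem and the floating potential are
solved in one shot as a bordered real system (real/imaginary blocks plus two
rows for charge conservation) — no outer iteration. The net gate charging
current vanishes to solver precision ($\sim10^{-22}$ of the drive scale).
Because the charging coefficient is uniform on the gate, charge conservation
makes $\tilde V_0$ the gate average of $\tilde\phi$; on the symmetric
geometry it equals $V_0/2$ exactly. $\omega = 0$ is rejected: the DC limit
is served by the closed forms (`dc_limit_slip`), against which the 10 Hz
numerical slip agrees pointwise to well under 10%. Independent limit solves
(`solve_potential_limit`) — insulating gate and equipotential-conductor gate
— bracket the RC solution at $f \ll f_{RC}$ and $f \gg f_{RC}$.

**Slip extraction.** $\tilde E_t$ is the arclength derivative of the
boundary potential per facet; $\tilde\zeta$ uses facet-midpoint potentials.
At raised-gate corners the facet-averaged evaluation is the mesh-size-limited
regularization of the field singularity — the slip formula is a thin-layer
model that is not valid at a geometric corner anyway, so we do not chase the
singular value. Profiles store signed tangential velocities; sweep outputs
report the length-weighted mean of magnitudes.

**Stokes.** Equal-order P1/P1 velocity–pressure elements with
Brezzi–Pitkaranta pressure stabilization ($\gamma h_K^2/\eta$, $\gamma =
0.05$), an inf-sup-stable formulation with no spurious pressure modes. The
closed chamber gauges pressure to zero mean through a Lagrange multiplier.
Slip enters as nodal Dirichlet data (facet slips averaged to nodes; gate end
nodes shared with no-slip walls stay at rest — the discrete version of the
corner regularization). Solutions are exactly linear in the slip amplitude
(checked to $10^{-10}$), divergence-free in the discrete sense to solver
precision, and superpose (chamber ICEO + Poiseuille = combined solve).
Inertia is dropped entirely ($Re \ll 1$) and the $2\omega$ oscillatory
component of the slip is ignored, consistent with time-averaged forcing.

**Transport–reaction.** Implicit first-order time stepping with the surface
ODE eliminated *into* the bulk solve: backward-Euler elimination of $B$
turns the flux-exchange condition into a linear wall term in $C^{n+1}$, so
bulk and surface advance together (a tightly coupled step, as the transient
problem demands). The advective term uses the conservative form
$-\int C\, u\cdot\nabla v$ plus streamline (SUPG) stabilization; with the
lumped wall coupling this conserves $\int C\,dV + \int B\,ds$ in the closed
chamber to linear-solver precision (measured drift $\sim10^{-14}$ over
100 s, against the $10^{-3}$ requirement). The constant part of the operator
is LU-factorized once and the step-dependent wall term (it tracks
$R_T - B^n$) is applied through the Woodbury identity — a rank-$k$ update
with $k$ = number of functionalized nodes — so a 400-step run costs one
factorization plus one triangular solve per step. The time step must resolve
the reaction scale ($dt \le 0.1/(k_{on}C_0 + k_{off})$, enforced with a
suggested value in the error); halving $dt$ moves $B(t_{end})$ by well under
1%. Concentrations can undershoot zero slightly near sharp depletion fronts
(SUPG is not monotone); runs abort if the undershoot exceeds 10% of $C_0$,
which in practice only triggers for drives $\ge 16$ V on coarse meshes.

# Verification strategy

Every stage has an independent reference:

* insulator/conductor limit solves bracket the RC electrostatics;
* the printed DC closed forms check zeta and slip at low frequency;
* exact quadratic drive scaling and odd symmetry of the slip;
* Poiseuille flow (centerline $1.5\times$ mean) and Stokes linearity /
  superposition;
* a 1D finite-volume diffusion–reaction oracle (independent code path)
  matches the quiescent 2D run on a near-1D configuration;
* the closed-form well-mixed Langmuir solution matches the coupled
  integrator when diffusivity is raised $10^4\times$ (with $R_T$ reduced so
  bulk depletion stays negligible — the constant-$C_0$ closed form is only
  the right reference without depletion);
* closed-chamber mass conservation, $0 \le B \le R_T$, $C \ge 0$.

The problem sizes used throughout are deliberate desk-scale choices:
`resolution = 1` ($\approx$ 8,700 nodes, $\approx$ 26,000 Stokes unknowns,
$dt = 0.25\,$s, 400 steps) for headline quantities, coarser meshes
(`resolution` 0.35–0.5) for trend checks, with `grid_independence()`
confirming the quantities of interest move by only a few percent between
levels.

# Findings the sweeps expose

* **Headline.** At 4 V, 10 Hz, $Da = 1000$ the chamber run gives
  $Be \approx 5.6$ (drive-off baseline $B_0 \approx 7.6\times10^{-12}$
  mol/m$^2$), i.e. the stirring multiplies 100-s binding about 5.5-fold.
* **Frequency response.** The surface-averaged slip is monotone in frequency
  and close to a single Lorentzian (fit RMS $\approx 4$%). The 50% crossing
  of the *numerical* sweep sits near 0.9 kHz — about 2.7$\times$ the
  half-width formula $f_{RC} = (1+\delta)\sigma_f\lambda_D/
  (2\pi\varepsilon_f R)$ at $R = 25\,\mu$m ($\approx 340\,$Hz). Charging of
  a strip electrode is edge-dominated, so the effective $R$ is smaller than
  the half-width; we report both numbers rather than tuning $R$. Binding
  declines far more slowly than slip: at the crossing the slip has halved
  while $Be$ drops by only $\sim30$%, because diffusion still feeds the
  reaction when convection fades.
* **Gate height.** Slip grows monotonically with gate height (corner field
  intensification plus slip-carrying sidewalls). $Be$ beats the flat gate at
  every raised height but peaks near $2\,\mu$m in this model: elevating the
  functionalized strip also exposes it to more purely *diffusive* baseline
  flux, so $B_0$ grows too and trims the ratio at $5\,\mu$m.
* **Through-flow.** At fixed $Da$, $Be$ falls with $Pe$: a faster base flow
  replenishes analyte on its own, shrinking the relative payoff of ICEO
  stirring.

# Known limitations

* 2D: the channel width and any spanwise structure of the vortices are
  outside the model (the geometry justifies this — width $\gg$ height).
* Linear double-layer model: no Poisson–Boltzmann correction, no surface
  conduction (Dukhin) or ion crowding at large induced zeta, no Faradaic
  reactions or bubble generation — all of which matter at the highest
  drives, which is one reason the large-voltage $Be$ values should be read
  as model statements, not device predictions.
* The slip model is invalid at geometric corners; raised-gate corner values
  are mesh-regularized.
* SUPG transport is not positivity-preserving; very strong drives on coarse
  meshes trip the undershoot guard and need finer meshes.
* The synthetic scenarios emulate the study geometry and parameters only;
  real devices add dielectric coatings, ion adsorption, and conductivity
  gradients that typically *reduce* ICEO below the standard-model value, so
  passing these tests demonstrates fidelity to the model, not to any
  laboratory measurement.
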