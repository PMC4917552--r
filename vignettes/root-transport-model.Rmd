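---
title: "A compartmental model of passive ion and water transport in a plant root"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compartmental model of passive ion and water transport in a plant root}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

rhizoflux simulates the strictly passive, coupled transport of water and
monovalent ions through a single plant root, and asks how the root's
developmental anatomy — the elongation zone (EZ), the maturation of the
xylem, the Casparian strip (CS), the suberin lamellae (SL) and their
passage cells — shapes where water and ions enter and how fast they reach
the shoot. This vignette is the package's account of the model: the
governing equations, the parameters and their defaults, the numerical
choices, and what the simulated conditions do and do not say about real
roots.

## The model root

The root is an axisymmetric right cylinder discretised radially into five
concentric tissue regions (outermost to innermost: epidermis 15 µm, cortex
20 µm, endodermis 10 µm, pericycle 5 µm, and a solid xylem core of radius
3 µm; outer radius 53 µm) and axially into compartments whose heights
follow individual cell lengths. Axial index $j$ counts upward from the root
tip. Cell heights ramp linearly from 20 µm at $j = 1$ to 150 µm at
$j = 11$ (the EZ) and stay at 150 µm thereafter; with the default 100 cells
the root is 14.3 mm long. Each compartment is rigid, water-filled and
well mixed: its state is one concentration per ion species. The default
soil solution is two monovalent cation–anion pairs, each species at
100 mol m⁻³ (mM), with identical transport properties — a charge-symmetric
roster under which the electric potential vanishes identically.

Development enters through three axial landmarks. The CS and functional
xylem begin at cell 12 and ramp to full strength over 4 further cells with
linear weight $w_j = \min(\max((j - \mathrm{start} + 1)/(\mathrm{ramp}+1),
0), 1)$. The SL may appear from cell 38 upward; each endodermal cell there
is independently a passage cell (SL absent, CS present) with probability
$e^{-j/30}$, so passage cells thin out with maturity. All of these
positions, ramps and probabilities are configuration parameters.

## Flux laws

**Water.** Membrane interfaces follow Kedem–Katchalsky non-equilibrium
thermodynamics with van't Hoff osmotic pressure $\pi = RT\sum_i c_i$:

$$J_v = L_p\!\left[(P_a - P_b - \rho g\,\Delta z) - RT\sum_i \sigma_i\,(c_{i,a} - c_{i,b})\right],$$

positive from side $a$ to $b$, with $\Delta z$ the elevation gain. The
mature xylem lumen has no axial membranes; its axial flow is Darcy flow
$J_v = (k^{ax}/\mu)\,(\Delta P/\Delta z - \rho g)$ with lumen permeability
$k^{ax} = 5\times10^{-13}$ m².

**Ions.** The extended Nernst–Planck flux per species combines diffusion,
electromigration and convection:

$$J_i = k_i\,(c_{i,a} - c_{i,b}) \;+\; k_i z_i \frac{F}{RT}\,\bar c_i\,(\psi_a - \psi_b) \;+\; (1 - \sigma_i)\,\tilde c_i\,J_v,$$

where $\bar c_i$ is the arithmetic interface mean and $\tilde c_i$ the
convective carrier concentration (upwind by default; see *Numerical
choices*). The decomposition into the three components is exact by
construction and is preserved in every flux snapshot.

**Quasi-static fields.** Pressure and electric potential are not part of
the ODE state. At every right-hand-side evaluation the hydraulic pressure
solves the linear incompressibility system (net volume flux into every
rigid compartment is zero; the system matrix is constant and factorised
once per model). The potential is obtained either by a finite-volume
Poisson solve on the compartment centres, grounded at the soil surface
(`potential_mode = "poisson"`), or by a zero-current constraint (net
charge flux into every compartment vanishes, `"electroneutral"`). For the
charge-symmetric rosters used in every bundled experiment both modes give
the identical answer $\psi \equiv 0$, which a test asserts.

**Boundary conditions.** The soil is an infinite reservoir with a
hydrostatic pressure profile (atmospheric at the top of the root,
$+\rho g z$ with depth) and fixed concentrations — hydroponics-like
conditions. The root bottom and the tops of the four outer tissues are
no-flux. The xylem top is held at constant pressure $P_b$ with no
concentration gradient, so its solute efflux is purely convective,
$J = c_{top} J_v$. $P_b \le 0$ stands in for transpiration pull; the
bundled experiments span 0 to −0.5 MPa.

## Parameters

| parameter | symbol | default | units |
|---|---|---|---|
| membrane water permeability | $L_p$ | 5.5×10⁻⁸ | m s⁻¹ MPa⁻¹ |
| membrane solute permeability | $k_m$ | 3×10⁻⁹ | m s⁻¹ |
| membrane reflection coefficient | $\sigma_m$ | 0.5 | – |
| xylem lumen permeability | $k^{ax}$ | 5×10⁻¹³ | m² |
| free-solution diffusivity (xylem axial) | $D$ | 1.5×10⁻⁹ | m² s⁻¹ |
| dynamic viscosity | $\mu$ | 1.002×10⁻³ | Pa s |
| water density | $\rho$ | 1000 | kg m⁻³ |
| relative permittivity | $\epsilon_r$ | 80 | – |
| temperature | $T$ | 298.15 | K |
| soil concentration (per species) | $c_0$ | 100 | mol m⁻³ |

Every membrane interface starts from the same composite baseline
($L_p$, $k_m$, $\sigma_m$); the tissue anatomy is expressed entirely as
interface rules:

* **CS and SL** act only on the endodermis–pericycle interface. Each
  barrier divides $k$ and $L_p$ by 10 and adds 0.2 to $\sigma$; across the
  CS ramp the permeabilities interpolate geometrically ($10^{-w}$) and
  $\sigma$ arithmetically ($+0.2\,w$), matching the order-of-magnitude
  character of the reductions. A full CS+SL interface therefore has
  $k = 3\times10^{-11}$ m s⁻¹, $L_p = 5.5\times10^{-10}$ m s⁻¹ MPa⁻¹ and
  $\sigma = 0.9$; a passage cell keeps the CS-only values.
* **Xylem maturation** turns the xylem's axial interfaces from membranes
  into open channels across the ramp: hydraulic and diffusive conductances
  interpolate geometrically between the membrane values and
  $k^{ax}/(\mu\,\Delta z)$ resp. $D/\Delta z$, and $\sigma^{ax}$ scales as
  $\sigma_m (1 - w)$.

Declared assumptions where the source anatomy leaves the value open, all
configurable: axial permeabilities of non-xylem tissues equal the radial
baselines; the immature xylem matches its surrounding tissue; the
soil–epidermis interface uses the baseline membrane (a composite
apoplast/symplast surface); the EZ cell-height profile is the 20→150 µm
linear ramp; development ramps span 4 cells ("several" cells of gradual
appearance); `n_axial = 100` so the mature-SL region is long enough to
average over.

## Simulation engine

The concentration ODE system (2000 states at the default size: 500
compartments × 4 species) is stiff and integrated with the sparse BDF
solver `deSolve::lsodes`, using the compartment-connectivity sparsity
pattern (all species in a compartment and in its interface neighbours).
Steady state is declared when the relative derivative norm

$$\max_{x,i}\; \frac{|\dot c_{i,x}|\,V_x}{k_m\,c_0\,A_x} \;\le\; 10^{-3}$$

holds at two consecutive checks (6-hourly by default), where $A_x$ is the
compartment's total interface area — i.e. no compartment's net mole rate
exceeds 0.1 % of its own membrane-exchange capacity. A single global
boundary-flux scale would make the criterion vacuous for the small inner
compartments, hence the per-compartment scale. The returned fields are
taken from the final integrated time (10 days by default), by which point
the norm is orders of magnitude below threshold; a dedicated test
confirms the steady state is independent of whether the root starts empty
or soil-equilibrated. The time-to-steady-state reported by the transient
protocol is the first check time at which the criterion holds for the
added species, with half-hourly checks.

## Numerical choices and why

* **Upwind convection (default).** With the arithmetic-mean carrier
  concentration the discrete convective flux becomes destabilising
  wherever the interface Péclet number $(1-\sigma)|J_v|/k$ exceeds ≈ 2 —
  which it does at the endodermal barriers under strong transpiration
  (≈ 3–10 there). In that regime the central scheme produced persistent
  negative concentrations whose osmotic feedback is explosive. The default
  carrier is therefore the upstream compartment (positivity-preserving,
  first order); `convection = "central"` keeps the second-order mean for
  low-Péclet work.
* **Zero-current potential for production runs.** With the physical
  permittivity the Poisson coupling relaxes any charge imbalance on a
  millisecond timescale — a stiffness ratio of ~10⁸ against the transport
  dynamics that the sparse Jacobian cannot represent (the Poisson response
  is global). The scenario runners therefore use the electroneutral mode,
  which is the singular-perturbation limit of the Poisson mode and
  identical to it for the charge-symmetric rosters of all bundled
  experiments (asserted by test). `root_model()` itself defaults to the
  Poisson mode, which remains fully functional for static solves and
  small grids.
* **Safeguards at unphysical states** (inactive at physical ones): the
  interface mean concentration is floored at 0 in carrier terms, and the
  zero-current conductance includes a background carrier level of 0.1 % of
  the soil concentration so the potential solve stays bounded while the
  root is still nearly ion-free.
* **Jacobian.** The default iteration matrix is the integrator's grouped
  finite-difference estimate on the connectivity pattern. An analytic
  alternative (`method = "lsodes_analytic"`) assembles the exact
  on-pattern Jacobian — including the quasi-static pressure and potential
  feedback, via multi-right-hand-side solves of the prefactorised elliptic
  systems — and doubles as a regression check on the flux derivatives
  (compared against dense finite differences in the tests).
* **Tolerances.** `rtol = atol = 10⁻⁶` on concentrations in mol m⁻³;
  negative excursions are controlled by the integrator's error test and
  the upwind scheme rather than by clipping the state.
* **Problem sizes.** The test suite runs its physics and property checks
  on small roots (6–38 axial cells, closed two-box systems, 3×3 potential
  grids) and the experiment reproductions on the full default root; a
  full steady state takes a few seconds, the complete experiment matrix
  (four barrier topologies × eleven transpiration levels, ten
  passage-cell seeds, five developmental offsets × three suctions, and the
  two-stage transient) runs in minutes.

## What the bundled conditions represent — and what they do not

The default configuration emulates a young Arabidopsis-like primary root
in hydroponic conditions: unlimited, well-mixed soil solution; a
symmetric salt mixture with identical ion mobilities; strictly passive
transport (no pumps, carriers or channels with selectivity); static
anatomy during a run; no lateral roots. Passing tests therefore
demonstrate the internal consistency of the passive composite-pathway
model under those idealisations, not fidelity to any particular
experimental root: real soils deplete and rewet, real ions differ in
mobility and valence, membrane transporters dominate several of the
fluxes modelled here as passive, and the apoplastic and symplastic routes
are lumped into single composite interfaces.

Two structural consequences of the boundary conditions are worth knowing
when comparing with measured roots. First, at $P_b = 0$ the uniform state
(every compartment at the soil concentration, hydrostatic pressure
everywhere) is an exact fixed point of the passive model: the soil water
potential is depth-independent and the xylem-top pressure matches the
hydrostatic column, so all fluxes vanish and the steady profiles are
flat. Any non-flat distribution observed in a real non-transpiring root
must come from drivers outside this model — active transport above all.
Second, under strong suction the mature-zone xylem profile reflects a
competition between dilution by freshly filtered water and axial/radial
diffusive re-equilibration; its slope is small and sensitive to the
axial discretisation and to the free-solution diffusivity assigned to the
open xylem.

## Known limitations

Axisymmetry makes every passage cell a full ring, so single-cell effects
are exaggerated relative to a three-dimensional root. The first-order
upwind carrier adds numerical diffusion at high-Péclet interfaces. The
composite apoplast/symplast representation cannot separate the CS's
apoplastic block from the SL's transmembrane block mechanistically — both
are permeability rules on one interface. Gravity is retained for fidelity
but contributes only ~140 Pa over the 14 mm root. The electroneutral mode
drops the ~millisecond charge-relaxation physics; for strongly asymmetric
electrolytes the Poisson mode on a reduced grid is the reference.
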