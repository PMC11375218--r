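---
title: "Effective charge of single-stranded nucleic acids: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective charge of single-stranded nucleic acids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement and the model

Escape-time electrometry measures the effective electrical charge of single
molecules in solution. A charged molecule diffusing in a nanoslit formed by
two like-charged plates (gap $2h \approx 70\text{--}75$ nm) is repelled by
both walls; where one wall is locally recessed by a pocket of depth $d$, the
repulsion is relieved and the molecule is trapped. The depth of that trap is

$$W = \Delta F_{el} + \Delta F_{trans}, \qquad
  \Delta F_{el} = q_{eff}\,\phi_m,$$

where $\phi_m \approx 2\phi_s e^{-\kappa h}$ is the midplane potential of
the slit relative to the (essentially field-free) pocket, $\phi_s$ the
effective wall surface potential, and $\kappa^{-1}$ the Debye length
($\approx 0.304/\sqrt{c_0}$ nm for a 1:1 salt). Mean residence times follow
Kramers' relation $t_{esc} = t_0 e^{W/k_BT}$ and the residence-time
distribution is exponential, so measuring $t_{esc}$ for $N$ events yields
$W$ (and hence $q_{eff}$) with relative precision $\approx 1/\sqrt N$.

The effective charge is smaller in magnitude than the structural charge
$q_{str}$ (the sum of ionized-group charges) because counterions accumulate
in the molecular ion atmosphere; the ratio $\eta = q_{eff}/q_{str}$ is the
charge renormalization factor. For a fully ionized acidic molecule $\eta$
depends only on the 3D geometry of the charge distribution, which is what
makes the measurement structurally informative: for an $n_b$-base strand the
core carries $-(n_b+1)e$, two fluorescent labels bring the total to
$-(n_b+3)e$, and the spacing of backbone charges controls how strongly the
molecule renormalizes.

This package implements both sides of that comparison:

* the *measurement chain*: residence-time tables → truncated-exponential
  maximum-likelihood fits → device calibration → inferred $q_{eff}$
  (`fit_escape_time()`, `calibrate_surface_potential()`, `infer_qeff()`,
  validated by `bd_escape_simulate()`);
* the *theory chain*: nonlinear Poisson–Boltzmann (PB) solvers for the
  device and for molecular models → effective charges $q_{calc}$
  (`solve_planar_slit()`, `solve_slit_pocket()`, `solve_rod()`,
  `solve_structure_grid()`, `qcalc_farfield()`, `qcalc_slit_pocket()`);
* the *rigid-rod inversion*: $|q_{calc}|$ versus axial charge spacing $b$
  relations whose inversion at a measured $|q_{eff}|$ estimates the axial
  charge spacing of the real chain (`compute_qcalc_vs_b()`,
  `invert_spacing()`, `spacing_report()`).

# Continuum electrostatics

In the electrolyte the nondimensional potential $\psi = e\phi/k_BT$ obeys
the nonlinear PB equation $\nabla^2\psi = \kappa^2\sinh\psi$; inside the
molecular volume there are no ions and a low dielectric constant
$\epsilon_{mol}$ applies, with continuity of potential and normal
displacement across the boundary. Charged surfaces carry constant-charge
(Neumann) conditions; the nominal silica wall charge can equivalently be
specified through the effective surface potential via the isolated-wall
Grahame relation (`sigma_from_phis()`).

The electrostatic free energy uses the solvent-region functional

$$F_{el}=\int_V\Big[\tfrac{\epsilon\epsilon_0}{2}|\nabla\phi|^2
 - 2c_0N_Ak_BT(\cosh\psi-\psi\sinh\psi-1)\Big]\,dV ,$$

evaluated with the same finite-volume discretization as the solve
(`free_energy()`). The molecular interior (including the self-energy of the
small charge seeds) is excluded; it cancels identically from the free-energy
*differences* that define effective charges.

Two equivalent definitions of the effective charge are implemented:

* **far-field matching** (`qcalc_farfield()`, the default): the nonlinear
  far field of the isolated molecule in bulk, sampled on a shell
  2–3 $\kappa^{-1}$ from the surface, is least-squares matched to the
  linearized (Debye–Hückel) field of the same charge geometry with an
  adjustable amplitude;
* **free-energy difference** (`qcalc_slit_pocket()`): the molecule is
  solved at the slit midplane and in the deep pocket, and
  $q_{calc} = (F_{slit}-F_{pocket})/\phi_m$ — the definition that mirrors
  the measurement. The two routes agree in the linear-response regime of
  the trap ($|\phi_m| \ll 1\,k_BT/e$, $\kappa h \gtrsim 5$); the far-field
  route costs a single solve and is used for production sweeps, the
  slit-pocket route for validation. Both states of the difference are
  solved on *identical grids* so that the molecular self-energy cancels at
  the discretization level, and the in-plane box must extend
  $\gtrsim 7\kappa^{-1}$ because the molecule–wall interaction energy
  density decays only like the molecular field itself.

## Numerical scheme

All solvers use graded tensor-product finite-volume grids: a uniform fine
band across the charged surfaces or the molecular region, and cells
stretched geometrically (ratio $\approx 1.2$, capped near
$0.3\kappa^{-1}$) towards the open boundary, where a radiation (Robin)
condition $\partial_n\psi = -(\kappa + 1/r)\psi$ represents outgoing
screened decay. This replaces nested focusing grids: a single grid spans the
0.02 nm charge-seed scale and the 10–30 nm screening scale. The nonlinear
system is solved by damped Newton iteration (inexact Newton with
Jacobi-preconditioned conjugate gradients for the 3D problems, sparse
direct factorization otherwise) to a relative residual of $10^{-8}$.
Step damping is applied only over electrolyte cells: the ion-free interior
is linear and legitimately reaches very large self-energy potentials under
a low dielectric constant.

Dielectric interfaces enter through harmonic-mean face permittivities, the
ion-accessible region through `ias_voxelize()`: a grid cell is
ion-inaccessible when it lies within $r_{vdW} + w$ of any atom, with
$w = 0.2$ nm the ion-exclusion width representing the finite size of a
hydrated cation, and crevices narrower than the 0.1 nm probe closed
morphologically. Partial charges are spread trilinearly onto the eight
neighbouring cell centres; the nominal 0.02 nm seed radius is recorded but
sub-grid — harmless, because only solvent-region energies and far fields are
reported.

Verification is by independent oracles rather than grid folklore: the
Grahame closed form and a shooting-method integration for the planar
problems; screened-Coulomb / line-superposition and Bessel-$K_0$ closed
forms in the linear limit for rods and 3D structures; electroneutrality of
the screening cloud (the ionic charge integral must return $-q_{str}$);
Richardson-style refinement for the charge-spacing curves. The nonlinear
saturation of strongly charged thin objects is physical: a *bare* unit
point charge already exceeds the saturation charge of a sub-0.1 nm sphere
and renormalizes visibly, so closed-form Debye–Hückel checks are asserted
in the weak-charge limit.

## Choices the continuum model leaves open

* Temperature 298.15 K, solvent permittivity 78.5, interior
  $\epsilon_{mol} = 2$: standard biomolecular-PB practice, all exposed in
  `electrolyte()` / `solver_options()`.
* Pocket gap convention: the pocket region has total gap $2h + d$ (the
  pocket is a recess in one wall). Two pocket depths circulate for the
  same devices (210 nm in the potential-map cross-section, 280 nm in the
  fabrication values); both are shipped as fixtures and the map geometry is
  used when reproducing the map.
* The half-helix model uses canonical B-form values (rise 0.338 nm, twist
  36°, phosphate radial distance 0.89 nm, bead radius 0.2 nm): a
  "half-helix" is one strand of the canonical duplex. These give a
  consecutive phosphate–phosphate chord of 0.646 nm.
* Dye contribution: the only quantified value for the renormalized charge
  of the ATTO labels is $-0.62\,e$ for the two-dye, 60-base configuration;
  it is applied as a constant total (halved for the singly labelled 5-base
  fragment) and exposed as a parameter. The value is known to depend on
  chain length; treating it as constant is the dominant model uncertainty
  in the short-fragment comparison, at the 0.1–0.3 e level.
* $\Delta F_{trans}$: modelled as the confinement-entropy difference of a
  sphere of the hydrodynamic radius,
  $\ln[(2h+d-2r_H)/(2h-2r_H)]$, positive (the roomier pocket deepens the
  well). It cancels between species of equal $r_H$ in one device and is
  config-overridable.
* The attempt-time prefactor $t_0$ defaults to the flat-trap mean
  first-passage time $a^2/4D$ of the pocket and is effectively fixed by
  the calibrator; only ratios of escape times matter for inferred charges.

# The charge-spacing inversion

`compute_qcalc_vs_b()` computes $|q_{calc}|$ for uniformly charged rods of
radius 0.05 nm (a line charge) and 0.4 nm (backbone plus hydrated-ion
excluded volume) over $b = 0.35$–$0.65$ nm at $n_b = 60$. The underlying
relation is mildly concave — it must saturate towards $|q_{str}|$ as the
charges spread out — so the linear fit is taken over the window in which
measured effective charges of the 60-base species actually fall
($b \in [0.45, 0.65]$ nm by default; inferred spacings span
0.48–0.71 nm). Points outside the window are computed, reported and
plotted, and `invert_spacing()` flags inversions that extrapolate beyond
the fitted window. The constant dye offset enters the intercept only, so
slope comparisons are dye-insensitive.

Because a rigid rectilinear rod replaces a curvilinear chain, the inverted
$b$ is a *projected* axial spacing and is expected to fall at or below the
contour length per base $b_c$; `spacing_report()` places inferred spacings
next to reference $b_c$ values from SAXS, X-ray diffraction, AFM, TEB and
FCS and flags violations of that expectation.

# Synthetic data

The generators in this package stand in for the study's raw inputs so that
every pipeline stage is testable offline.

* `generate_escape_events()` draws exponential residence times — directly
  from a mean, or from a true $q_{eff}$ through the trap model — and
  discretizes them to the camera frame interval (5 ms exposure at
  10–20 Hz in the experiments). An optional short-lived contaminant
  component (default mean 2 ms) reproduces the reason the shortest one or
  two lag bins are excluded from fitting.
* `bd_escape_simulate()` runs overdamped Langevin dynamics of an effective
  sphere (Stokes–Einstein diffusivity from the hydrodynamic radius) in a
  radial well with a linear rim ramp and a field-free run-out before the
  absorbing boundary; the run-out makes the mean escape time scale as a
  clean $e^W$. The flat-trap limit has the exact 2D first-passage time
  $R^2/4D$ used as its oracle.
* `generate_chain_ensemble()` produces discrete worm-like chains (fixed
  bond length $b_c$, bond-angle distribution
  $\propto e^{(l_p/b_c)\cos\theta}$) with one $-1e$ site per bead, and
  `select_representatives()` applies the conformational-landscape protocol:
  kernel density over $(R_g, R)$, the mode conformer, and the extreme-$R$
  members of the highest-density region holding the stated percentile of
  structures (bandwidths by the normal reference rule; the percentile
  region is the top-density subset of members, which for the max/min-$R$
  readout is equivalent to reading the contour).
* `generate_device_fixture()` bundles the study conditions: the 0.6 mM,
  $2h = 70$ nm, $\phi_s = -1.91$ device of the short-fragment panel; the
  1.2 mM, $2h = 75$ nm, $\phi_s = -2.24$ device of the 30/60-base panel;
  and the potential-map cross-section. The printed slit-regime parameter
  "$\kappa h \approx 5.5$" for the first device is stored verbatim next to
  the geometric $h/\kappa^{-1} = 2.8$; the two disagree (the printed value
  matches $\kappa \cdot 2h$) and are deliberately not reconciled.

What the generators do *not* emulate: forcefield-specific conformational
biases (the differences between Amber, CHARMM, DES-Amber and oxDNA
ensembles that the study probes), base-stacking chemistry, photophysics or
tracking noise. Passing tests therefore demonstrate that the analysis
chain is correct and self-consistent under its stated statistical model —
not that any particular forcefield reproduces nature.

# Problem sizes and known limitations

The shipped defaults solve the rod curves on ~20k-cell axisymmetric grids
(grid-refinement changes $q_{calc}$ by well under 1%), the device
cross-section on ~11k cells, and the 3D half-helix panel on 0.3–0.6M-cell
grids at 0.15 nm fine spacing — each molecule in a couple of minutes on one
core. The Brownian-dynamics checks use a 100 nm pocket and a few hundred
to a few thousand events, which resolves Kramers scaling to better than
10%.

Limitations worth keeping in mind:

* Point-ion PB with a sharp ion-accessible surface: no ion–ion
  correlations, no dielectric saturation, no specific binding. Finite ion
  size enters only through $w$; $|q_{calc}|$ rises monotonically with
  $w$ over 0.1–0.4 nm, and this sensitivity is part of the model's error
  budget.
* The analytic cylinder formula (`analytic_cylinder_qeff()`) is an
  asymptotic, logarithmic-accuracy estimate: against the nonlinear
  infinite-rod solve it holds to ~10% for $\kappa R \approx 0.2$–0.3 and
  degrades as $\kappa R$ shrinks (its correction term is a ratio of
  logarithms). The Manning limit $1/l_B$ is approached only
  logarithmically in $\kappa R$: at practical radii the saturated
  effective line density sits tens of percent below it (within 30% in the
  checked conditions) while the bare density is several times larger.
* The slit-pocket and far-field charge definitions differ at the percent
  level once the molecular bound layer samples the curvature of the wall
  background ($(\kappa\delta)^2$ effects); at the experimental salt
  concentrations this is within 2%.
* The trap model treats the molecule as a point (sphere) in the gap
  direction; the Kramers mapping is validated against internal
  Brownian-dynamics round trips and the device/calibrator fixtures, not
  against an external trajectory dataset.
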