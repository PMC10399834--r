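---
title: "Methods: from collagen fibrils to the critical landing height"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from collagen fibrils to the critical landing height}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landingmech)
```

This vignette is the package's own account of its science: the models, the
parameters and their defaults, the numerical choices, what the synthetic
data emulate, and what passing tests do and do not demonstrate about real
knees. The package implements a desk-scale multiscale chain: a
coarse-grained molecular-dynamics (MD) model of the collagen fibril; tissue
constitutive laws for cartilage, ligament/tendon and meniscus informed by
the fibril response; nonlinear height-regression models of landing
kinematics, kinetics and ground reaction; static optimisation of muscle
forces; and an elastic-foundation knee surrogate searched for the critical
landing height at which a cartilage damage indicator first activates.

## Coarse-grained collagen fibril

### Geometry and packing

A tropocollagen molecule (about 300 nm long and 1.6 nm thick) is idealised
as a straight chain of beads at 1.4 nm spacing; the mesoscale mechanics are
carried entirely by the force field, so atomistic coordinates are not
needed (an import hook for bead positions is easy to add but not
required). The fibril replicates the molecule on a quasi-hexagonal lattice
clipped to the circular cross-section, with a five-class axial stagger
(D-period-like, default 67 nm) and each group of five molecules recorded
as a microfibril.

One packing calibration matters: with molecule axes clipped to
`diameter/2 - 0.8 nm`, a plain hexagonal lattice at 1.6 nm pitch would put
139 molecules inside a 21.5 nm fibril, and clipping at the full radius
would put 163. The packing pitch defaults to 1.55 nm — a quasi-hexagonal
array slightly tighter than the nominal molecule diameter — which makes the
21.5 nm cross-section hold exactly 151 molecules. The count is insensitive
to small perturbations of this choice (any clip-radius/pitch ratio in
[6.26, 6.54] gives 151), so the calibration is not fragile.

Enzymatic crosslinks bond molecule ends (telopeptide beads) to the nearest
non-terminal bead of a different molecule. The density parameter β is the
fraction of molecule ends so connected: β = 1 connects every end, giving
exactly 2 connected ends per molecule; β = 0 gives none. Which ends are
connected at intermediate β is sampled under the build seed.

### Force field and units

Internal units are ångström, kcal/mol and amu; the derived time unit is
`sqrt(amu Å²/(kcal/mol))` ≈ 48.9 fs, and stresses convert to MPa with
1 kcal/mol/Å³ = 6947.7 MPa. Three terms act:

* a breakable piecewise-harmonic bond: harmonic about `r0` below `r1`, a
  stiffer branch centred on `r1_bar` between `r1` and `rb`, zero beyond
  `rb`, where the bond is flagged broken permanently;
* a harmonic bending energy `k_theta (theta - theta0)^2` for consecutive
  bead triples (straight equilibrium, `theta0 = pi`);
* truncated-and-shifted 12-6 Lennard-Jones interactions between all
  non-bonded bead pairs (chain neighbours at topological distance 1 and 2
  are excluded, as is conventional; the exclusion persists after a bond
  breaks).

The constants `C1` and `C2` are never free parameters: `C2` makes the
energy reach zero continuously at `rb`, and `C1` makes it continuous at
`r1`. By default `r1_bar` is placed so that the *force* is also continuous
at `r1` (`r1_bar = r1 - K_T0 (r1 - r0)/K_T1`), which is what a continuity
point of the force field means.

No universal values exist for the constants; the shipped defaults
(ε = 10.6 kcal/mol, σ = 14.72 Å, K_T0 = 15.41 and K_T1 = 47 kcal/mol/Å²,
r0 = 14 Å, r1 = 18.2 Å, rb = 21 Å, K_θ = 14.98 kcal/mol/rad², bead mass
1358 amu) follow the magnitudes of the mesoscopic bead-spring collagen
literature and are package defaults: every one can be overridden per call
or stored in a YAML parameter file. With these defaults the reduced fibril
shows a tensile modulus of a few GPa and fails at 8-10% strain — the right
order for collagen fibrils.

### Dynamics and the tensile protocol

Integration is velocity-Verlet with an optional Langevin thermostat
(friction and Gaussian noise applied as a force modification; the noise
draws from R's RNG, so trajectories are exact functions of `set.seed`).
The documented stability heuristic is `dt ≤ 0.05 sqrt(m/K_T0)` (≈ 0.47
time units at the defaults, >100 steps per bond period); at that `dt` an
NVE run of a perturbed 20-bead chain drifts less than 0.1% in total energy
over 1000 steps, and the test suite asserts it. A Verlet neighbour list
with a 0.3 σ skin is rebuilt every 10 steps.

The tensile test clamps beads within 5% of each axial end, equilibrates
briefly with both grips fixed, then displaces the top grip at a constant
engineering strain rate. Engineering stress is the axial reaction force on
the moving grip over the initial cross-section area π(d/2)²; the
configurational virial stress is reported as an alternative column. The
curve is sampled at uniform strain intervals with window-averaged forces.

Desk scale: the shipped analysis uses a 19-molecule fibril (8.7 nm
diameter) with molecules shortened to 28 nm and a 14 nm stagger — about
400 beads — for which a run to 20% strain takes a few seconds. The full
151-molecule, 300 nm construction is exercised as a topology/count check
and written out as a LAMMPS-style data file, not integrated.

## Articular cartilage

Cartilage is a fibril-reinforced, nearly incompressible hyperelastic
mixture evaluated at a normalised depth z (0 at the bone junction, 1 at
the articular surface):

* total collagen fraction `v_t(z) = 1.4 z² − 1.1 z + 0.59` (minimum at
  z ≈ 0.393) and elastic parameter `η₀s(z) = 0.1 z + 0.1`;
* nine fibril bundles per point: two primary bundles carrying `3/13 v_t`
  each and seven secondary bundles carrying `1/13 v_t` each (together
  exactly `v_t`). The primary orientation rotates linearly in z from
  perpendicular to the bone junction to parallel to the surface, splayed
  symmetrically; the secondaries are a fixed quasi-uniform set. The 2 + 7
  split is the smallest integer arrangement consistent with the 3:1
  primary:secondary weighting that sums to `v_t`.

The intact fibril stress is tension-only in the logarithmic fibril strain
ε_f = ln(fibre stretch): `σ_f = (η₀s/J)(E₀ ε_f + E_ε ε_f²) n⊗n`, zero for
ε_f ≤ 0. Its axial integral gives the intact energy
`W_fl = η₀s (E₀ ε_f²/2 + E_ε ε_f³/3)`. Failure is modelled by softening
hyperelasticity with an energy limiter Φ and sharpness m: the limited
energy is `ψ = (Φ/m)[Γ(1/m, 0) − Γ(1/m, (W_fl/Φ)^m)]` (upper incomplete
gamma, evaluated via `pracma::incgam`), whose derivative with respect to
`W_fl` is exactly the attenuation factor `exp(−(W_fl/Φ)^m)` multiplying
the softened stress. At `W_fl = Φ` the attenuation is e⁻¹; as Φ → ∞ the
intact law is recovered; the limited energy saturates at `(Φ/m) Γ(1/m)`.

The non-fibrillar part as printed in the source literature is
typographically corrupted, so the implementation declares a standard
compressible neo-Hookean energy scaled by the depth profile,
`W_nf = η₀s Gm/2 (Ī₁ − 3) + (1/D)(J − 1)²`, and derives the stress from
it; the binding contract — enforced by finite-difference tests at 100
random states to 1e-5 relative — is that stress equals the derivative of
the declared energy. Total stress mixes the parts as
`σ_c = Σ_bundles v_f σ_fl + (1 − v_t) σ_nf`.

Shipped parameter defaults: E₀ = 8.121 MPa, E_ε = 5326.32 MPa, Φ = 82.326
(treated as an energy density in MPa, the units of `W_fl`; the source does
not print units for it), m = 12, Gm = 0.723 MPa, D = 1e-4. Alternatively
`fit_fibril_params_to_md()` fits (E₀, E_ε) by linear least squares to the
pre-peak portion of a fibril MD curve scaled by 0.7 — the 30% stiffness
reduction of collagen II relative to the collagen I fibrils the MD
simulates. Because the law is linear in its coefficients, the scaling
multiplies the recovered coefficients exactly. Note that the shipped
desk-scale MD fibril is stiffer than the coefficients above imply (its
curve is nearly linear at a few GPa modulus); the analysis scripts report
both the MD-fitted and the shipped values, and the pipeline uses the
shipped ones.

**Damage indicator.** The downstream field maps "damage" where collagen
has yielded. In a softening-hyperelastic model there is no plastic strain
variable, so the faithful analogue is the energy-limiter attenuation at
the historical peak: `indicator = 1 − exp(−(max W_fl / Φ)^m)`, flagged
when it exceeds a configurable threshold (default 0.05). With m = 12 the
indicator switches sharply near `W_fl ≈ 0.78 Φ`, which makes the flagged
set robust to the exact threshold.

## Ligament and tendon

The hierarchical model reinforces the tissue with collagen fibres and the
fibres with fibrils. With the isochoric elastic Cauchy-Green tensor (total
deformation split as `F = Fe Fp`, `det Fp = 1`), the invariants are
`Ī₁e = tr(C̄e)`, `Ī₄e = n₀·C̄e n₀` and the fibre pseudo-invariant
`Ī₁ef = Ī₄ + 2 Ī₄^(−1/2)` (a function of the total fibre invariant). The
fibril energy is
`ψ_fb = ½ μ₀ tanh(a₁(Ī₄e − 1)) + a₂ exp(a₃(Ī₄e − I₀)) (Ī₁ef − 3)`.

Two printed-source ambiguities are resolved as follows and are selectable
or documented in code:

* The two-level shear-interaction coefficients are corrupted in the
  source; each mixing level carries a single effective shear coefficient:
  fibre level `κ_f μ_fm/2 (Ī₁e − Ī₁ef)` and tissue level
  `κ_t μ_m/2 (Ī₁ − Ī₁e)`, preserving the mixture structure with one
  documented knob per level.
* The printed pre-strain tensor `diag(α₀, α₀⁻¹, α₀⁻¹)` is not volume
  preserving; the default convention is the isochoric
  `diag(α₀, α₀^(−1/2), α₀^(−1/2))`, with the printed variant selectable.
  Pre-strain composes with the motion as `F·F₀`, and the response to F
  under pre-strain α₀ equals the response to `F·F₀` without pre-strain
  (asserted as a test).

Stresses are analytic push-forwards of the invariant derivatives
(deviatoric contributions from Ī₁, Ī₁e, Ī₄-through-Ī₁ef, Ī₄e, plus the
volumetric `Ek(J−1)I`), and the fibrillar terms vanish whenever Ī₄ ≤ 1
(tension switch). Finite-difference consistency at 100 random tensile
states is enforced at 1e-5 relative. With the default penalty Ek = 2000
MPa, uniaxial stretches to 10% keep J within [0.99, 1.01].

One consequence of the printed fibril energy deserves emphasis: the tanh
term has a nonzero derivative at the reference state, so the fibrillar
stress does not rise from zero at recruitment — it jumps to a finite
level (~10 MPa at the shipped fixture defaults) as Ī₄ crosses 1, like a
pre-tensioned cable engaging. The plastic return mapping therefore
requires yield curves that cross above that recruitment stress, and it
raises an informative error otherwise.

Plasticity is a single fibril-aligned mechanism: `Fp` is an isochoric
stretch along n₀. An elastic trial resolves the axial fibrillar stress; if
it exceeds the current yield stress — read from an MD-derived
stress-versus-slip curve by linear interpolation — the plastic stretch
grows (by 1-D root finding on the consistency condition) until
`|f| ≤ tol`, under the Karush-Kuhn-Tucker conditions: slip increments are
non-negative, `f ≤ tol` at return, and dissipation over closed cycles is
non-negative (all asserted as tests).

None of μ₀, I₀, a₁-a₃, the matrix moduli or per-ligament α₀ values are
printed in the source literature; the shipped defaults (μ₀ = 12 MPa,
I₀ = 1.10, a₁ = 1.5, a₂ = 1.2 MPa, a₃ = 20, μ_m = 0.4, μ_fm = 1.0 MPa,
v_f = 0.8, v_fb = 0.7, κ = 0.5, α₀ = 1 unless set) are package fixtures
producing a toe-then-linear tensile response, and
`calibrate_aggregate()` fits any chosen subset to a target curve.
Identifiability caveat: under uniaxial stretch along the fibre,
`Ī₁ − Ī₁ef` vanishes identically (both equal λ² + 2/λ), so the two matrix
moduli act through the single combination `v_m μ_m + v_f v_mb μ_fm`;
fitting both from a uniaxial target triggers the flat-ridge warning (the
Hessian's smallest eigenvalue at the optimum), and only the combination is
recovered. This is a property of the protocol, not a bug.

## Meniscus

Transversely isotropic linear elasticity in local axes with the
circumferential (fibre) direction stiff: Ec = 120 MPa, Et = Ea = 20 MPa,
ν_ct = ν_ca = 0.3, ν_ta = 0.2, G = 47 MPa, the single shear modulus
filling all three shear slots. The printed compliance is asymmetric as
typeset and swaps the two Poisson ratios relative to their verbal
definitions; the implementation follows the definitions — in-plane
coupling `−ν_ta/Et`, circumferential coupling `−ν_ct/Ec` (symmetric by
elastic reciprocity `ν_ct/Ec = ν_tc/Et`) — in Voigt order (11, 22, 33, 12,
13, 23) with engineering shear strains. Positive definiteness with the
shipped values is asserted, violations name the failing leading minor, and
frame objectivity (rotating axes and stress together) is tested.

## Landing-height regressions

Seven sagittal variables follow the shipped models of drop height x (power
`a x^b`, log `a ln x + b`, exponential `a e^{bx}`): hip/knee flexion and
ankle dorsiflexion angles and moments, and vertical ground reaction force
(vGRF = 0.4468 x^0.542). Three unit conventions are not stated where these
coefficients originate and are adopted here as documented assumptions:
x in cm (consistent with the 20/40/60 cm analysis heights), moments in
N·m/kg (the coefficient magnitudes imply body-mass normalisation), and
vGRF in body weights. All seven models are increasing on [10, 150] cm.

Fitting uses a log-transform linearisation as the initialiser and full
nonlinear least squares (`minpack.lm::nlsLM`) for the power and
exponential forms; the log form is linear and solved exactly. R² is
1 − SS_res/SS_tot (defined as 1 for constant data, which every form fits
exactly with a flat exponent). `select_best_form()` fits all three and
keeps the highest R², breaking ties within 1e-12 in the fixed order
power > log > exp. Extrapolation beyond 60 cm — the range of the
underlying drop tests — is allowed with a logged warning, since the
headline use of the chain is precisely supra-physiological extrapolation;
the default hard validity range is [10, 150] cm and the pipeline widens it
explicitly.

The synthetic dataset generator draws sagittal values as the regression
mean times multiplicative Gaussian noise (pooled literature spreads are
roughly symmetric about the mean), and frontal/transversal (coupled-plane)
variables as height-independent means plus additive noise — emulating a
pooled literature table in which coupled-plane quantities depend only
weakly on height. No tabulated coupled-plane means exist in the source;
the shipped means are explicit placeholders. Zero-noise datasets reproduce
the regression curves to machine precision, and refitting them recovers
every coefficient pair to 1e-6 with R² = 1 (tested).

## Muscle-force optimisation

The static problem minimises the sum of cubed muscle stresses
Σ(xᵢ/PCSAᵢ)³ under moment equilibrium [R]{x} = {M} and bounds
x_p ≤ x ≤ x_max. The equality is relaxed to a tolerance band
`|Rx − M|∞ ≤ tol_moment` (default 1 N·m), mirroring the coupling loop's
convergence criterion. After a linear-programming-style feasibility
pre-pass (minimum achievable residual under the bounds; infeasibility is
reported with the violating moment component), the primary solver ramps a
quadratic penalty under L-BFGS-B and then polishes on the dual: the
strictly convex objective lets the stationarity condition
`3x²/PCSA³ = −Rᵀλ` be inverted per muscle in closed form, and a damped
Newton iteration on the multipliers drives the equality residual to
~1e-10, giving machine-precision KKT residuals. The cross-check solver is
a real-coded genetic algorithm (tournament selection, blend crossover,
Gaussian mutation, feasibility repair by projection onto the equality set)
whose elites undergo an active-set projected-gradient local search — a
memetic GA, as hybrid GA implementations commonly do. Its penalty targets
exact equality so both methods solve the same problem; they agree to
machine precision on the 34-muscle fixture (the test tolerance is 1%).

The coupling loop mirrors the kinematics-driven workflow: solve, apply the
muscle forces to the joint surrogate, recompute residual reaction moments
(and optionally lever arms) from the passive response, update the targets,
repeat until the residual moment falls below 1 N·m. The linear passive
surrogate `passive(x) = P x` makes the loop a contraction for small P; a
passive-free joint converges after one solve, and `tol = Inf` degenerates
to a single solve.

## Reduced knee pipeline and the critical height

The knee itself is a surrogate: two tibial compartments (medial, lateral),
each a grid of surface nodes under a spherical condyle with parabolic
initial gap, loaded through an elastic foundation — nodal pressure
`k · penetration / thickness` with the approach solved by 1-D root finding
so integrated pressure balances each compartment's share of the load
(force conservation to 0.1% is asserted; penetration saturates at 95% of
the thickness and overload raises a capacity error). The axial joint load
is the vertical GRF plus the axial components of all muscle forces from a
line-of-action table. A patellofemoral pair is driven by the summed
quadriceps force through a wrap ratio.

The foundation kinematics also provide the local deformation: compressive
through-thickness stretch `λ_z = 1 − p/k` with isochoric lateral expansion
`λ_z^(−1/2)`, evaluated at depths z ∈ {0, 0.25, 0.5, 0.75, 1}. Lateral
expansion stretches the surface-parallel fibrils, so damage initiates in
the superficial layer — the depth pattern the chain is meant to probe —
while the deep perpendicular fibrils stay in compression.

All pipeline knobs are declared qualitative surrogates, set once and
documented: body mass 66.2 kg (the pooled-literature subject mean, which
defines the body-weight unit as 649 N), foundation modulus 40 MPa,
cartilage thickness 2 mm, condyle radius 30 mm, 20 × 20 mm patches,
uncovered (meniscus-covered) area fraction 0.39, a medial share that rises
with height and crosses 50% above 40 cm, line-of-action fractions 0.85,
wrap ratio 0.7, and a deterministic 34-muscle fixture with three sagittal
degrees of freedom. With these defaults the default-configuration critical
height lands at 116 cm with peak contact pressures in the tens of MPa —
physiologically plausible magnitudes, but not calibrated claims: the
absolute critical height of a real knee depends on anatomy and material
detail far beyond this surrogate.

The search itself starts at 1 m and steps upward with shrinking increments
(20, 10, 5, 1 cm): climb until damage flips on, restart from the last
undamaged height with the next increment, and return the first damaged
integer height. Evaluations are memoised; on monotone damage functions the
schedule provably returns the same answer as an exhaustive 1 cm scan, and
the tests assert that equivalence on 20 randomised synthetic thresholds as
well as the boundary case where damage is already present at the start.

## Numerical choices and test scale

* Finite-difference stress-energy oracles use central differences with
  step 1e-6 and a 1e-5 relative tolerance; random states are resampled
  away from the tension-switch kinks (within 2e-3 strain), where the
  derivative is genuinely one-sided.
* Root finding (contact equilibrium, lateral-stretch solves, plastic
  consistency) uses `stats::uniroot` with tolerances far below the
  physical scales; the optimiser's dual Newton stops at 1e-10 times the
  moment scale.
* The damage indicator underflows to exactly zero for tiny strains at
  m = 12 (double precision); the degenerate-threshold behaviour is
  exercised at gentler sharpness.
* Problem sizes used by the shipped tests and analyses: 19-molecule,
  28 nm fibrils (~400 beads) pulled to 20% strain; 1000-step NVE checks on
  20-bead chains; 9-25 node-per-side contact grids; 11-point height grids
  for monotonicity; the full 151-molecule fibril is built and counted but
  not integrated.

## What the synthetic data do and do not show

The generators emulate the *structure* of the real inputs — regression
means with literature-like spread, feasible musculoskeletal geometry,
convex-on-flat articular contact, fibril curves from the constitutive law
itself — so green tests demonstrate that every algorithm is implemented
faithfully: force fields conserve energy and break bonds irreversibly,
stresses derive from energies, fits recover generators, the optimiser is
KKT-exact, the search equals exhaustive scanning. They do not demonstrate
subject-level validity: no MRI geometry, no validated lever arms or
line-of-action table, no real kinematics. Known limitations shared with
the modelling tradition this follows: no poroelastic/biphasic transients
or osmotic swelling in cartilage, no matrix (proteoglycan) damage, no
viscoelasticity or 3-D insertion geometry in ligaments, no meniscal hoop
geometry, a single representative subject, and coupled-plane means as
placeholders. The absolute outputs of the surrogate pipeline (critical
height, peak pressures) are therefore qualitative; the quantities the
package stands behind are the construction counts, the constitutive and
optimisation mathematics, and the behaviour of the search.
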