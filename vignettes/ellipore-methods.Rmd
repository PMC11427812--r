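---
title: "Ellipsoidal pore profiling and the conductance heuristic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ellipsoidal pore profiling and the conductance heuristic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ellipore)
```

## The problem

Ion-channel structures are routinely annotated by pushing a spherical probe
through the permeation pathway: in each plane perpendicular to the channel
axis, the probe centre is adjusted to maximise its radius without
overlapping any atom's van der Waals sphere. The resulting radius profile
r(z) identifies constrictions and gates. A single radius per slice,
however, cannot represent an asymmetric cross-section — and asymmetry is
the norm for heteromeric assemblies and for thermally distorted
conformations from molecular dynamics. `ellipore` therefore inflates each
spherical probe into an in-plane ellipse with semi-axes a ≥ b and
orientation θ, reporting two radii per slice, and uses the two-radius
profile to refine a physical estimate of single-channel conductance.

## Pore geometry

**Spherical baseline.** After aligning the structure's principal axis
(largest eigenvalue of the mass-weighted gyration tensor) to z, the probe
walks parallel xy planes outward from the centre of mass. Per slice, the
clearance function

&nbsp;&nbsp;&nbsp;&nbsp;c(p) = min_i ( ‖p − x_i‖ − r_i )

is maximised by Monte Carlo simulated annealing (500 proposals, Gaussian
step starting at 0.5 Å decaying by 0.99 per proposal, Metropolis
temperature decaying geometrically from 0.5 to 0.005 Å) followed by a
Nelder-Mead polish. Each slice is seeded with the previous slice's
optimum, which keeps the search local; an explicit search box (default
±3 Å around the seed) prevents the probe from escaping through gaps in
sparse walls, and optima pinned to the box edge are flagged. A direction
of the walk terminates once the slice radius exceeds the termination
radius (default 15 Å, larger than any pore of interest here).

**Ellipsoidal expansion.** Each sphere is transformed into an ellipse
with the minor semi-axis b *fixed at the spherical radius* — the sphere
already measures the narrowest direction, and holding b fixed keeps the
two profiles directly comparable (the alternative reading, one global b
for the whole pathway, would contradict the fact that the spherical
radius varies along z). Atoms intersecting the slice plane are reduced
to discs of radius ρ = sqrt(r² − dz²), and the clearance of an ellipse is
the minimum over discs of the signed point-to-ellipse distance minus ρ.
The point-to-ellipse distance is computed by safeguarded bisection on the
closest-point parameterisation, which is branch-free, robust at high
aspect ratios, and accurate well below the 1e-6 Å tolerance used by the
tests.

The optimisation proceeds in stages, all derivative-free. Because the
sphere is optimal against three-dimensional atom spheres while the
ellipse is constrained by the strictly stronger in-plane disc
condition, the starting circle can itself violate the disc constraints
(its binding atoms sit out of the plane); in that case the centre is
first relocated to the best disc-feasible point nearby. Then:

1. Nelder-Mead over (x, y, a, θ) with tight bounds (centre shifts ≤ b/2,
   a ≤ 2b), maximising a with a quadratic overlap penalty (10⁴ Å⁻¹);
2. the same with wider bounds (centre shifts ≤ 2b, a ≤ min(8b,
   termination radius));
3. a feasible-direction polish: Nelder-Mead over (x, y, θ) only, whose
   objective is the *maximal feasible a* at that centre and orientation,
   found by bisection (feasibility is monotone in a). The polish is
   started from the stage-2 result and from each feasibility island of
   the circle centre: with discrete walls the set of centres where the
   b-circle fits can split into small disconnected islands (widths well
   below 0.1 Å) that no local search crosses, so they are enumerated by
   a vectorised 0.05 Å scan of the closed-form circle clearance and the
   orientation at each island is seeded by a coarse θ scan (θ = 0 is a
   saddle at which the objective is locally flat).

Stage 3 exists because the penalised 4-D search reliably stalls whenever
the starting circle is already in tangent contact with the wall at a
point off the future major axis — the commonest situation with discrete
walls — so growing a requires a coordinated centre shift along the
active-constraint ridge. Each stage's result is restored to feasibility
by shrinking a until the residual overlap is within 1e-3 Å, and the
stagewise maximal feasible a is returned, so stage 2 never regresses
below stage 1. If no growth is possible the circle is returned
unchanged. θ is reported modulo π. On every fixture tested, this scheme
matches or slightly exceeds an exhaustive grid search over centre,
orientation and major axis.

**Summaries.** Pore volume is the stacked-slab quadrature
V = Σ π a_i b_i dz over usable slices; the default integration range is
the maximal contiguous run of unflagged slices containing the global
minimum of b (the "pore proper"), a deterministic rule that is echoed in
all output metadata. The legacy spherocylinder (capsule) anisotropy
measure is supported through its area-equivalent effective radius
r_eff = sqrt(r² + 2 L r / π) for comparisons.

## Conductance heuristic

Treating the channel as a series of elliptical slabs, the resistance is

&nbsp;&nbsp;&nbsp;&nbsp;R = Σ_i dz / ( κ(a_i, b_i) · π a_i b_i ),

with all lengths converted from Å to m and conductance reported in pS.
With κ set to the bulk conductivity this recovers the classic
stacked-cylinder estimate (and exactly Hille's single-cylinder formula
R = ρL/A for a uniform pore). The bulk conductivity of KCl follows the
Nernst-Einstein form κ_bulk = q_e² n (D_K + D_Cl) / (k_B T) with n the
ion-pair number density. Defaults are the simulation condition the
training systems assume: 0.15 mol/L, 300 K, D_K = 1.96e-9 and
D_Cl = 2.03e-9 m²/s (the diffusivities are config-overridable and echoed
in output metadata). Access resistance at the pore mouths is deliberately
not modelled: the refined stacked-slab model absorbs the wide vestibule
slices directly, and the heuristic is meant for relative annotation, not
absolute electrode-geometry corrections.

Ions confined by narrow walls are less mobile than in bulk, so a
radius-dependent conductivity

&nbsp;&nbsp;&nbsp;&nbsp;κ(a, b) = σ(a c1 − c2) · σ(b c1 − c2) · κ_bulk

(σ the logistic function) interpolates between strongly reduced
conductivity at narrow radii and κ_bulk for wide pores; c1 > 0 (units
1/Å) sets the steepness and c2 the radius scale (midpoint at c2/c1 Å,
where κ = κ_bulk/4). The parameters are *fitted*, not shipped: each
training record (mean radii a, b, length L, reference conductance g)
yields an observed conductivity κ_obs = g L / (π a b), and (c1, c2)
minimise the squared κ residuals by Nelder-Mead from a 3×3 grid of
starting values (the surface is nearly flat when all pores are wide).
Fitting on κ rather than on g keeps wide, high-conductance records from
dominating the objective. The packaged 18-system training design — six
circular radii {3.4, 4.7, 5.9, 7.0, 8.3, 9.8} Å crossed with axis ratios
{1, ¾, ½} at L = 50 Å, deformations preserving the cross-sectional
area — reflects the nanotube systems conventionally used to calibrate
such models; `simulate_conductance_records()` generates conductances on
that design from known parameters for recovery studies. Uncertainty on a
heuristic estimate is obtained by analysing an ensemble of frames
(`ensemble_conductance()`) and reporting the standard deviation.

## The synthetic generators

`build_cnt()` places carbons on the rolled-graphene lattice of an (n, n)
armchair nanotube (C–C bond 1.421 Å, translational period √3·cc with 4n
carbons, ideal radius 3 n cc / 2π), caps the rims with axial hydrogens at
1.09 Å, and imposes ellipticity through the exact area-preserving map
x → x/√s, y → y√s. The deformation is an exact coordinate map rather
than the harmonic-restraint equilibration a simulation would use,
precisely so the ground truth is analytic. `build_bead_pore()` builds
cylinder, elliptical-channel and hourglass walls from rings of beads.

What these fixtures do *not* emulate: thermal disorder, wall relaxation,
solvent, and partial charges. Two consequences matter when reading test
results. First, a rigid ideal lattice produces slice geometries whose
maximal inscribed ellipse oscillates with the slice's phase relative to
the lattice rows — behaviour that thermal averaging smears out in real
ensembles. Second, with discrete walls the spherical probe settles
slightly into inter-atom gaps; because b is then fixed at that inflated
radius, the ellipse's room to elongate shrinks. On the exactly-deformed
(8,8) tube at axis ratio ½ the median probe axis ratio is therefore
~1.6 rather than the wall's 2 — a property of the exact geometry plus the
b-fixed convention, confirmed independently by exhaustive grid search,
not an optimiser failure. Passing pipeline tests on these fixtures
demonstrates geometric correctness against analytic walls; they are not
evidence about MD-relaxed or experimental structures.

Bead-wall ground truths hold up to the discretisation of the wall: tests
that assert analytic values use ≥360 beads per ring, where the residual
gap allowance is below the assertion tolerances.

## Numerical choices

- Slice spacing dz defaults to 0.25 Å; the nanotube validation runs in
  this package use dz = 0.5 Å and ~160 slices per tube, ample to resolve
  constrictions several Å wide.
- Termination radius 15 Å; sentinel (open/empty) slices carry a = b =
  termination radius, are flagged, and are excluded from volume
  quadrature and resistance sums.
- Volume comparisons on generated tubes integrate over the tube interior
  (|z| ≤ 20 Å for a 50 Å tube) using the generator's ground-truth length:
  beyond the rims the profile legitimately flares toward the termination
  radius and would swamp the quadrature.
- Overlap tolerance 1e-3 Å throughout; point-to-ellipse distance
  resolved to < 1e-9 Å; clearance self-consistency of returned probes is
  asserted to 1e-6 Å in the tests.
- Annealing and Nelder-Mead seeds are explicit everywhere; identical
  seeds give byte-identical profiles, and translation equivariance of
  the optimiser is exact by construction (the polish optimises the
  displacement, not the absolute position).
- Degenerate inputs: an all-collinear structure aligns with a
  deterministic tie-break (axis sign follows increasing residue index,
  then the +z hemisphere); a buried start point aborts with a clear
  message; empty disc lists yield +∞ clearance (no constraint).

## Known limitations

- Planes are always normal to z after alignment: strongly curved or
  tilted channels need a curved-axis method.
- One ellipse per slice cannot represent multi-lobed cross-sections or
  side tunnels; the ellipse is still more symmetric than a real wall.
- The conductivity model is a two-parameter heuristic calibrated on
  nanotube-like training data; it ignores ion-specific chemistry,
  surface charge, and hydration-shell effects, and its estimates are
  relative annotations rather than substitutes for measurement or
  simulation.
- Profiles are single-frame; ensemble statistics require explicit frame
  lists.
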