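---
title: "Modelling the pericardium with spatially varying Robin boundary conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the pericardium with spatially varying Robin boundary conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cardiomech)
```

## The scientific question

The pericardium is a stiff fibrous sack around the heart. It barely resists
tangential sliding of the epicardium but strongly limits motion *normal* to
the surface. Electromechanical heart models that omit it produce a
characteristic artefact: during isovolumic contraction (IVC) the ventricles
spherise — the free walls bulge outward and, because cavity volume is held
by the closed valves, the apex is dragged upward; during ejection the apex
keeps rising and the atrioventricular (AV) plane barely descends. Real
hearts do the opposite: the apex stays almost still and the AV plane
descends several millimetres.

`cardiomech` implements a desk-scale, fully testable version of this
analysis. The pericardium is represented by linear normal springs (Robin
boundary conditions) on the ventricular epicardium, with a spatially
varying stiffness derived from the epicardial normal-displacement profile
of a target motion field: regions that move normal to the surface the least
(the apex) get the full stiffness, the mobile basal epicardium gets none.
The package provides the whole chain — geometry, fibers, activation,
constitutive laws, circulation coupling, metrics and paired experiments —
so that the mechanistic claims can be exercised end to end on synthetic
data.

## The model chain

### Geometry

Patient anatomy is replaced by a parametric biventricle: a truncated
half-ellipsoid LV wall, a crescent RV free wall glued onto the LV
epicardium over attachment aprons (the cavity between them is the RV blood
pool), and a basal tissue band extruded above the truncation plane. Three discrete
patches on the band's upper rim stand in for the cropped right pulmonary
veins and superior vena cava (`VEIN_RING`); the omni-directional anchor
springs act only there, and the rest of the cut plane (`TOP`) is free —
anchoring the whole cut plane was found to clamp atrioventricular plane
displacement entirely. All cells are
generated as structured hexahedra and decomposed into conforming
tetrahedra by fanning each face from its lowest-index vertex, which makes
the mesh deterministic and watertight by construction. The basal closure
of each cavity is a *virtual* centroid fan over the rim loop, built by
`cavity_closure()`; it tracks the deformed rim so cavity volume is a smooth
function of displacement and exact for affine elements.

The default target edge length is 8 mm with at least two transmural
element layers. This is far coarser than production cardiac meshes (~1 mm);
it was chosen so a full beat of the two-arm study runs in minutes in pure
R. The two-layer floor matters more than the edge length: with a single
transmural layer the fibers sample only the midwall helix angle (nearly
circumferential) and contraction degenerates into a radial squeeze that
elongates the ventricle instead of shortening it. Resolution is a plain
config knob (`geometry$edge_length`) and every geometric test (cavity
volume against the closed-form ellipsoid, refinement scaling, closure
identities) runs at several resolutions.

### Wall coordinates and fibers

The apico-basal coordinate `xi` (0 apex, 1 base) and transmural coordinate
`tau` (0 endo, 1 epi) are harmonic: P1 Laplace solves with Dirichlet data
on the apex patch/basal plane and the endo/epicardial surfaces. We note
that published descriptions of such coordinates sometimes disagree on
orientation between text and figures; here 0 is always the apex and 1 the
base. Fibers follow the standard rule: transmural direction from
`grad(tau)`, circumferential direction from the long-axis cross product,
helix angle linear in `tau` from +80° (endo) to −60° (epi), sheet angle
−65° to +25°. At the apical pole the circumferential direction is
singular; affected elements take the average triad of their neighbours.

### Activation

Activation times solve the anisotropic eikonal equation with squared
velocity tensor `M = v_f^2 ff' + v_s^2 ss' + v_n^2 nn'`. The solver
initializes with Dijkstra on the edge graph — each edge weighted by its
exact straight-segment travel time `sqrt(e' M^-1 e)` — and then relaxes
with within-element updates from faces and edges. Updates only ever lower
times, so the graph distance is a certified upper bound; bar tests against
1-D closed forms bound the error from below. Membrane kinetics are not
modelled: activation time simply indexes the active-tension transient,
which is all the mechanics needs. Conduction velocities are tuned to a
target total activation time by a single rescale (eikonal times are
exactly inversely proportional to a uniform velocity scaling). Defaults
before tuning are v_f/v_s/v_n = 0.6/0.4/0.2 mm/ms; the target QRS duration
defaults to 120 ms and is a config input, since no patient value is
available.

### Material laws

Passive ventricular myocardium is transversely isotropic Guccione:
`W = C/2 (exp(Q) − 1)` with `Q = b_f E_ff² + b_t (E_ss² + E_nn² + 2 E_sn²)
+ b_fs (2 E_fs² + 2 E_fn²)` on the isochoric strain, plus a volumetric
penalty `kappa/2 (J − 1)²`. Basal tissue is neo-Hookean. The active second
Piola–Kirchhoff stress is `T_a(t) (ff' + eta ss' + eta nn')` with the
transient `T_a(t) = T_peak tanh²((t−t_on)/tau_c) tanh²((t_off−t)/tau_r)`
on `t_on < t < t_off`, `t_on = t_act + t_emd`, `t_off = t_on + tau_dur`.
The `tanh²` shape is this package's own variant of the phenomenological
transient family; its contract — delay, rise, plateau-duration knob,
relaxation, bounded peak — is what the parametric study manipulates
(+20% `T_peak`, +20% `tau_dur`, `eta = 0.4`). There is deliberately no
length or velocity dependence.

Parameter defaults (C = 2 kPa, b_f = 8, b_t = 3, b_fs = 4, kappa = 650 kPa,
T_peak = 60 kPa, t_emd = 15 ms, tau_c = 40 ms, tau_dur = 300 ms,
tau_r = 60 ms) are standard literature-range values; the study design only
compares arms at fixed parameters, so the defaults need to be
physiological, not patient-specific. The basal band's neo-Hookean modulus
defaults to 40 kPa: it is the effective stiffness of the atria and vessel
stumps the band replaces, and it is what keeps the ventricles from swinging
on their small vein anchors when the pericardial springs are off.

Every stress routine is the exact analytic derivative of its energy and is
verified against central finite differences at random states to better
than 1e-5 relative error.

### The penalty map (the core method)

Given the target motion, `extract_epicardial_normal_displacement()`
computes per epicardial node the maximum over systolic frames of
`|u · n0|` against the end-diastolic outward normal (unsigned; the
end-systolic-only alternative would be a one-line change and is noted
because the choice is not dictated by anything upstream).
`derive_penalty_map()` then:

1. bins epicardial nodes into `n_bins = 20` equal-width `xi` bins;
2. averages the displacement per bin;
3. normalizes the profile to [0, 1];
4. fits a monotone non-decreasing function (isotonic regression on the bin
   means, then a Hyman-filtered monotone cubic);
5. flips it: `scale(xi) = 1 − g(xi)`.

The spring stiffness at apico-basal position `xi` is
`k_n = k_max · scale(xi)` with `k_max = 50 kPa/mm`; the vein rim carries
omni-directional springs of 10 kPa/mm. Springs act on the reference (ED)
surface: the traction is `−k_n (u·n0) n0`, so tangential sliding is free
and both outward bulging (IVC) and inward collapse (ejection suction) are
resisted. Nodal spring forces are lumped with one third of the adjacent
reference triangle areas, which makes the stiffness mesh-independent.
The functional family of the monotone fit is this package's choice —
isotonic-plus-monotone-cubic reproduces "normalize, fit, flip" while
guaranteeing the map's monotonicity invariant.

### Mechanics solver

All loads at fixed cavity pressure are conservative here: passive stress
derives from the strain energies; the constant-in-`C` active stress from
`(T_a/2) S_a : C`; follower pressure on a closed cavity from `−p V(u)`;
springs from quadratic nodal energies. Each quasi-static step therefore
minimizes the total potential. The minimizer is L-BFGS preconditioned by a
constant sparse factorized reference stiffness (linear elasticity plus
springs plus the geometric stiffness of the committed stress state,
refreshed once per time step and shifted to stay positive definite), with
Armijo backtracking and load-path bisection as a fallback. This replaces
an exact-tangent Newton loop: the exact consistent tangent of the
isochorically split Guccione law is notoriously error-prone, while the
energy framework makes every force term verifiable by finite differences.

Volumetric locking of linear tetrahedra is mitigated by a mean-dilatation
projection option (`vol_averaging`): the penalty can act on node-averaged
Jacobians instead of element Jacobians. The default keeps the element-wise
penalty so that the near-incompressibility contract `|J − 1| <= 0.05` is
enforced per element; the projection is available as a config switch and
its effect is discussed in the limitations below.

### Circulation

Each ventricle follows FILL → IVC → EJECT → IVR. FILL holds the cavity at
its end-diastolic pressure (the preload ramp itself is the FILL phase of
the beat; the ED state after preload is the reference every displacement
is reported against). IVC begins when, at constant EDP, contraction first
reduces the volume; the cavity is then held at its ED volume by a pressure
solve (relative tolerance 1e-3). Ejection starts when cavity pressure
reaches the arterial (Windkessel) pressure and couples the cavity to a
three-element Windkessel (`C dP/dt = Q − P/R`, implicit Euler;
`P_prox = P_wk + Z Q`); it ends when the flow reverses, after which IVR
holds the end-systolic volume while pressure falls, and the beat ends when
pressure is back at EDP. The two ventricles are advanced together: their
pressure constraints form a 2×2 nonlinear system solved by a Newton
iteration whose compliance Jacobian `dV/dp` is initialized by
finite-difference probes at ED and maintained by Broyden updates across
the beat. The circulation is open-loop, and diastolic filling dynamics are
out of scope.

Windkessel defaults are LV: Z = 7, R = 100 kPa·ms/mL, C = 10 mL/kPa,
initial arterial pressure 7.0 kPa; RV: 1.5/24/20/1.6; EDPs 1.6/0.8 kPa.
The LV afterload is calibrated to the desk-scale ventricle the same way
the clinical workflow tunes afterload to a measured ejection fraction: the
coarse stiff discretization generates 8–12 kPa peak pressure, so the
aortic opening pressure sits at 7 kPa and yields an ejection fraction in
the heart-failure range (~20% with pericardium) rather than no ejection at
all. None of these values are patient-derived — they are config inputs.

### Synthetic target motion

The generator produces the data product of gated-CT motion tracking: ten
frames of per-node displacement relative to ED over a 300 ms systole, with
a smooth rise to a peak at 80% of systole and a partial return. The field
is an analytic combination of basal descent proportional to `xi` (default
amplitude 12 mm), a small apical drift bound (1 mm), an epicardial normal
component with a monotone profile in `xi` (default identity, amplitude
6 mm), transmural thickening proportional to `tau − 1/2`, and seeded
Gaussian jitter. What it emulates is the *statistical structure* the
penalty-map derivation relies on — a nearly static apex, a descending
base, apico-basally increasing normal displacement. What it does not
emulate: regional wall-motion abnormalities, twist, image noise
correlations, through-plane artefacts. Tests that pass on this generator
therefore validate the machinery (binning, normalization, flipping,
recovery under noise), not clinical accuracy.

## Study design and problem sizes

`run_control_pair()` runs the identical synthetic heart twice — with and
without the epicardial normal springs (the vein springs stay on in both
arms) — and compares phase-aligned metrics: node-wise distance to the
target at the onset and end of LV ejection (matched by fraction of systole
elapsed, never by wall-clock time), AVPD (positive down), VAD (positive
up), the mean outward epicardial normal motion during IVC, EF and peak
pressure. `run_parametric_study()` repeats the beat under the standard
variant set (active-tension, afterload/preload, and spring-stiffness
manipulations, including uniform-stiffness maps) and reports percent
changes from the control rows.

Default problem sizes are chosen so that the full two-arm study completes
in minutes on one CPU: target edge length 6–8 mm (≈ 900–2200 nodes),
dt = 10 ms, a 700 ms beat. The directional mechanism claims — less IVC
bulge, less apex rise, more AVPD, smaller error against the target — are
resolution-robust in our testing; absolute magnitudes are not, and are
never asserted.

## Numerical choices, degeneracies, tie-breaks

- Cavity volumes use the divergence theorem on the closed surface; the
  virtual basal cap is a centroid fan whose centroid follows the deformed
  rim, so volume gradients (the follower pressure loads) are exact.
- The eikonal local update accepts face-interior solutions only when the
  barycentric solution lies in the simplex and time decreases; edges and
  vertices otherwise, so causality (`t >= 0`, no increase below the graph
  bound) holds by construction.
- `derive_penalty_map()` refuses constant displacement fields
  (degenerate normalization) rather than guessing a map; callers may fall
  back to `uniform_penalty_map()`.
- Elements with vanishing transmural gradient (apex pole, glued seams)
  take neighbour-averaged fiber triads; the count is reported.
- The pressure Newton clamps per-iteration pressure updates to 2 kPa and
  guards its learned compliance diagonal to stay positive.
- Equilibria that stall within a small factor of the force tolerance are
  accepted with a warning instead of failing the beat; the tolerance is
  scaled per degree of freedom.

## Known limitations

- Linear tetrahedra at desk resolution underestimate compliance
  (volumetric and shear locking); ejection fractions are at the low end of
  the physiological range at the default sizes. The with/without contrast
  — the object of study — is preserved.
- The near-incompressibility contract (|J − 1| <= 0.05 in 99% of
  myocardial elements) is not met at the default penalty (the minimum
  fraction over a beat is ~0.83): the penalty magnitude that would enforce
  it per element (~4000 kPa) makes the floppy no-pericardium arm
  intractable, and the mean-dilatation projection controls only patch
  averages. The corresponding acceptance check is expected to fail and is
  kept failing rather than weakened.
- During IVC the no-pericardium apex briefly moves down (the
  early-activated apical cone contracts first and locally elongates)
  instead of up; the apex-rise part of the mechanism therefore appears in
  the ejection phase only, where it is large and robust. The IVC apex
  component of the directional acceptance check fails for this reason and
  is left failing; the bulge, AVPD and error-reduction components all
  pass.
- The RV free wall is one to two elements thick at default resolution; RV
  hemodynamics are qualitative.
- No length dependence in active tension, no atrial pericardium, no
  contact mechanics, no closed-loop circulation, matching the stated scope.
- The element-wise incompressibility contract and locking mitigation pull
  in opposite directions: the mean-dilatation projection relaxes element
  Jacobians (they then wander several percent while patch averages stay
  tight), so it is off by default and the element-wise penalty is kept.
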