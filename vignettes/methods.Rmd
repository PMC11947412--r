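---
title: "Methods: load-case transfer and the quasi-static simulator twin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: load-case transfer and the quasi-static simulator twin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneetwin)
```

## Scope

`kneetwin` models the workflow of testing a total knee replacement (TKR) on a
six degree-of-freedom joint simulator under physiological load cases and a
virtual soft-tissue envelope. It covers four stages:

1. **Load-case preparation** — body-weight scaling of telemetric load data,
   rigid re-registration of kinematics and load wrenches from the coordinate
   system of one implant design into another, conversion into the
   Grood–Suntay joint coordinate convention, and periodisation of the
   waveforms for cyclic control.
2. **Virtual ligaments** — a twelve-strand point-to-point apparatus with a
   nonlinear toe-region force law, referenced at a known joint pose.
3. **The quasi-static twin** — hybrid force/position control resolved by
   direct equilibrium between penalty contact, ligament tension and the
   target loads, plus contact footprints and flexion-binned comparison of
   soft-tissue variants (cruciate resection, collateral stiffening).
4. **Synthetic data** — deterministic generators for the five activities of
   daily living (ADLs) so the whole pipeline is testable at desk scale.

## Joint coordinate convention

Kinematics are described by the motion of the tibial frame relative to the
femoral frame. At the neutral pose both frames coincide, with x anterior,
y proximal (distal to proximal) and z lateral for a right knee. The three
joint axes are the femoral body-fixed medial–lateral axis `e1` (flexion),
the tibial body-fixed long axis `e3` (internal–external rotation) and the
floating axis `e2 = e3 × e1` (abduction–adduction). Translations are the
oblique components of the tibial origin along `(e1, e2, e3)`; because `e2`
is orthogonal to the other two axes, only the `e1`/`e3` pair needs a 2×2
solve, and the decomposition round-trips poses to machine precision. The
convention is singular when `e1` becomes parallel to `e3` (±90° adduction);
poses within 1e-6 degrees of the singularity are rejected with an explicit
error naming the offending angle rather than silently clamped.

Angles are degrees and translations millimetres at every user-facing
boundary; radians are used internally.

**Load components.** By default, joint loads are the *projections* of the
applied wrench (taken about the tibial origin) onto the three joint axes —
the quantity a simulator's display reports. The strict generalized-force
conjugate of the joint coordinates, which adds the translation-carrying
coupling terms `∂t/∂angle`, is available via `method = "conjugate"` in
`jcs_load_from_wrench()` and satisfies the virtual-work identity against
finite differences of `pose_from_jcs()` to better than 1e-6 relative. The
projection reading is the default because it is the conventional
interpretation of machine-reported loads; the conjugate variant exists so
the identity can be verified and used where exact duality matters.

**Signs.** Positive anterior–posterior force pushes the tibia anteriorly.
The long axis points proximally, so a compressive joint load appears as a
*negative* inferior–superior force — the convention used throughout the
package (e.g. a stairs-descent peak of −2943 N). One display convention in
the field flips this axis so that compression reads positive; we keep plain
axis projections so that forces and translations share their axes.

**Sides.** All internal mathematics is right-handed on a canonical right
knee; the `side` flag flips the reported signs of adduction, internal
rotation and medial–lateral translation for a left knee, and nothing else.

## Re-registration between implant frames

Standardized load cases are published in the coordinate system of the
instrumented implant they were recorded with. Testing a different design
requires re-expressing both the kinematics and the load wrenches in the new
implant's frame. A `frame_registration` carries the attitude of the target
frame expressed in the source frame plus an origin shift, defined as the
position of the source origin measured from the target origin (in source
axes). With that convention the moment transported to the new origin is
`M' = Qᵀ(M + r × F)`, so a pure 10 mm x-shift under a 100 N z-force adds
exactly (0, −1, 0) N·m — the sign convention every wrench operation in the
package is consistent with and that the adjoint-matrix oracle in the test
suite checks on a thousand random cases.

The default registration models the transfer from an ultra-congruent
instrumented design to a cruciate-retaining design implanted at an equal
posterior tibial slope with matched functional surfaces: a 6.5° tilt about
the medial–lateral axis and an origin shift below 1 mm. Both component
frames receive the same transform by default (the matched-surface reading);
per-component registrations are supported.

Body-weight scaling multiplies the four force/moment-controlled channels by
the ratio of target to reference body weight (75 kg target by default) and
leaves the kinematic channels and the cycle frequency untouched. Moments
scale by the same ratio as forces because lever arms are unchanged by load
normalisation.

## Periodisation

Cyclic (iteration-based) control needs waveforms whose first and last
samples agree. Raw standardized cycles do not close, so each channel is
extended by 15% of its length. The extension method is not dictated by the
underlying protocol, only the harmonised endpoints are; we chose a quintic
Hermite blend matching value, slope and (finite-difference estimated)
curvature at the old endpoint and at the cycle start. This makes the output
C1-periodic, keeps the appended segment free of ringing, and for an
already-periodic channel stays inside the channel's min/max envelope. All
original samples are preserved bitwise; the final sample is *assigned* equal
to the first so the periodicity is exact in floating point. The extension is
appended (not prepended or split) — an arbitrary choice exposed through the
`extension_fraction` argument and the stage's documentation.

## Virtual ligament apparatus

Each strand is a tension-only point-to-point element from a femoral origin
to a tibial insertion. Its input parameters are the attachment points, a
stiffness `k` (N per unit strain) and a reference strain `εr`, the
pre-tension at a known reference pose (typically full extension), where the
reference length `lr` is recorded.

**Strain.** Two definitions are implemented. The default measures strain
relative to the zero-load length `lr / (1 + εr)`:

\[ \varepsilon = \frac{l\,(1+\varepsilon_r) - l_r}{l_r}, \]

which equals `εr` at the reference pose and crosses zero (slack) when the
strand shortens below its zero-load length — the behaviour a tension-only
element must have. A second variant, `as_printed`, rescales the reference
strain by the length ratio (`ε = εr·l/lr`); it also equals `εr` at the
reference pose but never reaches zero for a positive pre-tension, so it
cannot go slack. Because a slack regime is required for the force law below,
the zero-load-length form is the default and the rescaling variant is
retained only for fidelity experiments.

**Force law.** With toe strain `ε₁` (default 0.03, the value used on the
commercial simulator this emulates):

\[ f(\varepsilon) = \begin{cases} 0 & \varepsilon < 0 \\
\tfrac14\, k\,\varepsilon^2/\varepsilon_1 & 0 \le \varepsilon \le 2\varepsilon_1 \\
k\,(\varepsilon - \varepsilon_1) & \varepsilon > 2\varepsilon_1 \end{cases} \]

Both branches meet at `2ε₁` with value `k·ε₁` and slope `k`, so the law is
C1 and non-decreasing. Stiffness is interpreted as N per unit strain; file
inputs quoted in N per percent are converted (×100) on reading.

Strand tension acts at the tibial insertion toward the femoral origin;
forces and insertion-point moments are summed into one wrench about the
tibial origin. The reaction on the femur is not tracked, mirroring how a
simulator folds ligament loads into the tibial load channel. Strands cannot
wrap around bone — a stated limitation of point-to-point elements.

**Variations.** `resect_group()` removes a group (e.g. the PCL);
`scale_group_stiffness()` multiplies a group's stiffnesses (e.g. doubling
the medial or lateral structures). Both return new apparatus objects and are
exactly additive/linear in the underlying statics, which the test suite
checks by superposition.

## The quasi-static twin

The physical machine drives flexion–extension and external–internal rotation
in position control and the remaining four components (anterior–posterior,
medial–lateral and inferior–superior force, abduction–adduction moment) in
force control, using an iterative learning controller that converges over
hundreds of cycles. The twin has no plant dynamics, so cycle-to-cycle
learning would be vacuous: each time step is solved directly for the
equilibrium pose at which contact plus ligament loads equal the target
loads on the four force-controlled components, with the two position-
controlled components clamped.

**Contact.** Articulation is frictionless penalty contact between analytic
surfaces: one femoral sphere per condyle against a concave spherical dish
(or a plane). Penetration follows from centre distances in closed form; the
normal force is `k_c·δⁿ` (default `k_c` = 5000 N/mm, `n` = 1). Analytic
geometry keeps every contact quantity differentiable except at liftoff and
provides closed-form oracles (penetration = F/k_c on a single condyle;
chord-circle contact areas) for the tests. Real implant surfaces are out of
scope by design.

**Solver.** A damped Newton (Levenberg-style) iteration on a central-
difference Jacobian (step 1e-5 in mm/deg) over the four free coordinates,
with backtracking line search to cross the piecewise-smooth kinks of
penalty contact and the ligament law, a damping floor relative to the
dominant curvature so directions with no local stiffness (a lifted condyle,
in-plane motion on a flat plateau) stay regularised, and deterministic
restarts from neutral seats when a warm start stalls. The iteration drives
residuals four orders of magnitude below the reporting tolerances
(defaults 0.5 N force, 0.05 N·m moment) so the solved pose is a function of
the targets rather than of the warm start; the reported residuals are
recomputed from the returned pose, not taken from the solver state.
Non-convergence is a flagged state on the step, not an exception; a run is
marked failed if more than 10% of its steps fail to converge.

**Cycles.** `run_load_case()` replays the periodised track (default two
cycles) with warm starts and reports the last cycle plus the maximum
coordinate change between the final two cycles. For this memoryless system
the change is at the solver-slop level (~1e-6) by the second cycle. Deep
flexion under light load can admit more than one static equilibrium
(ligament-suspended vs contact-seated); the deterministic restart order
makes the returned branch reproducible.

**Compliance compensation.** A machine that sags elastically under axial
load misrecords strand reference lengths if referenced unloaded. The
standard remedy references the joint under the load case's mean compression;
here that is modelled as shifting the nominal reference pose axially by
`compliance × mean axial load` (time-weighted trapezoidal mean over one
cycle) before recording strand lengths. With zero compliance this reduces
exactly to plain referencing, and the compensated apparatus depends on the
track only through its mean axial load.

**Footprints.** The contact patch of each pose is the analytic intersection
circle of sphere and dish (or the chord circle on a plane), projected onto a
per-condyle grid on the tibial surface; a trajectory's footprint is the
union of marked cells. At 0.1 mm resolution the static patch area is within
2% of the closed form. This is a qualitative analogue of a scanning-spray
footprint — an indication of where contact occurred, not a stress map.

**Flexion-binned comparison.** Soft-tissue variants are compared the way
simulator studies present them: samples are split into flexion and extension
phases by the sign of the flexion rate, binned by flexion angle (10° bins by
default), and per-bin mean differences of anterior-posterior translation,
abduction-adduction angle and transmitted (contact) axial force are
reported. On the toy joint, PCL resection shifts the equilibrium posteriorly
in bins above 40° with much smaller change below 30°, and doubling one
collateral group's stiffness moves abduction–adduction toward the stiffened
side. One caveat the package documents rather than resolves: descriptions of
post-resection behaviour in the literature differ in sign between "more
anterior" and "posterior shift at higher flexion"; mechanically (and in this
twin) the tibia settles *posteriorly* at deep flexion once the PCL's
anterior pull is removed, and the directional tests use that reading.

## Synthetic activities of daily living

The generator produces smooth one-cycle tracks from sums of raised-cosine
bumps — not digitised recordings — and honours published scalar landmarks
exactly by construction: cycle frequencies (level walking 0.625 Hz, squat
0.2 Hz), peak flexion (level walking 49°, stairs descent 87°) and peak
compression (stairs descent 2943 N, downhill walking 2930 N, level walking
2401 N, squat 2336 N). Values with no published counterpart — the
intermediate frequencies (downhill 0.5 Hz, stairs 0.4 Hz, sit-to-stand
0.25 Hz), sit-to-stand's peak flexion and compression, and all
anterior-posterior/medial-lateral/abduction magnitudes — are package fixture
defaults chosen to be physiologically plausible, and are documented as such.

Locomotion activities share a two-hump stance compression shape and start
and end near full extension; sit-to-stand starts and ends at its flexion
maximum (approximately a half-cycle phase shift of the squat). The
anterior-posterior force and abduction moment channels are expressed as
fractions of the instantaneous compression (peaks of 12% and a 4 mm
equivalent lever respectively), so every sample is transmissible through a
condylar contact — the property that lets the twin converge at every step.
A seeded linear ramp injects a configurable endpoint mismatch so raw tracks
genuinely exercise the periodisation stage; generation is pure (an internal
splitmix-style generator; R's global random state is untouched).

The default ligament apparatus is likewise a *synthetic fixture*: twelve
strands over the four groups (capsular 4, medial 3, lateral 3, PCL 2) with
anatomically plausible attachments on a generic-size right knee. Femoral
origins sit close to the flexion axis so the collaterals are near-isometric
over flexion, the PCL bundles lengthen with flexion (by ~9–13% at 87°), and
the posterior capsule engages in deep flexion. Stiffnesses (1000–3000 N per
unit strain) and reference strains (−0.01 to 0.05) are in the range used for
strand models of the human knee, but they are not measured parameters of any
specific specimen, and the seed only jitters attachments by ±0.5 mm.

**What passing tests show — and what they do not.** The synthetic waveforms
reproduce printed landmark magnitudes and qualitative shapes, not real
telemetric curves; the toy surfaces are spheres, not implant CAD; the
apparatus is generic. Green tests therefore demonstrate that the *pipeline*
is correct (transform identities, force-law arithmetic, equilibrium
residuals, directional soft-tissue responses), not that the twin reproduces
any physical machine's measured kinematics. Quantities such as the ~0.2 mm
posterior shift after PCL resection on the toy joint are internally
consistent but should not be compared numerically against cadaver or
simulator data.

## Numerical choices and problem sizes

* Pose orthogonality tolerance 1e-10; gimbal guard 1e-6°.
* Newton: central differences (1e-5), λ from 1e-3 adapted ×10 / ÷3,
  backtracking ½-steps, at most 50 iterations per step including restarts
  (each attempt capped at 20).
* Convergence reported at 0.5 N / 0.05 N·m; iterated to 1e-4 of that.
* Default runs in tests and the acceptance script use 48 samples per cycle
  and 2 cycles per activity — enough for every property tested while keeping
  a full five-activity replay around half a minute on one core.
* CSV numerics are written with 17 significant digits so write/read round
  trips are bitwise.

## Known limitations

No friction, wear, creep or inertial dynamics; no post-cam contact for
posterior-stabilised designs; no ligament viscoelasticity or wrapping; the
iterative learning controller of the physical machine is intentionally
replaced by direct equilibrium solving; and the contact surfaces are
analytic surrogates. The registration transform is user-supplied
configuration — virtual implantation of CAD geometry is out of scope.
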