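---
title: "Bilateral upper-limb modeling and bimanual load simulation with bimanum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilateral upper-limb modeling and bimanual load simulation with bimanum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimanum)
```

`bimanum` builds a bilateral upper-extremity musculoskeletal model from a
unilateral one, imposes graded unilateral rotator-cuff-tear (RCT)
severities and bimanual shared loads, and resolves the muscle-redundancy
problem quasi-statically to quantify bilateral compensation. This
vignette is the package's account of the science behind each stage: the
models and their assumptions, the tunable parameters, the numerical
choices, and the limits of what the synthetic test fixture can show.

## Mirroring: constructing the bilateral model

The mirror plane is the mid-sagittal plane, taken as the ground-frame
plane whose normal is the *z* (medial/lateral) axis; models with other
conventions can configure the axis and the side-suffix name map
(`mirror_convention()`). Reflection of a point negates its *z* component.
For orientations stored as body-fixed XYZ Euler angles the mirrored
rotation is the conjugation $R \mapsto M R M$ with $M =
\mathrm{diag}(1, 1, -1)$; since $M R_x(a) M = R_x(-a)$, $M R_y(b) M =
R_y(-b)$ and $M R_z(c) M = R_z(c)$, this negates the two in-plane
rotations and preserves rotations about the plane normal, and the result
is always a proper rotation. Wordings that describe shoulder-joint
mirroring in terms of "local x and y directions" are ambiguous between
several sign conventions; the conjugation above is the unique transform
under which a mirrored chain satisfies the forward-kinematics symmetry
oracle (below), which is why the package implements it.

A rotation axis $a$ driven by a coordinate $\theta$ conjugates to
$R(Ma, -\theta)$. The package realizes this as $R(-Ma, \theta)$: the
**axis vector is flipped and the coordinate keeps its sign**, so
coordinate ranges and defaults carry over unchanged and *identical*
coordinate values on the two sides produce mirror-symmetric postures.
This sign policy is what lets one set of recorded joint angles drive both
sides of a bimanual simulation directly. Translation axes map to $Ma$.
The inertia tensor maps to $M I M^{\mathsf T}$ (products $I_{xz}$ and
$I_{yz}$ negate); the mass-property mirroring covers the full tensor, not
only the center of mass, because a mirrored body with unmirrored products
would be dynamically asymmetric. Triangle meshes have every vertex
reflected and every face's winding order reversed, restoring outward
normals (stored normals are recomputed, not mirrored).

Two properties are enforced by tests rather than assumed:

* **Involution** — mirroring any component twice returns the original to
  at worst 1e-12 relative error.
* **Mirror-symmetry oracle** — on the bilateral fixture, applying the same
  coordinate vector to both sides places every right-side station at the
  mirror image of its left twin to below 1e-9 m, and left/right
  musculotendon lengths agree to the same tolerance.

Euler extraction uses the standard branch; at the gimbal singularity
(second angle within 1e-9 of ±π/2) the third angle is set to zero and the
in-plane rotation folds into the first angle, making round-trips
deterministic.

## Pathology and the shared load

RCT severity is modeled purely as scaling of peak isometric force on the
affected side (the model's right by default), under the assumption that
lost force capacity is proportional to the torn tendon fraction: partial
(supraspinatus 0.5), full (supraspinatus 0, infraspinatus 0.75), massive
(supraspinatus 0, infraspinatus 0.25, subscapularis 0.5); teres minor is
never scaled. `apply_rct()` snapshots the pristine baseline on first use
and always scales that baseline, so severities are absolute and
re-application never compounds. Muscle atrophy, fatty infiltration and
pain-driven kinematic adaptation are outside the model.

The shared load is a box of weight 13.3 N or 44.5 N. Printed weight/mass
pairs for such objects are often rounded inconsistently (4.5 kg × g is
44.1 N, not 44.5 N); the package treats the **weight as authoritative**
and derives mass as `W / g` with g = 9.80665 m/s². The box is welded to
the left hand and tied to the right hand by a weld constraint, with its
center of mass at the midpoint of the two hand COMs in the default
posture (palms toward the midline, arms extended). Its inertia is that of
a uniform 0.2 × 0.2 × 0.4 m box (long axis spanning the hands); inertia
is irrelevant for the static tasks and second order for the slow reach.

## Task battery

Tasks are coordinate-space profiles rendered to `.mot`-style tables in
degrees at a configurable rate (default 100 Hz over 7 s):

| task | parameters |
|---|---|
| low static hold | shoulder elevation 80°, elevation plane 80°, elbows extended |
| high static hold | shoulder elevation 130°, elevation plane 80° |
| forward reach | minimum-jerk out-and-back, peak 75° elevation at mid-task, elbow 90° → 20° coupled linearly to the elevation fraction |
| verification static | arm by the side, shoulder rotation −25° |
| verification dynamic | rotation −45°, elevation 0 → 90 → 0° |

Wrist coordinates are locked at 0° throughout. The reach trajectory shape
is a design choice: recorded kinematics for such reaches are typically
participant-specific and not redistributable, and a minimum-jerk
out-and-back profile is the standard smooth surrogate; recorded `.mot`
kinematics can be substituted anywhere a task is accepted. The elbow
coupling (90° toward 20° at peak reach) is likewise a configurable
surrogate, as is the mapping of the two static targets onto the fixture's
(elevation-plane, elevation) coordinate pair.

## Kinematics processing

Joint-angle and marker series are smoothed with a zero-phase dual-pass
Butterworth low-pass at 6 Hz. The total order (default 4) is split so the
per-pass design order is `order/2` and the raw cutoff is passed to the
design without dual-pass compensation; the amplitude at the cutoff after
both passes is then exactly $(1/\sqrt2)^2 = 0.5$, which the tests assert.
The implementation wraps `signal::filtfilt` with odd-reflection end
padding (pad length `9 / W_n` samples) and endpoint offset removal so
that edge transients decay inside the pads and the DC gain is exactly 1 —
a constant input column passes through unchanged.

Marker tables from single-sided capture are mirrored by negating one
stated lab axis (conventionally *x*; the lab frame's mirror axis need not
be the model's, so both are explicit parameters). Joint-angle tables are
mirrored by renaming columns through the side map; because the package's
own bilateral models absorb the reflection sign into the axis vectors,
the default per-coordinate sign is +1, with an explicit `sign_map` for
models that instead flip axial-rotation signs. Symmetry is verified as a
per-DOF RMSE between sides with a 1.5° pass envelope — on exactly
mirrored synthetic kinematics the RMSE is numerically zero, and injected
Gaussian noise of 0.5° is recovered as ≈0.5° RMSE.

## The reduced solver

The full tracking-control pipeline (closed-loop controller with
activation and contraction dynamics) is deliberately replaced by
**per-step static optimization** with rigid tendons and activation-linear
force: for 7 s quasi-static tasks, time-averaged normalized forces from
static optimization are the accepted surrogate, and reproducing a
specific controller is a non-goal. Inertial torques during the reach are
neglected (quasi-static treatment) — the main fidelity gap.

Per time step at pose $q$:

1. **Moment arms** $r_{ij} = -\partial L_i / \partial q_j$ by central
   finite differences of polyline musculotendon length, step 1e-5 rad.
2. **Demand** $\tau_j$ from virtual work: the negated generalized gravity
   force of all bodies, $-\sum_b m_b\, g^{\mathsf T} \partial p_b /
   \partial q_j$ (a point mass $m$ at horizontal distance $d$ from an
   elevation axis demands $mgd$), plus the load contact contributions.
3. **Redundancy resolution**: minimize
   $\sum_i a_i^2 + w\|\tau_{\mathrm{slack}}\|^2 + \varepsilon P(c)$
   subject to torque balance and $0 \le a \le 1$, with $w = 10^6$
   (N·m)⁻². The squared-activation cost (exponent 2) makes the program
   strictly convex, so no tie-breaking is needed among muscles; other
   exponents are available and solved by bounded quasi-Newton refinement.
   Force–length/velocity scaling is omitted (factor 1.0) because the
   pathology model modulates only peak isometric force; a multiplier hook
   can be added where muscle state is known.

Balance is enforced on the **muscle-actuated coordinates**: the unlocked
coordinates whose joints are structurally crossed by at least one muscle
path. Coordinates no actuator can influence (the fixture's elbow, since
all fourteen actuators span only the shoulder) are treated as externally
supported — the reduced analogue of reserve actuators at non-analysed
degrees of freedom in a full controller.

**The interaction wrench.** The box couples the two arms. Its contact
with the arms is a force and couple at each hand station, constrained by
the box's rigid-body equilibrium, so no net free wrench can be invented;
the single free 6-vector $c$ is the wrench transmitted through the weld
constraint at the second hand, and the left-hand contact is the
equilibrium remainder. A small tie-break $\varepsilon P(c)$
($\varepsilon = 10^{-4}$) penalizes both stations' deviation from the
symmetric half-weight, zero-couple share; it is mirror-invariant, which
guarantees that symmetric tasks at severity *none* recruit both sides
identically (the tests require equality to 1e-9). There is no grip-force
bound, matching the rigid weld construction — consequently a weakened arm
can lean on the box and demand genuinely saturates only when the system
as a whole runs out of capacity. A zero-weight box transmits nothing and
leaves the solution bit-identical to the unloaded model.

The inner problem is solved exactly by a primal-dual active-set method on
the stacked least-squares form (the identity rows keep every free
subproblem full column rank; subproblems use QR). Torque balance
$\sum_i r_{ij} F_{\max,i} a_i + \tau_{\mathrm{slack},j} = \tau_j$ holds
by construction to ≤1e-8 N·m, and the solution matches exhaustive grid
search on small instances to ≤2e-3. A step is flagged feasible when
$\|\tau_{\mathrm{slack}}\|_\infty \le$ 1e-5 N·m (with $w = 10^6$ the
residual slack of a truly feasible step is orders of magnitude below
this).

**Load deviation.** Tracking the box with a forward-dynamic controller is
out of scope, so unmet demand is mapped to a box displacement by an
explicit surrogate: with $J = \partial p_{\mathrm{box}} / \partial q$
(averaged over the two supporting chains) and unit generalized compliance
1 rad/(N·m),
$\delta = -J\, \tau_{\mathrm{slack}}$. A feasible step maps to exactly
zero; a bilateral elevation deficit maps strictly inferior (gravity wins
along the coordinates it loads); a one-sided deficit acquires a
mediolateral component toward the unaffected side. The magnitude scale of
$\delta$ is the surrogate's, not a calibrated displacement — only its
directions are interpreted. The tracked box position itself is the
midpoint of the two hand COMs, which is invariant under symmetric posture
changes.

## Outcome measures

Muscle force is normalized to model-specific peak isometric force
(% maximum). For torn muscles the **post-injury** capacity is the default
denominator, with the zero-capacity case reported as 0 % and flagged;
"model-specific peak isometric force" does not disambiguate pre/post, so
the pre-injury denominator is available by flag. Severity and load
contrasts are **percentage-point differences** of time-averaged % maximum
("a 12 % increase in average contribution (% maximum)" is read as points,
the natural unit of an already-normalized outcome); the relative change
is reported alongside. Deviation summaries decompose static displacement
into inferior/superior (ground *y*) and toward-affected/unaffected
(ground *z*, affected = right = positive) components in mm, and report
per-direction RMSE against the input-kinematics trajectory for the
dynamic task (a full 3-D RMSE is a trivial combination if preferred).

## The synthetic fixture, and what passing tests show

`make_unilateral_fixture()` emits a three-body right-sided model — thorax
(welded to ground), humerus (0.30 m, 2.0 kg), forearm+hand (0.30 m,
1.5 kg) — with a three-rotation shoulder (plane of elevation about *y*,
with 0° the frontal plane and 90° sagittal-forward; elevation; axial
rotation), an elbow-flexion coordinate, locked wrist
flexion/pronation coordinates, and fourteen two-point shoulder-crossing
actuators (supraspinatus 487 N, infraspinatus 1210 N, subscapularis
1378 N, teres minor/major, three deltoid, three pectoralis major and
three latissimus dorsi compartments with order-of-magnitude defaults).
Each actuator has a usable (>1 mm) moment arm about at least one shoulder
coordinate, and the muscle set can hold every task in the battery at full
capacity. Generation is deterministic; the seed feeds only the optional
noise used in RMSE-sensitivity checks.

The fixture emulates the *structure* of an upper-extremity model — sided
naming, custom joints with coordinate-driven rotation axes, phantom
(locked) coordinates, actuator paths spanning the shoulder — but not the
redundancy breadth, wrapping surfaces, multi-articular paths or validated
moment-arm profiles of a full model. Tests passing on it establish the
correctness of the transforms (mirroring, I/O round trips, filtering,
torque balance, QP optimality, symmetry) and the *directions* of the
compensation and deviation trends; they do not reproduce any published
force magnitude, and simulated contrasts on the fixture are
correspondingly small. Trend assertions are made at the resolution at
which such outcomes are conventionally reported (whole percentage
points): "non-decreasing" tolerates sub-resolution wobble of <0.5 points,
which arises because the free interaction wrench lets the optimizer shift
a little support contralaterally as severity grows.

Default problem sizes in the tests and the acceptance script — 1 s static
holds at 25 Hz (a static hold is one unique pose; repeated rows are
solved once) and the 7 s reach at 25 Hz — were chosen as the smallest
grids on which the per-step solver's behavior is fully exercised;
rendering tasks at 100 Hz reproduces the same solutions row for row.

## Known limitations

* Quasi-static: no activation/contraction dynamics, no inertial torques,
  no forward-dynamic tracking; the deviation surrogate is directional,
  not calibrated.
* Rigid-tendon, activation-linear muscle force; no force–length/velocity
  effects.
* Joint contact forces, humeral-head translation, scapular rhythm and EMG
  validation are out of scope.
* The kinematic loop closed by the weld constraint is treated through
  statics only; asymmetric postures that would strain the closed loop are
  not checked for assembly consistency.
* The `.osim` reader supports the 3.3-dialect subset the pipeline touches
  (bodies, custom/weld joints, coordinates, muscle actuators as opaque
  classes with `max_isometric_force` and path points, weld constraints,
  display meshes); everything else is preserved verbatim but not
  interpreted. Wrap surfaces are carried as opaque frames, not mirrored
  geometry.
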