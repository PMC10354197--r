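---
title: "Modelling seated-occupant whole-body vibration with seatvibe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seated-occupant whole-body vibration with seatvibe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seatvibe)
library(ggplot2)
```

## The model

seatvibe implements a linear lumped-parameter model of a seated vehicle
occupant.  The body is divided into sixteen rigid segments — head, thorax,
abdomen, pelvis, and paired upper arms, forearms, hands, thighs, legs and
feet — each carrying a fore-aft (x) and a vertical (z) translation, giving
32 degrees of freedom.  Adjacent segments, and segments in contact with the
seat structure, are joined by 26 spring–damper elements.  Every element
carries a full 2×2 coupling matrix in each of stiffness and damping, with
direct entries (xx, zz) on the diagonal and cross-coupled entries (xz, zx)
off it, so vertical seat motion can drive fore-aft segment motion and vice
versa.  Displacements are measured from static equilibrium; gravity drops
out of the linearised small-vibration equations.  Cross-coupled entries are
taken symmetric (xz = zx), which makes the assembled global stiffness and
damping matrices exactly symmetric.

For steady harmonic base motion $z_0 e^{j\omega t}$ the response solves the
dynamic-stiffness system

$$(-\omega^2 M + j\omega C + K)\,\chi = F(\omega),$$

where $M$ is diagonal with each segment's mass on its two dofs, $K$ and $C$
are assembled by standard two-node superposition (+ the element matrix on
both endpoint blocks, − on the off-diagonal blocks), and the forcing
collects $([K_i] + j\omega[C_i])(0, z_0)^T$ over every element anchored to
a moving support.  The package solves this with a dense complex direct
solve per frequency and verifies each solution against a residual bound of
$10^{-8}\,\lVert F\rVert$.

Three response curves summarise the dynamics:

* **STHT** (seat-to-head transmissibility).  Two definitions are exposed:
  the *literal* form $|Z_1|\sin\theta_1 / z_0$, which projects the head
  motion on the inclined backrest direction ($\theta_1$ = backrest angle,
  default 24°), and the *conventional* $|Z_1|/z_0$.  The literal form goes
  to $\sin\theta_1$ instead of 1 in the rigid low-frequency limit and
  vanishes for a vertical backrest, which no measured seated-occupant curve
  does; because the projected form is the one printed alongside the
  packaged parameter set it remains the default, and the conventional form
  is one flag away.  The peak frequency is identical in both modes.
* **AM** (apparent mass), the complex force/acceleration ratio at the
  body–seat interface, in kg.  The default `pelvis` mode uses the force
  carried by the seat–pelvis element over the pelvis acceleration; the
  `seat` mode sums force over all seat elements and divides by the seat
  acceleration, recovering the seat-borne static mass as $\omega \to 0$.
  Which thigh/seat paths belong in the numerator is ambiguous for a real
  seat; both readings are implemented.
* **TR** (segmental vibration transmissibility), $|Z_s|/z_0$ per segment,
  used for the head, thorax, abdomen and pelvis curves.

Peaks are located on the analysis grid (0.5–20 Hz at 0.01 Hz by default)
and refined by a quadratic fit through the three points around the discrete
maximum, with ties broken toward the lower frequency and boundary maxima
flagged rather than refined.

## The connection topology

The packaged parameter table numbers its 26 elements but does not print the
element-to-joint map, so the topology is a design decision of this package
and is fully overridable through the model file.  Two arrangements ship
with the package (`default_topology()`):

* **`seat_path`** (default).  The only body-to-ground element is the seat
  cushion under the pelvis (index 4).  The seat frame — pan, backrest,
  footrest — is treated as rigid, massless and carried at the pelvis–seat
  interface, consistent with regarding pelvis and seat as effectively
  rigidly connected while every other segment connects flexibly.  The
  lumbar-support elements sit at indices 11–12 and the remaining contact
  elements (headrest, seat pan under the thighs, footrest, hands resting on
  thighs) act between their segment and the pelvis-borne frame.
* **`full_contact`**.  Seat, backrest and floor are independent moving
  supports attached directly to pelvis and thighs, to head, thorax,
  abdomen and pelvis, and to the feet.

The choice matters.  The packaged stiffness entries are all of order
$2\times10^5$ N/m; anchoring the body through a single such element places
the primary transmissibility resonance near 5 Hz, where seated humans
actually resonate and where the packaged model is reported to resonate,
whereas anchoring through nine support springs (the `full_contact`
arrangement) stiffens the system to a 12–14 Hz primary peak.  Because only
the single-ground-path arrangement is dynamically consistent with both the
packaged parameter magnitudes and the documented resonance behaviour, it is
the default; `full_contact` is retained for sensitivity studies on the
anchoring assumption.  All supports move in phase with equal amplitude by
default, with per-support scaling available.

With the default topology the seat-cushion element dominates the response:
its direct vertical stiffness and damping are by far the most influential
individual parameters of the transmissibility peak.  Two finer published
orderings — the pelvis and abdomen masses ranking above the thorax mass,
and direct vertical stiffness dominating cross-coupled stiffness *on
average* — do not reproduce under this topology (the thorax, as the
heaviest segment on the single load path, outranks the pelvis mass, and
the cushion's own cross term is influential even though all 25 other cross
terms are negligible).  The sensitivity tests therefore assert the robust
properties rather than those orderings.

## Parameter identification

The 224 decision variables (16 masses, then per element the four stiffness
and four damping entries) are identified by minimising the weighted
sum-square error between target and model curves at the $p$ target
frequencies,

$$O_f = \sum_{i=1}^{p} \alpha_1\lambda_1 + \alpha_2\lambda_2 +
  \alpha_3\lambda_3 + \alpha_4\lambda_4,$$

with $\lambda_{1..4}$ the squared STHT-magnitude, STHT-phase, AM-magnitude
and AM-phase errors.  Phase differences are wrapped to (−180°, 180°]
before squaring.  The default weights are all 1, with phases in degrees.
Note that equal unit weights mix units (a degree² of phase error counts as
much as a kg² of apparent-mass error and far more than a dimensionless
STHT-magnitude error); for studies that care about balanced curve recovery
we recommend nondimensionalising the weights by the target scales, as the
package's own recovery tests do.

Constraints are enforced by projection, not penalty, so every vector the
optimizer returns satisfies them exactly: the masses are rescaled
multiplicatively to the 77.3 kg total, left/right limb masses are averaged
and duplicated, xz/zx cross entries are averaged, and direct entries are
clipped into the (100, 300000) N/m and N s/m bounds.  Cross entries share
the direct magnitude interval but are sign-free.  The projection is
idempotent.  (The packaged mass table itself sums to 75.72 kg — it is
preserved verbatim rather than re-normalised to the 77.3 kg used during
identification.)

The optimizer is a firefly algorithm: brightness is the negated objective,
and at each iteration every firefly moves toward every brighter one by
$\beta_0 e^{-\gamma r^2}(x_j - x_i)$ plus a decaying uniform random step,
with distances and steps taken in bound-normalised coordinates so one
$\gamma$ covers masses and stiffnesses alike.  The best firefly is kept
elitistically, and additionally performs a Gaussian random walk whose scale
adapts by a success rule — grown when a trial improves, shrunk otherwise —
which is what lets the swarm descend a basin once found.  Because the
identification valleys are strongly ill-conditioned, `fa_config()` also
offers a derivative-free Nelder–Mead polish of several diverse swarm
candidates (best-first, then most-distant) in normalised coordinates;
it is off by default and enabled in the curve-recovery studies.
Termination is at the iteration cap or when the best objective reaches the
sum-square-error tolerance (10⁻⁶ by default).  A fixed seed makes the whole
run bit-reproducible.

Fits are scored with the goodness-of-fit statistic

$$\varepsilon = 1 - \frac{\sqrt{\sum(\tau_e - \tau_a)^2/(N-2)}}
  {\sum \tau_e / N},$$

which equals 1 exactly for identical series, with deviation
$\delta = (1 - \varepsilon)\cdot 100\%$.

## Synthetic targets

`make_targets()` forward-solves a source model at $p$ frequencies over
0.5–15 Hz (the band of the laboratory seated-occupant experiments the
identification step is designed for, vertical random excitation of
1 m/s² r.m.s.) and optionally corrupts the curves: multiplicative Gaussian
noise on magnitudes, additive Gaussian noise in degrees on phases.  The
noise model is the package's own invention — no noise characterisation of
the original reference data exists — and zero noise returns the model
curves exactly, which is what makes the self-consistency and recovery
tests meaningful.  Synthetic targets emulate a single averaged subject;
they carry none of the inter-subject variability, nonlinearity or
measurement bias of real laboratory curves, so passing recovery tests
demonstrates correctness of the identification machinery, not fidelity of
any fitted model to a particular human.

The curve-recovery study uses a two-segment vertical-path reference model
(50 + 27.3 kg in series above the seat), twelve noiseless target points,
a swarm of 20 for 60 iterations with the adaptive walk, and a polish of
the four most diverse candidates; the acceptance surface is the recovered
curve (goodness of fit at least 0.99 on both magnitude curves), since the
parameters themselves are not identifiable from smooth curves.

## One-factor-at-a-time sensitivity

`oat_sensitivity()` perturbs one parameter at a time by ±20% (the mirror
limb parameter and the zx twin of an xz entry move jointly while symmetry
is active), re-solves the model, and reports the relative change of the
STHT peak magnitude, with the peak-frequency shift as auxiliary output.
The STHT mode defaults to the literal projected form for consistency with
the identification pipeline; relative changes are identical in either mode
because the projection factor cancels.  A 0.05 Hz grid is the sensitivity
default — the quadratic peak refinement makes the finer 0.01 Hz grid
unnecessary here.  Perturbations that would drive a mass or direct entry
non-positive are flagged invalid rather than evaluated.

## Ride comfort

For ride studies the occupant is coupled to a 7-dof full-car model: body
heave, pitch and roll plus four unsprung vertical dofs, assembled from
corner suspension elements and tire stiffnesses.  The occupant's support
elements then couple their segments to the linearised car-body vertical
motion at the seat position (heave − x·pitch + y·roll) instead of a
prescribed base.  The coupled matrices remain symmetric, and clamping the
car (suspension and tire stiffness → ∞) reproduces the standalone occupant
response — a property the tests verify at 1%.

The default car is a synthetic mid-size-sedan stand-in (1500 kg body,
2.7 m wheelbase, passive suspension, seat on the centreline 0.3 m behind
the centre of gravity); no published parameter set is reproduced, and the
file name marks it as synthetic.  Harmonic wheel inputs of amplitude
0.025 m are applied in phase by default, with an optional wheelbase
time-lag policy.  Segment acceleration spectra ($\omega^2 |Z_s|$) are
classified against exposure-limit curves by linear interpolation of the
limit tables onto the response grid; the packaged 4/8/16-hour tables are
synthetic fatigue-decreased-proficiency-style vertical-acceleration
boundaries (constant over 4–8 Hz, rising as $2/\sqrt{f}$ below and $f/8$
above), shipped as editable CSV because users comparing against a
particular standard's charts should supply that standard's tables.

## Numerical choices and limitations

* Direct dense complex solves per frequency; no modal reduction.  The
  32-dof model solves the full 0.5–20 Hz grid (1951 points) in about a
  second.
* Validation is aggregated: a model file with several schema violations
  reports all of them at once.
* The model is linear: no joint nonlinearity, no seat-cushion contact
  separation, vertical excitation only, no 3-D rotations.  Fore-aft motion
  exists only through the cross-coupled terms.
* The identification study sizes quoted above (swarm 20–100, 10–60
  iterations, 10–12 target points) are the package's test and example
  conditions; production identification from measured curves will
  generally want the full swarm of 100 and more iterations.
* The goodness-of-fit statistic divides by the series mean, so it is
  scale-free for magnitude curves but ill-suited to phase series whose
  mean is near zero or negative; the package reports per-curve values and
  leaves phase interpretation to the user.
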