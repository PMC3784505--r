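---
title: "vibrisim: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vibrisim: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibrisim)
```

## The model

`vibrisim` simulates a rat-like agent in a 2-D plane whose only sensors
are fourteen whiskers (seven per side) and whose behaviour — where the
snout points and how far each whisker sweeps — is driven by a single
internal variable: the currently attended region of space, represented as
a peak in a head-centric salience map. Attention is overt in this model:
whisker posture asymmetries and head orienting are both read-outs of the
same map.

### Physical plane model

The head is a fovea (snout tip) and a neck joint 50 mm apart; the neck
trails the fovea along the straight line towards it, so the bearing is the
fovea-neck direction. Whisker bases sit on a "mystacial pad arc": an
ellipse in the head frame with its rostral tip at the fovea and semi-axes
30 mm (longitudinal) by 12 mm (lateral), with the seven bases per side
evenly spaced in ellipse parameter between 75 and 15 degrees from the tip.
The ellipse dimensions are not anatomical constants but a stand-in of the
right scale; the behavioural results below were insensitive to moderate
variations. Each whisker is a constant-curvature arc of length 44 to 8 mm
(caudal to rostral) and rest curvature -0.01 to 0.08 per mm. Protraction
angles are measured from the caudal direction of the midline, increasing
rostrally, so 180 degrees points straight ahead. The shaft leaves the base
exactly at the protraction angle (no fixed tangent offset; the offset is
unobservable here because only angle *changes* drive the analyses).

Bending against oriented rectangular obstacles is quasistatic: the
curvature is adjusted increasingly caudally until the shaft just clears
every obstacle. The solver bisects a caudal curvature offset on
[0, 0.25 mm^-1] to a tolerance of 1e-4 mm^-1 with the arc discretised at
1 mm; if even the bound still penetrates (for instance when the
collisionless snout carries a whisker base inside a wall) the result is
clamped and the sample flagged. The contact signal is
`tanh(g_i * delta)`, where `delta` is the displacement of the point 5 mm
along the shaft and `g_i = k_g * sqrt(L_i)`. The square-root length
dependence approximately equalises signal strength across the array; the
scale `k_g` is fixed by `calibrate_sensing_gain()`, which searches a log
grid for the smallest value whose median nonzero contact signal during a
60 s arena exploration lands in [0.5, 0.8] (the calibrated default is
0.178, median 0.59).

### Attention maps

All maps share a head-centric grid, 80 mm longitudinal (20 behind the
fovea to 60 ahead) by 120 mm lateral, at 2 mm resolution. Contacts
deposit Gaussian blobs (width 8 mm, read as two sigma) of height equal to
the contact signal; at each 8 Hz oscillator tick the "other"
(non-tactile) channel deposits one blob (width 20 mm, height 0.5) at a
location uniform over the grid — a deliberately crude stand-in for
motivation, olfaction, vision and audition.

Each excitation map is a leaky max with memory,

    E' = clip( max(lambda * remap(E), I), 0, 1 ),

where `remap` re-samples the previous state so that stored activity stays
fixed in the world while the head moves (rigid transform, bilinear
interpolation, zero inflow at the boundary). Because bilinear resampling
of a smooth blob is nearly lossless, the decay that repeated re-sampling
is meant to provide is made explicit as `lambda` (`excitation_decay`,
default 0.9 per sample, i.e. roughly 20 % retention across one whisk
cycle). The choice is a memory-span argument: contact memory must bridge
the silent retraction phase between whisks, but old attended locations
must fade within a cycle or two, or their remapped residues — which swing
to the contralateral side whenever the head turns — dominate the
caudally-biased arbitration and invert the head-turning asymmetry.

The coloured per-cell noise (gain 0.025, bandwidth 8 Hz, unit stationary
variance via a first-order autoregressive process) perturbs the *salience
read-out* each sample rather than being integrated into the stored map:

    S = clip(E + g * n, 0, 1) * (1 - H).

Integrating the noise into `E` under the clip at zero rectifies it into a
standing positive background (mean about 0.05) whose arbitration weight
exceeds that of the "reach forward" proposals of any attended blob, which
abolishes the contralateral half of contact-induced asymmetry at every
decay setting; treating the noise as a transient perturbation of the
read-out keeps the same ingredients while storing only genuine input
memory.

Inhibition combines obstacle inhibition (unity inside obstacles and in
their line-of-sight shadow from the fovea) with inhibition of return:
each completed head movement adds the fovea location to a world-frame
memory with a 4 s lifetime; visited locations contribute blobs (width
20 mm, gain 0.5) capped at 0.66. Salience is `E (1 - H)` per channel, and
the channel with the higher peak is re-selected at each tick (ties keep
the previous channel, avoiding chatter).

### Motor output

At each tick the fovea is given a minimum-jerk plan (duration 0.175 s,
zero endpoint velocity and acceleration) towards the salience peak of the
selected map; since ticks arrive every 0.125 s, movements are normally
interrupted and re-planned from the current position, reaching about 86 %
of the way per tick. Exact peak ties go to the nearest cell, then the
lowest index, for determinism.

The salience-to-protraction transform works from a precomputed geometric
table: for whisker i and cell e, the protraction angle at which the
unperturbed arc passes through the cell centre (closed form: the chord of
a circular arc subtends `kappa * s / 2` at the base). Cells beyond the
whisker tip propose the maximum angle (175 degrees) so whiskers reach
towards objects they cannot touch; so do cells outside the whisker's own
half-plane (0-180 degrees), which the shaft could only meet by sweeping
through the head — without this occlusion rule such cells would clip to
the minimum angle and acquire the largest caudal-bias weights, dragging
both sides fully caudal and abolishing every asymmetry. Reachable cells
propose their geometric angle plus the impingement offset (0 degrees),
clipped to [30, 175]. The arbitrated angle is the weighted mean with
weight `(2 S_e)^2 * 500^(-(prop - 30)/145)`, the map contrast is
`C = clip(max(S) - mean(S), 0, 1)`, and the commanded maximum protraction
is `theta_nom + gamma * C * (theta_hat - theta_nom)` with `gamma = 0.5`.
(A normalised contrast `(max - mean)/max` was evaluated: it strengthens
the head-turning asymmetry about threefold but drives whiskers to
converge on single targets so hard that base-angle order inverts and the
spread-reduction ordering is destroyed; the absolute form is kept.)
Whisking is the first-order lag (25 ms) of the base angle towards the
maximum during the final 70 % of each cycle and towards maximum minus the
per-whisker amplitude (30-45 degrees) otherwise, so peak protraction
coincides with the tick.

### Sub-step order and state

Within a sample: oscillator; bending and contacts at the current pose and
angles; input deposition and excitation updates (remapping with the pose
change from the previous sample); at ticks, IOR update, then channel
re-selection and foveation re-planning; inhibition, salience and the
protraction transform every sample (maximum protraction is an
instantaneous quantity); whisk step; head advance with neck drag. Initial
conditions: whiskers at nominal angles, empty maps, empty IOR memory,
"other" channel selected. Randomness comes from three internal
`splitmix64` streams (tactile noise, other-channel noise, target
locations) derived from the run seed, so runs are exactly reproducible
and component-wise stable under parameter changes; experiment-level
randomisation (wall angles, speeds, per-trial seeds) uses R's RNG seeded
from the experiment seed.

Two diagnostic manipulations are built in. `flip_noise` mirrors the noise
streams and stochastic target draws about the midline; with a mirrored
world and pose, the whole log mirrors to machine precision (accumulations
over grid cells are performed in mirror-paired order to make this exact).
`flip_attention` mirrors the selected salience map left/right within the
whisker-control pathway only, which reverses the sense of both
behavioural asymmetries while leaving gross behaviour intact.

## The simulated experiments

**Head-turning asymmetry.** 30 s in free space, where foveation is driven
only by the stochastic channel. The left-minus-right bilateral mean
measured angle is regressed on the head turn rate (central difference of
the unwrapped bearing, zero-phase 2 Hz Butterworth, in degrees per
millisecond). At reference parameters the slope is about -9 with
r of about -0.5; it is flat at zero modulation strength and reverses sign
under `flip_attention`. The magnitude is sensitive to how often strong
turns are aimed at whisker-reachable locations: turns towards targets
beyond reach command symmetric "reach forward" postures and dilute the
regression.

**Contact-induced asymmetry.** An hour (or a stated fraction) in a 400 mm
square arena. Bilateral mean *base* angles and the filtered nose position
are down-sampled to one sample per whisk; whisks with the nose within
25 mm of exactly one wall and at least 100 mm from the rest form the NEAR
set, whisks at least 100 mm from every wall the FAR set, whose grand mean
is the baseline. Base angles are used because shaft angles near a wall
measure physical deformation rather than control (the package exposes the
shaft variant as a control analysis). Relative angles are accumulated in
4 mm bins of the nose-relative nearest wall point, right-side data
mirrored and pooled. At reference parameters protraction is reduced by
more than 2 degrees towards an ipsilateral wall and increased by about
2 degrees or more contralaterally in the 10-25 mm lateral band. The model's
thigmotaxis is strong — wall-following bouts are long because contact
salience keeps refreshing just ahead of the inhibition-of-return trail —
so NEAR occupancy is roughly twice and FAR occupancy roughly a fifth of
what uniform exploration would give.

**Spread reduction.** 100 trials; a wall angled uniformly within +/-10
degrees of perpendicular is approached in a straight line at a speed
uniform in 10-50 mm/s (head control overridden, whisker control live),
from 50 mm down to 5 mm. Each trial offers two side-samples; one is
selected if the pre-contact whisk is contact-free and at least two
whiskers contact during the first contact whisk (about a third of
side-samples qualify). The spread (measured angle of the fifth-from-rear
minus the rearmost whisker) is summarised per whisk by min/mean/max and
averaged across selected side-samples: it falls moderately in the first
contact whisk and strongly in the second, and the base-angle control is
lower overall with the same ordering.

## What the simulations do and do not show

The generator *is* the model: there is no external data, and passing
tests show that the implementation expresses the three attention-driven
motor signatures and their controls, not that real rats work this way.
The stochastic channel is a caricature of everything non-tactile; the
plane model has no inertia, no whisker-on-whisker contact, no body
collision, no whisk-frequency modulation and no within-whisk contact
reflexes. Quantities that depend on fine motor timing (regression
magnitudes, occupancy splits) are therefore softer claims than the signs,
orderings and flatness/reversal controls, which are robust across seeds.

## Numerical choices and problem sizes

Grid 40 x 60 cells at 2 mm; dt = 1/125 s; Gaussian blob support truncated
at four sigma; bending bisection tolerance 1e-4 mm^-1 on the
non-penetrating side, so no resolvable shaft enters an obstacle by more
than 0.01 mm; degenerate inputs (all-zero maps, coincident fovea targets,
empty NEAR/FAR sets) either fall back to documented defaults or raise
classed errors. The test suite runs the experiments at reduced sizes
chosen to keep the full suite under a few minutes while leaving the
statistics clearly resolved: 30 s head-turning runs, 300-600 s arena runs
(counts rescale linearly with duration), and 25-100 approach trials; the
acceptance script runs the arena experiment at the full hour.
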