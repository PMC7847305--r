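---
title: "Methods: contact classification, response calling and SE/LH coincidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact classification, response calling and SE/LH coincidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsegen)
```

This vignette records the methodological conventions behind each analysis
in `pulsegen`, and the reasoning for every operational choice that the
underlying measurement rules leave open. The companion simulators plant
known ground truth so that each convention can be validated quantitatively;
the package's acceptance tests do exactly that.

## 1. Contact classification in ExM stacks

### Coordinate and unit conventions

Volumes are `[x, y, z]` arrays with voxel-centre, zero-based physical
coordinates: voxel `(i, j, k)` sits at `((i-1)·voxel_xy, (j-1)·voxel_xy,
(k-1)·voxel_z)` micrometres. All thresholds are expressed in the imaged
(post-expansion) frame; census densities divide by the expansion factor so
they are reported per micrometre of real tissue.

### Segmentation

The GFP channel is thresholded with a single global Otsu level (a per-plane
threshold would collapse to the noise level on signal-free planes), 3D
6-connected components are labelled, and each tube-like component is
reduced to a centre-line by binning voxel centroids along the component's
principal axis. Because the end bins' centroids sit half a slab inside the
component, the centre-line is extended to the extreme axial projections;
without this correction tube length is underestimated by roughly one bin
width, which matters when a segment sits near the minimum analysable
length. Segment radius is estimated from the component volume as
`sqrt(V / (π·L))`.

Boutons are detected in the kisspeptin channel the same way. Their size is
summarized as the *half-maximum equivalent diameter*: the diameter of a
sphere whose volume equals that of the voxels above half of the
background-subtracted component peak. This makes the size estimate
threshold-independent to first order. Components are kept only when the
equivalent diameter strictly exceeds 0.4 µm; few-voxel components (noise
fluctuations riding on blob tails) are removed by a minimum component size.
Channel co-labelling (`has_kisspeptin`, `has_synaptophysin`) is flagged
when the mean in-mask intensity of the other channel reaches that
channel's own global Otsu level.

### Profiles and overlap

Each bouton is paired with its nearest centre-line point. The viewing
orientation is `"face"` when the bouton–dendron axis lies within 45° of
the optical axis, otherwise `"side"`. Side-view profiles are sampled along
the line from the dendron axis through the bouton centre (extended 1.5 µm
past both surfaces), averaged over three parallel lines one voxel apart —
the usual wide line scan. Face-view profiles are the per-plane mean inside
a 2 × 2 µm box centred on the bouton, taken through the z-stack.

Each channel is normalized to its own in-scan peak, and *overlap* is the
length of the longest contiguous span over which both normalized channels
sit at or above half-maximum. Half-maximum is the natural measurement
level: for a blurred step edge (the dendron wall) and a Gaussian-profiled
bouton whose nominal diameter is its full width at half maximum, the
half-maximum crossings sit at the true geometric boundaries, so the
measured overlap equals the planted interpenetration depth. Crossings are
located by linear interpolation between samples, so the measurement is not
quantized to the sampling pitch; the acceptance suite verifies agreement
with a 1 nm brute-force oracle to within one pitch.

A contact is a **synapse** when its overlap *strictly* exceeds 0.95 µm
(side view) or 1.75 µm (face view); otherwise it is a **close
non-synaptic contact** when the surface-to-surface gap is at most 1 µm,
else **separate**. Synapses additionally require a
synaptophysin-positive bouton: a kisspeptin-only bouton with large overlap
is demoted to a close contact. In confocal scenes no synapse call is ever
made; contacts are close when no sample between the two labelled surfaces
falls below both channels' thresholds (the no-dark-pixel rule).

## 2. Calcium response calling

ΔF% is `100·(F − F0)/F0` with `F0` the mean of the initial pre-puff
baseline frames. (Response amplitudes are therefore percentage *changes*;
a formula of the form `100·(F/F0)` would read 100 at baseline and is
treated as shorthand for the same quantity.) The measure is invariant to
detector gain.

Baseline drift is the absolute fluorescence change implied by a linear fit
to the pre-puff segment, extrapolated across the whole recording, as a
percentage of `F0`; recordings with drift of 5% or more are rejected (the
limit is strict: exactly 5% fails).

The response threshold is calibrated from vehicle-puff controls as
mean + 2 SD; the canonical control distribution of 4.5 ± 0.5% gives the
5.5% rule, which the package reproduces exactly. A ROI is a **responder**
when (i) its peak |ΔF%| after puff onset strictly exceeds the threshold
(increases and decreases both count, and the sign is retained), and
(ii) |ΔF%| stays above threshold for at least one frame after the puff
ends. The duration arm is what rejects pressure artifacts: an artifact of
4.5 ± 0.5% confined to the puff window occasionally exceeds 5.5% in
amplitude, but collapses with the puff and so fails the persistence test.
Group comparisons use rank-based tests (Mann–Whitney, Wilcoxon
signed-rank, Kruskal–Wallis with tie-corrected, Bonferroni-adjusted Dunn
post hoc z-tests, Friedman), with all-tied inputs reported as `p = 1`
rather than an error.

## 3. Photometry and LH pulse coincidence

Scheduled recordings (5 s on / 15 s off) are reduced to one sample per
burst (the burst mean). The running baseline is the rolling 10th
percentile over 30 min — a low quantile tracks slow drift while ignoring
the sparse upward excursions of the events themselves — and
`dF/F (%) = 100·(F − baseline)/baseline`. Synchronization events are local
maxima that exceed 10% of the recording maximum (making detection
gain-invariant), rise from their preceding trough within 2 min
(abruptness), and respect a 2 min refractory separation.

LH pulses must clear two arms: a rise from the preceding nadir greater
than `max(2·CV·nadir, 2·floor)` — twice the assay noise at the nadir,
floored at twice the assay sensitivity — *and* a subsequent fall of at
least half that criterion. The descending flank distinguishes a secretory
pulse (rise, then clearance-driven decay) from a one-sample noise
excursion; with a 9.3% CV, a rise-only rule produces a non-trivial
false-pulse rate on flat series, which the flank requirement suppresses.
A peak at the final sample of a bleed is kept without the flank check, so
a pulse that peaks at the end of the session is not lost.

Coincidence is scored by greedy one-to-one matching in pulse-time order:
each pulse is assigned the nearest preceding unused SE within 10 min
(covering the 1–2 min SE lead plus blood-sampling granularity). Coupled
sessions should show both fractions — pulses preceded by an SE, SEs
followed by a pulse — at 1.0; uncoupled sessions keep their SEs but yield
no pulses, and the pulse-conditional fraction is reported as `NA` rather
than 0.

## 4. Simulators and validation

Each module ships a generator that plants known truth: scene simulations
record every bouton's gap, orientation and intended class (with class
counts assigned by largest-remainder rounding so they are exact); trace
simulations record responder status and artifact amplitudes; photometry
simulations record SE and pulse times. Class margins, SNR and geometry
are chosen so that intended classes sit well clear of the decision
thresholds, which is what makes ≥95% recovery a meaningful test of the
measurement chain rather than of luck. All simulators restore the
caller's RNG state and are bit-for-bit reproducible under a fixed seed.

```{r example, eval = FALSE}
sim <- simulate_exm_scene(scene_params(seed = 11))
res <- classify_contacts(sim$scene)
table(planted = sim$truth$intended_class)
table(detected = res$appositions$class)
```
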