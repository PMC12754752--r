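---
title: "Methods: desk-scale transcranial ultrasound simulation, correction, and surrogate modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale transcranial ultrasound simulation, correction, and surrogate modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and conventions

`tfus` is a self-contained 2D toolkit for studying transcranial focused
ultrasound (tFUS) planning: how a flat phased array focuses through a
heterogeneous skull plate, how per-element emission delays correct the
skull-induced phase aberration, how focal spots are scored, and how a
multi-task recurrent-convolutional surrogate can learn to predict
fields and corrections directly from a skull raster.

Conventions used throughout:

* Rasters are numeric matrices indexed **1-based (row, col)**, row 1 at
  the top; the transducer sits near the top edge and the beam
  propagates downward.
* Lengths are mm, pressures Pa, times s, frequencies Hz.
* Every stochastic generator takes an explicit integer seed and
  restores the session RNG afterwards, so corpora are bit-reproducible.

Two scales appear in the package. The *full scale* mirrors a clinical
2D setup: a 6 cm x 6 cm window at 512 x 512 (0.117 mm spacing), an
80-element array at 0.7 mm pitch (55.3 mm aperture) driven at 500 kHz
with 5-cycle bursts of 1 MPa per element, 3 mm above the window. The
*reduced scale* used by the test and benchmark suites keeps the same
window but 128 x 128 pixels, 40 elements, and 250 kHz, which keeps a
single forward solve under a second on one CPU core. All full-scale
values remain available through `sim_config()` and `array_spec()`.

# Skull phantoms

`generate_skull_phantom()` draws a curved bone plate between two
concentric arcs: an outer and inner cortical table at high HU and a
trabecular (diploic) core at lower HU. Parameters are sampled uniformly
from the ranges in `phantom_spec()`. The reduced-scale family
(`reduced_phantom_spec()`) uses adult-typical values: total thickness
5-7 mm, curvature radius 100-160 mm, a finite 44 mm plate width
(temporal/parietal segments do not span the whole head), apex
2.5-3.5 mm below the array, and two forms of heterogeneity that make
the aberration problem realistic rather than benign:

* **Lateral thickness modulation** (15-30% amplitude, 2-5 lobes):
  calvarial thickness varies by a few mm across an aperture, which
  gives each element a different bone path.
* **Spatially correlated diploic noise** (smoothed Gaussian field,
  sd 250 HU): mm-scale trabecular structure scatters and refracts the
  beam in ways a straight-ray model cannot capture.

Early drafts with thin (3-5 mm), laterally uniform plates and
independent per-pixel noise made straight-ray tracing essentially
optimal, which removes the phenomenon the correction comparison is
about; the family above was fixed before the comparison suites were
frozen. The skull mask is `HU > 150`; the threshold is configurable
and the background is 0 HU (water).

`diversity_filter()` reproduces the corpus-curation step: a greedy pass
in input order that keeps a slice only if its mean squared HU error to
every kept slice exceeds a threshold. The threshold is left
configurable because no canonical value exists; the filter's contract
(order-stable subset, no retained pair at or below the threshold) is
what the tests pin down.

# Acoustic model

`map_hu_to_medium()` converts HU to acoustic maps using the standard CT
piecewise-linear calibration: air (-1000 HU) maps to 1.293 kg/m^3,
water (0 HU) to 997 kg/m^3, and a linear bone segment reaches
2000 kg/m^3 at 1600 HU. Density is clipped below at 997 kg/m^3 so
everything outside bone behaves as water; sound speed is the linear map
`c = 1.33 rho + 166.67` m/s (water: 1492.68 m/s); attenuation is a
constant 13.3 dB/(MHz cm) on the skull mask (power-law exponent 1,
evaluated at the carrier and applied as a frequency-independent
pressure loss rate) and zero elsewhere. All coefficients are exposed as
arguments.

`simulate_forward()` integrates the first-order linear acoustic system
(pressure + two staggered velocity components) with a second-order
finite-difference time-domain (FDTD) scheme and a split-field perfectly
matched layer (PML, 20 px, quadratic profile, theoretical reflection
1e-4). A pseudospectral scheme would admit coarser grids, but the FDTD
stencil is dependency-free, easy to verify, and adequate at the grid
densities used here (6-24 points per wavelength); this choice is
documented rather than hidden. Numerical choices:

* CFL number 0.3; the step is then shortened so one carrier period
  contains an integer number of steps (clean tone-burst sampling).
* Total time defaults to burst duration + diagonal transit at the
  minimum speed + 20% margin: the printed 10 us burst window of the
  full-scale setup cannot reach 3-5 cm targets, so propagation time is
  budgeted separately.
* Sources are additive ("soft") pressure injections over
  `element_width_mm` of pixels per element, driving a Hann-windowed
  5-cycle tone burst; a continuous-wave flag holds the envelope at 1
  after ramp-up. The absolute calibration between drive amplitude and
  radiated pressure is a documented constant; every metric in the
  package is relative, so only field ratios matter.
* The per-pixel maximum-amplitude projection starts once every element
  has finished emitting (burst + largest delay). In 2D, point-like
  sources carry a 1/sqrt(r) near-field singularity that would otherwise
  register as the window peak.

The solver's verified properties (test suite): exact linearity in the
drive amplitude, exact mirror-reflection equivariance, attenuation
monotonicity of the transmitted focal peak, sub-pixel agreement of the
focal peak between 64- and 128-pixel grids in water, transit-time
reciprocity, and focal positioning within half a wavelength of an
analytically focused target in water.

## Focusing regime

The correction and benchmark suites place targets about 15 mm below the
array (F-number ~0.55 for the 27.3 mm reduced aperture), matching the
strongly focused regime of the full-scale setup (F# ~0.5-0.7). At
weak focusing (deep targets at the reduced aperture) the 2D beam
has no pronounced amplitude maximum near the geometric focus — the
well-known axial focal shift — and focal metrics stop being
informative about correction quality.

At the reduced scale the reverberant field trapped between array and
outer table can exceed the transmitted focal amplitude. Focal metrics
are therefore evaluated on the *brain region* below the skull
(`brain_region()`, `crop_pressure_field()`): rows from 4 px below the
deepest skull row to the PML, columns between the PMLs. The metric
formulas are unchanged; only the evaluation window is restricted, and
the full-window forms remain available by passing an explicit region.

# Phase aberration correction

`PhaseVector` stores per-element emission delays in seconds (smallest
delay 0) plus wrapped carrier phases; `phase_fractions()` expresses
delays as fractions of one period in [0, 1), the representation the
surrogate is trained on. Plain L1 on these fractions has a wrap-around
discontinuity (a delay of 0.999 periods is nearly identical to 0); this
is accepted as the training-target convention and noted here rather
than patched, because the delays the corrections produce concentrate
well inside one period at the reduced scale.

Three correction routes are implemented:

* `geometric_focus_phases()` — the closed-form water focusing law
  `t_k = |x_k - x_target| / c0`, delays `max(t_k) - t_k`; the analytic
  oracle for homogeneous scenes.
* `ray_trace_phases()` — straight-segment time of flight through the
  heterogeneous speed map, sampled every quarter pixel with bilinear
  interpolation; refraction is deliberately ignored (this is the
  geometric baseline a fast clinical system would use).
* `time_reversal_phases()` — the full-wave route: a test pulse is
  emitted from the target (`record_at_elements()`), and each element's
  arrival delay is estimated from its received trace. The default
  estimator takes the phase of the trace's DFT component at the
  carrier, anchored to the analytic water time of flight: the
  skull-induced residuals span well under one period, so circular
  re-centering around their mean recovers them without unwrapping.
  A nearest-neighbor phase unwrap across the array (no reference) and
  a cross-correlation envelope-peak estimator are available as
  fallbacks; elements whose received amplitude falls below threshold
  are flagged and interpolated from neighbors. Emission delays are the
  conjugated arrivals `max(tau) - tau`.

On aberrating phantoms the expected ordering — time reversal recovers
more focal pressure than ray tracing, which beats no correction — is
asserted as a paired-median property over a fixed-seed phantom batch in
the acceptance suite.

# Focal-spot metrics

`half_max_mask()` thresholds a field at half its window peak (ties
included). `largest_component_ellipse()` selects the largest
8-connected component and fits an ellipse by second-order moments
(semi-axes `2 sqrt(eigenvalue)` with the 1/12 single-pixel variance
correction); the tilt is measured from the array normal, negative to
the right, in (-90, 90], and reported as 0 for near-circular
components (axis ratio < 1.05) to stabilize the axial/lateral
projections. Area error and IoU are computed on the rasterized fitted
ellipses by default (raw-mask mode via `use_ellipse = FALSE`); the area
error is the absolute *area difference* over the reference area, not a
symmetric difference. The modified Hausdorff distance runs on the
outer boundary pixels (those with a 4-neighbor outside) of the largest
components. Peak-location ties resolve to the first occurrence in
row-major order. Axial/lateral errors are the focal displacement
rotated into the predicted ellipse's axes; the rotation is an isometry,
which the property tests assert to 1e-9.

# The surrogate network

The surrogate (`tusnet()`) is built from LSTM-Conv cells: four LSTM
chains scan the square input top-down, bottom-up, left-right, and
right-left (hidden size = input size; the orthogonal axis is the
feature axis), their outputs are concatenated into 4 channels and
passed through an 8-channel 3x3 convolution, a 16-channel 3x3
convolution that halves (encoder) or doubles (decoder, nearest
upsampling then convolution) the resolution, and a 1x1 pooling
convolution back to one channel — batch normalization and ReLU after
each convolution, dropout 0.2 after the 16-channel stage. Five cells
encode (grid/32 bottleneck: the *reduced embedding*) and five decode,
with skip connections merging each encoder level into the matching
decoder level by channel concatenation plus a 1x1 convolution. The
normalized field head is a 3x3 linear convolution followed by a
sigmoid: the bounded activation enforces [0, 1] outputs, and the 3x3
extent lets pixels whose single-channel input is zeroed by the final
ReLU borrow from neighbors (a 1x1 head leaves them stuck at a
constant, which caps single-sample overfitting around 2e-3).

The phase decoder passes the *first* encoder cell's output through
three further down-sampling LSTM-Conv cells, flattens, and applies two
fully connected layers with a sigmoid, yielding per-element delays as
period fractions. The absolute-pressure decoder applies a 3x3
convolution and two fully connected layers to the reduced embedding,
scaled to Pa. The absolute field is reconstructed exactly as
normalized field x predicted peak.

Design points the architecture description leaves open, decided here:

* **State hand-off.** Each cell returns its four directional final
  (hidden, cell) states; the next cell resizes them to its width
  (average pooling down, nearest repetition up) and uses them to
  initialize its layer-1 scans. Gradients flow through this pathway —
  numerical gradient checks showed the state path carries most of the
  upstream signal at initialization, so truncating it would cripple
  training.
* **Directional weights** are independent per direction by default;
  `tie_dirs = TRUE` shares them, and then a left-right scan of an
  image equals the flipped right-left scan of the flipped image — the
  contract the tests assert.
* **Scan depth**: 1 stacked LSTM layer by default, 4 supported;
  `transfer_weights()` copies every shape-matching tensor from a
  trained shallow model into a deep one.

## Losses and training

The field loss is a spatially weighted MSE: rows above
`split_row = round(180/512 * grid_n)` (the transducer/skull band)
carry `lambda_skull(t)`, rows below carry `1 - lambda_skull(t)`, with
`lambda_skull(t) = 0.5` for epochs `t < 5` and `0.5^(t-4)` afterwards
(1-based epochs; the shift happens entering epoch 5). The phase and
absolute-pressure losses are plain L1 (the latter on Pa scaled by
1e-6 internally for conditioning). Training is staged: encoder +
field decoder first, then the phase decoder and then the
absolute-pressure decoder with the encoder frozen — immutability is
verified by digesting the encoder weights before and after.
Optimization is Adam with a reduce-on-plateau schedule (factor 0.1,
patience 2, relative threshold 1e-3) and optional early stopping.

The full-scale prescription (learning rate 2e-4, batch 256, ~50
epochs over ~180k samples) implies tens of thousands of optimizer
steps. The desk-scale suites run a few hundred steps, so they use a
proportionally larger learning rate (1e-2), a plateau patience of 4
epochs, and checkpointed early stopping (each stage restores its
best-validation weights); the plateau factor and threshold, the
staging, and the losses are unchanged. Problem sizes used by the
acceptance suite: a 432-sample dataset (72 skulls x 6 lattice
targets) on a 32 x 32 window with a per-skull 80/20
train/validation split and 25/10/8 epochs for the three stages; the
single-sample capacity check uses the same 32 x 32 window. The
training lattice keeps the full-scale target-box extent (about
22 x 26 mm) at a doubled pitch: target diversity, not lattice
density, is what allows generalization across unseen skulls.

## What the synthetic conditions do and do not show

The phantom family emulates the geometry and heterogeneity scale of
calvarial bone but not CT imaging physics (no beam hardening, streaks,
partial-volume effects), not real trabecular microarchitecture, and
not frontal/occipital or 3D geometry. Fields are linear, lossy-fluid,
2D simulations. Passing suites therefore demonstrate that the
pipeline's mechanics — solver properties, correction ordering, metric
definitions, surrogate trainability — are correct at desk scale; they
do not certify clinical accuracy on real skulls, which in the original
setting required orders of magnitude more data and compute.

# Reproducibility

Every stochastic step takes a seed; datasets rebuild byte-identically
from (phantom seeds, split seed, solver config). `scripts/acceptance.R`
recomputes the package's verifiable configuration arithmetic and a
water-focusing positioning check from a fresh session, writing plain
JSON.
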