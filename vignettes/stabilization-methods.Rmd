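---
title: "Fiduciary-free stabilization of time-lapse microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiduciary-free stabilization of time-lapse microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multi-sample time-lapse microscopes image many wells with one objective by
repositioning a motorized stage between every acquisition. Without physical
fiduciary markers (lock plates) and instrument feedback, each return to a
well misses the previous field of view by a random lateral offset: the
recorded stack carries frame-to-frame jitter of up to ~100 px superimposed
on a slow directional drift. Any downstream quantification of cell motility
is meaningless until that stage motion is removed — and the removal must
not be confused by the cells themselves, which move and change shape
independently of the stage.

stackstab corrects this in software. The model is deliberately restricted
to pure lateral translation: on the instruments this method targets, the
stage error has no measurable rotation or shear component, and fitting a
richer transform to data that does not contain one injects spurious
off-axis terms instead of reducing error. Rotation, scaling, shear, and
nonlinear (holomorphic) distortion are out of scope by design, as is focus
(z) drift, which instruments prevent by refocusing before each exposure.

## The estimator: a robust reduction of apparent motion

For frames $I(t)$ and $I(t+1)$ the package estimates one global
translation $\Delta(t) = (\delta_x, \delta_y)$ per frame pair, by one of
two routes.

**Median of a dense flow field.** A dense optical-flow backend produces a
per-pixel displacement field $A \in \mathbb{R}^{H\times W\times 2}$.
Pixels belonging to cells move with the cells; pixels belonging to the
static background move with the stage. As long as the cell footprint stays
below half the field of view, the marginal median of each flow component
is determined by the background population: the median has a 50%
breakdown point, so the estimate ignores the group motion of sparse
objects entirely. The component-wise median is the package default
reducer. A histogram-mode reducer is also provided (bin width 0.1 px by
default, first bin wins ties); for symmetric unimodal displacement
histograms median and mode agree to within a bin, but real displacement
histograms often have flat tops, which the median summarizes more stably.
The arithmetic mean, by contrast, is linearly dragged by any coherent cell
motion — the scene generator's `cell_drift` parameter exists to
demonstrate exactly this failure, and the test suite asserts it.

**Phase cross-correlation (PCC).** The normalized cross-power spectrum
$R(f) = \frac{F_1 \overline{F_2}}{|F_1 \overline{F_2}|}$ has a linear
phase whose slope is the translation; its inverse transform peaks at the
(wrapped, negated) shift. The peak is refined to resolution
$1/\kappa$ with a matrix-multiply DFT evaluated on a small window around
the integer peak upsampled by the factor $\kappa$, so no full-size
upsampled transform is ever formed.

Two numerical choices matter here:

* *Spectral floor.* Textbook phase normalization weights every frequency
  bin equally, including bins that carry essentially no signal. For
  band-limited images (smooth textures, interpolated frames) those empty
  bins contribute pure phase noise, and for bilinearly interpolated input
  the high-frequency phase is additionally distorted by the interpolation
  kernel. `pcc_shift()` therefore normalizes by $|R| + \lambda$ with
  $\lambda = 0.2 \cdot \mathrm{mean}|R|$. The floor leaves cyclic
  (wrap-around) shifts exact to machine precision while weighting the
  correlation toward bins that actually carry energy; on bilinearly warped
  textures it reduces the estimation error by roughly an order of
  magnitude. Setting `spectral_floor = 0` restores the textbook
  normalization.
* *Mean subtraction.* Both frames are centred before the FFT, which
  removes the DC term and with it the largest single leakage source from
  non-periodic borders.

Default $\kappa = 81$: the estimation error of the upsampled refinement
stops fluctuating and sits on its quantization floor around this factor,
and larger factors only grow the refinement window ($\lceil 1.5\kappa
\rceil$ per side) without measurable benefit.

**Dense Lucas–Kanade.** The flow backend solves, at every pixel, the
windowed least-squares system built from image gradients: with structure
tensor $G = \sum_W \nabla I \nabla I^\top$ and mismatch vector $b = -
\sum_W \nabla I \, I_t$ accumulated over a uniform square window of
radius $r$ (side $2r+1$), the flow is $d = G^{-1} b$. The window sums are
computed with summed-area tables, so the cost is independent of the
radius. Pixels with a rank-deficient structure tensor (determinant below
$10^{-12}$) keep zero flow, which is neutral under the median when such
pixels are sparse. Default radius 23, the dispersion minimum of the
radius sweep on this method's benchmarks; the error surface is flat for
larger radii, so the exact value is uncritical.

One linearized solve is only valid for displacements within the texture
correlation length. `lk_dense_flow()` therefore iterates the solve in
Gauss–Newton fashion (default 5 iterations): warp the moving frame by the
current field with per-pixel bilinear sampling, re-linearize, accumulate.
This is the original iterative formulation of the method, kept
single-level (no pyramid); it converges for the displacement range the
jitter model produces. The gradient is taken on the average of the
reference and the warped moving frame, which symmetrizes the estimate and
roughly halves the sub-pixel bias of the one-sided form.

**Deep flow plug-in.** A third backend slot accepts a user-registered
dense-flow function (`register_deep_flow()`), intended for pretrained
recurrent flow models. The package ships no weights and makes no network
access; without a registered plug-in the backend raises a capability
error that names the built-in alternatives. The registry keeps the
package's tests and benchmarks fully self-contained while letting users
slot in a stronger flow model where one is available.

All backends share one convention, asserted by a common test: x runs
along columns (rightward), y along rows (downward), and the returned
$(dx, dy)$ is the motion of the second frame relative to the first, so
translating the second frame by $(-dx, -dy)$ aligns it.

Reduced precision: `precision = "float16"` quantizes the input
intensities to half-precision resolution (10-bit mantissa) before
estimation, emulating inference on hardware that stores images in half
floats; all accumulation stays in double precision. The backends agree
with their full-precision results to well under 0.1 px.

## From pairs to a corrected stack

`estimate_nn_series()` applies the pair estimator to each adjacent pair;
`accumulate()` forms the drift trajectory $s(t) = \sum_{u<t} \Delta(u)$
as an exact prefix sum anchored at $s(1) = (0,0)$. Frame $t$ is then
corrected by the single composed translation $-s(t)$ — never by $t$
sequential warps, so bilinear interpolation blur enters exactly once per
frame regardless of stack length.

Because corrected frames occupy shifted footprints, a framing policy
chooses the common canvas:

* **maximum** — union bounding box; every input pixel of every frame is
  preserved; unobserved pixels are filled.
* **minimum** — intersection box; no fill pixel ever appears; an empty
  intersection raises a degenerate-framing error reporting the deficit.
* **center** — input-sized box centred on the arithmetic mean of the
  corrected frame positions. (The anchor could equally be the median
  position; the mean was fixed here as the simpler convention.)
* **reference** — the footprint of one designated frame.

Fractional canvas bounds are expanded outward (floor/ceil) in maximum
mode and inward in minimum mode, so the no-clipping and no-fill
guarantees hold exactly; the closed-form dimension formulas are asserted
over random trajectories in the test suite. Fill intensity defaults to
the per-frame median brightness — per frame, not per stack, so a frame
with drifting illumination is padded with its own brightness level.

## The jitter model (ground truth)

Real multi-well stages show a beat-patterned periodic jitter. The
synthesizer reproduces it as a per-step displacement, per axis,

$$\delta(t) = A(t)\,\cos(\omega_1 t)\cos(\omega_2 t), \qquad
A(t) \sim \mathcal{U}[0, A_{\max}]^2,$$

with defaults $\omega_1 = 0.5$, $\omega_2 = 1.2$ rad/frame and $A_{\max}
= 120$ px — the regime of a stage without positional feedback, whose
primary jitter amplitude is on the order of 100 px with a slower
secondary modulation. The amplitude is redrawn uniformly per step and
axis; the uniform box is the minimal reading of an unspecified "random
vector" bound. The product-of-cosines form is read as an additive
per-step displacement (a pure translation independent of position):
the recursive position update is a translation, and observed stage traces
are bounded, which a position-proportional scaling would violate.
`apply_jitter()` renders the cumulative displacement with one bilinear
warp per frame on a canvas enlarged by an explicit margin, so the ground
truth is never destroyed at the borders; an insufficient margin is a
validation error that names the required value.

## The synthetic scene

`generate_scene()` emulates the relevant features of a bright-field well:

* a static background texture with tunable correlation length
  (`background_grain`, default 2 px), synthesized in the frequency domain
  so it is *periodic* — integer cyclic shifts of a scene frame are exact
  translations, which supplies oracles with zero modelling error;
* sparse soft-edged blobs with a dark rim and lighter core, *weakly
  modulated* relative to the background — the contrast regime of
  bright-field cell bodies on a structured substrate;
* per-blob seeded random walks (reflected at borders), optional common
  drift (`cell_drift`) for adversarial coherent motion, and a
  multiplicative radius perturbation per frame (`morph_rate`) standing in
  for morphological change;
* optional per-frame additive Gaussian noise.

The generator reports the exact blob footprint fraction from the
rendered masks and refuses to build scenes above 50% footprint, where the
median's breakdown point would be violated by construction.

What the scene does *not* model: illumination drift, photobleaching,
focus changes, cell division/death, or realistic cell morphology. Tests
passing on these scenes therefore demonstrate the estimator's behaviour
under controlled translation, contamination, and scene evolution — not
performance on any particular instrument's data.

## Evaluation design

`offset_errors()`, `dispersion_summary()` (median, quartiles, maximum —
absolute per-axis errors), `coherence_curve()` and `parameter_sweep()`
reproduce the method's standard diagnostics at desk scale. Two design
points deserve a note:

* *All-pairs matrices* are estimated independently in both orders
  $(i,j)$ and $(j,i)$, because the asymmetry $d_{ij} + d_{ji}$ is itself
  a diagnostic: PCC is anti-symmetric by construction up to the sub-pixel
  grid (bounded by $2/\kappa$), while learned flow backends need not be.
* *Coherence versus frame distance* is meaningful in the regime where the
  scene evolves slowly relative to the observation: blob displacement
  over the longest lag should stay within about one blob radius, with
  morphological change accumulating monotonically. In that regime the
  flow-based error grows with temporal distance. Outside it the premise
  inverts for correlation-based estimators: once the blob configuration
  fully decorrelates, a background-locked estimator gets *cleaner* with
  distance, not worse. The package's benchmark therefore uses the
  flow backend on slow scenes and averages the curve over three scene
  replicates to stabilize the sparse long-lag estimates.

Benchmark problem sizes were chosen to exercise every mechanism at
desk scale: 64–160 px frames for the single-pair oracles, a 50-frame
256×256 stack for the end-to-end round trip, 10–12 frame stacks for the
all-pairs analyses.

## Degenerate inputs and tie-breaks

* Constant (zero-variance) frames have no definable translation: PCC
  raises a degenerate-input error rather than returning the spurious peak
  of a flat spectrum.
* Structure-tensor singularities in the flow backend yield zero vectors,
  not errors; they only matter if they stop being sparse, which the
  scene generator's grain default prevents.
* The mode reducer resolves ties toward the lowest bin; the median of an
  even count is the usual midpoint.
* Intensities are clipped to $[0,1]$ after warping, and normalization on
  load divides by the dtype's theoretical maximum (255, 65535) — not the
  observed maximum — so brightness drift across frames is preserved for
  the brightness-sensitive flow estimator.

## Known limitations

* Translation-only: any true rotation or shear in the input is not
  corrected and will leak into the residual.
* The corrected stack is for visual inspection and stack-level analysis;
  sub-pixel interpolation slightly smooths each frame, and per-cell
  tracking should run on coordinates corrected with the exported
  trajectory rather than on re-interpolated pixels.
* Correction quality inherits the nearest-neighbour chain: per-step
  errors random-walk into the trajectory. The all-pairs tools quantify
  this; the package deliberately does not bundle-adjust over the pairwise
  matrix, correcting from the NN chain only.
* Video containers are not decoded; convert recordings to multi-page
  TIFF or an image sequence first.
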