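# stackstab

Fiduciary-free stabilization of time-lapse microscopy stacks.

Multi-sample time-lapse microscopes (one objective serially scanning many
wells) reposition the stage before every frame. Without fiduciary markers
and hardware feedback, each frame of a well lands a random lateral offset
away from the last one: the stack jitters and drifts, and any cell
motility measured on it is an artifact of the stage. stackstab removes
this motion in software, for people who have such stacks (multi-page
TIFF or image sequences) and need them registered to sub-pixel accuracy
before quantifying what the cells themselves do.

## Method

For each adjacent frame pair the global translation Δ(t) is estimated by
one of two backends:

- **Median of dense optical flow** — a dense Lucas–Kanade field
  A ∈ ℝ^(H×W×2) is computed by windowed least squares over image
  gradients (Gauss–Newton refined, window radius 23 by default), then
  collapsed to one vector by the component-wise **median**. Cells move
  independently of the stage, but as long as their footprint is sparse
  the median of the field is determined by the background and reports
  pure stage motion (50% breakdown point; the mean has none and is
  dragged by any coherent cell drift).
- **Phase cross-correlation** — the normalized cross-power spectrum
  F₁·conj(F₂)/(|F₁·conj(F₂)| + λ) is inverted and its peak refined on an
  upsampled DFT grid (factor 81 by default, i.e. ~0.012 px resolution).

The per-step estimates are accumulated into a drift trajectory
s(t) = Σ Δ, each frame is corrected by the single composed translation
−s(t) (bilinear, one interpolation per frame), and the corrected frames
are re-rendered under a framing policy: **maximum** (union canvas, keeps
every pixel), **minimum** (intersection, never shows fill), **center**,
or **reference** framing, with unobserved pixels filled by the per-frame
median brightness.

Ground truth for benchmarking comes from a parametric stage-jitter model
— per-step displacement δ(t) = A(t)·cos(ω₁t)·cos(ω₂t), A(t) ~ U[0,
A_max]² with ω₁ = 0.5, ω₂ = 1.2 rad/frame — and a synthetic scene
generator (textured background plus sparse motile, morphing blobs) so
every mechanism is testable without any data download.

## Worked example

Shake a known synthetic scene with the jitter model, stabilize it, and
compare against the ground truth:

```r
library(stackstab)

scene  <- generate_scene(20, 256, 256, scene_params(n_cells = 10, seed = 42))
truth  <- synthesize_displacements(20, jitter_params(amplitude_max = 15, seed = 43))
shaken <- apply_jitter(scene$stack, truth, canvas_margin = 30)

res <- stabilize(shaken$stack, backend_config("pcc"), framing_spec("maximum"))
res$stack
#> <frame_stack> 20 frames of 339 x 330 px, intensities [0.132, 0.795]
#>   source: synthetic scene (seed 42) | jittered | reframed (maximum)

dispersion_summary(offset_errors(res$series, truth))
#>   axis  n median     q1    q3   max
#> x    x 19  0.159 0.0912 0.205 0.289
#> y    y 19  0.190 0.0861 0.214 0.384

sqrt(mean((unclass(res$trajectory) - unclass(accumulate(truth)))^2))
#> [1] 0.143
```

The per-step estimation error has a median below 0.2 px on both axes and
the recovered cumulative trajectory matches the injected drift with an
RMSE of 0.14 px — the corrected stack is registered to a small fraction
of a pixel despite jitter steps of up to 15 px. The maximum-framing
canvas (339 × 330) is the union of all corrected footprints, so no
content was cropped. `export_trajectory()` writes the per-step and
cumulative displacements as CSV for downstream coordinate correction.

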