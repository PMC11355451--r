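#' Parametric stage-jitter model
#'
#' Parameters of the synthetic stage-jitter generator used for ground
#' truth benchmarking. The per-step lateral displacement of the stage is
#' modelled as a beat-modulated oscillation,
#' `delta(t) = A(t) * cos(omega1 * t) * cos(omega2 * t)` per axis, with
#' the amplitude `A(t)` redrawn uniformly in `[0, amplitude_max]` per
#' axis and step. The defaults `omega1 = 0.5`, `omega2 = 1.2` and
#' `amplitude_max = 120` reproduce the periodic jitter with primary
#' amplitude around 100 px and a slower secondary modulation seen on
#' multi-sample stages without positional feedback.
#'
#' @param omega1,omega2 angular frequencies, radians per frame.
#' @param amplitude_max upper bound of the uniform amplitude draw, pixels.
#' @param seed integer seed for the amplitude draw (`NULL` leaves the
#'   global RNG in charge).
#' @export
jitter_params <- function(omega1 = 0.5, omega2 = 1.2, amplitude_max = 120,
                          seed = NULL) {
  stopifnot_scalar_number(omega1, "omega1")
  stopifnot_scalar_number(omega2, "omega2")
  stopifnot_scalar_number(amplitude_max, "amplitude_max")
  if (amplitude_max < 0) abort_validation("`amplitude_max` must be >= 0")
  structure(list(omega1 = omega1, omega2 = omega2,
                 amplitude_max = amplitude_max, seed = seed),
            class = "jitter_params")
}

#' Synthesize a ground-truth displacement series
#'
#' Draws the per-step stage displacements `delta(t) = A(t) cos(omega1 t)
#' cos(omega2 t)` for `t = 0 ... T-2`, each axis independently, from the
#' seeded generator. Deterministic given the seed; `|delta| <=
#' amplitude_max` always.
#'
#' @param n_frames number of frames `T >= 2`; the series has `T - 1` steps.
#' @param params a [jitter_params].
#' @return a [translation_series].
#' @examples
#' synthesize_displacements(5, jitter_params(amplitude_max = 10, seed = 1))
#' @export
synthesize_displacements <- function(n_frames, params = jitter_params()) {
  if (n_frames < 2) abort_validation("`n_frames` must be >= 2")
  n <- n_frames - 1L
  t <- seq_len(n) - 1
  A <- with_seed(params$seed,
                 matrix(stats::runif(2L * n, 0, params$amplitude_max), n, 2L))
  env <- cos(params$omega1 * t) * cos(params$omega2 * t)
  translation_series(A * env)
}

#' Displace a stable stack with a known jitter series
#'
#' Applies the cumulative sum of the per-step series to each frame (frame
#' 1 is untouched) with a single bilinear translation per frame, placing
#' all frames on a canvas enlarged by `canvas_margin` pixels on every
#' side so the displaced content is never clipped. Unobserved canvas
#' pixels take the per-frame median brightness. The returned series is
#' the exact ground truth for round-trip benchmarks.
#'
#' @param stack a stable [frame_stack].
#' @param series a [translation_series] of length `T - 1`.
#' @param canvas_margin margin in pixels; must cover the maximum absolute
#'   cumulative displacement.
#' @return `list(stack, series)`: the jittered stack and the ground truth.
#' @export
apply_jitter <- function(stack, series, canvas_margin) {
  if (!inherits(stack, "frame_stack"))
    abort_validation("`stack` must be a frame_stack")
  series <- as_translation_series(series)
  T <- n_frames(stack)
  if (nrow(series) != T - 1L)
    abort_validation(sprintf("series has %d steps for %d frames",
                             nrow(series), T))
  m <- as.integer(canvas_margin)
  s <- accumulate(series)
  need <- ceiling(max(abs(s)))
  if (need > m)
    abort_validation(sprintf(
      "cumulative displacement reaches %d px; canvas_margin must be >= %d",
      need, need))
  h <- frame_shape(stack)[1]; w <- frame_shape(stack)[2]
  out <- array(0, c(h + 2L * m, w + 2L * m, T))
  for (t in seq_len(T)) {
    f <- stack$frames[, , t]
    out[, , t] <- translate_frame(f, s[t, 1] + m, s[t, 2] + m,
                                  c(h + 2L * m, w + 2L * m),
                                  fill = stats::median(f))
  }
  out <- pmin(pmax(out, 0), 1)
  list(stack = frame_stack(out, frame_interval = stack$frame_interval,
                           pixel_size = stack$pixel_size,
                           source = paste0(stack$source, " | jittered")),
       series = series)
}
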