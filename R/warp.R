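#' Framing policy for corrected stacks
#'
#' After drift correction each frame occupies a shifted footprint; a
#' framing policy decides the common output canvas. `maximum` takes the
#' union bounding box of all footprints (no content is lost, fill appears
#' where a frame does not reach); `minimum` the intersection (no fill ever
#' appears, borders are cropped); `center` keeps the input size centred on
#' the mean corrected position; `reference` keeps the footprint of one
#' chosen frame. Fill intensity is either the per-frame median brightness
#' or a constant.
#'
#' @param mode one of `"maximum"`, `"minimum"`, `"center"`, `"reference"`.
#' @param reference_index 1-based frame index (reference mode).
#' @param fill `"median_brightness"` or `"constant"`.
#' @param fill_value intensity used when `fill = "constant"`.
#' @export
framing_spec <- function(mode = c("maximum", "minimum", "center", "reference"),
                         reference_index = 1L,
                         fill = c("median_brightness", "constant"),
                         fill_value = 0) {
  mode <- match.arg(mode)
  fill <- match.arg(fill)
  if (reference_index < 1) abort_validation("`reference_index` must be >= 1")
  stopifnot_scalar_number(fill_value, "fill_value")
  structure(list(mode = mode, reference_index = as.integer(reference_index),
                 fill = fill, fill_value = fill_value),
            class = "framing_spec")
}

#' Sub-pixel translation of a single frame
#'
#' Produces an output frame of shape `out_shape` whose pixel at position
#' `p` is the bilinear interpolation of the input at `p - (dx, dy)`:
#' content moves by `+(dx, dy)` (x rightward along columns, y downward
#' along rows). Positions that fall outside the input take the `fill`
#' intensity. Integer shifts reproduce the input exactly on the overlap
#' region.
#'
#' @param frame 2-D numeric matrix.
#' @param dx,dy translation in pixels.
#' @param out_shape `c(height, width)` of the output.
#' @param fill intensity for unobserved output pixels.
#' @return a matrix of shape `out_shape`.
#' @export
translate_frame <- function(frame, dx, dy, out_shape = dim(frame), fill = 0) {
  if (!is.matrix(frame)) abort_validation("`frame` must be a matrix")
  stopifnot_scalar_number(dx, "dx")
  stopifnot_scalar_number(dy, "dy")
  ho <- as.integer(out_shape[1]); wo <- as.integer(out_shape[2])
  Y <- matrix(seq_len(ho) - dy, ho, wo)
  X <- matrix(seq_len(wo) - dx, ho, wo, byrow = TRUE)
  fb <- matrix(fill, ho, wo)
  bilinear_sample(frame, Y, X, fb)
}

#' Output canvas for a correction trajectory
#'
#' Given the estimated cumulative drift of each frame (the correction
#' applied to frame `t` is its negation) and the input frame shape,
#' computes the canvas dimensions and the per-frame translation that
#' places each corrected frame on the canvas. Fractional bounds are
#' expanded outward (maximum mode) or inward (minimum mode) so that no
#' valid pixel is clipped and, respectively, no fill pixel survives.
#'
#' Closed forms, with `c(t)` the per-frame correction:
#' maximum height `H + ceil(max cy) - floor(min cy)` (width analogous);
#' minimum height `H - (ceil(max cy) - floor(min cy))`;
#' center and reference keep `H x W`.
#'
#' @param trajectory a [correction_trajectory] (cumulative drift, pixels).
#' @param frame_shape `c(H, W)` of the input frames.
#' @param spec a [framing_spec].
#' @return a `canvas` list: `height`, `width`, `origin` (x, y of the
#'   canvas in corrected coordinates) and `offsets`, the `T x 2` matrix of
#'   translations to apply when rendering each frame.
#' @export
compute_canvas <- function(trajectory, frame_shape, spec = framing_spec()) {
  trajectory <- as_correction_trajectory(trajectory)
  if (!inherits(spec, "framing_spec"))
    abort_validation("`spec` must be a framing_spec")
  h <- as.integer(frame_shape[1]); w <- as.integer(frame_shape[2])
  corr <- -trajectory                # correction = negated drift
  cx <- corr[, 1]; cy <- corr[, 2]
  T <- nrow(corr)
  if (spec$mode == "reference" && spec$reference_index > T)
    abort_validation(sprintf("reference_index %d exceeds %d frames",
                             spec$reference_index, T))
  dims_origin <- switch(
    spec$mode,
    maximum = {
      ox <- floor(min(cx)); oy <- floor(min(cy))
      list(h = h + ceiling(max(cy)) - oy, w = w + ceiling(max(cx)) - ox,
           origin = c(ox, oy))
    },
    minimum = {
      wc <- w + floor(min(cx)) - ceiling(max(cx))
      hc <- h + floor(min(cy)) - ceiling(max(cy))
      if (wc < 1 || hc < 1)
        abort_degenerate(sprintf(
          "empty intersection in minimum framing: overlap deficit %d x %d px",
          max(0, 1 - hc), max(0, 1 - wc)))
      list(h = hc, w = wc, origin = c(ceiling(max(cx)), ceiling(max(cy))))
    },
    center = list(h = h, w = w, origin = c(mean(cx), mean(cy))),
    reference = list(h = h, w = w,
                     origin = c(cx[spec$reference_index],
                                cy[spec$reference_index])))
  offsets <- cbind(dx = cx - dims_origin$origin[1],
                   dy = cy - dims_origin$origin[2])
  structure(list(height = as.integer(dims_origin$h),
                 width = as.integer(dims_origin$w),
                 origin = dims_origin$origin, offsets = offsets),
            class = "canvas")
}

#' Re-render a stack on a common corrected canvas
#'
#' Applies the (negated) correction trajectory to every frame and places
#' the results on the canvas chosen by the framing policy. Unobserved
#' canvas pixels take the per-frame median brightness (or the configured
#' constant); in maximum mode every input pixel of every frame is
#' conserved on the canvas.
#'
#' @param stack a [frame_stack].
#' @param trajectory a [correction_trajectory]; the correction applied to
#'   frame `t` is `-trajectory[t, ]`.
#' @param spec a [framing_spec].
#' @return a [frame_stack] on the new canvas.
#' @export
reframe <- function(stack, trajectory, spec = framing_spec()) {
  if (!inherits(stack, "frame_stack"))
    abort_validation("`stack` must be a frame_stack")
  trajectory <- as_correction_trajectory(trajectory)
  T <- n_frames(stack)
  if (nrow(trajectory) != T)
    abort_validation(sprintf("trajectory has %d rows for %d frames",
                             nrow(trajectory), T))
  cv <- compute_canvas(trajectory, frame_shape(stack), spec)
  out <- array(0, c(cv$height, cv$width, T))
  for (t in seq_len(T)) {
    f <- stack$frames[, , t]
    fill <- if (spec$fill == "median_brightness") stats::median(f) else spec$fill_value
    out[, , t] <- translate_frame(f, cv$offsets[t, 1], cv$offsets[t, 2],
                                  c(cv$height, cv$width), fill)
  }
  out <- pmin(pmax(out, 0), 1)
  frame_stack(out, frame_interval = stack$frame_interval,
              pixel_size = stack$pixel_size,
              source = sprintf("%s | reframed (%s)", stack$source, spec$mode))
}
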