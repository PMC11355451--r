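#' Time-lapse frame stack
#'
#' A `frame_stack` is the package's core container: an ordered sequence of
#' 2-D grayscale frames with a common shape, stored as an `H x W x T` array
#' of intensities in `[0, 1]`. Optional acquisition metadata (minutes per
#' frame, micrometres per pixel) is carried along but never interpreted by
#' the registration core.
#'
#' @param frames an `H x W x T` numeric array, a list of `H x W` matrices,
#'   or a single matrix (promoted to `T = 1`; at least two frames are
#'   required for a valid stack).
#' @param frame_interval optional minutes between consecutive frames.
#' @param pixel_size optional micrometres per pixel.
#' @param source provenance string (file path or generator description).
#' @return an object of class `frame_stack` with elements `frames`,
#'   `frame_interval`, `pixel_size`, `source`.
#' @examples
#' fs <- frame_stack(array(runif(32 * 32 * 3), c(32, 32, 3)))
#' n_frames(fs)
#' @export
frame_stack <- function(frames, frame_interval = NULL, pixel_size = NULL,
                        source = "memory") {
  if (is.list(frames)) {
    if (length(frames) == 0L) abort_validation("empty frame list")
    dims <- vapply(frames, dim, integer(2))
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
    if (length(bad))
      abort_validation(sprintf(
        "frames with mismatched shape at indices: %s",
        paste(bad, collapse = ", ")))
    frames <- array(unlist(frames, use.names = FALSE),
                    c(dims[1, 1], dims[2, 1], length(frames)))
  }
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    abort_validation("`frames` must be an H x W x T array or list of matrices")
  if (dim(frames)[3] < 2L)
    abort_validation("a frame stack needs at least 2 frames")
  if (!all(is.finite(frames)))
    abort_validation("frame intensities must all be finite")
  if (min(frames) < 0 || max(frames) > 1)
    abort_validation("frame intensities must lie in [0, 1]")
  structure(
    list(frames = frames, frame_interval = frame_interval,
         pixel_size = pixel_size, source = source),
    class = "frame_stack")
}

#' @rdname frame_stack
#' @param x,stack a `frame_stack`.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' @rdname frame_stack
#' @export
frame_shape <- function(stack) dim(stack$frames)[1:2]

#' @rdname frame_stack
#' @param t frame index in `1:T`.
#' @export
get_frame <- function(stack, t) {
  T <- n_frames(stack)
  if (t < 1 || t > T) abort_validation(sprintf("frame index %d not in 1..%d", t, T))
  stack$frames[, , t]
}

#' @rdname frame_stack
#' @param ... ignored.
#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d px, intensities [%.3f, %.3f]\n",
              d[3], d[1], d[2], min(x$frames), max(x$frames)))
  if (!is.null(x$frame_interval))
    cat(sprintf("  frame interval: %g min\n", x$frame_interval))
  if (!is.null(x$pixel_size))
    cat(sprintf("  pixel size: %g um\n", x$pixel_size))
  cat(sprintf("  source: %s\n", x$source))
  invisible(x)
}
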