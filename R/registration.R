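#' Per-step and cumulative displacement containers
#'
#' A `translation_series` holds the `(T-1) x 2` per-step displacements
#' `steps[t, ] = (dx, dy)` of frame `t + 1` relative to frame `t`. A
#' `correction_trajectory` holds the `T x 2` cumulative displacement per
#' frame, anchored at `(0, 0)` for frame 1; differencing it recovers the
#' series exactly.
#'
#' @param steps numeric `(T-1) x 2` matrix.
#' @export
translation_series <- function(steps) {
  steps <- as.matrix(steps)
  if (ncol(steps) != 2L || nrow(steps) < 1L)
    abort_validation("`steps` must be a (T-1) x 2 matrix with T >= 2")
  if (!all(is.finite(steps))) abort_validation("steps must be finite")
  colnames(steps) <- c("dx", "dy")
  structure(steps, class = c("translation_series", "matrix", "array"))
}

as_translation_series <- function(x) {
  if (inherits(x, "translation_series")) x else translation_series(x)
}

#' @rdname translation_series
#' @param cumulative numeric `T x 2` matrix with first row `(0, 0)`.
#' @export
correction_trajectory <- function(cumulative) {
  cumulative <- as.matrix(cumulative)
  if (ncol(cumulative) != 2L || nrow(cumulative) < 2L)
    abort_validation("`cumulative` must be a T x 2 matrix with T >= 2")
  if (!all(is.finite(cumulative))) abort_validation("trajectory must be finite")
  if (any(cumulative[1, ] != 0))
    abort_validation("trajectory must start at (0, 0)")
  colnames(cumulative) <- c("dx", "dy")
  structure(cumulative, class = c("correction_trajectory", "matrix", "array"))
}

as_correction_trajectory <- function(x) {
  if (inherits(x, "correction_trajectory")) x else correction_trajectory(x)
}

#' Accumulate per-step displacements into a drift trajectory
#'
#' Prefix sum with a leading `(0, 0)` row: `cumulative[t] =
#' sum(steps[1..t-1])`, in exact floating-point arithmetic (no rounding).
#'
#' @param series a [translation_series].
#' @return a [correction_trajectory] of length `T`.
#' @examples
#' accumulate(translation_series(rbind(c(1, 0), c(2, 0))))
#' @export
accumulate <- function(series) {
  series <- as_translation_series(series)
  correction_trajectory(rbind(c(0, 0),
                              apply(unclass(series), 2, cumsum)))
}

#' Nearest-neighbour displacement series of a stack
#'
#' Runs the configured backend on every pair of temporally adjacent
#' frames: `steps[t, ] = estimate_pair(frames[t], frames[t+1], config)`.
#'
#' @param stack a [frame_stack].
#' @param config a [backend_config].
#' @return a [translation_series] of length `T - 1`.
#' @export
estimate_nn_series <- function(stack, config = backend_config()) {
  if (!inherits(stack, "frame_stack"))
    abort_validation("`stack` must be a frame_stack")
  T <- n_frames(stack)
  steps <- matrix(0, T - 1L, 2L)
  for (t in seq_len(T - 1L)) {
    steps[t, ] <- tryCatch(
      estimate_pair(stack$frames[, , t], stack$frames[, , t + 1L], config),
      error = function(e) {
        if (inherits(e, "stackstab_capability_error")) stop(e)
        abort(sprintf("backend failed on frame pair (%d, %d): %s",
                      t, t + 1L, conditionMessage(e)),
              "stackstab_backend_error")
      })
  }
  translation_series(steps)
}

#' All-pairs displacement matrix
#'
#' Estimates the displacement of frame `j` relative to frame `i` for
#' every ordered off-diagonal pair, independently in both orders (needed
#' for the commutativity diagnostic). The diagonal is `(0, 0)` by
#' construction. For long stacks a pair budget evaluates a deterministic
#' stride subsample of the ordered pairs and leaves the rest `NA`.
#'
#' @param stack a [frame_stack].
#' @param config a [backend_config].
#' @param max_pairs optional cap on the number of ordered pairs evaluated.
#' @return a `pairwise_matrix`: `T x T x 2` array, `[i, j, ]` the
#'   `(dx, dy)` of frame `j` relative to frame `i`.
#' @export
estimate_pairwise_matrix <- function(stack, config = backend_config(),
                                     max_pairs = NULL) {
  if (!inherits(stack, "frame_stack"))
    abort_validation("`stack` must be a frame_stack")
  T <- n_frames(stack)
  pairs <- which(outer(seq_len(T), seq_len(T), "!="), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  if (!is.null(max_pairs) && nrow(pairs) > max_pairs) {
    keep <- unique(round(seq(1, nrow(pairs), length.out = max_pairs)))
    pairs <- pairs[keep, , drop = FALSE]
  }
  dmat <- array(NA_real_, c(T, T, 2L))
  for (t in seq_len(T)) dmat[t, t, ] <- c(0, 0)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    dmat[i, j, ] <- tryCatch(
      estimate_pair(stack$frames[, , i], stack$frames[, , j], config),
      error = function(e) {
        if (inherits(e, "stackstab_capability_error")) stop(e)
        abort(sprintf("backend failed on frame pair (%d, %d): %s", i, j,
                      conditionMessage(e)), "stackstab_backend_error")
      })
  }
  structure(dmat, class = c("pairwise_matrix", "array"))
}

#' Stabilize a time-lapse stack
#'
#' The full correction pipeline: estimate the nearest-neighbour
#' displacement series, accumulate it into the drift trajectory, translate
#' every frame by the negated cumulative displacement (one composed
#' translation per frame, so interpolation blur is applied exactly once),
#' and re-render on the canvas chosen by the framing policy.
#'
#' @param stack a [frame_stack].
#' @param config a [backend_config].
#' @param framing a [framing_spec].
#' @return `list(stack, series, trajectory)`: the corrected stack plus the
#'   estimates used to produce it.
#' @examples
#' \donttest{
#' sc <- generate_scene(6, 96, 96, scene_params(n_cells = 3, seed = 1))
#' jit <- synthesize_displacements(6, jitter_params(amplitude_max = 4, seed = 2))
#' shaken <- apply_jitter(sc$stack, jit, canvas_margin = 12)
#' fixed <- stabilize(shaken$stack, backend_config("pcc"))
#' max(abs(fixed$trajectory - accumulate(jit)))
#' }
#' @export
stabilize <- function(stack, config = backend_config(),
                      framing = framing_spec()) {
  series <- estimate_nn_series(stack, config)
  trajectory <- accumulate(series)
  corrected <- reframe(stack, trajectory, framing)
  list(stack = corrected, series = series, trajectory = trajectory)
}
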