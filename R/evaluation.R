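#' Ground-truth pairwise displacement matrix
#'
#' For a known drift trajectory `s`, the true displacement of frame `j`
#' relative to frame `i` is `s[j] - s[i]`; this expands a trajectory into
#' the corresponding all-pairs matrix for error analysis.
#'
#' @param trajectory a [correction_trajectory].
#' @return a `pairwise_matrix`.
#' @export
pairwise_truth <- function(trajectory) {
  trajectory <- as_correction_trajectory(trajectory)
  T <- nrow(trajectory)
  dmat <- array(0, c(T, T, 2L))
  for (a in 1:2)
    dmat[, , a] <- outer(trajectory[, a], trajectory[, a],
                         function(si, sj) sj - si)
  structure(dmat, class = c("pairwise_matrix", "array"))
}

#' Signed and absolute estimation errors
#'
#' Per-entry differences between an estimate and its ground truth, per
#' axis, in long format. Accepts matching [translation_series] pairs or
#' matching `pairwise_matrix` pairs (a trajectory given as pairwise truth
#' is expanded with [pairwise_truth()]); unevaluated (`NA`) pairs are
#' dropped.
#'
#' @param estimated,truth objects of the same kind.
#' @return a data frame with index columns (`t`, or `i` and `j`), `axis`
#'   (`"x"`/`"y"`), `error`, `abs_error`.
#' @export
offset_errors <- function(estimated, truth) {
  if (inherits(estimated, "pairwise_matrix")) {
    if (inherits(truth, "correction_trajectory") ||
        (is.matrix(truth) && ncol(truth) == 2))
      truth <- pairwise_truth(truth)
    if (!inherits(truth, "pairwise_matrix") ||
        !identical(dim(estimated), dim(truth)))
      abort_validation("`truth` must be a pairwise_matrix of matching shape")
    T <- dim(estimated)[1]
    idx <- expand.grid(i = seq_len(T), j = seq_len(T))
    out <- do.call(rbind, lapply(1:2, function(a) {
      e <- as.vector(estimated[, , a]) - as.vector(truth[, , a])
      data.frame(i = idx$i, j = idx$j, axis = c("x", "y")[a],
                 error = e, abs_error = abs(e))
    }))
    return(out[!is.na(out$error), ])
  }
  estimated <- as_translation_series(estimated)
  truth <- as_translation_series(truth)
  if (!identical(dim(estimated), dim(truth)))
    abort_validation(sprintf("shape mismatch: %d vs %d steps",
                             nrow(estimated), nrow(truth)))
  do.call(rbind, lapply(1:2, function(a) {
    e <- estimated[, a] - truth[, a]
    data.frame(t = seq_len(nrow(estimated)), axis = c("x", "y")[a],
               error = e, abs_error = abs(e))
  }))
}

#' Dispersion summary of error samples
#'
#' Standard order statistics (median, lower and upper quartile, maximum).
#' A numeric vector is summarized directly; an error table from
#' [offset_errors()] is summarized per axis on the absolute errors.
#'
#' @param samples numeric vector, or a data frame with `axis` and
#'   `abs_error` columns.
#' @return a data frame with columns `axis` (where applicable), `n`,
#'   `median`, `q1`, `q3`, `max`.
#' @export
dispersion_summary <- function(samples) {
  summ <- function(x, axis = NA_character_) {
    if (length(x) == 0L) abort_validation("empty samples")
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(axis = axis, n = length(x), median = q[2], q1 = q[1],
               q3 = q[3], max = max(x))
  }
  if (is.numeric(samples)) {
    out <- summ(samples)
    out$axis <- NULL
    return(out)
  }
  if (is.data.frame(samples) && all(c("axis", "abs_error") %in% names(samples))) {
    if (nrow(samples) == 0L) abort_validation("empty samples")
    return(do.call(rbind, lapply(split(samples, samples$axis), function(g)
      summ(g$abs_error, g$axis[1]))))
  }
  abort_validation("`samples` must be numeric or an offset_errors table")
}

#' Registration error versus frame distance
#'
#' Aggregates all-pairs estimation errors by temporal distance `|j - i|`,
#' separately for forward (`j > i`) and reverse (`j < i`) frame order and
#' per axis. On evolving scenes the curve grows with distance (the
#' coherence length of the method); differences between the forward and
#' reverse branches expose non-commutative backends.
#'
#' @param estimated a `pairwise_matrix` of estimates.
#' @param truth matching `pairwise_matrix` or the drift
#'   [correction_trajectory].
#' @return a data frame with `distance`, `direction`
#'   (`"forward"`/`"reverse"`), `axis`, `mae`, `n`.
#' @export
coherence_curve <- function(estimated, truth) {
  err <- offset_errors(estimated, truth)
  if (!all(c("i", "j") %in% names(err)))
    abort_validation("`estimated` must be a pairwise_matrix")
  err <- err[err$i != err$j, ]
  err$distance <- abs(err$j - err$i)
  err$direction <- ifelse(err$j > err$i, "forward", "reverse")
  agg <- stats::aggregate(abs_error ~ distance + direction + axis, err,
                          function(x) c(mae = mean(x), n = length(x)))
  out <- data.frame(distance = agg$distance, direction = agg$direction,
                    axis = agg$axis, mae = agg$abs_error[, "mae"],
                    n = as.integer(agg$abs_error[, "n"]))
  out[order(out$direction, out$axis, out$distance), ]
}

#' Free-parameter sweep of a backend
#'
#' Re-estimates the nearest-neighbour series of a stack for every value
#' of the backend's free parameter (upsampling factor for `pcc`, window
#' radius for `lucas_kanade`, iterations for `deep_flow`) and records the
#' per-axis dispersion of the errors against the ground truth. A failing
#' grid point is marked `failed` and the sweep continues.
#'
#' @param stack a [frame_stack].
#' @param truth the ground-truth [translation_series].
#' @param method backend name.
#' @param grid numeric vector of parameter values.
#' @param ... further arguments passed to [backend_config()].
#' @return a tidy data frame, one row per grid value and axis, with the
#'   columns of [dispersion_summary()] plus `method`, `parameter`,
#'   `value`, `failed`.
#' @export
parameter_sweep <- function(stack, truth,
                            method = c("pcc", "lucas_kanade", "deep_flow"),
                            grid, ...) {
  method <- match.arg(method)
  if (length(grid) == 0L) abort_validation("`grid` must be nonempty")
  pname <- switch(method, pcc = "upsample_factor", lucas_kanade = "radius",
                  deep_flow = "iterations")
  rows <- lapply(grid, function(v) {
    args <- c(list(method = method), stats::setNames(list(v), pname),
              list(...))
    res <- tryCatch({
      cfg <- do.call(backend_config, args)
      est <- estimate_nn_series(stack, cfg)
      s <- dispersion_summary(offset_errors(est, truth))
      s$failed <- FALSE
      s
    }, error = function(e)
      data.frame(axis = c("x", "y"), n = NA_integer_, median = NA_real_,
                 q1 = NA_real_, q3 = NA_real_, max = NA_real_, failed = TRUE))
    res$method <- method
    res$parameter <- pname
    res$value <- v
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("method", "parameter", "value", "axis", "n", "median", "q1", "q3",
          "max", "failed")]
}
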