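#' Synthetic microscopy scene parameters
#'
#' Controls the generator of bright-field-like test stacks: a static
#' textured background plus sparse, independently motile, shape-changing
#' dark blobs standing in for cells. The background is synthesized in the
#' frequency domain (Gaussian-filtered white noise), which makes it
#' periodic: integer cyclic shifts of a generated frame are then exact
#' translations, the reference construction for registration oracles.
#'
#' @param n_cells number of blobs.
#' @param cell_radius `c(min, max)` blob radius range, pixels.
#' @param cell_speed `c(min, max)` per-blob random-walk speed, px/frame.
#' @param morph_rate fractional radius perturbation per frame (the
#'   "morphological change" of real cells).
#' @param background_grain correlation length of the background texture,
#'   pixels; the default 2 keeps enough gradient energy for the windowed
#'   least-squares flow to be full rank essentially everywhere.
#' @param noise_sigma additive Gaussian noise std per frame, intensity
#'   units.
#' @param cell_drift `c(dx, dy)` common velocity added to every blob
#'   (px/frame); nonzero values create coherent group motion, the
#'   adversarial case for non-robust reducers.
#' @param seed integer seed; identical seeds give bit-identical stacks.
#' @export
scene_params <- function(n_cells = 10L, cell_radius = c(4, 8),
                         cell_speed = c(0.5, 2), morph_rate = 0.1,
                         background_grain = 2, noise_sigma = 0.005,
                         cell_drift = c(0, 0), seed = NULL) {
  if (n_cells < 0) abort_validation("`n_cells` must be >= 0")
  if (length(cell_radius) != 2L || any(cell_radius <= 0))
    abort_validation("`cell_radius` must be a positive range c(min, max)")
  if (background_grain <= 0) abort_validation("`background_grain` must be > 0")
  if (noise_sigma < 0) abort_validation("`noise_sigma` must be >= 0")
  structure(list(n_cells = as.integer(n_cells), cell_radius = cell_radius,
                 cell_speed = cell_speed, morph_rate = morph_rate,
                 background_grain = background_grain,
                 noise_sigma = noise_sigma, cell_drift = cell_drift,
                 seed = seed),
            class = "scene_params")
}

# periodic textured background: white noise low-passed by a Gaussian of
# std `grain` via circular convolution, rescaled to [0.2, 0.8]
periodic_texture <- function(h, w, grain) {
  dyv <- c(0:(floor(h / 2)), (ceiling(h / 2) - 1):1)[seq_len(h)]
  dxv <- c(0:(floor(w / 2)), (ceiling(w / 2) - 1):1)[seq_len(w)]
  k <- exp(-outer(dyv^2, dxv^2, "+") / (2 * grain^2))
  z <- matrix(stats::rnorm(h * w), h, w)
  s <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (h * w)
  0.2 + 0.6 * (s - min(s)) / (max(s) - min(s))
}

#' Generate a synthetic time-lapse scene
#'
#' Deterministic given `params$seed`. Blobs follow seeded random walks
#' (reflected at the borders) with per-frame radius perturbations and are
#' composited as soft-edged dark disks over the static background; white
#' noise of `noise_sigma` is added per frame. The returned object tracks
#' every blob and reports the exact footprint fraction computed from the
#' rendered masks, so tests can verify the contamination level stays
#' below the median's breakdown point.
#'
#' @param n_frames,height,width stack dimensions (height and width at
#'   least 64 px for a meaningful texture).
#' @param params a [scene_params].
#' @return `list(stack, tracks, footprint_fraction)`: the [frame_stack],
#'   a data frame with columns `frame`, `cell`, `x`, `y`, `radius`, and
#'   the mean fraction of pixels covered by blobs.
#' @examples
#' sc <- generate_scene(4, 64, 64, scene_params(n_cells = 3, seed = 1))
#' sc$footprint_fraction
#' @export
generate_scene <- function(n_frames, height, width, params = scene_params()) {
  if (n_frames < 2) abort_validation("`n_frames` must be >= 2")
  if (height < 64 || width < 64)
    abort_validation("`height` and `width` must be >= 64")
  with_seed(params$seed, {
    bg <- periodic_texture(height, width, params$background_grain)
    n <- params$n_cells
    frames <- array(0, c(height, width, n_frames))
    tracks <- NULL
    foot <- numeric(n_frames)
    if (n > 0L) {
      px <- stats::runif(n, 1, width)
      py <- stats::runif(n, 1, height)
      r <- stats::runif(n, params$cell_radius[1], params$cell_radius[2])
      speed <- stats::runif(n, params$cell_speed[1], params$cell_speed[2])
      tracks <- vector("list", n_frames)
    }
    for (t in seq_len(n_frames)) {
      f <- bg
      mask <- matrix(FALSE, height, width)
      if (n > 0L) {
        for (b in seq_len(n)) {
          res <- render_blob(f, mask, px[b], py[b], r[b])
          f <- res$f; mask <- res$mask
        }
        tracks[[t]] <- data.frame(frame = t, cell = seq_len(n),
                                  x = px, y = py, radius = r)
        ang <- stats::runif(n, 0, 2 * pi)
        px <- reflect(px + speed * cos(ang) + params$cell_drift[1], width)
        py <- reflect(py + speed * sin(ang) + params$cell_drift[2], height)
        r <- pmin(pmax(r * (1 + params$morph_rate * stats::rnorm(n)),
                       params$cell_radius[1] / 2),
                  params$cell_radius[2] * 2)
      }
      foot[t] <- mean(mask)
      if (foot[t] > 0.5)
        abort_validation(sprintf(
          "blob footprint %.0f%% of frame %d exceeds 50%%: the median reducer's breakdown point would be violated by construction",
          100 * foot[t], t))
      if (params$noise_sigma > 0)
        f <- f + stats::rnorm(height * width, 0, params$noise_sigma)
      frames[, , t] <- pmin(pmax(f, 0), 1)
    }
    list(stack = frame_stack(frames,
                             source = sprintf("synthetic scene (seed %s)",
                                              format(params$seed))),
         tracks = if (n > 0L) do.call(rbind, tracks) else
           data.frame(frame = integer(), cell = integer(), x = numeric(),
                      y = numeric(), radius = numeric()),
         footprint_fraction = mean(foot))
  })
}

reflect <- function(x, n) {
  x <- abs(x - 1) %% (2 * (n - 1)) + 1
  ifelse(x > n, 2 * n - x, x)
}

# soft-edged dark blob with a lighter core, rendered on a local patch
render_blob <- function(f, mask, cx, cy, r) {
  h <- nrow(f); w <- ncol(f)
  ex <- ceiling(2 * r)
  xs <- max(1, floor(cx - ex)):min(w, ceiling(cx + ex))
  ys <- max(1, floor(cy - ex)):min(h, ceiling(cy + ex))
  if (!length(xs) || !length(ys)) return(list(f = f, mask = mask))
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  prof <- exp(-(d2 / r^2)^2)
  core <- exp(-(d2 / (0.45 * r)^2)^2)
  # weakly modulated relative to the background texture, as bright-field
  # cell bodies are against a structured substrate
  f[ys, xs] <- f[ys, xs] - 0.18 * prof + 0.12 * core
  mask[ys, xs] <- mask[ys, xs] | (prof > 0.05)
  list(f = f, mask = mask)
}
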