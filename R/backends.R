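#' Backend configuration for pairwise displacement estimation
#'
#' Bundles the choice of registration backend with its free parameter.
#' `pcc` estimates a single global translation from the normalized
#' cross-power spectrum with sub-pixel refinement on an upsampled DFT
#' grid; `lucas_kanade` computes a dense flow field by windowed least
#' squares and reduces it to one translation; `deep_flow` dispatches to a
#' user-registered pretrained flow model (see [register_deep_flow()]).
#'
#' Defaults follow the stability plateaus of the method's free-parameter
#' sweeps: upsampling factor 81 for `pcc` and window radius 23 for
#' `lucas_kanade`.
#'
#' @param method one of `"pcc"`, `"lucas_kanade"`, `"deep_flow"`.
#' @param upsample_factor sub-pixel resolution `1/upsample_factor` (pcc).
#' @param radius window radius in pixels (lucas_kanade).
#' @param iterations refinement iterations (deep_flow).
#' @param precision `"float32"` (native) or `"float16"`; the reduced mode
#'   quantizes input intensities to half-precision resolution before
#'   estimation while all accumulation stays in higher precision.
#' @param reducer how a dense flow field is collapsed to one translation:
#'   the component-wise `"median"` (robust up to 50% contaminated pixels)
#'   or the `"mode"` of a histogram with bins of `mode_bin_width` pixels.
#' @param mode_bin_width histogram bin width for the mode reducer.
#' @return a `backend_config` object.
#' @examples
#' cfg <- backend_config("pcc")
#' cfg
#' @export
backend_config <- function(method = c("pcc", "lucas_kanade", "deep_flow"),
                           upsample_factor = 81L, radius = 23L,
                           iterations = 12L,
                           precision = c("float32", "float16"),
                           reducer = c("median", "mode"),
                           mode_bin_width = 0.1) {
  method <- match.arg(method)
  precision <- match.arg(precision)
  reducer <- match.arg(reducer)
  if (upsample_factor < 1) abort_validation("`upsample_factor` must be >= 1")
  if (radius < 1) abort_validation("`radius` must be >= 1")
  if (iterations < 1) abort_validation("`iterations` must be >= 1")
  if (mode_bin_width <= 0) abort_validation("`mode_bin_width` must be > 0")
  structure(list(method = method,
                 upsample_factor = as.integer(upsample_factor),
                 radius = as.integer(radius),
                 iterations = as.integer(iterations),
                 precision = precision, reducer = reducer,
                 mode_bin_width = mode_bin_width),
            class = "backend_config")
}

#' @rdname backend_config
#' @param x a `backend_config`.
#' @param ... ignored.
#' @export
print.backend_config <- function(x, ...) {
  par <- switch(x$method,
                pcc = sprintf("upsample_factor = %d", x$upsample_factor),
                lucas_kanade = sprintf("radius = %d", x$radius),
                deep_flow = sprintf("iterations = %d", x$iterations))
  cat(sprintf("<backend_config> %s (%s), %s, reducer = %s\n",
              x$method, par, x$precision, x$reducer))
  invisible(x)
}

#' @rdname backend_config
#' @param path JSON file path.
#' @export
write_backend_config <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname backend_config
#' @export
read_backend_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  backend_config(method = j$method, upsample_factor = j$upsample_factor,
                 radius = j$radius, iterations = j$iterations,
                 precision = j$precision, reducer = j$reducer,
                 mode_bin_width = j$mode_bin_width)
}

#' Dense per-pixel displacement field
#'
#' Container for a per-pixel 2-vector displacement map between two frames:
#' `u` holds the displacement along x (columns, positive rightward) and
#' `v` along y (rows, positive downward), both in pixels.
#'
#' @param u,v numeric matrices of equal shape.
#' @export
flow_field <- function(u, v) {
  if (!is.matrix(u) || !is.matrix(v) || !identical(dim(u), dim(v)))
    abort_validation("`u` and `v` must be matrices of identical shape")
  if (!all(is.finite(u)) || !all(is.finite(v)))
    abort_validation("flow field entries must be finite")
  structure(list(u = u, v = v), class = "flow_field")
}

check_pair <- function(reference, moving) {
  if (!is.matrix(reference) || !is.matrix(moving))
    abort_validation("frames must be 2-D matrices")
  if (!identical(dim(reference), dim(moving)))
    abort_validation(sprintf("frame shapes differ: %dx%d vs %dx%d",
                             nrow(reference), ncol(reference),
                             nrow(moving), ncol(moving)))
}

# matrix-multiply DFT of `data` on an `ups x ups` grid upsampled by
# `usfac`, offset by (roff, coff) samples (Guizar-Sicairos style kernel)
upsampled_dft <- function(data, ups, usfac, roff, coff) {
  h <- nrow(data); w <- ncol(data)
  fy <- c(seq(0, floor((h - 1) / 2)), seq(-floor(h / 2), -1))
  fx <- c(seq(0, floor((w - 1) / 2)), seq(-floor(w / 2), -1))
  kr <- exp((-2i * pi / (h * usfac)) * outer(seq_len(ups) - 1 - roff, fy))
  kc <- exp((-2i * pi / (w * usfac)) * outer(fx, seq_len(ups) - 1 - coff))
  kr %*% data %*% kc
}

#' Sub-pixel translation by phase cross-correlation
#'
#' Computes the normalized cross-power spectrum of the two frames, locates
#' the integer correlation peak, and refines it to resolution
#' `1/upsample_factor` with a matrix-multiply DFT evaluated only around
#' the peak. The normalization divides each spectral bin by its
#' cross-power magnitude plus a relative floor (`spectral_floor` times the
#' mean magnitude); the floor leaves pure cyclic shifts exact while
#' preventing near-empty frequency bins of band-limited images from
#' dominating the phase correlation.
#'
#' Sign convention: the returned `(dx, dy)` is the motion of `moving`
#' relative to `reference` (x along columns rightward, y along rows
#' downward); translating `moving` by `(-dx, -dy)` aligns it to
#' `reference`.
#'
#' @param reference,moving 2-D frames of identical shape.
#' @param upsample_factor integer >= 1; sub-pixel resolution.
#' @param spectral_floor relative magnitude floor of the normalization
#'   (0 recovers the textbook phase-only normalization).
#' @return named vector `c(dx, dy)` in pixels.
#' @examples
#' f <- matrix(runif(64 * 64), 64, 64)
#' pcc_shift(f, cyclic_shift(f, 7, -3))  # c(7, -3), exactly
#' @export
pcc_shift <- function(reference, moving, upsample_factor = 81L,
                      spectral_floor = 0.2) {
  check_pair(reference, moving)
  if (upsample_factor < 1) abort_validation("`upsample_factor` must be >= 1")
  if (stats::var(as.vector(reference)) == 0 || stats::var(as.vector(moving)) == 0)
    abort_degenerate("constant (zero-variance) frame: translation is undefined")
  h <- nrow(reference); w <- ncol(reference)
  F1 <- stats::fft(reference - mean(reference))
  F2 <- stats::fft(moving - mean(moving))
  R <- F1 * Conj(F2)
  m <- Mod(R)
  lam <- if (spectral_floor > 0) spectral_floor * mean(m) else
    100 * .Machine$double.eps
  R <- R / (m + lam)
  cc <- stats::fft(R, inverse = TRUE)
  pk <- which.max(Mod(cc)) - 1L
  py <- pk %% h; px <- pk %/% h
  # the correlation peaks at minus the motion, wrapped to [-n/2, n/2)
  dy <- -(if (py > h / 2) py - h else py)
  dx <- -(if (px > w / 2) px - w else px)
  usfac <- as.integer(upsample_factor)
  if (usfac > 1L) {
    ups <- ceiling(usfac * 1.5)
    dsh <- floor(ups / 2)
    cc2 <- Conj(upsampled_dft(Conj(R), ups, usfac,
                              dsh - (-dy) * usfac, dsh - (-dx) * usfac))
    pk2 <- which.max(Mod(cc2)) - 1L
    dy <- -((-dy) + ((pk2 %% ups) - dsh) / usfac)
    dx <- -((-dx) + ((pk2 %/% ups) - dsh) / usfac)
  }
  c(dx = as.numeric(dx), dy = as.numeric(dy))
}

# box-window sums via a summed-area table; windows truncate at borders
boxsum <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  s <- matrix(0, h + 1L, w + 1L)
  s[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  r1 <- pmin(seq_len(h) + r, h) + 1L; r0 <- pmax(seq_len(h) - r - 1L, 0L) + 1L
  c1 <- pmin(seq_len(w) + r, w) + 1L; c0 <- pmax(seq_len(w) - r - 1L, 0L) + 1L
  s[r1, c1] - s[r0, c1] - s[r1, c0] + s[r0, c0]
}

grad_x <- function(m) {
  w <- ncol(m)
  g <- (m[, c(2:w, w)] - m[, c(1, 1:(w - 1))]) / 2
  g[, 1] <- m[, 2] - m[, 1]
  g[, w] <- m[, w] - m[, w - 1]
  g
}
grad_y <- function(m) t(grad_x(t(m)))

# per-pixel bilinear gather of m at (Y, X); out-of-range falls back to `fb`
bilinear_sample <- function(m, Y, X, fb) {
  h <- nrow(m); w <- ncol(m)
  y0 <- floor(Y); x0 <- floor(X)
  wy <- Y - y0; wx <- X - x0
  cl <- function(i, n) pmin(pmax(i, 1), n)
  i00 <- cbind(as.vector(cl(y0, h)), as.vector(cl(x0, w)))
  i01 <- cbind(as.vector(cl(y0, h)), as.vector(cl(x0 + 1, w)))
  i10 <- cbind(as.vector(cl(y0 + 1, h)), as.vector(cl(x0, w)))
  i11 <- cbind(as.vector(cl(y0 + 1, h)), as.vector(cl(x0 + 1, w)))
  val <- (1 - wy) * (1 - wx) * m[i00] + (1 - wy) * wx * m[i01] +
    wy * (1 - wx) * m[i10] + wy * wx * m[i11]
  dim(val) <- dim(Y)
  bad <- y0 < 1 | y0 + (wy > 0) > h | x0 < 1 | x0 + (wx > 0) > w
  val[bad] <- fb[bad]
  val
}

#' Dense Lucas-Kanade flow
#'
#' Estimates a per-pixel displacement field by windowed least squares over
#' image gradients: for every pixel the translational flow is solved from
#' the structure tensor accumulated over a uniform square window of the
#' given radius. The solve is refined by Gauss-Newton iterations that warp
#' the moving frame by the current field before re-linearizing, which
#' extends the valid displacement range well beyond the texture
#' correlation length. Pixels whose structure tensor is rank deficient
#' keep a zero flow vector, which is neutral under the median reducer
#' when such pixels are sparse.
#'
#' @inheritParams pcc_shift
#' @param radius window radius in pixels (window side `2 * radius + 1`).
#' @param n_iter Gauss-Newton refinement iterations.
#' @return a [flow_field]; same sign convention as [pcc_shift()].
#' @export
lk_dense_flow <- function(reference, moving, radius = 23L, n_iter = 5L) {
  check_pair(reference, moving)
  if (radius < 1) abort_validation("`radius` must be >= 1")
  h <- nrow(reference); w <- ncol(reference)
  u <- v <- matrix(0, h, w)
  Yg <- matrix(seq_len(h), h, w)
  Xg <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (k in seq_len(n_iter)) {
    movw <- if (k == 1L) moving else bilinear_sample(moving, Yg + v, Xg + u, reference)
    avg <- (reference + movw) / 2
    Ix <- grad_x(avg); Iy <- grad_y(avg); It <- movw - reference
    Sxx <- boxsum(Ix * Ix, radius); Syy <- boxsum(Iy * Iy, radius)
    Sxy <- boxsum(Ix * Iy, radius)
    Sxt <- boxsum(Ix * It, radius); Syt <- boxsum(Iy * It, radius)
    det <- Sxx * Syy - Sxy * Sxy
    ok <- det > 1e-12
    du <- dv <- matrix(0, h, w)
    du[ok] <- (-Syy[ok] * Sxt[ok] + Sxy[ok] * Syt[ok]) / det[ok]
    dv[ok] <- (Sxy[ok] * Sxt[ok] - Sxx[ok] * Syt[ok]) / det[ok]
    u <- u + du; v <- v + dv
  }
  flow_field(u, v)
}

# ---- deep-flow plugin registry ----

the_registry <- new.env(parent = emptyenv())

#' Optional deep optical-flow plugin
#'
#' `deep_flow()` delegates to a user-registered dense-flow callable, e.g.
#' an interface to a pretrained recurrent all-pairs field transform model.
#' The package ships no model weights; without a registered plugin the
#' call raises a capability error advising fallback to the built-in
#' backends. A plugin is a `function(reference, moving, iterations)`
#' returning a [flow_field] (or a list with `u` and `v`) in input-pixel
#' units.
#'
#' @inheritParams pcc_shift
#' @param iterations number of recurrent refinement iterations.
#' @param fn plugin function, or `NULL` to unregister.
#' @export
deep_flow <- function(reference, moving, iterations = 12L) {
  check_pair(reference, moving)
  fn <- the_registry$deep_flow
  if (is.null(fn))
    abort_capability(paste(
      "no deep-flow plugin registered; install one with register_deep_flow()",
      "or use method 'pcc' or 'lucas_kanade'"))
  out <- fn(reference, moving, iterations)
  if (!inherits(out, "flow_field")) out <- flow_field(out$u, out$v)
  out
}

#' @rdname deep_flow
#' @export
register_deep_flow <- function(fn) {
  if (!is.null(fn) && !is.function(fn))
    abort_validation("`fn` must be a function(reference, moving, iterations) or NULL")
  the_registry$deep_flow <- fn
  invisible(fn)
}

#' @rdname deep_flow
#' @export
has_deep_flow <- function() !is.null(the_registry$deep_flow)

#' Collapse a flow field to one global translation
#'
#' The `median` reducer takes the marginal median of the u and v
#' components independently; with up to half the pixels moving with the
#' scene's objects rather than the stage, the median still reports the
#' stage motion (50% breakdown point). The `mode` reducer returns the
#' center of the most populated histogram bin per component (first bin
#' wins ties); for symmetric unimodal fields both agree to within one bin
#' width, but the median characterizes flat-topped displacement
#' histograms better and is the package default.
#'
#' @param field a [flow_field].
#' @param reducer `"median"` or `"mode"`.
#' @param mode_bin_width histogram bin width in pixels (mode only).
#' @return named vector `c(dx, dy)`.
#' @export
flow_to_translation <- function(field, reducer = c("median", "mode"),
                                mode_bin_width = 0.1) {
  if (!inherits(field, "flow_field"))
    abort_validation("`field` must be a flow_field")
  if (length(field$u) == 0L) abort_validation("empty flow field")
  reducer <- match.arg(reducer)
  if (reducer == "median") {
    c(dx = stats::median(field$u), dy = stats::median(field$v))
  } else {
    if (mode_bin_width <= 0) abort_validation("`mode_bin_width` must be > 0")
    c(dx = hist_mode(field$u, mode_bin_width),
      dy = hist_mode(field$v, mode_bin_width))
  }
}

hist_mode <- function(x, w) {
  x <- as.vector(x)
  b <- floor(x / w)
  tab <- table(b)
  best <- as.numeric(names(tab)[which.max(tab)])
  (best + 0.5) * w
}

#' Estimate the global translation between two frames
#'
#' Dispatches on the configured backend: `pcc` returns its translation
#' directly; the flow backends compute a dense field which is collapsed by
#' the configured reducer. All backends share the sign convention of
#' [pcc_shift()]. With `precision = "float16"` the input frames are
#' quantized to half-precision resolution first.
#'
#' @inheritParams pcc_shift
#' @param config a [backend_config].
#' @return named vector `c(dx, dy)` in pixels.
#' @export
estimate_pair <- function(reference, moving, config = backend_config()) {
  if (!inherits(config, "backend_config"))
    abort_validation("`config` must be a backend_config")
  if (config$precision == "float16") {
    reference <- quantize_half(reference)
    moving <- quantize_half(moving)
  }
  if (config$method == "pcc")
    return(pcc_shift(reference, moving, config$upsample_factor))
  field <- switch(config$method,
                  lucas_kanade = lk_dense_flow(reference, moving, config$radius),
                  deep_flow = deep_flow(reference, moving, config$iterations))
  flow_to_translation(field, config$reducer, config$mode_bin_width)
}
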