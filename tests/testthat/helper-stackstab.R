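# shared fixtures: all generated in code, nothing stored on disk

# exact sub-pixel translation via the Fourier shift theorem; periodic, so
# it is the independent oracle for sub-pixel registration tests
fourier_shift <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  fy <- c(seq(0, floor((h - 1) / 2)), seq(-floor(h / 2), -1)) / h
  fx <- c(seq(0, floor((w - 1) / 2)), seq(-floor(w / 2), -1)) / w
  ph <- exp(-2i * pi * (outer(fy * dy, rep(1, w)) + outer(rep(1, h), fx * dx)))
  Re(fft(fft(m) * ph, inverse = TRUE)) / (h * w)
}

# clean periodic texture (no blobs, no noise) for registration oracles
test_texture <- function(n = 96, seed = 42) {
  sc <- generate_scene(2, n, n,
                       scene_params(n_cells = 0, noise_sigma = 0, seed = seed))
  get_frame(sc$stack, 1)
}

# stack whose frame t is a known cyclic shift of frame 1
shifted_stack <- function(base, shifts_xy) {
  frames <- lapply(seq_len(nrow(shifts_xy)), function(t)
    cyclic_shift(base, shifts_xy[t, 1], shifts_xy[t, 2]))
  frame_stack(frames, source = "constructed shifts")
}
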