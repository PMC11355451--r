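test_that("offset errors are plain differences in long format", {
  ser <- translation_series(rbind(c(1, 2), c(3, -1)))
  err <- offset_errors(ser, ser)
  expect_true(all(err$error == 0))
  # zero truth returns the estimate itself
  zero <- translation_series(matrix(0, 2, 2))
  err <- offset_errors(ser, zero)
  expect_equal(err$error[err$axis == "x"], c(1, 3))
  expect_equal(err$error[err$axis == "y"], c(2, -1))
  expect_equal(err$abs_error, abs(err$error))
  expect_error(offset_errors(ser, translation_series(matrix(0, 3, 2))),
               class = "stackstab_validation_error")
})

test_that("pairwise errors against a trajectory use s_j - s_i as truth", {
  traj <- accumulate(translation_series(rbind(c(1, 0), c(2, 2))))
  truth <- pairwise_truth(traj)
  expect_equal(truth[1, 3, ], c(3, 2))
  expect_equal(truth[3, 2, ], c(-2, -2))
  err <- offset_errors(truth, traj)
  expect_true(all(err$error == 0))
})

test_that("dispersion summary matches a sort-based oracle", {
  expect_equal(dispersion_summary(c(1, 2, 3))$median, 2)
  expect_equal(dispersion_summary(c(1, 2, 3))$max, 3)
  s <- dispersion_summary(rep(4.2, 10))
  expect_equal(s$q3 - s$q1, 0)

  # brute-force oracle: linear interpolation on the sorted samples
  sort_quantile <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  set.seed(99)
  x <- rnorm(1000)
  s <- dispersion_summary(x)
  expect_equal(s$median, sort_quantile(x, 0.5))
  expect_equal(s$q1, sort_quantile(x, 0.25))
  expect_equal(s$q3, sort_quantile(x, 0.75))
  expect_equal(s$max, max(x))
  expect_error(dispersion_summary(numeric(0)),
               class = "stackstab_validation_error")
})

test_that("coherence curve is flat for perfect and symmetric estimators", {
  traj <- accumulate(translation_series(matrix(rnorm(8), 4, 2)))
  truth <- pairwise_truth(traj)
  cc <- coherence_curve(truth, traj)
  expect_true(all(cc$mae == 0))
  expect_setequal(unique(cc$direction), c("forward", "reverse"))

  # exactly anti-symmetric error: forward and reverse branches agree
  est <- truth
  for (i in 1:4) for (j in 1:4) if (i != j)
    est[i, j, ] <- est[i, j, ] + 0.3 * (j - i)
  cc <- coherence_curve(est, traj)
  fw <- cc[cc$direction == "forward", ]
  rv <- cc[cc$direction == "reverse", ]
  expect_equal(fw$mae, rv$mae)
})

test_that("coherence curve resolves distance-proportional error growth", {
  # estimator whose error magnitude is proportional to the frame distance,
  # with seeded noise on top: the aggregated curve must recover the trend
  set.seed(61)
  T <- 12
  traj <- accumulate(translation_series(matrix(rnorm(2 * (T - 1)), T - 1, 2)))
  truth <- pairwise_truth(traj)
  est <- truth
  for (i in seq_len(T)) for (j in seq_len(T)) if (i != j)
    est[i, j, ] <- est[i, j, ] + 0.05 * (j - i) + rnorm(2, 0, 0.02)
  cc <- coherence_curve(est, traj)
  agg <- aggregate(mae ~ distance, cc, mean)
  expect_gt(cor(agg$distance, agg$mae, method = "spearman"), 0)
  # and the mean trend is close to the planted slope
  fit <- coef(lm(mae ~ distance, agg))
  expect_equal(unname(fit["distance"]), 0.05, tolerance = 0.2)
})

test_that("parameter sweeps reduce to single runs and respect quantization", {
  tex <- test_texture(80, seed = 41)
  steps <- rbind(c(1.3, -0.4), c(-0.7, 2.1), c(0.4, 0.9))
  traj <- accumulate(translation_series(steps))
  frames <- lapply(seq_len(4), function(t)
    fourier_shift(tex, traj[t, 1], traj[t, 2]))
  st <- frame_stack(frames)
  truth <- translation_series(steps)

  # one grid point equals the direct run
  sw <- parameter_sweep(st, truth, "pcc", grid = 50)
  direct <- dispersion_summary(offset_errors(
    estimate_nn_series(st, backend_config("pcc", upsample_factor = 50)), truth))
  expect_equal(sw$max, direct$max)
  expect_equal(sw$median, direct$median)
  expect_false(any(sw$failed))

  # error bounded by the sub-pixel quantization envelope
  sw <- parameter_sweep(st, truth, "pcc", grid = c(1, 2, 5, 10, 20, 50))
  for (v in unique(sw$value)) {
    expect_lte(max(sw$max[sw$value == v]), 0.5 / v + 0.05)
  }

  # a failing grid point is marked and the sweep continues
  sw <- parameter_sweep(st, truth, "pcc", grid = c(-1, 10))
  expect_true(all(sw$failed[sw$value == -1]))
  expect_false(any(sw$failed[sw$value == 10]))
})

test_that("deterministic reports reproduce bit-for-bit", {
  sc <- generate_scene(5, 64, 64, scene_params(n_cells = 4, seed = 55))
  ser <- synthesize_displacements(5, jitter_params(amplitude_max = 4, seed = 56))
  jj <- apply_jitter(sc$stack, ser, canvas_margin = 10)
  run <- function() {
    est <- estimate_nn_series(jj$stack, backend_config("pcc"))
    dispersion_summary(offset_errors(est, ser))
  }
  expect_identical(run(), run())
})
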