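tex <- test_texture(96)

test_that("pcc recovers cyclic integer shifts exactly and is anti-symmetric", {
  expect_equal(pcc_shift(tex, tex), c(dx = 0, dy = 0))
  mov <- cyclic_shift(tex, 7, -3)
  expect_identical(unname(pcc_shift(tex, mov, 81)), c(7, -3))
  expect_identical(unname(pcc_shift(tex, mov, 1)), c(7, -3))
  # anti-symmetry within the sub-pixel grid resolution
  for (usf in c(10, 81)) {
    ab <- pcc_shift(tex, mov, usf); ba <- pcc_shift(mov, tex, usf)
    expect_true(max(abs(ab + ba)) <= 2 / usf)
  }
})

test_that("pcc resolves Fourier-shifted sub-pixel translations to 1/upsample", {
  for (sh in list(c(2.25, -1.75), c(0.4, 0.7), c(-5.12, 3.33))) {
    mov <- fourier_shift(tex, sh[1], sh[2])
    est <- pcc_shift(tex, mov, 100)
    expect_true(max(abs(est - sh)) <= 1 / 100 + 1e-9)
  }
})

test_that("pcc rejects invalid input", {
  expect_error(pcc_shift(tex, tex[1:50, ]), class = "stackstab_validation_error")
  expect_error(pcc_shift(matrix(0.5, 32, 32), matrix(0.5, 32, 32)),
               class = "stackstab_degenerate_error")
})

test_that("dense LK flow is zero on identical frames and tracks warps", {
  fl <- lk_dense_flow(tex, tex, radius = 23)
  expect_lt(max(abs(fl$u)), 1e-6)
  expect_lt(max(abs(fl$v)), 1e-6)
  # sub-pixel bilinear warp: interior median within 0.3 px
  big <- test_texture(160, seed = 5)
  mov <- translate_frame(big, 0.5, 0.5, fill = median(big))
  fl <- lk_dense_flow(big, mov, radius = 23)
  it <- 40:120
  expect_lt(abs(median(fl$u[it, it]) - 0.5), 0.3)
  expect_lt(abs(median(fl$v[it, it]) - 0.5), 0.3)
  expect_error(lk_dense_flow(tex, tex[1:50, ]),
               class = "stackstab_validation_error")
})

test_that("flow reducers collapse fields as specified", {
  u <- matrix(2.5, 20, 20); v <- matrix(-1, 20, 20)
  fld <- flow_field(u, v)
  expect_equal(flow_to_translation(fld, "median"), c(dx = 2.5, dy = -1))
  md <- flow_to_translation(fld, "mode", 0.1)
  expect_true(max(abs(md - c(2.5, -1))) <= 0.1)

  # median survives 10% contamination with arbitrary large vectors
  set.seed(3)
  u2 <- matrix(5, 20, 20); v2 <- matrix(-3, 20, 20)
  bad <- sample(400, 40)
  u2[bad] <- runif(40, -500, 500); v2[bad] <- runif(40, -500, 500)
  expect_equal(flow_to_translation(flow_field(u2, v2), "median"),
               c(dx = 5, dy = -3))
})

test_that("median reducer tolerates 40% contamination", {
  set.seed(9)
  n <- 50
  for (rep in 1:5) {
    u <- matrix(rnorm(n * n, 1.5, 0.05), n, n)
    v <- matrix(rnorm(n * n, -0.5, 0.05), n, n)
    clean <- flow_to_translation(flow_field(u, v), "median")
    bad <- sample(n * n, round(0.4 * n * n))
    u[bad] <- runif(length(bad), -1e4, 1e4)
    v[bad] <- runif(length(bad), -1e4, 1e4)
    est <- flow_to_translation(flow_field(u, v), "median")
    expect_true(max(abs(est - clean)) < 0.05)
  }
})

test_that("median and mode agree for symmetric unimodal fields", {
  set.seed(7)
  u <- matrix(rnorm(2500, 1.23, 0.3), 50, 50)
  v <- matrix(rnorm(2500, -0.77, 0.3), 50, 50)
  fld <- flow_field(u, v)
  med <- flow_to_translation(fld, "median")
  mod <- flow_to_translation(fld, "mode", 0.1)
  expect_true(max(abs(med - mod)) <= 0.1)
})

test_that("all backends share one sign convention and agree on integer shifts", {
  register_deep_flow(function(ref, mov, iterations)
    lk_dense_flow(ref, mov, radius = 15, n_iter = min(iterations, 5)))
  withr::defer(register_deep_flow(NULL))
  mov <- cyclic_shift(tex, 4, 4)
  for (m in c("pcc", "lucas_kanade", "deep_flow")) {
    est <- estimate_pair(tex, mov, backend_config(m))
    expect_true(max(abs(est - c(4, 4))) < 0.5,
                label = sprintf("%s within 0.5 px of (4,4)", m))
    idn <- estimate_pair(tex, tex, backend_config(m))
    expect_true(max(abs(idn)) < 0.1,
                label = sprintf("%s identity", m))
  }
})

test_that("flow backends are anti-symmetric within tolerance", {
  mov <- fourier_shift(tex, 1.3, -0.8)
  ab <- estimate_pair(tex, mov, backend_config("lucas_kanade"))
  ba <- estimate_pair(mov, tex, backend_config("lucas_kanade"))
  expect_true(max(abs(ab + ba)) < 0.5)
})

test_that("deep flow without a plugin raises a capability error naming fallbacks", {
  register_deep_flow(NULL)
  expect_false(has_deep_flow())
  err <- expect_error(deep_flow(tex, tex), class = "stackstab_capability_error")
  expect_match(conditionMessage(err), "pcc")
  expect_error(estimate_pair(tex, tex, backend_config("deep_flow")),
               class = "stackstab_capability_error")
})

test_that("half-precision input quantization changes estimates by < 0.1 px", {
  mov <- fourier_shift(tex, 2.25, -1.75)
  for (m in c("pcc", "lucas_kanade")) {
    e32 <- estimate_pair(tex, mov, backend_config(m, precision = "float32"))
    e16 <- estimate_pair(tex, mov, backend_config(m, precision = "float16"))
    expect_true(max(abs(e32 - e16)) < 0.1, label = m)
  }
})

test_that("backend config validates and round trips through JSON", {
  expect_error(backend_config(upsample_factor = 0),
               class = "stackstab_validation_error")
  expect_error(backend_config(radius = 0), class = "stackstab_validation_error")
  cfg <- backend_config("lucas_kanade", radius = 31, precision = "float16",
                        reducer = "mode", mode_bin_width = 0.25)
  p <- file.path(withr::local_tempdir(), "cfg.json")
  write_backend_config(cfg, p)
  expect_identical(read_backend_config(p), cfg)
})
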