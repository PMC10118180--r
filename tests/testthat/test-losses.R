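test_that("rss is the plain point-by-point sum of squares", {
  g <- curve_grid(1:2)
  expect_equal(rss(curve_single(g, c(1, 2)), curve_single(g, c(1, 2))), 0)
  expect_equal(rss(curve_single(g, c(1, 2)), curve_single(g, c(0, 0))), 5)
  # not invariant under a scalar factor, unlike every smart error sum
  crv <- cauchy_curve(cauchy_params(), curve_grid(901:1099), t = 2)
  scaled <- curve_single(crv$grid, 1.1 * crv$intensities)
  expect_gt(rss(scaled, crv), 0)
  expect_error(rss(curve_single(g, 1:2), curve_series(g, 1, matrix(1:2, 1))),
               "same shape")
})

test_that("srss and arss quantify symmetry violations of hybrid maps", {
  mk <- function(phi = NULL, psi = NULL)
    correlation_maps(phi, psi, "hybrid-series", NULL)
  expect_equal(srss(mk(phi = matrix(c(1, 0, 2, 1), 2))), 4)  # (2-0)^2
  expect_equal(srss(mk(phi = matrix(c(10, 14, 14, 20), 2))), 0)
  expect_equal(arss(mk(psi = matrix(c(0, 0, 1, 0), 2))), 1)  # (1+0)^2
  expect_equal(arss(mk(psi = matrix(c(0, 1, -1, 0), 2))), 0)

  # hybrid maps of a scalar-scaled series: both residual sums vanish
  y <- generate_series(cauchy_params(b = 1), curve_grid(901:1099), 1:4)
  y2 <- curve_series(y$grid, y$t_values, 2.7 * y$intensities)
  maps <- series_maps(y, y2)
  expect_equal(srss(maps), 0)
  expect_lt(arss(maps), 1e-20)

  expect_error(srss(mk(psi = diag(2))), "no synchronous")
  expect_error(arss(mk(phi = diag(2))), "no asynchronous")
  expect_error(srss(mk(phi = diag(2)), p = 3), "even")
})

test_that("the series smart error sum bottoms out at 2 ln(epsilon)", {
  w <- ref_world()
  spec <- loss_spec("SES_SERIES", epsilon = 1e-10)
  floor_val <- 2 * log(1e-10)  # ~ -46.0517

  v_scaled <- ses_series(w$truth, w$measured, spec)  # measured = 1.1 * truth
  expect_equal(as.numeric(v_scaled), floor_val, tolerance = 1e-6)
  expect_named(attr(v_scaled, "components"), c("srss", "arss"))

  v_self <- ses_series(w$truth, w$truth, spec)
  expect_equal(as.numeric(v_self), floor_val, tolerance = 1e-12)

  # shifting every perturbation breaks the correlations: loss rises
  y_shift <- generate_series(w$params, w$grid, w$t_values + 0.5)
  expect_gt(as.numeric(ses_series(w$measured, y_shift, spec)), floor_val + 1)
})

test_that("two-trace losses agree with their oracles and closed forms", {
  g <- curve_grid(1:2)
  s <- curve_single(g, c(1, 0)); m <- curve_single(g, c(0, 1))
  expect_equal(async_2t2d(s, m), 1 / 4)
  expect_equal(async_2t2d_fast(s, m), 1 / 2)
  expect_equal(phase_2t2d(s, m), (pi / 2)^2, tolerance = 1e-8)

  s2 <- curve_single(g, c(1, 2))
  for (C in c(1, 0.3, 5)) {
    mC <- curve_single(g, C * c(1, 2))
    expect_lt(async_2t2d(s2, mC), 1e-25)
    expect_lt(async_2t2d_fast(s2, mC), 1e-25)
    expect_lt(phase_2t2d(s2, mC), 1e-15)
  }

  # O(N) closed form == 2 x upper-triangle form == brute-force double loop,
  # and the NCC link holds, on many random pairs
  for (seed in 1:10) {
    pr <- random_curve_pair(50, seed = seed)
    fast <- async_2t2d_fast(pr$s, pr$m)
    tri <- async_2t2d(pr$s, pr$m)
    brute <- brute_async_full(pr$s$intensities, pr$m$intensities)
    expect_equal(fast, 2 * tri, tolerance = 1e-12)
    expect_equal(fast, brute, tolerance = 1e-10)
    denom <- sum(pr$s$intensities^2) * sum(pr$m$intensities^2)
    expect_equal(ncc(pr$s, pr$m)^2, 1 - 2 * fast / denom, tolerance = 1e-10)
  }

  expect_error(async_2t2d(s, m, p = 3), "even")
})

test_that("ncc and zncc match their closed-form examples", {
  g <- curve_grid(1:2)
  s <- curve_single(g, c(1, 2))
  expect_equal(ncc(s, curve_single(g, 3 * c(1, 2))), 1)
  expect_equal(ncc(curve_single(g, c(1, 0)), curve_single(g, c(0, 1))), 0)
  expect_equal(ncc(s, curve_single(g, c(2, 1))), 4 / 5)
  expect_error(ncc(s, curve_single(g, c(0, 0))), "all-zero")

  g3 <- curve_grid(1:3)
  s3 <- curve_single(g3, c(1, 2, 3))
  expect_equal(zncc(s3, curve_single(g3, 2 * c(1, 2, 3) + 7)), 1)
  expect_equal(zncc(s3, curve_single(g3, c(3, 2, 1))), -1)
  expect_equal(zncc(s3, s3), 1)
  expect_error(zncc(s3, curve_single(g3, c(5, 5, 5))), "zero-variance")

  # strict-as-printed mode: population sd with 1/(l+1) prefactor, i.e. the
  # matched-divisor value shrunk by l/(l+1)
  pr <- random_curve_pair(30, seed = 3)
  expect_equal(zncc(pr$s, pr$m, strict_printed = TRUE),
               zncc(pr$s, pr$m) * 30 / 31, tolerance = 1e-12)
})

test_that("phase-series loss is invariant under scaling and detects shifts", {
  w <- ref_world()
  spec <- loss_spec("PHASE_SERIES")
  expect_equal(phase_series_ses(w$truth, w$truth, spec), 0)
  scaled <- curve_series(w$grid, w$t_values, 4.2 * w$truth$intensities)
  expect_lt(phase_series_ses(w$truth, scaled, spec), 1e-10)
  y_shift <- generate_series(w$params, w$grid, w$t_values + 0.5)
  expect_gt(phase_series_ses(w$truth, y_shift, spec), 1e-4)
})

test_that("every family except RSS is minimized by a scalar multiple", {
  w <- ref_world()
  crv <- cauchy_curve(w$params, w$grid, t = 3)
  for (C in c(0.5, 1.1, 2)) {
    mC <- curve_single(w$grid, C * crv$intensities)
    expect_lt(async_2t2d(crv, mC), 1e-12)
    expect_lt(async_2t2d_fast(crv, mC), 1e-12)
    expect_lt(phase_2t2d(crv, mC), 1e-10)
    expect_equal(ncc(crv, mC), 1, tolerance = 1e-12)
    expect_equal(zncc(crv, mC), 1, tolerance = 1e-12)
    expect_gt(rss(mC, crv), 0)
  }
  # offset invariance is specific to zncc
  mO <- curve_single(w$grid, 1.3 * crv$intensities + 0.7)
  expect_equal(zncc(crv, mO), 1, tolerance = 1e-12)
  expect_lt(ncc(crv, mO), 1)
})

test_that("loss_spec validates its fields and evaluate_loss dispatches", {
  expect_error(loss_spec("RSS", p = 3), "even")
  expect_error(loss_spec("RSS", epsilon = 0), "positive")
  expect_error(loss_spec("NOPE"), "arg")

  w <- ref_world()
  crv <- cauchy_curve(w$params, w$grid, t = 2)
  meas <- curve_single(w$grid, 1.1 * crv$intensities, role = "measured")
  expect_equal(evaluate_loss(loss_spec("NEG_NCC"), meas, crv), -1,
               tolerance = 1e-12)
  expect_equal(evaluate_loss(loss_spec("ASYNC_2T2D"), meas, crv),
               async_2t2d(crv, meas))
  expect_equal(evaluate_loss(loss_spec("RSS"), meas, crv), rss(meas, crv))
})
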