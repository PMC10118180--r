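test_that("noda_matrix matches its closed form and the brute-force oracle", {
  expect_equal(noda_matrix(2), matrix(c(0, -1 / pi, 1 / pi, 0), 2, 2))
  expect_equal(noda_matrix(3),
               matrix(c(0, -1 / pi, -1 / (2 * pi),
                        1 / pi, 0, -1 / pi,
                        1 / (2 * pi), 1 / pi, 0), 3, 3))
  for (m in c(2L, 5L, 9L)) {
    N <- noda_matrix(m)
    expect_identical(N, brute_noda(m))
    expect_true(all(N + t(N) == 0))  # antisymmetry, exact
  }
  expect_error(noda_matrix(1), "m must be")
  expect_error(noda_matrix(2.5), "m must be")
})

test_that("build_dynamic_matrix removes a shared offset and nothing else", {
  s <- curve_series(curve_grid(1:3), c(1, 2),
                    rbind(c(1, 2, 3), c(2, 4, 6)))
  expect_identical(build_dynamic_matrix(s), s)

  shifted <- curve_series(s$grid, s$t_values, s$intensities + 5)
  fixed <- build_dynamic_matrix(shifted, remove_common_offset = TRUE)
  # global minimum restored to zero-offset scale
  expect_equal(min(fixed$intensities), 0)
  expect_equal(fixed$intensities, s$intensities - min(s$intensities))

  # clean Cauchy bands carry no common offset worth removing: values intact
  g <- curve_grid(901:1099)
  ser <- generate_series(cauchy_params(x0 = 1000, gamma = 30), g, c(1, 2))
  expect_identical(build_dynamic_matrix(ser), ser)
  expect_equal(ser$intensities[, which(unclass(g) == 1000)], c(1, 2) / 30)
})

test_that("series constructors validate their invariants", {
  expect_error(curve_grid(c(1, 1, 2)), "strictly increasing")
  expect_error(curve_grid(5), "at least 2")
  expect_error(curve_grid(c(1, NA)), "finite")
  expect_error(curve_series(curve_grid(1:3), 1:2, matrix(1, 2, 2)),
               "column count")
  expect_error(curve_series(curve_grid(1:2), 1:3, matrix(1, 2, 2)),
               "row count")
  expect_error(curve_series(curve_grid(1:2), 1:2, matrix(c(1, Inf, 0, 0), 2)),
               "finite")
  expect_error(curve_single(curve_grid(1:3), 1:2), "length")
})

test_that("synchronous map matches the hand product and its symmetry laws", {
  y <- curve_series(curve_grid(1:2), c(1, 2), rbind(c(1, 2), c(3, 4)))
  phi <- synchronous_map(y)$synchronous
  expect_equal(phi, matrix(c(10, 14, 14, 20), 2, 2))
  expect_identical(synchronous_map(y)$kind, "conventional")

  # hybrid from a scaled copy: scalar commutes, symmetry preserved
  y2 <- curve_series(y$grid, y$t_values, 1.1 * y$intensities)
  hyb <- synchronous_map(y, y2)
  expect_identical(hyb$kind, "hybrid-series")
  expect_equal(hyb$synchronous, 1.1 * phi)
  expect_equal(hyb$synchronous, t(hyb$synchronous))

  expect_error(synchronous_map(y, curve_series(curve_grid(2:3), y$t_values,
                                               y$intensities)),
               "grid")
})

test_that("asynchronous map matches the hand computation and the separability null", {
  y <- curve_series(curve_grid(1:2), c(1, 2), rbind(c(1, 2), c(3, 4)))
  psi <- asynchronous_map(y)$asynchronous
  expect_equal(psi, matrix(c(0, 2 / pi, -2 / pi, 0), 2, 2))

  # b = 0 makes the intensities separable g(t)h(x): asynchronous map is zero
  # everywhere, for any amplitude nonlinearity a, and stays zero under a
  # constant multiplicative corruption
  g <- curve_grid(901:1099)
  for (a in c(0, 1)) {
    ser <- generate_series(cauchy_params(a = a, b = 0), g, 1:5)
    expect_lt(max(abs(asynchronous_map(ser)$asynchronous)), 1e-12)
    scaled <- curve_series(g, ser$t_values, 1.1 * ser$intensities)
    expect_lt(max(abs(asynchronous_map(ser, scaled)$asynchronous)), 1e-12)
  }
})

test_that("conventional maps satisfy the aggregate symmetry relations", {
  # upper-triangle sums of symmetry/antisymmetry violations vanish
  w <- ref_world()
  maps <- series_maps(w$truth)
  phi <- maps$synchronous; psi <- maps$asynchronous
  ut <- upper.tri(phi, diag = TRUE)
  dphi <- (phi - t(phi))[ut]
  spsi <- (psi + t(psi))[ut]
  expect_lt(abs(sum(dphi)) / sum(abs(phi)), 1e-10)
  expect_lt(abs(sum(spsi)) / max(sum(abs(psi)), 1e-300), 1e-10)
})

test_that("two-trace maps are symmetric/antisymmetric by construction", {
  g <- curve_grid(1:2)
  s <- curve_single(g, c(1, 0), role = "simulated")
  m <- curve_single(g, c(0, 1), role = "measured")
  maps <- two_trace_maps(s, m)
  expect_identical(maps$kind, "two-trace")
  expect_equal(maps$synchronous, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(maps$asynchronous, matrix(c(0, -0.5, 0.5, 0), 2, 2))

  # p = 2 antisymmetry relation holds exactly
  pr <- random_curve_pair(40, seed = 7)
  psi <- two_trace_maps(pr$s, pr$m)$asynchronous
  expect_identical(psi^2, t(psi)^2)

  # proportional (or identical) curves null the asynchronous map
  s3 <- curve_single(g, c(1, 2))
  expect_true(all(two_trace_maps(s3, s3)$asynchronous == 0))
  m3 <- curve_single(g, 3.7 * c(1, 2))
  expect_true(all(abs(two_trace_maps(s3, m3)$asynchronous) < 1e-15))
})

test_that("phase angles are regularized, branch-adjusted, and confined", {
  mk <- function(phi, psi) {
    correlation_maps(matrix(phi), matrix(psi), kind = "two-trace",
                     grid = NULL)
  }
  expect_equal(phase_angle_map(mk(1, 1))$theta[1, 1], pi / 4)
  expect_equal(phase_angle_map(mk(1, 0))$theta[1, 1], 0)
  # raw arctan of -pi/3 lies in (-pi/2, -pi/4): branch rule adds pi
  pm <- phase_angle_map(mk(1, -tan(pi / 3)))
  expect_equal(pm$theta[1, 1], 2 * pi / 3, tolerance = 1e-9)
  expect_identical(pm$branch_adjusted_count, 1L)
  # 0/0 resolves to zero through the sign-matched epsilon
  expect_equal(phase_angle_map(mk(0, 0))$theta[1, 1], 0)

  expect_error(phase_angle_map(mk(1, 1), epsilon = 0), "positive")
  expect_error(phase_angle_map(mk(1, 1), epsilon = -1), "positive")

  # confinement to (-pi/4, 3*pi/4] over random maps
  set.seed(42)
  for (i in 1:20) {
    phi <- matrix(stats::rnorm(25), 5)
    psi <- matrix(stats::rnorm(25), 5)
    th <- phase_angle_map(correlation_maps(phi, psi, "hybrid-series",
                                           NULL))$theta
    expect_true(all(th > -pi / 4 & th <= 3 * pi / 4))
  }
})

test_that("map export writes square CSVs labelled by the grid", {
  w <- ref_world()
  small <- generate_series(w$params, curve_grid(seq(960, 1040, by = 10)), 1:3)
  maps <- series_maps(small)
  path <- withr::local_tempfile(fileext = ".csv")
  write_map(maps$synchronous, small$grid, path)
  tab <- utils::read.csv(path, check.names = FALSE)
  expect_identical(dim(tab), c(9L, 10L))
  expect_equal(tab[[1]], as.numeric(unclass(small$grid)))
  expect_equal(as.matrix(tab[, -1]), maps$synchronous,
               ignore_attr = TRUE)
})
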