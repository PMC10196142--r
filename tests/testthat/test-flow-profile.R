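test_that("trapezoidal profile reproduces the recorded maneuver summaries", {
  # Control-group pMDI means: ivc/pif = 1.287 s >= t_in/2 -> trapezoid
  fp <- flow_profile(ivc_d = 3.36, pif_d = 2.61, t_in = 2.23, t_bh = 9.95)
  expect_identical(fp$family, "trapezoid")
  expect_equal(fp$t_ramp, 2.23 - 3.36 / 2.61, tolerance = 1e-12)
  expect_equal(fp$t_ramp, 0.943, tolerance = 1e-3)
  # peak, inhaled volume, duration recovered
  grid <- seq(0, fp$t_in, length.out = 20001)
  expect_equal(max(flow_at(fp, grid)), 2.61, tolerance = 1e-9)
  vol <- stats::integrate(function(t) flow_at(fp, t), 0, fp$t_in,
                          rel.tol = 1e-10, subdivisions = 1000L)$value
  expect_equal(vol, 3.36, tolerance = 1e-6)
  expect_equal(volume_at(fp, fp$t_in), 3.36, tolerance = 1e-12)
})

test_that("boundary maneuver gives a rectangular profile", {
  fp <- flow_profile(ivc_d = 4, pif_d = 2, t_in = 2, t_bh = 0)
  expect_equal(fp$t_ramp, 0)
  expect_equal(flow_at(fp, c(0.01, 1, 1.99)), rep(2, 3))
  expect_equal(volume_at(fp, 1), 2)
})

test_that("spiky breaths take the rise-and-exponential-decay branch", {
  # ivc = pif * t_in / 4 -> below the trapezoid threshold
  fp <- flow_profile(ivc_d = 1, pif_d = 2, t_in = 2, t_bh = 0)
  expect_identical(fp$family, "spike")
  vol <- stats::integrate(function(t) flow_at(fp, t), 0, fp$t_in,
                          rel.tol = 1e-11, subdivisions = 2000L)$value
  expect_equal(vol, 1, tolerance = 1e-6)
  expect_equal(max(flow_at(fp, seq(0, 2, length.out = 40001))), 2,
               tolerance = 1e-9)
})

test_that("profile round-trips peak, volume and duration for fuzzed maneuvers", {
  withr::with_seed(42, {
    for (k in 1:60) {
      pif <- runif(1, 0.5, 6)
      t_in <- runif(1, 0.8, 5)
      frac <- runif(1, 0.12, 0.99) # both families
      ivc <- frac * pif * t_in
      fp <- flow_profile(ivc, pif, t_in, t_bh = runif(1, 0, 12))
      expect_equal(volume_at(fp, fp$t_in), ivc, tolerance = 1e-9)
      grid <- seq(0, t_in, length.out = 5000)
      q <- flow_at(fp, grid)
      expect_lte(max(q), pif + 1e-9)
      expect_gte(max(q), pif - 1e-3 * pif) # grid resolution on the peak
      # nondecreasing inhaled volume, constant during breath-hold
      v <- volume_at(fp, grid)
      expect_true(all(diff(v) >= -1e-12))
      expect_equal(volume_at(fp, fp$t_in + fp$t_bh / 2), ivc)
      # analytic volume agrees with quadrature at a random interior time
      tt <- runif(1, 0, t_in)
      vq <- stats::integrate(function(x) flow_at(fp, x), 0, tt,
                             rel.tol = 1e-9, subdivisions = 1000L)$value
      expect_equal(volume_at(fp, tt), vq, tolerance = 1e-6)
      # time_at_volume inverts volume_at
      vv <- runif(1, 0, ivc)
      expect_equal(volume_at(fp, time_at_volume(fp, vv)), vv,
                   tolerance = 1e-8)
    }
  })
})

test_that("infeasible maneuvers are rejected with a diagnostic naming the bound", {
  expect_error(flow_profile(ivc_d = 5, pif_d = 2, t_in = 2, t_bh = 0),
               "pif_d \\* t_in")
  # 1% slack absorbs rounded inputs
  expect_s3_class(flow_profile(ivc_d = 4.02, pif_d = 2, t_in = 2, t_bh = 0),
                  "flow_profile")
})

test_that("exhalation mirrors inhalation volume and respects the duration multiplier", {
  fp <- flow_profile(3.36, 2.61, 2.23, 9.95, exhale_mult = 1.5)
  expect_equal(fp$t_ex, 1.5 * 2.23)
  expect_equal(volume_at(fp, fp$t_end), 0, tolerance = 1e-9)
  grid <- seq(fp$t_end_bh, fp$t_end, length.out = 2000)
  expect_true(all(diff(volume_at(fp, grid)) <= 1e-12))
  vol_ex <- stats::integrate(function(t) flow_at(fp, t), fp$t_end_bh,
                             fp$t_end, rel.tol = 1e-9,
                             subdivisions = 1000L)$value
  expect_equal(vol_ex, fp$ivc_d, tolerance = 1e-5)
})

test_that("lung volume trajectory starts at RV and tracks the inhaled volume", {
  fp <- flow_profile(2, 1, 2, 5) # rectangular Q = 1 L/s for 2 s
  v <- lung_volume_trajectory(fp, rv = 2)
  expect_equal(v(0), 2)
  expect_equal(v(2), 4) # rv + 1 L/s * 2 s
  fp2 <- flow_profile(3.36, 2.61, 2.23, 9.95)
  v2 <- lung_volume_trajectory(fp2, rv = 2, tlc = 6)
  expect_equal(v2(fp2$t_in), 5.36)
  expect_warning(lung_volume_trajectory(fp2, rv = 3, tlc = 6),
                 "exceeds tlc")
})

test_that("geometry scale factor is the cube root of the volume ratio", {
  expect_equal(geometry_scale_factor(4.8, 4.8), 1)
  expect_equal(geometry_scale_factor(8 * 4.8, 4.8), 2)
  expect_equal(geometry_scale_factor(3, 4.8), (3 / 4.8)^(1 / 3))
  expect_equal(geometry_scale_factor(3, 4.8), 0.855, tolerance = 1e-3)
  expect_error(geometry_scale_factor(-1, 4.8), "positive")
})
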