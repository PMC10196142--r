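test_that("Cunningham slip factor matches direct evaluation and limits", {
  lam <- physics_constants()$mean_free_path
  direct <- function(d) 1 + (lam / d) * (2.514 + 0.8 * exp(-0.55 * d / lam))
  expect_equal(cunningham(1), direct(1))
  expect_equal(cunningham(1), 1.166, tolerance = 1e-3)
  expect_equal(cunningham(10), 1.017, tolerance = 1e-3)
  expect_equal(cunningham(1e4), 1, tolerance = 1e-4) # slip vanishes
  expect_error(cunningham(0), "positive")
})

test_that("settling velocity follows the Stokes aerodynamic form", {
  expect_equal(settling_velocity(0), 0)
  # independent evaluation: rho g d^2 Cc / (18 mu)
  const <- physics_constants()
  direct <- function(d) {
    1000 * const$g * (d * 1e-6)^2 * cunningham(d) / (18 * const$viscosity)
  }
  expect_equal(settling_velocity(1), direct(1))
  expect_equal(settling_velocity(1), 3.5e-5, tolerance = 0.01)
  expect_equal(settling_velocity(3), 2.9e-4, tolerance = 0.02)
})

test_that("diffusion coefficient is Stokes-Einstein with slip and decreasing in size", {
  const <- physics_constants()
  direct <- function(d) {
    const$boltzmann * const$temperature * cunningham(d) /
      (3 * pi * const$viscosity * d * 1e-6)
  }
  expect_equal(diffusion_coefficient(1), direct(1))
  expect_equal(diffusion_coefficient(1), 2.93e-11, tolerance = 1e-3)
  expect_equal(diffusion_coefficient(0.1), direct(0.1))
  d_grid <- diffusion_coefficient(c(0.05, 0.1, 0.5, 1, 5, 10))
  expect_true(all(diff(d_grid) < 0))
})

test_that("impaction probability has the arccos closed form with saturation", {
  expect_equal(prob_impaction(0, 30), 0)
  expect_equal(prob_impaction(3, 30), 1) # theta_rad * St >= 1
  # independent re-evaluation of the same expression
  x <- (30 * pi / 180) * 0.5
  expected <- 1 - (2 / pi) * acos(x) - (1 / pi) * sin(2 * acos(x))
  expect_equal(prob_impaction(0.5, 30), expected)
  st <- seq(0, 4, by = 0.05)
  p <- prob_impaction(st, 45)
  expect_true(all(diff(p) >= 0)) # monotone in St
  expect_true(all(p >= 0 & p <= 1))
  expect_error(prob_impaction(-1, 30), ">= 0")
})

test_that("sedimentation probability matches the tube formula", {
  expect_equal(prob_sedimentation(0.2, 3.5e-5, 1, 0), 0)
  expect_equal(prob_sedimentation(0.2, 3.5e-5, 0, 5), 0) # horizontal tube
  expect_equal(prob_sedimentation(0.2, 3.5e-5, 1, 1),
               1 - exp(-4 * 3.5e-5 / (pi * 0.002)))
  expect_equal(prob_sedimentation(0.2, 3.5e-5, 1, 1), 0.0221,
               tolerance = 1e-2)
  # sign of the gravity cosine is irrelevant
  expect_equal(prob_sedimentation(0.3, 1e-4, -0.6, 2),
               prob_sedimentation(0.3, 1e-4, 0.6, 2))
})

test_that("diffusional loss probability matches the first-mode formula", {
  expect_equal(prob_diffusion(1e-3, 2.9e-11, 0), 0)
  expect_equal(prob_diffusion(1e-3, 0, 10), 0)
  expect_equal(prob_diffusion(1e-3, 2.9e-11, 1),
               1 - exp(-5.784 * 2.9e-11 / 1e-6))
  expect_equal(prob_diffusion(1e-3, 2.9e-11, 1), 1.68e-4, tolerance = 1e-2)
})

test_that("mechanisms combine independently and clip to [0, 1]", {
  expect_equal(combine_mechanisms(0, 0, 0), 0)
  expect_equal(combine_mechanisms(1, 0.2, 0.1), 1)
  expect_equal(combine_mechanisms(0.1, 0.2, 0.3), 0.496)
})

test_that("extrathoracic efficiency is monotone in the impaction parameter", {
  # for fine particles the inertial term vanishes; capture reduces to the
  # diffusive term
  expect_lt(extrathoracic_efficiency(0.5, 30), 0.05)
  const0 <- physics_constants()
  expect_lt(1 - exp(-const0$et_a * (0.5^2 * 30)^const0$et_b), 0.005)
  expect_gt(extrathoracic_efficiency(5, 60), extrathoracic_efficiency(1, 30))
  d2q <- function(d, q) d^2 * q
  combos <- expand.grid(d = c(0.5, 1, 3, 5, 8), q = c(15, 30, 60, 90))
  combos <- combos[order(d2q(combos$d, combos$q)), ]
  eta_imp <- 1 - exp(-physics_constants()$et_a *
                       (combos$d^2 * combos$q)^physics_constants()$et_b)
  expect_true(all(diff(eta_imp) >= 0))
  # inertial term equals its stated closed form
  const <- physics_constants()
  eta <- extrathoracic_efficiency(5, 60, const)
  expect_gte(eta, 1 - exp(-const$et_a * (25 * 60)^const$et_b))
  expect_error(extrathoracic_efficiency(-1, 30), ">= 0")
})

test_that("particle properties bundle is consistent with the scalar functions", {
  p <- particle_properties(c(0.5, 2, 6))
  expect_equal(p$cc, cunningham(c(0.5, 2, 6)))
  expect_equal(p$v_s, settling_velocity(c(0.5, 2, 6)))
  expect_equal(p$d_diff, diffusion_coefficient(c(0.5, 2, 6)))
})
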