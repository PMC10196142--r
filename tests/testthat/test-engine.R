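test_that("every simulation conserves the tracked dose exactly", {
  for (seed in 1:3) {
    r <- simulate_deposition(2.2, 1.8, 2.4, 10, rv = 3.0, tlc = 6.2,
                             aerosol = device_preset("Trimbow_pMDI"),
                             n_particles = 3000, seed = seed)
    expect_lt(abs(r$pd_pct + r$etd_pct + r$exhaled_pct - 100), 1e-9)
    expect_lt(abs(sum(r$per_generation$pct) - 100), 1e-9)
    expect_true(all(r$per_generation$pct >= 0))
    expect_equal(r$se_pd,
                 sqrt(r$pd_pct / 100 * (1 - r$pd_pct / 100) / 3000) * 100)
  }
})

test_that("very coarse aerosols are captured extrathoracically", {
  spec <- aerosol_spec(100, 1.2, label = "coarse")
  r <- simulate_deposition(3.36, 2.61, 2.23, 10, rv = 1.7,
                           aerosol = spec, n_particles = 2e4, seed = 1)
  expect_gt(r$etd_pct, 99)
})

test_that("an arbitrarily long breath-hold deposits everything that entered the lung", {
  r <- simulate_deposition(3.36, 2.61, 2.23, 1e4, rv = 1.7,
                           aerosol = device_preset("Spiriva_Respimat"),
                           n_particles = 2e4, seed = 2)
  expect_lt(r$exhaled_pct, 1)
})

test_that("single-tube Monte Carlo converges to the closed-form probability", {
  withr::with_seed(11, {
    for (k in 1:6) {
      len <- runif(1, 5, 20); dia <- runif(1, 0.2, 0.8)
      th <- runif(1, 10, 70); cp <- runif(1, -1, 1)
      d <- runif(1, 1, 8); q <- runif(1, 0.1, 0.6)
      t_in <- 3; ivc <- q * t_in
      spec <- aerosol_spec(d, 1, 1, c(0, 0.05), "tube")
      r <- simulate_deposition(
        ivc, q, t_in, 0, rv = 2, aerosol = spec, n_particles = 1e5,
        seed = 1000 + k,
        geom = single_tube_geometry(len, dia, th, cp),
        et_enabled = FALSE, exhalation_enabled = FALSE,
        scale_geometry = FALSE)
      p <- single_tube_prob(d, q, len, dia, th, cp)
      se <- sqrt(max(p * (1 - p), 1e-10) / 1e5)
      expect_lt(abs(r$pd_pct / 100 - p), 3 * se + 3e-5)
    }
  })
})

test_that("repetition means average the two runs", {
  spec <- device_preset("Foster_pMDI")
  a <- simulate_deposition(3.3, 2.6, 2.2, 10, rv = 1.7, aerosol = spec,
                           n_particles = 500, seed = 1)
  b <- simulate_deposition(3.4, 2.7, 2.3, 10, rv = 1.7, aerosol = spec,
                           n_particles = 500, seed = 2)
  m <- mean_of_two(a, b)
  expect_equal(m$pd_mean, (a$pd_pct + b$pd_pct) / 2)
  expect_equal(mean_of_two(b, a), m) # commutes
  expect_equal(mean_of_two(a, a)$pd_mean, a$pd_pct)
})

test_that("cohort runs are deterministic and row-complete", {
  cohort <- generate_cohort(cohort_config(n_per_group = 2), seed = 5,
                            groups = "Control")
  r1 <- run_cohort(cohort, n_particles = 400, seed = 77)
  r2 <- run_cohort(cohort, n_particles = 400, seed = 77)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 2 * 3 * 2) # subjects x devices x repetitions
  expect_true(all(!is.na(r1$pd_pct)))
  # per-row streams keyed by subject/device/repetition: row order irrelevant
  shuffled <- cohort[rev(seq_len(nrow(cohort))), ]
  r3 <- run_cohort(shuffled, n_particles = 400, seed = 77)
  expect_equal(dplyr::arrange(r3, subject_id, device, repetition)$pd_pct,
               dplyr::arrange(r1, subject_id, device, repetition)$pd_pct)
})

test_that("Monte Carlo standard errors scale roughly with 1/sqrt(N)", {
  spec <- device_preset("Foster_pMDI")
  big <- simulate_deposition(3.36, 2.61, 2.23, 10, rv = 1.7, aerosol = spec,
                             n_particles = 8000, seed = 3)
  small <- simulate_deposition(3.36, 2.61, 2.23, 10, rv = 1.7, aerosol = spec,
                               n_particles = 2000, seed = 4)
  expect_gt(small$se_pd / big$se_pd, 1.6)
  expect_lt(small$se_pd / big$se_pd, 2.4)
})

test_that("failed rows are reported and carried as NA", {
  cohort <- generate_cohort(cohort_config(n_per_group = 1), seed = 1,
                            groups = "Control")
  cohort$ivc_d_l[1] <- 99 # infeasible
  expect_warning(r <- run_cohort(cohort, n_particles = 100, seed = 1),
                 "could not be simulated")
  expect_true(any(is.na(r$pd_pct)))
  expect_true(any(!is.na(r$pd_pct)))
})

test_that("derived seeds are stable, keyed and within integer range", {
  expect_identical(derive_seed(42, "a/b/1"), derive_seed(42, "a/b/1"))
  expect_false(derive_seed(42, "a/b/1") == derive_seed(42, "a/b/2"))
  expect_false(derive_seed(42, "a/b/1") == derive_seed(43, "a/b/1"))
  expect_lt(derive_seed(2^30, "x"), 2^31)
})
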