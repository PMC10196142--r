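test_that("identical measurements give zero bias, LoA and CR", {
  ba <- bland_altman(c(10, 20, 30), c(10, 20, 30))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_low, 0)
  expect_equal(ba$loa_high, 0)
  expect_equal(ba$cr, 0)
  expect_equal(ba$p_value, 1)
})

test_that("hand-computed two-point example reproduces all summaries", {
  ba <- bland_altman(c(1, 0), c(0, 1)) # d = {+1, -1}
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_d, sqrt(2))
  expect_equal(ba$loa_high, 1.96 * sqrt(2))
  expect_equal(ba$loa_high, 2.772, tolerance = 1e-3)
  expect_equal(ba$cr, 1.96) # 1.96 * sqrt((1 + 1)/2)
})

test_that("published-style moments give the published CR", {
  # n = 17, mean difference 0.80, SD 1.2653 (reconstructed from the LoA)
  d <- vector_with_moments(17, 0.80, 1.2653)
  ba <- bland_altman(d, rep(0, 17))
  expect_equal(mean(d), 0.80)
  expect_equal(sd(d), 1.2653)
  expect_equal(ba$cr, 2.87, tolerance = 0.005)
  expect_lt(abs(ba$p_value - 0.019), 0.001)
})

test_that("the two CR code paths agree to numerical precision", {
  withr::with_seed(8, {
    for (k in 1:300) {
      n <- sample(2:40, 1)
      d <- rnorm(n, mean = runif(1, -3, 3), sd = runif(1, 0.01, 5))
      ba <- bland_altman(d, rep(0, n))
      expect_equal(ba$cr, cr_from_moments(ba$bias, ba$sd_d, n),
                   tolerance = 1e-12)
      expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_d,
                   tolerance = 1e-12)
    }
  })
})

test_that("Bland-Altman output is invariant under a common shift", {
  withr::with_seed(3, {
    a <- rnorm(20, 30, 5); b <- rnorm(20, 30, 5)
    x <- bland_altman(a, b); y <- bland_altman(a + 100, b + 100)
    expect_equal(x$bias, y$bias)
    expect_equal(x$cr, y$cr)
    expect_equal(x$p_value, y$p_value)
  })
})

test_that("degenerate or missing inputs are rejected", {
  expect_error(bland_altman(1, 1), "at least 2")
  expect_error(bland_altman(c(1, NA), c(1, 2)), "Missing")
  expect_error(bland_altman(c(1, 2, 3), c(1, 2)), "equal length")
})

test_that("all 18 published repeatability rows reconstruct within rounding", {
  rec <- reconstruct_repeatability()
  expect_equal(nrow(rec), 18)
  expect_true(all(abs(rec$cr_error) < 0.1))
  # published bias t-test p-values for the control rows reconstruct to
  # within 0.005 (the lung/Trimbow row prints 0.005 where the standard
  # t-test on the printed moments gives ~0.009 -- still inside the band)
  ctrl <- rec[rec$group == "Control", ]
  expect_true(all(abs(ctrl$p_reconstructed - ctrl$p_printed) < 0.005))
  trimbow <- ctrl[ctrl$site == "lung" & ctrl$device == "Trimbow_pMDI", ]
  expect_lt(abs(trimbow$p_reconstructed - 0.0092), 0.001)
})

test_that("device ranking orders by absolute difference with fixed tie-break", {
  d <- tibble::tibble(subject_id = "S1", device = device_levels(),
                      difference = c(1, -2, 3))
  r <- rank_devices(d)
  expect_equal(r$rank[match(device_levels(), r$device)], c(1L, 2L, 3L))
  # permutation invariance: relabeling devices permutes ranks identically
  d2 <- d; d2$difference <- c(3, 1, -2)
  r2 <- rank_devices(d2)
  expect_equal(r2$rank[r2$device == "Trimbow_pMDI"], 1L)
  # ties broken by the fixed device order, with a warning
  d3 <- tibble::tibble(subject_id = "S1", device = device_levels(),
                       difference = c(2, 2, 2))
  expect_warning(r3 <- rank_devices(d3), "Ties")
  expect_equal(r3$rank[match(device_levels(), r3$device)], c(1L, 2L, 3L))
  # each subject uses each rank exactly once
  expect_setequal(r$rank, 1:3)
})

test_that("rank summaries count subjects per group, device and rank", {
  d <- tibble::tibble(
    subject_id = rep(c("S1", "S2"), each = 3),
    group = "Control",
    device = rep(device_levels(), 2),
    difference = c(1, 2, 3, 3, 2, 1))
  rs <- rank_summary(rank_devices(d))
  expect_equal(sum(rs$n_subjects), 6)
  expect_equal(rs$n_subjects[rs$device == "Foster_pMDI" & rs$rank == 1], 1L)
})

test_that("group comparison selects the right branch and adjusts p-values", {
  # same values in every group: no rejection
  same <- tibble::tibble(g = rep(c("a", "b", "c"), each = 5),
                         y = rep(c(1, 2, 3, 4, 5), 3))
  gc1 <- group_compare(same, "y", "g")
  expect_gt(gc1$omnibus_p, 0.9)
  # two groups shifted by 10 SD: decisive rejection
  withr::with_seed(4, {
    shifted <- tibble::tibble(
      g = rep(c("a", "b"), each = 20),
      y = c(rnorm(20, 0, 1), rnorm(20, 10, 1)))
  })
  gc2 <- group_compare(shifted, "y", "g")
  expect_lt(min(gc2$pairwise$p_adj), 0.001)
  # Bonferroni monotonicity
  expect_true(all(gc2$pairwise$p_adj >= gc2$pairwise$p_raw))
  # tiny groups force the nonparametric branch
  tiny <- tibble::tibble(g = rep(c("a", "b", "c"), each = 2), y = rnorm(6))
  expect_warning(gc3 <- group_compare(tiny, "y", "g"), "n < 3")
  expect_equal(gc3$method, "kruskal")
  # explicit method selection honored
  expect_equal(group_compare(shifted, "y", "g", method = "kruskal")$method,
               "kruskal")
})

test_that("repeatability table reproduces direct Bland-Altman computations", {
  withr::with_seed(6, {
    res <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:8),
                              device = device_levels(),
                              repetition = 1:2)
    res$group <- "Control"
    res$pd_pct <- rnorm(nrow(res), 30, 5)
    res$etd_pct <- 100 - res$pd_pct - 1
  })
  tab <- repeatability_table(res)
  expect_equal(nrow(tab), 6) # 2 sites x 3 devices, one group
  row <- tab[tab$site == "lung" & tab$device == "Foster_pMDI", ]
  wide <- tidyr::pivot_wider(
    res[res$device == "Foster_pMDI", c("subject_id", "repetition", "pd_pct")],
    names_from = "repetition", values_from = "pd_pct")
  ba <- bland_altman(wide$`1`, wide$`2`)
  expect_equal(row$cr, ba$cr)
  expect_equal(row$bias, ba$bias)
  # differences feed the ranking layer with one row per subject/device
  diffs <- repetition_differences(res)
  expect_equal(nrow(diffs), 24)
  expect_equal(diffs$difference[1],
               res$pd_pct[1] - res$pd_pct[2])
})
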