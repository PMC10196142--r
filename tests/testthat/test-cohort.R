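test_that("zero intra-subject CV makes the two repetitions identical", {
  co <- generate_cohort(cohort_config(n_per_group = 5, intra_cv = 0),
                        seed = 1)
  wide <- tidyr::pivot_wider(
    co[, c("subject_id", "device", "repetition", "ivc_d_l", "pif_d_lps",
           "t_in_s", "t_bh_s")],
    names_from = "repetition",
    values_from = c("ivc_d_l", "pif_d_lps", "t_in_s", "t_bh_s"))
  expect_equal(wide$ivc_d_l_1, wide$ivc_d_l_2)
  expect_equal(wide$t_bh_s_1, wide$t_bh_s_2)
})

test_that("a fixed master seed yields a byte-identical cohort file", {
  cfg <- cohort_config(n_per_group = 4)
  a <- generate_cohort(cfg, seed = 9)
  b <- generate_cohort(cfg, seed = 9)
  expect_identical(a, b)
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  utils::write.csv(a, fa, row.names = FALSE)
  utils::write.csv(b, fb, row.names = FALSE)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("large samples recover the published group targets", {
  co <- generate_cohort(cohort_config(n_per_group = 10000), seed = 3,
                        groups = "Control")
  pmdi <- co[co$device == "Foster_pMDI" & co$repetition == 1, ]
  expect_lt(abs(mean(pmdi$ivc_d_l) / 3.36 - 1), 0.01)
  expect_lt(abs(mean(pmdi$pif_d_lps) / 2.61 - 1), 0.01)
  smi <- co[co$device == "Spiriva_Respimat" & co$repetition == 1, ]
  expect_lt(abs(mean(smi$ivc_d_l) / 3.61 - 1), 0.01)
  expect_lt(abs(mean(smi$pif_d_lps) / 2.19 - 1), 0.01)
  # severity factor induces the negative IVC-RV correlation
  expect_lt(cor(pmdi$ivc_d_l, pmdi$rv_l), -0.3)
})

test_that("every generated row satisfies the maneuver and volume invariants", {
  co <- generate_cohort(cohort_config(n_per_group = 200), seed = 11)
  expect_true(all(co$ivc_d_l > 0 & co$pif_d_lps > 0 & co$t_in_s > 0 &
                    co$t_bh_s >= 0))
  expect_true(all(co$ivc_d_l <= co$pif_d_lps * co$t_in_s * (1 + 1e-9)))
  expect_true(all(co$rv_l < co$frc_l & co$frc_l < co$tlc_l))
  expect_true(all(co$rv_l + co$ivc_d_l <= co$tlc_l + 1e-9))
  # pMDI products share their maneuvers within subject and repetition
  foster <- co[co$device == "Foster_pMDI", ]
  trimbow <- co[co$device == "Trimbow_pMDI", ]
  expect_equal(foster$ivc_d_l, trimbow$ivc_d_l)
})

test_that("impossible configurations are rejected", {
  expect_error(
    cohort_config(floors = c(ivc_d = 50, pif_d = 0.3, t_in = 0.5, t_bh = 0)),
    "impossible")
  expect_error(cohort_config(severity_cor = 1.2), "< 1")
})

test_that("tiny end-to-end fixture completes, conserves mass and keeps schema", {
  st <- run_study(cohort_config(n_per_group = 3), n_particles = 800,
                  seed = 5)
  expect_equal(nrow(st$cohort), 3 * 3 * 3 * 2)
  expect_true(all(abs(st$results$pd_pct + st$results$etd_pct +
                        st$results$exhaled_pct - 100) < 1e-9))
  expect_equal(nrow(st$repeatability), 18) # 3 groups x 2 sites x 3 devices
  expect_setequal(names(st$rank_counts),
                  c("group", "device", "rank", "n_subjects"))
  expect_true(all(table(st$ranks$subject_id) == 3))
})

test_that("with zero CV and shared engine streams the CR is exactly zero", {
  st <- run_study(cohort_config(n_per_group = 3, intra_cv = 0),
                  n_particles = 500, seed = 7, repetition_in_seed = FALSE)
  expect_true(all(st$repeatability$cr == 0))
  expect_true(all(st$repeatability$bias == 0))
})

test_that("larger intra-subject CV degrades repeatability", {
  crs <- vapply(c(0.02, 0.08, 0.25), function(cv) {
    st <- run_study(cohort_config(n_per_group = 8, intra_cv = cv),
                    n_particles = 700, seed = 13,
                    repetition_in_seed = FALSE)
    stats::median(st$repeatability$cr[st$repeatability$site == "lung"])
  }, numeric(1))
  expect_true(all(diff(crs) > 0))
})
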