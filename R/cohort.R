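#' Synthetic cohort configuration
#'
#' Targets and dispersion settings for the synthetic maneuver cohort. The
#' defaults emulate the published group-level maneuver and lung-function
#' statistics (see [maneuver_reference()], [lung_function_reference()]):
#' subject-level parameters are drawn truncated-normal around the group
#' means with SD = SEM * sqrt(n_published); percent-predicted lung volumes
#' are converted to litres with configurable adult reference volumes; a
#' common latent severity factor induces the negative correlation between
#' inspiratory capacity and residual volume; the second repetition of each
#' maneuver is the first times mean-one lognormal noise with the configured
#' intra-subject coefficient of variation.
#'
#' The intra-subject between-repetition CV is not published; the default
#' 0.08 is chosen so synthetic Bland-Altman coefficients of repeatability
#' land in the single-digit percentage-point range reported for deposition
#' repeatability.
#'
#' @param maneuvers Maneuver target table, format of [maneuver_reference()].
#' @param lung_function Lung-volume target table, format of
#'   [lung_function_reference()].
#' @param n_per_group `NULL` (use published group sizes) or a named vector /
#'   single number of subjects per group.
#' @param intra_cv Intra-subject between-repetition coefficient of
#'   variation.
#' @param severity_cor Target magnitude of the severity-driven correlation
#'   between through-device inspiratory capacity and residual volume.
#' @param tlc_ref_l,rv_ref_l,frc_ref_l Adult reference volumes (litres) that
#'   convert percent-predicted targets to absolute volumes.
#' @param floors Named numeric physiologic floors used to truncate draws.
#' @return A list of class `"cohort_config"`.
#' @examples
#' cohort_config(intra_cv = 0)$intra_cv
#' @export
cohort_config <- function(maneuvers = maneuver_reference(),
                          lung_function = lung_function_reference(),
                          n_per_group = NULL,
                          intra_cv = 0.08,
                          severity_cor = 0.6,
                          tlc_ref_l = 6.0,
                          rv_ref_l = 2.0,
                          frc_ref_l = 3.0,
                          floors = c(ivc_d = 0.5, pif_d = 0.3,
                                     t_in = 0.5, t_bh = 0)) {
  check_number(intra_cv, "intra_cv", min = 0)
  check_number(severity_cor, "severity_cor", min = 0)
  if (severity_cor >= 1) bad_input("`severity_cor` must be < 1.")
  for (nm in c("tlc_ref_l", "rv_ref_l", "frc_ref_l")) {
    check_number(get(nm), nm, min = 0, strict = TRUE)
  }
  if (any(maneuvers$n < 2)) bad_input("published group sizes must be >= 2.")
  # impossible configs: a floor above mean + 4 SD leaves no sampling mass
  mus <- list(ivc_d = maneuvers$ivc_d_l, pif_d = maneuvers$pif_d_lps,
              t_in = maneuvers$t_in_s)
  for (p in names(mus)) {
    sdv <- maneuvers[[paste0(p, "_sem")]] * sqrt(maneuvers$n)
    if (any(floors[[p]] > mus[[p]] + 4 * sdv)) {
      bad_input(sprintf("floor for %s lies above mean + 4 SD; config impossible.", p))
    }
  }
  structure(list(
    maneuvers = maneuvers, lung_function = lung_function,
    n_per_group = n_per_group, intra_cv = intra_cv,
    severity_cor = severity_cor, tlc_ref_l = tlc_ref_l,
    rv_ref_l = rv_ref_l, frc_ref_l = frc_ref_l, floors = floors
  ), class = "cohort_config")
}

# truncated-normal draw by resampling below `floor`; max 100 rounds, then
# clamp to the floor (floors sit several SD below the means, so the clamp is
# essentially never reached with default targets)
rtrunc_norm <- function(n, mean, sd, floor) {
  x <- rnorm(n, mean, sd)
  for (i in seq_len(100)) {
    bad <- x < floor
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), if (length(mean) > 1) mean[bad] else mean,
                    if (length(sd) > 1) sd[bad] else sd)
  }
  pmax(x, floor)
}

# mix a latent factor z into iid noise so the result is standard normal
# with loading `lambda` on z
load_latent <- function(z, lambda) {
  lambda * z + sqrt(1 - lambda^2) * rnorm(length(z))
}

#' Generate a synthetic through-device maneuver cohort
#'
#' Draws subjects per group, two device classes per subject (the two pMDI
#' products share their maneuvers, as they were recorded through the same
#' placebo pMDI), two repetitions per device. Subject parameters are
#' truncated-normal around the group targets with SD = SEM * sqrt(n);
#' repetition 2 equals repetition 1 times mean-one lognormal noise with the
#' configured intra-subject CV. Maneuver feasibility (`ivc_d <= pif_d *
#' t_in`) is enforced by redrawing the inhalation time conditional on the
#' subject's inspiratory capacity and peak flow (so the IVC and PIF
#' marginals, which carry the published targets, are untouched); after 100
#' failed redraws the inhalation time is clamped. Residual volume is capped
#' so that `rv + ivc_d <= tlc` for every generated row.
#'
#' @param config A [cohort_config()].
#' @param seed Master seed; a fixed seed gives a byte-identical table.
#' @param groups Subset of groups to generate (default: all).
#' @return Tibble with one row per subject x device x repetition, columns
#'   `subject_id`, `group`, `device`, `repetition`, `ivc_d_l`, `pif_d_lps`,
#'   `t_in_s`, `t_bh_s`, `rv_l`, `tlc_l`, `frc_l`.
#' @examples
#' generate_cohort(cohort_config(n_per_group = 3), seed = 1)
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1,
                            groups = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    lam <- sqrt(config$severity_cor)
    man <- config$maneuvers
    lf <- config$lung_function
    group_names <- unique(man$group)
    if (!is.null(groups)) group_names <- intersect(group_names, groups)
    prefix <- c("Control" = "C", "S-COPD" = "S", "AE-COPD" = "A")

    out <- purrr::map_dfr(group_names, function(gname) {
      g_man <- man[man$group == gname, ]
      g_lf <- lf[lf$group == gname, ]
      n_pub <- g_man$n[1]
      n_sub <- if (is.null(config$n_per_group)) {
        n_pub
      } else if (length(config$n_per_group) == 1 &&
                 is.null(names(config$n_per_group))) {
        as.integer(config$n_per_group)
      } else {
        as.integer(config$n_per_group[[gname]])
      }

      z <- rnorm(n_sub) # latent severity, higher = worse

      # lung volumes (L): severity raises RV/FRC and, weakly, TLC
      vol <- function(pct, sem, ref, loading) {
        mu <- pct / 100 * ref
        sdv <- sem * sqrt(n_pub) / 100 * ref
        mu + sdv * load_latent(z, loading)
      }
      tlc <- pmax(vol(g_lf$tlc_pctpred, g_lf$tlc_sem, config$tlc_ref_l,
                      lam / 2), 2.5)
      rv <- rtrunc_norm_latent(
        n = n_sub, z = z, lambda = lam,
        mean = g_lf$rv_pctpred / 100 * config$rv_ref_l,
        sd = g_lf$rv_sem * sqrt(n_pub) / 100 * config$rv_ref_l,
        floor = 0.5)
      frc <- rtrunc_norm_latent(
        n = n_sub, z = z, lambda = lam,
        mean = g_lf$frc_pctpred / 100 * config$frc_ref_l,
        sd = g_lf$frc_sem * sqrt(n_pub) / 100 * config$frc_ref_l,
        floor = 0.6)

      per_class <- purrr::map(c("pMDI", "SMI"), function(cls) {
        r <- g_man[g_man$device_class == cls, ]
        sdv <- function(sem) sem * sqrt(n_pub)
        ivc <- rtrunc_norm_latent(n_sub, z, -lam, r$ivc_d_l,
                                  sdv(r$ivc_d_sem),
                                  config$floors[["ivc_d"]])
        pif <- rtrunc_norm_latent(n_sub, z, -lam, r$pif_d_lps,
                                  sdv(r$pif_d_sem),
                                  config$floors[["pif_d"]])
        tin <- rtrunc_norm(n_sub, r$t_in_s, sdv(r$t_in_sem),
                           config$floors[["t_in"]])
        tbh <- rtrunc_norm(n_sub, r$t_bh_s, sdv(r$t_bh_sem),
                           config$floors[["t_bh"]])
        # feasibility: redraw t_in until ivc <= pif * t_in
        tin <- repair_t_in(tin, ivc, pif, r$t_in_s, sdv(r$t_in_sem),
                           config$floors[["t_in"]])
        rep1 <- tibble(ivc_d_l = ivc, pif_d_lps = pif, t_in_s = tin,
                       t_bh_s = tbh)
        rep2 <- if (config$intra_cv == 0) {
          rep1
        } else {
          sdlog <- sqrt(log1p(config$intra_cv^2))
          noise <- function() rlnorm(n_sub, -sdlog^2 / 2, sdlog)
          r2 <- tibble(
            ivc_d_l = ivc * noise(), pif_d_lps = pif * noise(),
            t_in_s = pmax(tin * noise(), config$floors[["t_in"]]),
            t_bh_s = tbh * noise()
          )
          r2$t_in_s <- repair_t_in(r2$t_in_s, r2$ivc_d_l, r2$pif_d_lps,
                                   r$t_in_s, sdv(r$t_in_sem),
                                   config$floors[["t_in"]])
          r2
        }
        list(rep1 = rep1, rep2 = rep2)
      })
      names(per_class) <- c("pMDI", "SMI")

      # reconcile volumes so every row satisfies rv + ivc_d <= tlc with
      # rv >= 0.3 L: widen tlc for the rare subject whose drawn capacity
      # cannot hold the inhaled volume, then cap rv
      ivc_max <- pmax(per_class$pMDI$rep1$ivc_d_l, per_class$pMDI$rep2$ivc_d_l,
                      per_class$SMI$rep1$ivc_d_l, per_class$SMI$rep2$ivc_d_l)
      tlc <- pmax(tlc, ivc_max + 0.35)
      rv <- pmax(pmin(rv, tlc - ivc_max - 0.05), 0.3)
      frc <- pmin(pmax(frc, rv + 0.05), tlc - 0.05)

      sid <- sprintf("%s%03d", prefix[[gname]], seq_len(n_sub))
      class_of_device <- c(Foster_pMDI = "pMDI", Trimbow_pMDI = "pMDI",
                           Spiriva_Respimat = "SMI")
      purrr::map_dfr(device_levels(), function(dev) {
        cls <- class_of_device[[dev]]
        purrr::map_dfr(1:2, function(rep_i) {
          m <- per_class[[cls]][[paste0("rep", rep_i)]]
          tibble(subject_id = sid, group = gname, device = dev,
                 repetition = rep_i,
                 ivc_d_l = m$ivc_d_l, pif_d_lps = m$pif_d_lps,
                 t_in_s = m$t_in_s, t_bh_s = m$t_bh_s,
                 rv_l = rv, tlc_l = tlc, frc_l = frc)
        })
      })
    })
    dplyr::arrange(out, match(.data$group, group_names), .data$subject_id,
                   match(.data$device, device_levels()), .data$repetition)
  })
}

# truncated normal with a latent-factor loading: the systematic part
# (lambda * z) is kept, only the idiosyncratic part is redrawn on
# truncation, then clamped
rtrunc_norm_latent <- function(n, z, lambda, mean, sd, floor) {
  x <- mean + sd * load_latent(z, lambda)
  for (i in seq_len(100)) {
    bad <- x < floor
    if (!any(bad)) break
    x[bad] <- mean + sd * load_latent(z[bad], lambda)
  }
  pmax(x, floor)
}

# redraw t_in (only) until the maneuver is feasible; preserves the ivc/pif
# marginals that carry the published group targets
repair_t_in <- function(tin, ivc, pif, mu, sdv, floor) {
  need <- ivc / pif
  for (i in seq_len(100)) {
    bad <- tin < need
    if (!any(bad)) break
    tin[bad] <- pmax(rnorm(sum(bad), mu, sdv), floor)
  }
  ifelse(tin < need, need * 1.02, tin)
}

#' Run generator, engine and repeatability analysis end to end
#'
#' Small-scale orchestration used for integration checks: generates a
#' synthetic cohort, simulates every row, and computes the repeatability
#' grid and device ranks.
#'
#' @param config A [cohort_config()].
#' @param n_particles Particles per simulated row.
#' @param seed Master seed (cohort and engine streams are both derived from
#'   it).
#' @param aerosols Named list of [aerosol_spec()] per device.
#' @param repetition_in_seed See [run_cohort()].
#' @param ... Passed to [simulate_deposition()].
#' @return List with elements `cohort`, `results`, `repeatability`, `ranks`,
#'   `rank_counts`.
#' @export
run_study <- function(config = cohort_config(), n_particles = 2000,
                      seed = 1, aerosols = NULL,
                      repetition_in_seed = TRUE, ...) {
  cohort <- generate_cohort(config, seed = seed)
  results <- run_cohort(cohort, aerosols = aerosols,
                        n_particles = n_particles,
                        seed = derive_seed(seed, "engine"),
                        repetition_in_seed = repetition_in_seed, ...)
  repeat_tab <- repeatability_table(results)
  diffs <- repetition_differences(results, "lung")
  ranks <- rank_devices(diffs)
  list(cohort = cohort, results = results, repeatability = repeat_tab,
       ranks = ranks, rank_counts = rank_summary(ranks))
}
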