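#' Simulate whole-lung deposition of an inhaled aerosol
#'
#' Monte Carlo particle-tracking over stochastic airway paths. Each tracked
#' particle: (1) receives an aerodynamic diameter from the device's lognormal
#' size distribution and an entry time uniform over the device's emission
#' window; (2) faces an extrathoracic (mouth-throat) capture trial with
#' efficiency driven by the impaction parameter `d^2 Q` at the instantaneous
#' inspiratory flow; (3) if it survives, is advected along a freshly sampled
#' stochastic conducting + acinar path at the volumetric flow front, with a
#' per-airway deposition trial combining inertial impaction, gravitational
#' settling and Brownian diffusion; its penetration depth is limited by the
#' volume of air inhaled behind it; (4) undergoes settling and diffusion in
#' its segment of residence during the breath-hold; and (5) retraces its path
#' during exhalation with further deposition trials. Particles exiting the
#' trachea are counted as exhaled.
#'
#' Residence time in an airway is its (volume-scaled) geometric volume
#' divided by the local volumetric flow, the local flow being the mouth flow
#' times the product of flow fractions down the path. Airway linear
#' dimensions are rescaled to the instantaneous lung volume by
#' `(V / V_ref)^(1/3)`. In alveolated acinar airways, settling and diffusion
#' act over the effective alveolar capture radius in proportion to the
#' alveolar surface fraction.
#'
#' Reported fractions are percent of tracked (inhaled) particles; device and
#' mouthpiece retention are not modeled.
#'
#' @param ivc_d,pif_d,t_in,t_bh Through-device maneuver summaries (L, L/s, s,
#'   s); see [flow_profile()].
#' @param rv Subject residual volume, L (lung volume at start of maneuver).
#' @param tlc Total lung capacity, L; used only for a consistency warning.
#' @param aerosol An [aerosol_spec()], e.g. from [device_preset()].
#' @param n_particles Number of particles to track.
#' @param seed Optional integer seed (reproducible runs).
#' @param geom [airway_geometry()] configuration.
#' @param const [physics_constants()].
#' @param exhale_mult Exhalation duration multiplier, see [flow_profile()].
#' @param et_enabled Disable the extrathoracic filter (validation harness).
#' @param exhalation_enabled Disable the exhalation retrace (validation
#'   harness).
#' @param scale_geometry Rescale airway dimensions to instantaneous lung
#'   volume; disable for closed-form validation against fixed tubes.
#' @return An object of class `"deposition_result"`: a list with elements
#'   `pd_pct`, `etd_pct`, `exhaled_pct`, `se_pd`, `se_etd`, `per_generation`
#'   (tibble of percentages by airway generation), `n_particles`, `seed`.
#' @examples
#' simulate_deposition(3.36, 2.61, 2.23, 9.95, rv = 1.7,
#'                     aerosol = device_preset("Foster_pMDI"),
#'                     n_particles = 2000, seed = 1)
#' @export
simulate_deposition <- function(ivc_d, pif_d, t_in, t_bh,
                                rv = 2, tlc = Inf,
                                aerosol = device_preset("Foster_pMDI"),
                                n_particles = 10000, seed = NULL,
                                geom = airway_geometry(),
                                const = physics_constants(),
                                exhale_mult = 1,
                                et_enabled = TRUE,
                                exhalation_enabled = TRUE,
                                scale_geometry = TRUE) {
  stopifnot(inherits(aerosol, "aerosol_spec"))
  if (n_particles < 1) bad_input("`n_particles` must be >= 1.")
  n <- as.integer(n_particles)
  fp <- flow_profile(ivc_d, pif_d, t_in, t_bh, exhale_mult = exhale_mult)
  check_number(rv, "rv", min = 0, strict = TRUE)
  if (is.finite(tlc) && rv + fp$ivc_d > tlc + 0.1) {
    warn(sprintf("rv + ivc_d (%.2f L) exceeds tlc (%.2f L); check the subject record.",
                 rv + fp$ivc_d, tlc))
  }

  with_seed(seed, {
    # --- particles and entry times ------------------------------------
    part <- sample_particles(aerosol, n, seed = NULL, const = const)
    w <- c(max(0, aerosol$emission_window[1]),
           min(aerosol$emission_window[2], fp$t_in))
    if (w[2] <= w[1]) w <- c(0, fp$t_in)
    t0 <- runif(n, w[1], w[2])
    v0 <- v_inhale(fp, t0)
    q0_lpm <- q_inhale(fp, t0) * 60

    # --- extrathoracic filter -----------------------------------------
    dep_et <- if (et_enabled) {
      runif(n) < extrathoracic_efficiency(part$d_um, q0_lpm, const)
    } else {
      rep(FALSE, n)
    }

    # --- airway transit during inhalation -----------------------------
    g <- sample_path_matrices(n, geom, seed = NULL)
    n_seg <- g$n_seg
    alive <- !dep_et
    advancing <- alive
    t_cur <- t0
    v_cum <- v0
    cum_f <- rep(1, n)
    halt_col <- rep(NA_integer_, n)
    dep_col <- rep(NA_integer_, n)
    r_alv_m <- const$alveolar_radius_cm * 1e-2
    # stored for breath-hold and exhalation
    dia_s <- matrix(0, n, n_seg)
    dw <- matrix(0, n, n_seg) # crossing volume at the mouth, L

    for (j in seq_len(n_seg)) {
      act <- advancing & g$mask[, j]
      if (!any(act)) next
      s <- if (scale_geometry) {
        ((rv + v_cum) / geom$v_ref_l)^(1 / 3)
      } else {
        rep(1, n)
      }
      cum_f_j <- cum_f * g$f_local[, j]
      d_j <- g$dia[, j] * s
      vol_l <- (pi / 4) * d_j^2 * (g$len[, j] * s) * 1e-3 # cm^3 -> L
      dw_j <- vol_l / cum_f_j
      dia_s[, j] <- d_j
      dw[, j] <- dw_j

      v_target <- v_cum + dw_j
      passes <- act & (v_target < fp$ivc_d)
      halts <- act & !passes
      t_next <- t_at_v_inhale(fp, pmin(v_target, fp$ivc_d))
      t_res <- ifelse(passes, pmax(t_next - t_cur, 0),
                      pmax(fp$t_in - t_cur, 0))
      t_res[!act] <- 0
      # mean local (per-tube) flow while the particle is in the segment
      vol_crossed <- ifelse(passes, dw_j, pmax(fp$ivc_d - v_cum, 0)) * cum_f_j
      q_tube <- ifelse(t_res > 0, vol_crossed / t_res, 0) # L/s
      u_ms <- q_tube * 1e-3 / ((pi / 4) * (pmax(d_j, 1e-9) * 1e-2)^2)

      st <- stokes_number(part$d_um, pmax(u_ms, 0), pmax(d_j, 1e-9),
                          aerosol$density, const)
      p_i <- prob_impaction(pmax(st, 0), g$theta[, j])
      a <- g$alv[, j]
      p_s_tube <- prob_sedimentation(pmax(d_j, 1e-9), part$v_s,
                                     g$cos_phi[, j], t_res)
      p_d_tube <- prob_diffusion(pmax(d_j * 1e-2 / 2, 1e-9), part$d_diff,
                                 t_res, const)
      p_s_alv <- 1 - exp(-part$v_s * t_res / r_alv_m)
      p_d_alv <- 1 - exp(-const$k_geo * part$d_diff * t_res / r_alv_m^2)
      p_s <- (1 - a) * p_s_tube + a * p_s_alv
      p_d <- (1 - a) * p_d_tube + a * p_d_alv
      p <- combine_mechanisms(p_i, p_s, p_d)

      dep <- act & (runif(n) < p)
      dep_col[dep & is.na(dep_col)] <- j
      alive <- alive & !dep

      # advance survivors; halting particles stop here for the breath-hold
      halt_col[halts] <- j
      advancing <- advancing & passes
      t_cur <- ifelse(passes, t_next, t_cur)
      v_cum <- ifelse(passes, v_target, v_cum)
      cum_f <- ifelse(act, cum_f_j, cum_f)
      is_last <- if (j < n_seg) !g$mask[, j + 1L] else rep(TRUE, n)
      end_of_path <- advancing & g$mask[, j] & is_last
      halt_col[end_of_path] <- j
      advancing <- advancing & !end_of_path
    }
    halt_col[is.na(halt_col) & alive] <- 1L # never entered: sits at the top

    # --- breath-hold ---------------------------------------------------
    if (fp$t_bh > 0) {
      idx <- which(alive)
      if (length(idx)) {
        h <- halt_col[idx]
        pick <- cbind(idx, h)
        d_h <- pmax(dia_s[pick], 1e-9)
        a <- g$alv[pick]
        p_s_tube <- prob_sedimentation(d_h, part$v_s[idx], g$cos_phi[pick],
                                       fp$t_bh)
        p_d_tube <- prob_diffusion(d_h * 1e-2 / 2, part$d_diff[idx],
                                   fp$t_bh, const)
        p_s_alv <- 1 - exp(-part$v_s[idx] * fp$t_bh / r_alv_m)
        p_d_alv <- 1 - exp(-const$k_geo * part$d_diff[idx] * fp$t_bh / r_alv_m^2)
        p <- combine_mechanisms(0, (1 - a) * p_s_tube + a * p_s_alv,
                                (1 - a) * p_d_tube + a * p_d_alv)
        dep <- runif(length(idx)) < p
        dep_col[idx[dep]] <- h[dep]
        alive[idx[dep]] <- FALSE
      }
    }

    # --- exhalation retrace -------------------------------------------
    if (exhalation_enabled) {
      q_ex_mean <- fp$ivc_d / fp$t_ex # mean mouth flow, L/s
      for (j in rev(seq_len(n_seg))) {
        act <- alive & !is.na(halt_col) & (halt_col >= j) & g$mask[, j]
        if (!any(act)) next
        t_res <- ifelse(act, dw[, j] / q_ex_mean, 0)
        d_j <- pmax(dia_s[, j], 1e-9)
        # the air column clears the (scaled) tube length in t_res
        len_scaled_m <- g$len[, j] * (d_j / pmax(g$dia[, j], 1e-12)) * 1e-2
        u_ms <- ifelse(t_res > 0, len_scaled_m / t_res, 0)
        st <- stokes_number(part$d_um, pmax(u_ms, 0), d_j,
                            aerosol$density, const)
        p_i <- prob_impaction(pmax(st, 0), g$theta[, j])
        a <- g$alv[, j]
        p_s_tube <- prob_sedimentation(d_j, part$v_s, g$cos_phi[, j], t_res)
        p_d_tube <- prob_diffusion(d_j * 1e-2 / 2, part$d_diff, t_res, const)
        p_s_alv <- 1 - exp(-part$v_s * t_res / r_alv_m)
        p_d_alv <- 1 - exp(-const$k_geo * part$d_diff * t_res / r_alv_m^2)
        p <- combine_mechanisms(p_i, (1 - a) * p_s_tube + a * p_s_alv,
                                (1 - a) * p_d_tube + a * p_d_alv)
        dep <- act & (runif(n) < p)
        dep_col[dep] <- j
        alive <- alive & !dep
      }
    }

    exhaled <- alive

    # --- tally ---------------------------------------------------------
    lab <- rep(NA_character_, n)
    has_dep <- !is.na(dep_col)
    cond_dep <- has_dep & (dep_col <= g$n_cond)
    lab[cond_dep] <- paste0("G", dep_col[cond_dep] - 1L)
    acin_dep <- has_dep & (dep_col > g$n_cond)
    lab[acin_dep] <- paste0("A", dep_col[acin_dep] - g$n_cond[acin_dep])
    lab[dep_et] <- "ET"
    lab[exhaled] <- "exhaled"

    cond_levels <- paste0("G", 0:(max(g$n_cond) - 1L))
    acin_levels <- if (is.null(geom$acinar)) character(0) else
      paste0("A", seq_len(nrow(geom$acinar)))
    levels <- c("ET", cond_levels, acin_levels, "exhaled")
    counts <- table(factor(lab, levels = levels))
    pct <- as.numeric(counts) / n * 100

    etd_pct <- pct[1]
    exhaled_pct <- pct[length(pct)]
    pd_pct <- 100 - etd_pct - exhaled_pct
    se <- function(p) sqrt(p / 100 * (1 - p / 100) / n) * 100
    per_gen <- tibble(
      region = c("extrathoracic",
                 rep("conducting", length(cond_levels)),
                 rep("acinar", length(acin_levels)),
                 "exhaled"),
      generation = levels,
      pct = pct
    )
    structure(list(
      pd_pct = pd_pct, etd_pct = etd_pct, exhaled_pct = exhaled_pct,
      se_pd = se(pd_pct), se_etd = se(etd_pct),
      per_generation = per_gen,
      n_particles = n, seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      device = aerosol$label
    ), class = "deposition_result")
  })
}

#' @export
print.deposition_result <- function(x, ...) {
  cat(sprintf(
    "<deposition_result '%s': PD %.2f%% (SE %.2f), ETD %.2f%% (SE %.2f), exhaled %.2f%%; N=%d>\n",
    x$device, x$pd_pct, x$se_pd, x$etd_pct, x$se_etd, x$exhaled_pct,
    x$n_particles))
  invisible(x)
}

#' Tidy per-generation deposition fractions
#'
#' @param x A `deposition_result`.
#' @param ... Unused.
#' @return Tibble with columns `region`, `generation`, `pct`.
#' @method tidy deposition_result
#' @export
tidy.deposition_result <- function(x, ...) x$per_generation

#' One-row summary of a deposition result
#'
#' @param x A `deposition_result`.
#' @param ... Unused.
#' @return One-row tibble with `pd_pct`, `etd_pct`, `exhaled_pct`, `se_pd`,
#'   `se_etd`, `n_particles`.
#' @method glance deposition_result
#' @export
glance.deposition_result <- function(x, ...) {
  tibble(pd_pct = x$pd_pct, etd_pct = x$etd_pct, exhaled_pct = x$exhaled_pct,
         se_pd = x$se_pd, se_etd = x$se_etd, n_particles = x$n_particles)
}

#' @rdname tidy.deposition_result
#' @param object A `deposition_result`.
#' @method autoplot deposition_result
#' @export
autoplot.deposition_result <- function(object, ...) {
  dat <- object$per_generation
  dat$generation <- factor(dat$generation, levels = dat$generation)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$generation, y = .data$pct,
                                    fill = .data$region)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of tracked dose", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Average deposition over the two repeated maneuvers
#'
#' Deposition is computed from the first and the second inhalation maneuver
#' and their arithmetic mean is used for further statistical analysis.
#'
#' @param first,second `deposition_result` objects.
#' @return One-row tibble with `pd_mean`, `etd_mean`.
#' @examples
#' a <- simulate_deposition(3.3, 2.6, 2.2, 10, aerosol = device_preset("Foster_pMDI"),
#'                          n_particles = 500, seed = 1)
#' b <- simulate_deposition(3.4, 2.7, 2.3, 10, aerosol = device_preset("Foster_pMDI"),
#'                          n_particles = 500, seed = 2)
#' mean_of_two(a, b)
#' @export
mean_of_two <- function(first, second) {
  stopifnot(inherits(first, "deposition_result"),
            inherits(second, "deposition_result"))
  tibble(pd_mean = (first$pd_pct + second$pd_pct) / 2,
         etd_mean = (first$etd_pct + second$etd_pct) / 2)
}

#' Run the deposition engine over a cohort table
#'
#' Simulates every subject x device x repetition row of a maneuver table (the
#' format produced by [generate_cohort()]) and returns a long results table.
#' Each row gets its own RNG stream derived from the master seed by stable
#' hashing of `subject_id/device/repetition`, so results are independent of
#' row order.
#'
#' @param data Tibble with columns `subject_id`, `group`, `device`,
#'   `repetition`, `ivc_d_l`, `pif_d_lps`, `t_in_s`, `t_bh_s`, `rv_l`,
#'   `tlc_l`.
#' @param aerosols Named list mapping device name to [aerosol_spec()];
#'   defaults to the packaged presets.
#' @param n_particles Particles per row.
#' @param seed Master seed.
#' @param repetition_in_seed Include the repetition index in the per-row
#'   stream key. Set `FALSE` to give both repetitions of a subject/device the
#'   same engine stream, isolating maneuver variability from Monte Carlo
#'   noise.
#' @param ... Passed to [simulate_deposition()] (e.g. `geom`, `const`).
#' @return `data` with columns `pd_pct`, `etd_pct`, `exhaled_pct`, `se_pd`,
#'   `se_etd` appended. Rows that fail to simulate are reported in a warning
#'   and carried with `NA` results.
#' @export
run_cohort <- function(data,
                       aerosols = NULL,
                       n_particles = 10000, seed = 1,
                       repetition_in_seed = TRUE, ...) {
  req <- c("subject_id", "group", "device", "repetition", "ivc_d_l",
           "pif_d_lps", "t_in_s", "t_bh_s", "rv_l", "tlc_l")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    bad_input(paste0("`data` lacks columns: ",
                     paste(missing_cols, collapse = ", ")))
  }
  if (is.null(aerosols)) {
    aerosols <- stats::setNames(lapply(device_levels(), device_preset),
                                device_levels())
  }
  failures <- character(0)
  res <- purrr::pmap(
    list(data$subject_id, data$device, data$repetition,
         data$ivc_d_l, data$pif_d_lps, data$t_in_s, data$t_bh_s,
         data$rv_l, data$tlc_l),
    function(sid, dev, rep_i, ivc, pif, tin, tbh, rv, tlc) {
      key <- if (repetition_in_seed) {
        paste(sid, dev, rep_i, sep = "/")
      } else {
        paste(sid, dev, sep = "/")
      }
      spec <- aerosols[[dev]]
      if (is.null(spec)) {
        failures <<- c(failures, sprintf("%s: unknown device '%s'", sid, dev))
        return(tibble(pd_pct = NA_real_, etd_pct = NA_real_,
                      exhaled_pct = NA_real_, se_pd = NA_real_,
                      se_etd = NA_real_))
      }
      out <- tryCatch(
        simulate_deposition(ivc, pif, tin, tbh, rv = rv, tlc = tlc,
                            aerosol = spec, n_particles = n_particles,
                            seed = derive_seed(seed, key), ...),
        error = function(e) e
      )
      if (inherits(out, "error")) {
        failures <<- c(failures,
                       sprintf("%s/%s/rep%s: %s", sid, dev, rep_i,
                               conditionMessage(out)))
        return(tibble(pd_pct = NA_real_, etd_pct = NA_real_,
                      exhaled_pct = NA_real_, se_pd = NA_real_,
                      se_etd = NA_real_))
      }
      glance.deposition_result(out)[, c("pd_pct", "etd_pct", "exhaled_pct",
                                        "se_pd", "se_etd")]
    }
  )
  if (length(failures)) {
    warn(paste0("Some rows could not be simulated:\n  ",
                paste(failures, collapse = "\n  ")))
  }
  dplyr::bind_cols(as_tibble(data), dplyr::bind_rows(res))
}

#' Per-subject mean deposition across repetitions
#'
#' Convenience wrapper computing the repetition means used by the
#' repeatability analysis.
#'
#' @param results Output of [run_cohort()].
#' @return Tibble keyed by `subject_id`, `group`, `device` with `pd_mean`,
#'   `etd_mean`.
#' @export
average_repetitions <- function(results) {
  results |>
    dplyr::group_by(.data$subject_id, .data$group, .data$device) |>
    dplyr::summarise(pd_mean = mean(.data$pd_pct),
                     etd_mean = mean(.data$etd_pct), .groups = "drop")
}
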