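#' Build a time-resolved flow profile from through-device maneuver summaries
#'
#' A spirometer trace behind an inhaler is summarized by four numbers: the
#' inhaled volume `ivc_d` (L), the peak inspiratory flow `pif_d` (L/s), the
#' inhalation time `t_in` (s) and the breath-hold time `t_bh` (s). This
#' function reconstructs a continuous inspiratory flow profile `Q(t)` that
#' reproduces all three flow summaries exactly, appends a zero-flow
#' breath-hold and a passive exhalation phase.
#'
#' Two profile families cover all feasible summaries:
#' * `ivc_d / pif_d >= t_in / 2`: a symmetric trapezoid with ramp time
#'   `t_in - ivc_d / pif_d`;
#' * otherwise (a "spiky" breath whose mean flow is well below its peak): a
#'   linear rise to `pif_d` over `0.1 t_in` followed by an exponential decay
#'   whose time constant is solved numerically so the inhaled volume equals
#'   `ivc_d` (bracketed root find, tolerance 1e-9 L).
#'
#' Exhalation is the time-reversed inhalation profile stretched by
#' `exhale_mult` (flow scaled down correspondingly), so its duration is
#' `exhale_mult * t_in` and its volume is `ivc_d`.
#'
#' @param ivc_d Through-device inspiratory vital capacity, L.
#' @param pif_d Through-device peak inspiratory flow, L/s.
#' @param t_in Inhalation time, s.
#' @param t_bh Breath-hold time, s (>= 0).
#' @param exhale_mult Exhalation duration as a multiple of `t_in`.
#' @param feasibility_tol Relative slack allowed on `ivc_d <= pif_d * t_in`
#'   before the maneuver is rejected; absorbs rounding of printed inputs.
#' @return An object of class `"flow_profile"`. Use [flow_at()],
#'   [volume_at()], [time_at_volume()] and [tidy.flow_profile()] to query it.
#' @examples
#' fp <- flow_profile(ivc_d = 3.36, pif_d = 2.61, t_in = 2.23, t_bh = 9.95)
#' fp$t_ramp
#' volume_at(fp, fp$t_in) # = ivc_d
#' @export
flow_profile <- function(ivc_d, pif_d, t_in, t_bh,
                         exhale_mult = 1, feasibility_tol = 0.01) {
  check_number(ivc_d, "ivc_d", min = 0, strict = TRUE)
  check_number(pif_d, "pif_d", min = 0, strict = TRUE)
  check_number(t_in, "t_in", min = 0, strict = TRUE)
  check_number(t_bh, "t_bh", min = 0)
  check_number(exhale_mult, "exhale_mult", min = 0, strict = TRUE)

  if (ivc_d > pif_d * t_in * (1 + feasibility_tol)) {
    bad_input(sprintf(
      paste0("Infeasible maneuver: ivc_d (%.4g L) exceeds pif_d * t_in ",
             "(%.4g L/s * %.4g s = %.4g L); the inhaled volume cannot ",
             "exceed peak flow times inhalation time."),
      ivc_d, pif_d, t_in, pif_d * t_in))
  }
  # within tolerance: clamp to the rectangular boundary
  ivc_eff <- min(ivc_d, pif_d * t_in)

  if (ivc_eff / pif_d >= t_in / 2) {
    family <- "trapezoid"
    t_ramp <- t_in - ivc_eff / pif_d # in [0, t_in/2]
    pars <- list(t_ramp = t_ramp)
  } else {
    family <- "spike"
    t_rise <- 0.1 * t_in
    if (ivc_eff <= pif_d * t_rise / 2 * 1.1) {
      # extremely small inhaled volume: shrink the rise so half the volume
      # sits in the rise, half in the decay
      t_rise <- ivc_eff / pif_d
    }
    v_decay <- ivc_eff - pif_d * t_rise / 2
    delta <- t_in - t_rise
    # pif * tau * (1 - exp(-delta/tau)) = v_decay, monotone increasing in tau
    f <- function(tau) pif_d * tau * (1 - exp(-delta / tau)) - v_decay
    tau <- uniroot(f, lower = 1e-9, upper = 1e6, tol = 1e-12)$root
    pars <- list(t_rise = t_rise, tau = tau)
  }

  structure(
    c(list(
      ivc_d = ivc_eff, pif_d = pif_d, t_in = t_in, t_bh = t_bh,
      t_ex = exhale_mult * t_in, exhale_mult = exhale_mult,
      family = family,
      t_end_bh = t_in + t_bh,
      t_end = t_in + t_bh + exhale_mult * t_in
    ), pars),
    class = "flow_profile"
  )
}

#' @export
print.flow_profile <- function(x, ...) {
  cat(sprintf(
    "<flow_profile: %s; ivc_d %.3g L, pif_d %.3g L/s, t_in %.3g s, t_bh %.3g s>\n",
    x$family, x$ivc_d, x$pif_d, x$t_in, x$t_bh))
  invisible(x)
}

# inspiratory flow, inhalation phase only (t clipped to [0, t_in])
q_inhale <- function(fp, t) {
  t <- pmin(pmax(t, 0), fp$t_in)
  if (fp$family == "trapezoid") {
    tr <- fp$t_ramp
    if (tr <= 0) return(rep(fp$pif_d, length(t)))
    q <- ifelse(t < tr, fp$pif_d * t / tr,
         ifelse(t <= fp$t_in - tr, fp$pif_d,
                fp$pif_d * (fp$t_in - t) / tr))
  } else {
    q <- ifelse(t <= fp$t_rise,
                if (fp$t_rise > 0) fp$pif_d * t / fp$t_rise else fp$pif_d,
                fp$pif_d * exp(-(t - fp$t_rise) / fp$tau))
  }
  q
}

# cumulative inhaled volume during inhalation (analytic)
v_inhale <- function(fp, t) {
  t <- pmin(pmax(t, 0), fp$t_in)
  if (fp$family == "trapezoid") {
    tr <- fp$t_ramp
    if (tr <= 0) return(fp$pif_d * t)
    ifelse(t < tr, fp$pif_d * t^2 / (2 * tr),
    ifelse(t <= fp$t_in - tr, fp$pif_d * (t - tr / 2),
           fp$ivc_d - fp$pif_d * (fp$t_in - t)^2 / (2 * tr)))
  } else {
    v_rise <- fp$pif_d * fp$t_rise / 2
    ifelse(t <= fp$t_rise,
           if (fp$t_rise > 0) fp$pif_d * t^2 / (2 * fp$t_rise) else 0,
           v_rise + fp$pif_d * fp$tau * (1 - exp(-(t - fp$t_rise) / fp$tau)))
  }
}

# analytic inverse of v_inhale: time at which cumulative inhaled volume
# first reaches v (v clipped to [0, ivc_d]); vectorized, NA-free
t_at_v_inhale <- function(fp, v) {
  v <- pmin(pmax(v, 0), fp$ivc_d)
  if (fp$family == "trapezoid") {
    tr <- fp$t_ramp
    if (tr <= 0) return(v / fp$pif_d)
    v1 <- fp$pif_d * tr / 2
    ifelse(v <= v1, sqrt(pmax(2 * v * tr / fp$pif_d, 0)),
    ifelse(v <= fp$ivc_d - v1, v / fp$pif_d + tr / 2,
           fp$t_in - sqrt(pmax(2 * (fp$ivc_d - v) * tr / fp$pif_d, 0))))
  } else {
    v_rise <- fp$pif_d * fp$t_rise / 2
    v_decay_tot <- fp$pif_d * fp$tau * (1 - exp(-(fp$t_in - fp$t_rise) / fp$tau))
    frac <- pmin((v - v_rise) / (fp$pif_d * fp$tau), 1 - 1e-15)
    ifelse(v <= v_rise,
           if (fp$t_rise > 0) sqrt(pmax(2 * v * fp$t_rise / fp$pif_d, 0)) else 0,
           ifelse(v - v_rise >= v_decay_tot, fp$t_in,
                  fp$t_rise - fp$tau * log1p(-frac)))
  }
}

#' Flow magnitude at time t
#'
#' Returns `|Q(t)|` over the full maneuver: inhalation, breath-hold (zero
#' flow) and exhalation. Times outside `[0, t_end]` give zero.
#'
#' @param fp A [flow_profile()].
#' @param t Time since start of inhalation, s (vectorized).
#' @return Flow, L/s.
#' @export
flow_at <- function(fp, t) {
  stopifnot(inherits(fp, "flow_profile"))
  q <- numeric(length(t))
  inh <- t >= 0 & t <= fp$t_in
  q[inh] <- q_inhale(fp, t[inh])
  exh <- t > fp$t_end_bh & t <= fp$t_end
  if (any(exh)) {
    u <- t[exh] - fp$t_end_bh
    q[exh] <- q_inhale(fp, fp$t_in - u / fp$exhale_mult) / fp$exhale_mult
  }
  q
}

#' Cumulative inhaled volume at time t
#'
#' Volume of air in the lung above the starting volume: increases to `ivc_d`
#' during inhalation, constant during breath-hold, returns to 0 during
#' exhalation.
#'
#' @inheritParams flow_at
#' @return Volume above start-of-inhalation lung volume, L.
#' @export
volume_at <- function(fp, t) {
  stopifnot(inherits(fp, "flow_profile"))
  v <- numeric(length(t))
  inh <- t >= 0 & t <= fp$t_in
  v[inh] <- v_inhale(fp, t[inh])
  bh <- t > fp$t_in & t <= fp$t_end_bh
  v[bh] <- fp$ivc_d
  exh <- t > fp$t_end_bh & t <= fp$t_end
  if (any(exh)) {
    u <- t[exh] - fp$t_end_bh
    v[exh] <- v_inhale(fp, fp$t_in - u / fp$exhale_mult)
  }
  v
}

#' Time at which a given volume has been inhaled
#'
#' Analytic inverse of the inhalation-phase cumulative volume; used by the
#' Monte Carlo engine to convert volumetric particle positions into segment
#' entry times. Volumes above `ivc_d` map to `t_in`.
#'
#' @param fp A [flow_profile()].
#' @param v Inhaled volume, L (vectorized).
#' @return Time since start of inhalation, s.
#' @export
time_at_volume <- function(fp, v) {
  stopifnot(inherits(fp, "flow_profile"))
  t_at_v_inhale(fp, v)
}

#' Lung volume trajectory for a subject
#'
#' Combines a flow profile with a subject's lung volumes: the maneuver starts
#' from residual volume after a long exhalation, so the absolute lung volume
#' is `V(t) = rv + ` cumulative inhaled volume. Warns (not fatal) when
#' `rv + ivc_d` exceeds `tlc` by more than 0.1 L, which indicates an
#' inconsistent subject record.
#'
#' @param fp A [flow_profile()].
#' @param rv Residual volume, L.
#' @param tlc Total lung capacity, L (used only for the consistency check).
#' @return A function `t -> lung volume (L)`, vectorized over `t`.
#' @examples
#' fp <- flow_profile(3.36, 2.61, 2.23, 9.95)
#' V <- lung_volume_trajectory(fp, rv = 2, tlc = 6)
#' V(fp$t_in)
#' @export
lung_volume_trajectory <- function(fp, rv, tlc = Inf) {
  stopifnot(inherits(fp, "flow_profile"))
  check_number(rv, "rv", min = 0, strict = TRUE)
  if (is.finite(tlc) && rv + fp$ivc_d > tlc + 0.1) {
    warn(sprintf(
      "rv + ivc_d (%.2f L) exceeds tlc (%.2f L) by more than 0.1 L; subject record may be inconsistent.",
      rv + fp$ivc_d, tlc))
  }
  function(t) rv + volume_at(fp, t)
}

#' Isotropic geometry scale factor for lung inflation
#'
#' Airway lengths and diameters are rescaled from the morphometric reference
#' volume to the instantaneous lung volume by `(V / V_ref)^(1/3)`.
#'
#' @param v Lung volume, L (vectorized).
#' @param v_ref Reference volume of the morphometry tables, L.
#' @return Dimensionless multiplicative scale factor.
#' @examples
#' geometry_scale_factor(3, 4.8)
#' @export
geometry_scale_factor <- function(v, v_ref = 4.8) {
  if (any(v <= 0) || any(v_ref <= 0)) {
    bad_input("volumes must be positive.")
  }
  (v / v_ref)^(1 / 3)
}

#' Tidy a flow profile into a sampled time grid
#'
#' @param x A [flow_profile()].
#' @param n Number of grid points.
#' @param ... Unused.
#' @return A tibble with columns `time`, `flow`, `volume`, `phase`.
#' @method tidy flow_profile
#' @export
tidy.flow_profile <- function(x, n = 400, ...) {
  t <- seq(0, x$t_end, length.out = n)
  phase <- dplyr::case_when(
    t <= x$t_in ~ "inhalation",
    t <= x$t_end_bh ~ "breath_hold",
    TRUE ~ "exhalation"
  )
  tibble(time = t, flow = flow_at(x, t), volume = volume_at(x, t),
         phase = factor(phase, c("inhalation", "breath_hold", "exhalation")))
}

#' @rdname tidy.flow_profile
#' @param object A [flow_profile()].
#' @method autoplot flow_profile
#' @export
autoplot.flow_profile <- function(object, n = 400, ...) {
  dat <- tidy.flow_profile(object, n = n)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$flow,
                                    colour = .data$phase)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time (s)", y = "flow magnitude (L/s)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
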