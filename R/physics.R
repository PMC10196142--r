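#' Physical constants used by the deposition model
#'
#' Returns the constants entering the transport-property and deposition
#' probability formulas. All values are configurable through the `physics:`
#' block of a study configuration; the defaults describe air at body
#' temperature.
#'
#' @param viscosity Dynamic viscosity of air, Pa s.
#' @param mean_free_path Mean free path of air molecules, um.
#' @param g Gravitational acceleration, m/s^2.
#' @param boltzmann Boltzmann constant, J/K.
#' @param temperature Absolute temperature, K (body temperature).
#' @param k_geo Geometry constant of the first-mode diffusional loss term for
#'   a cylinder (dimensionless).
#' @param et_a,et_b Coefficients of the extrathoracic inertial impaction
#'   efficiency `1 - exp(-a * (d^2 Q)^b)` with `d` in um and `Q` in L/min.
#' @param et_volume_ml Mouth-throat compartment volume, mL.
#' @param et_radius_cm Effective mouth-throat radius, cm.
#' @param et_min_flow_lpm Floor on the flow used in the extrathoracic model,
#'   L/min; avoids a singular residence time when a particle is emitted at the
#'   very start of inhalation where the instantaneous flow is zero.
#' @param alveolar_radius_cm Effective alveolar capture radius, cm, used for
#'   settling/diffusion of particles pausing in alveolated airways.
#' @return A named list of constants, class `"physics_constants"`.
#' @examples
#' physics_constants()$viscosity
#' @export
physics_constants <- function(viscosity = 1.81e-5,
                              mean_free_path = 0.066,
                              g = 9.81,
                              boltzmann = 1.380649e-23,
                              temperature = 310,
                              k_geo = 5.784,
                              et_a = 1.1e-4,
                              et_b = 1.4,
                              et_volume_ml = 50,
                              et_radius_cm = 1,
                              et_min_flow_lpm = 0.5,
                              alveolar_radius_cm = 0.014) {
  vals <- list(
    viscosity = viscosity, mean_free_path = mean_free_path, g = g,
    boltzmann = boltzmann, temperature = temperature, k_geo = k_geo,
    et_a = et_a, et_b = et_b, et_volume_ml = et_volume_ml,
    et_radius_cm = et_radius_cm, et_min_flow_lpm = et_min_flow_lpm,
    alveolar_radius_cm = alveolar_radius_cm
  )
  for (nm in names(vals)) check_number(vals[[nm]], nm, min = 0, strict = TRUE)
  structure(vals, class = "physics_constants")
}

#' Cunningham slip correction factor
#'
#' Correction to Stokes drag for particles whose diameter is comparable to the
#' mean free path of air.
#'
#' @param d_um Aerodynamic particle diameter, um (vectorized).
#' @param const Physical constants, see [physics_constants()].
#' @return Dimensionless slip factor, `>= 1`.
#' @examples
#' cunningham(c(0.1, 1, 10))
#' @export
cunningham <- function(d_um, const = physics_constants()) {
  if (any(!is.finite(d_um)) || any(d_um <= 0)) {
    bad_input("`d_um` must be positive and finite.")
  }
  lam <- const$mean_free_path
  1 + (lam / d_um) * (2.514 + 0.8 * exp(-0.55 * d_um / lam))
}

#' Gravitational settling velocity
#'
#' Terminal settling velocity in the aerodynamic-diameter convention (unit
#' density particle): `v_s = rho g d^2 Cc / (18 mu)`.
#'
#' @inheritParams cunningham
#' @param rho_gcc Particle density, g/cm^3. 1.0 under the aerodynamic
#'   convention.
#' @return Settling velocity, m/s (vectorized over `d_um`).
#' @examples
#' settling_velocity(3)
#' @export
settling_velocity <- function(d_um, rho_gcc = 1, const = physics_constants()) {
  if (any(d_um < 0)) bad_input("`d_um` must be >= 0.")
  v <- numeric(length(d_um))
  pos <- d_um > 0
  d_m <- d_um[pos] * 1e-6
  cc <- cunningham(d_um[pos], const)
  v[pos] <- (rho_gcc * 1000) * const$g * d_m^2 * cc / (18 * const$viscosity)
  v
}

#' Brownian diffusion coefficient
#'
#' Stokes-Einstein diffusivity with slip correction:
#' `D = k_B T Cc / (3 pi mu d)`.
#'
#' @inheritParams cunningham
#' @return Diffusion coefficient, m^2/s (vectorized).
#' @examples
#' diffusion_coefficient(c(0.1, 1))
#' @export
diffusion_coefficient <- function(d_um, const = physics_constants()) {
  cc <- cunningham(d_um, const)
  const$boltzmann * const$temperature * cc /
    (3 * pi * const$viscosity * d_um * 1e-6)
}

#' Particle transport properties
#'
#' Bundles slip factor, settling velocity and diffusivity for a vector of
#' aerodynamic diameters into a tibble, one row per particle.
#'
#' @inheritParams settling_velocity
#' @return A tibble with columns `d_um`, `cc`, `v_s` (m/s), `d_diff` (m^2/s).
#' @examples
#' particle_properties(c(1, 3, 5))
#' @export
particle_properties <- function(d_um, rho_gcc = 1, const = physics_constants()) {
  tibble(
    d_um = d_um,
    cc = cunningham(d_um, const),
    v_s = settling_velocity(d_um, rho_gcc, const),
    d_diff = diffusion_coefficient(d_um, const)
  )
}

#' Stokes number in an airway
#'
#' Inertial impaction parameter `St = rho d^2 Cc U / (18 mu D)` with `U` the
#' mean air speed in the parent airway and `D` the airway diameter.
#'
#' @inheritParams settling_velocity
#' @param u_ms Mean airflow speed, m/s.
#' @param d_airway_cm Airway diameter, cm.
#' @return Dimensionless Stokes number (vectorized).
#' @export
stokes_number <- function(d_um, u_ms, d_airway_cm, rho_gcc = 1,
                          const = physics_constants()) {
  if (any(d_airway_cm <= 0)) bad_input("`d_airway_cm` must be > 0.")
  cc <- cunningham(pmax(d_um, 1e-12), const)
  (rho_gcc * 1000) * (d_um * 1e-6)^2 * cc * u_ms /
    (18 * const$viscosity * d_airway_cm * 1e-2)
}

#' Inertial impaction deposition probability at a bifurcation
#'
#' Closed-form impaction efficiency in terms of the Stokes number and the
#' branching angle: with `x = theta_rad * St`, the probability is
#' `1 - (2/pi) acos(x) - (1/pi) sin(2 acos(x))` for `x < 1` and 1 otherwise.
#'
#' @param st Stokes number (vectorized).
#' @param theta_deg Branching angle, degrees in `[0, 90]`.
#' @return Deposition probability in `[0, 1]`.
#' @examples
#' prob_impaction(0.5, 30)
#' @export
prob_impaction <- function(st, theta_deg) {
  if (any(st < 0)) bad_input("`st` must be >= 0.")
  if (any(theta_deg < 0)) bad_input("`theta_deg` must be >= 0.")
  x <- (theta_deg * pi / 180) * st
  p <- numeric(length(x))
  sat <- x >= 1
  p[sat] <- 1
  a <- acos(x[!sat])
  p[!sat] <- 1 - (2 / pi) * a - (1 / pi) * sin(2 * a)
  pmin(pmax(p, 0), 1)
}

#' Gravitational settling deposition probability in a tube
#'
#' `p = 1 - exp(-4 v_s |cos(phi)| t / (pi D))` with `D` the airway diameter
#' converted to metres and `phi` the gravity angle of the tube axis.
#'
#' @param d_airway_cm Airway diameter, cm.
#' @param v_s Settling velocity, m/s.
#' @param cos_phi Cosine of the gravity angle; the absolute value is used.
#' @param t_res Residence time, s.
#' @return Deposition probability in `[0, 1]` (vectorized).
#' @examples
#' prob_sedimentation(0.2, 3.5e-5, 1, 1)
#' @export
prob_sedimentation <- function(d_airway_cm, v_s, cos_phi, t_res) {
  if (any(t_res < 0)) bad_input("`t_res` must be >= 0.")
  1 - exp(-(4 * v_s * abs(cos_phi) * t_res) / (pi * d_airway_cm * 1e-2))
}

#' Brownian diffusion deposition probability in a tube
#'
#' First diffusional mode of a cylinder:
#' `p = 1 - exp(-k_geo D_diff t / R^2)` with `R` in metres.
#'
#' @param r_airway_m Airway radius, m.
#' @param d_diff Diffusion coefficient, m^2/s.
#' @param t_res Residence time, s.
#' @param const Physical constants (supplies `k_geo`).
#' @return Deposition probability in `[0, 1]` (vectorized).
#' @examples
#' prob_diffusion(1e-3, 2.9e-11, 1)
#' @export
prob_diffusion <- function(r_airway_m, d_diff, t_res,
                           const = physics_constants()) {
  if (any(t_res < 0)) bad_input("`t_res` must be >= 0.")
  1 - exp(-(const$k_geo * d_diff * t_res) / r_airway_m^2)
}

#' Combine independent deposition mechanisms
#'
#' Probabilities of impaction, sedimentation and diffusion acting in the same
#' airway are combined assuming independence:
#' `p = 1 - (1 - p_i)(1 - p_s)(1 - p_d)`.
#'
#' @param p_i,p_s,p_d Per-mechanism probabilities (vectorized).
#' @return Combined probability, clipped to `[0, 1]`.
#' @examples
#' combine_mechanisms(0.1, 0.2, 0.3)
#' @export
combine_mechanisms <- function(p_i, p_s, p_d) {
  pmin(pmax(1 - (1 - p_i) * (1 - p_s) * (1 - p_d), 0), 1)
}

#' Extrathoracic (mouth-throat) deposition efficiency
#'
#' Single-compartment empirical model: an inertial term driven by the
#' impaction parameter `d^2 Q` (um^2 L/min) plus a small-particle diffusive
#' term `1 - exp(-9 sqrt(D_diff t_ET) / R_ET)` with `t_ET = V_ET / Q`.
#' Monotone increasing in `d^2 Q`.
#'
#' @param d_um Aerodynamic diameter, um (vectorized).
#' @param q_lpm Inspiratory flow at the mouth, L/min.
#' @param const Physical constants (supplies the empirical coefficients).
#' @return Capture probability in `[0, 1]`.
#' @examples
#' extrathoracic_efficiency(5, 60)
#' @export
extrathoracic_efficiency <- function(d_um, q_lpm, const = physics_constants()) {
  if (any(d_um < 0) || any(q_lpm < 0)) {
    bad_input("`d_um` and `q_lpm` must be >= 0.")
  }
  q <- pmax(q_lpm, const$et_min_flow_lpm)
  p_imp <- 1 - exp(-const$et_a * (d_um^2 * q)^const$et_b)
  d_diff <- diffusion_coefficient(pmax(d_um, 1e-12), const)
  t_et <- (const$et_volume_ml / 1000) / q * 60 # s
  p_diff <- 1 - exp(-9 * sqrt(d_diff * t_et) / (const$et_radius_cm * 1e-2))
  pmin(pmax(p_imp + p_diff * (1 - p_imp), 0), 1)
}
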