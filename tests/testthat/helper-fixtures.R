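# Reduce the stochastic lung to a single straight tube with frozen angles:
# used to validate the Monte Carlo engine against the closed-form
# per-airway deposition probability.
single_tube_geometry <- function(length_cm, diameter_cm, branch_deg,
                                 gravity_cos) {
  tab <- tibble::tibble(
    generation = 0L, mean_length_cm = length_cm,
    mean_diameter_cm = diameter_cm, cv_length = 0, cv_diameter = 0
  )
  airway_geometry(morphometry = tab, acinar = NULL,
                  terminal_range = c(0L, 0L), cv_scale = 0,
                  fixed_branch_deg = branch_deg,
                  fixed_gravity_cos = gravity_cos)
}

# Closed-form combined deposition probability for a particle carried at
# constant flow through that tube (the independent oracle).
single_tube_prob <- function(d_um, q_lps, length_cm, diameter_cm,
                             branch_deg, gravity_cos) {
  vol_l <- pi / 4 * diameter_cm^2 * length_cm * 1e-3
  t_res <- vol_l / q_lps
  u_ms <- q_lps * 1e-3 / (pi / 4 * (diameter_cm * 1e-2)^2)
  combine_mechanisms(
    prob_impaction(stokes_number(d_um, u_ms, diameter_cm), branch_deg),
    prob_sedimentation(diameter_cm, settling_velocity(d_um), gravity_cos,
                       t_res),
    prob_diffusion(diameter_cm * 1e-2 / 2, diffusion_coefficient(d_um),
                   t_res)
  )
}

# group-mean maneuver + lung volumes for the three groups at defaults
group_mean_inputs <- function(group, device_class) {
  man <- maneuver_reference()
  lf <- lung_function_reference()
  m <- man[man$group == group & man$device_class == device_class, ]
  l <- lf[lf$group == group, ]
  list(ivc = m$ivc_d_l, pif = m$pif_d_lps, t_in = m$t_in_s, t_bh = m$t_bh_s,
       rv = l$rv_pctpred / 100 * 2.0, tlc = l$tlc_pctpred / 100 * 6.0)
}

# a difference vector with exact mean and exact sample SD
vector_with_moments <- function(n, mean, sd, seed = 1) {
  x <- withr::with_seed(seed, stats::rnorm(n))
  mean + sd * as.numeric(scale(x))
}
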