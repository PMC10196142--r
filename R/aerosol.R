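#' Aerosol specification for an inhaler product
#'
#' A lognormal aerodynamic particle size distribution (mass median
#' aerodynamic diameter and geometric standard deviation), particle density,
#' and the emission window during which the device releases its dose,
#' relative to the start of inhalation.
#'
#' @param mmad Mass median aerodynamic diameter, um.
#' @param gsd Geometric standard deviation, dimensionless `>= 1`.
#' @param density Particle density, g/cm^3 (1.0 under the aerodynamic
#'   convention).
#' @param emission_window Numeric length-2: start and end of dose emission,
#'   s after inhalation start. Clipped to the inhalation phase at simulation
#'   time if the subject's inhalation is shorter.
#' @param label Device name carried through outputs.
#' @return An object of class `"aerosol_spec"`.
#' @examples
#' aerosol_spec(2.5, 1.6, label = "example")
#' @export
aerosol_spec <- function(mmad, gsd, density = 1,
                         emission_window = c(0, 0.3), label = "aerosol") {
  check_number(mmad, "mmad", min = 0, strict = TRUE)
  check_number(gsd, "gsd", min = 1)
  check_number(density, "density", min = 0, strict = TRUE)
  if (length(emission_window) != 2L || emission_window[1] < 0 ||
      emission_window[2] < emission_window[1]) {
    bad_input("`emission_window` must be c(start, end) with 0 <= start <= end.")
  }
  structure(list(mmad = mmad, gsd = gsd, density = density,
                 emission_window = as.numeric(emission_window),
                 label = label),
            class = "aerosol_spec")
}

#' @export
print.aerosol_spec <- function(x, ...) {
  cat(sprintf(
    "<aerosol_spec '%s': MMAD %.3g um, GSD %.3g, density %.3g g/cm3, emission %.3g-%.3g s>\n",
    x$label, x$mmad, x$gsd, x$density,
    x$emission_window[1], x$emission_window[2]))
  invisible(x)
}

#' Packaged device presets
#'
#' Default aerosol specifications for the three studied inhalers. The two
#' pMDI products share one preset; the soft-mist inhaler has its own, with a
#' longer emission window reflecting its slow, long-lasting mist.
#'
#' The preset size distributions are *effective inertial* size distributions
#' at the mouth, not cascade-impactor PSDs of the formulations: the model
#' carries no plume-momentum term, so the ballistic momentum of a pMDI spray
#' is folded into a coarse effective PSD, while the slow soft mist is
#' represented by a fine one. They are configuration, not measurements, and
#' can be overridden through the `aerosol:` block of a study configuration.
#'
#' @param name One of `"Foster_pMDI"`, `"Trimbow_pMDI"`, `"Spiriva_Respimat"`.
#' @return An [aerosol_spec()].
#' @examples
#' device_preset("Spiriva_Respimat")
#' @export
device_preset <- function(name = c("Foster_pMDI", "Trimbow_pMDI",
                                   "Spiriva_Respimat")) {
  name <- match.arg(name)
  switch(name,
    Foster_pMDI = aerosol_spec(10.0, 2.2, 1, c(0, 0.3), "Foster_pMDI"),
    Trimbow_pMDI = aerosol_spec(10.0, 2.2, 1, c(0, 0.3), "Trimbow_pMDI"),
    Spiriva_Respimat = aerosol_spec(3.4, 1.7, 1, c(0, 1.5),
                                    "Spiriva_Respimat")
  )
}

#' Device names known to the package
#' @return Character vector in the fixed reporting/tie-break order.
#' @export
device_levels <- function() {
  c("Foster_pMDI", "Trimbow_pMDI", "Spiriva_Respimat")
}

#' Sample particles from an aerosol specification
#'
#' Aerodynamic diameters are drawn from a lognormal with median `mmad` and
#' log-sd `log(gsd)`; transport properties (slip factor, settling velocity,
#' diffusivity) are attached.
#'
#' @param spec An [aerosol_spec()].
#' @param n Number of particles.
#' @param seed Optional integer seed.
#' @param const Physical constants, see [physics_constants()].
#' @return A tibble, one row per particle: `d_um`, `cc`, `v_s`, `d_diff`.
#' @examples
#' sample_particles(device_preset("Foster_pMDI"), 5, seed = 1)
#' @export
sample_particles <- function(spec, n, seed = NULL,
                             const = physics_constants()) {
  stopifnot(inherits(spec, "aerosol_spec"))
  if (n < 1) bad_input("`n` must be >= 1.")
  with_seed(seed, {
    d <- if (spec$gsd == 1) {
      rep(spec$mmad, n)
    } else {
      rlnorm(n, meanlog = log(spec$mmad), sdlog = log(spec$gsd))
    }
    particle_properties(d, rho_gcc = spec$density, const = const)
  })
}

# serialize/deserialize for the config layer
aerosol_to_list <- function(spec) {
  list(mmad = spec$mmad, gsd = spec$gsd, density = spec$density,
       emission_window = spec$emission_window, label = spec$label)
}

aerosol_from_list <- function(x) {
  aerosol_spec(x$mmad, x$gsd, x$density %||% 1,
               unlist(x$emission_window), x$label %||% "aerosol")
}
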