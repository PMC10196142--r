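#' Baseline conducting-airway morphometry table
#'
#' Per-generation mean lengths and diameters of the conducting airways of an
#' adult lung at a reference volume of 4.8 L, following the classic symmetric
#' adult morphometry (trachea 12 cm long, 1.8 cm wide, down to terminal
#' bronchioles of ~0.05-0.06 cm), used as the means of the stochastic
#' airway-dimension distributions. Shipped as a plain CSV so alternative
#' tables can be swapped in.
#'
#' @param path Optional path to a CSV with columns `generation`,
#'   `mean_length_cm`, `mean_diameter_cm`, `cv_length`, `cv_diameter`.
#' @return A tibble, one row per conducting generation starting at 0
#'   (trachea).
#' @examples
#' morphometry_default()
#' @export
morphometry_default <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "morphometry_default.csv",
                        package = "lungdepo", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("generation", "mean_length_cm", "mean_diameter_cm",
              "cv_length", "cv_diameter")
  if (!all(needed %in% names(tab))) {
    bad_input(paste0("Morphometry table must have columns: ",
                     paste(needed, collapse = ", ")))
  }
  if (any(tab$mean_length_cm <= 0) || any(tab$mean_diameter_cm <= 0) ||
      any(tab$cv_length < 0) || any(tab$cv_diameter < 0)) {
    bad_input("Morphometry table: lengths/diameters must be > 0 and CVs >= 0.")
  }
  as_tibble(tab)
}

#' Acinar morphometry table
#'
#' Mean duct lengths, inner diameters and alveolar surface fractions of the
#' eight acinar generations appended after the terminal bronchiole, in the
#' spirit of published acinar morphometry (transitional and respiratory
#' bronchioles through alveolar ducts and sacs). The alveolar fraction ramps
#' from 0.2 to 1.0 with acinar depth.
#'
#' @param n_generations Number of acinar generations.
#' @param cv Lognormal coefficient of variation applied to sampled acinar
#'   duct dimensions.
#' @return A tibble with columns `acinar_generation`, `mean_length_cm`,
#'   `mean_diameter_cm`, `alveolar_fraction`, `cv`.
#' @export
acinar_default <- function(n_generations = 8, cv = 0.1) {
  len <- c(0.140, 0.133, 0.112, 0.093, 0.083, 0.070, 0.070, 0.070)
  dia <- c(0.050, 0.049, 0.047, 0.045, 0.044, 0.043, 0.043, 0.041)
  n <- n_generations
  tibble(
    acinar_generation = seq_len(n),
    mean_length_cm = len[pmin(seq_len(n), 8)],
    mean_diameter_cm = dia[pmin(seq_len(n), 8)],
    alveolar_fraction = if (n > 1) seq(0.2, 1.0, length.out = n) else 1.0,
    cv = cv
  )
}

#' Stochastic airway geometry configuration
#'
#' Bundles everything needed to sample random airway paths: the conducting
#' morphometry table (means + CVs), the acinar table, the parent-daughter
#' diameter correlation, branching-angle and terminal-generation ranges, and
#' optional overrides that freeze angles (used, e.g., to reduce the model to
#' a single straight tube when validating against closed-form deposition
#' probabilities).
#'
#' @param morphometry Conducting table, see [morphometry_default()].
#' @param acinar Acinar table, see [acinar_default()]; `NULL` disables the
#'   acinar region.
#' @param parent_cor Correlation of log-diameters between parent and daughter
#'   airways, in `[0, 1)`.
#' @param branch_range Branching-angle range, degrees (uniform draw); the
#'   trachea has no bifurcation and gets angle 0.
#' @param terminal_range Integer range of the terminal conducting generation
#'   (uniform draw), mimicking variable path depth of an asymmetric tree.
#' @param cv_scale Multiplier applied to all morphometry CVs (0 collapses the
#'   geometry onto the table means).
#' @param fixed_branch_deg If non-`NULL`, all branching angles are fixed at
#'   this value.
#' @param fixed_gravity_cos If non-`NULL`, `cos(gravity angle)` is fixed at
#'   this value instead of being drawn uniformly on `[-1, 1]`.
#' @param v_ref_l Morphometric reference lung volume, L.
#' @return A list of class `"airway_geometry"`.
#' @examples
#' geom <- airway_geometry()
#' geom$terminal_range
#' @export
airway_geometry <- function(morphometry = morphometry_default(),
                            acinar = acinar_default(),
                            parent_cor = 0.5,
                            branch_range = c(15, 60),
                            terminal_range = c(12L, 17L),
                            cv_scale = 1,
                            fixed_branch_deg = NULL,
                            fixed_gravity_cos = NULL,
                            v_ref_l = 4.8) {
  check_number(parent_cor, "parent_cor", min = 0)
  if (parent_cor >= 1) bad_input("`parent_cor` must be < 1.")
  check_number(cv_scale, "cv_scale", min = 0)
  check_number(v_ref_l, "v_ref_l", min = 0, strict = TRUE)
  terminal_range <- as.integer(terminal_range)
  if (length(terminal_range) != 2L || terminal_range[1] > terminal_range[2]) {
    bad_input("`terminal_range` must be two non-decreasing integers.")
  }
  max_gen <- max(morphometry$generation)
  if (terminal_range[2] > max_gen) {
    bad_input(sprintf(
      "`terminal_range` upper bound (%d) exceeds last morphometry generation (%d).",
      terminal_range[2], max_gen))
  }
  structure(list(
    morphometry = morphometry, acinar = acinar, parent_cor = parent_cor,
    branch_range = branch_range, terminal_range = terminal_range,
    cv_scale = cv_scale, fixed_branch_deg = fixed_branch_deg,
    fixed_gravity_cos = fixed_gravity_cos, v_ref_l = v_ref_l
  ), class = "airway_geometry")
}

# lognormal parameters with arithmetic mean `m` and coefficient of
# variation `cv`
lnorm_pars <- function(m, cv) {
  sdlog <- sqrt(log1p(cv^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Flow partition between two daughter airways
#'
#' Flow fractions at a bifurcation are proportional to the squared daughter
#' diameters, normalized to sum to 1.
#'
#' @param d_first,d_second Daughter diameters (any common unit; vectorized).
#' @return A tibble with columns `f_first`, `f_second` summing to 1.
#' @examples
#' flow_split(0.4, 0.2)
#' @export
flow_split <- function(d_first, d_second) {
  if (any(d_first <= 0) || any(d_second <= 0)) {
    bad_input("daughter diameters must be > 0.")
  }
  s <- d_first^2 + d_second^2
  tibble(f_first = d_first^2 / s, f_second = d_second^2 / s)
}

# Sample n random airway paths as compacted matrices.
# Column j (1-based) is the j-th segment along the path: conducting
# generations 0..G_i followed by the acinar generations. Matrices:
#   len, dia (cm), cos_phi, theta (deg), f_local (flow fraction of the
#   chosen daughter), alv (alveolar fraction, 0 in conducting airways),
#   mask (segment exists). Vector n_cond = G_i + 1.
sample_path_matrices <- function(n, geom = airway_geometry(), seed = NULL) {
  with_seed(seed, {
    tab <- geom$morphometry
    n_cond_max <- geom$terminal_range[2] + 1L
    n_acin <- if (is.null(geom$acinar)) 0L else nrow(geom$acinar)
    n_seg <- n_cond_max + n_acin

    g_term <- if (geom$terminal_range[1] == geom$terminal_range[2]) {
      rep(geom$terminal_range[1], n)
    } else {
      sample(seq(geom$terminal_range[1], geom$terminal_range[2]), n,
             replace = TRUE)
    }
    n_cond <- g_term + 1L

    len <- dia <- cos_phi <- theta <- f_local <- alv <-
      matrix(0, nrow = n, ncol = n_seg)
    mask <- matrix(FALSE, n, n_seg)

    z_parent <- rep(0, n) # standardized log-diameter of the parent
    rho <- geom$parent_cor
    for (j in seq_len(n_seg)) {
      is_cond <- (j <= n_cond)
      is_acin <- !is_cond & (j <= n_cond + n_acin)
      mask[, j] <- is_cond | is_acin

      if (any(is_cond)) {
        g <- j # table row for generation j-1 (table is 0-indexed by row order)
        row <- tab[g, ]
        cvl <- row$cv_length * geom$cv_scale
        cvd <- row$cv_diameter * geom$cv_scale
        pl <- lnorm_pars(row$mean_length_cm, cvl)
        pd <- lnorm_pars(row$mean_diameter_cm, cvd)
        idx <- which(is_cond)
        len[idx, j] <- if (cvl > 0) {
          rlnorm(length(idx), pl$meanlog, pl$sdlog)
        } else {
          rep(row$mean_length_cm, length(idx))
        }
        if (cvd > 0) {
          # correlated daughters: both carry the parent's standardized
          # log-diameter. The traversed airway keeps its marginal lognormal
          # draw (so per-generation sample means track the table); the
          # sibling draw only sets the flow fraction of the bifurcation.
          eps_a <- rnorm(length(idx))
          eps_b <- rnorm(length(idx))
          z_a <- rho * z_parent[idx] + sqrt(1 - rho^2) * eps_a
          z_b <- rho * z_parent[idx] + sqrt(1 - rho^2) * eps_b
          d_a <- exp(pd$meanlog + pd$sdlog * z_a)
          d_b <- exp(pd$meanlog + pd$sdlog * z_b)
          dia[idx, j] <- d_a
          z_parent[idx] <- z_a
          if (j == 1L) {
            # trachea: single conduit, no sibling
            f_local[idx, j] <- 1
          } else {
            f_local[idx, j] <- d_a^2 / (d_a^2 + d_b^2)
          }
        } else {
          dia[idx, j] <- row$mean_diameter_cm
          f_local[idx, j] <- if (j == 1L) 1 else 0.5
          z_parent[idx] <- 0
        }
        theta[idx, j] <- if (!is.null(geom$fixed_branch_deg)) {
          geom$fixed_branch_deg
        } else if (j == 1L) {
          0
        } else {
          runif(length(idx), geom$branch_range[1], geom$branch_range[2])
        }
        cos_phi[idx, j] <- if (!is.null(geom$fixed_gravity_cos)) {
          geom$fixed_gravity_cos
        } else {
          runif(length(idx), -1, 1)
        }
      }

      if (any(is_acin)) {
        idx <- which(is_acin)
        a_gen <- j - n_cond[idx] # acinar generation, 1-based
        arow_len <- geom$acinar$mean_length_cm[a_gen]
        arow_dia <- geom$acinar$mean_diameter_cm[a_gen]
        acv <- geom$acinar$cv[a_gen] * geom$cv_scale
        noise_l <- if (any(acv > 0)) {
          rlnorm(length(idx), -log1p(acv^2) / 2, sqrt(log1p(acv^2)))
        } else {
          rep(1, length(idx))
        }
        noise_d <- if (any(acv > 0)) {
          rlnorm(length(idx), -log1p(acv^2) / 2, sqrt(log1p(acv^2)))
        } else {
          rep(1, length(idx))
        }
        len[idx, j] <- arow_len * noise_l
        dia[idx, j] <- arow_dia * noise_d
        alv[idx, j] <- geom$acinar$alveolar_fraction[a_gen]
        theta[idx, j] <- if (!is.null(geom$fixed_branch_deg)) {
          geom$fixed_branch_deg
        } else {
          35
        }
        cos_phi[idx, j] <- if (!is.null(geom$fixed_gravity_cos)) {
          geom$fixed_gravity_cos
        } else {
          runif(length(idx), -1, 1)
        }
        f_local[idx, j] <- 0.5
      }
    }

    list(len = len, dia = dia, cos_phi = cos_phi, theta = theta,
         f_local = f_local, alv = alv, mask = mask,
         n_cond = n_cond, n_seg = n_seg)
  })
}

#' Sample one stochastic conducting-airway path
#'
#' Draws a random path from the trachea to a terminal bronchiole: airway
#' lengths and diameters lognormal around the per-generation means of the
#' morphometry table, daughter diameters correlated with their parent,
#' branching angles uniform in the configured range, gravity angles isotropic
#' (`cos(phi)` uniform on `[-1, 1]`). At each bifurcation a sibling diameter
#' is drawn from the same distribution and the flow fraction carried by the
#' traversed daughter is proportional to its squared diameter.
#'
#' @param geom An [airway_geometry()] configuration.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with one row per conducting generation: `generation`,
#'   `length_cm`, `diameter_cm`, `branching_angle_deg`, `gravity_cos`,
#'   `flow_fraction` (local fraction at the feeding bifurcation).
#' @examples
#' sample_conducting_path(seed = 1)
#' @export
sample_conducting_path <- function(geom = airway_geometry(), seed = NULL) {
  m <- sample_path_matrices(1L, geom, seed)
  j <- seq_len(m$n_cond[1])
  tibble(
    generation = j - 1L,
    length_cm = m$len[1, j],
    diameter_cm = m$dia[1, j],
    branching_angle_deg = m$theta[1, j],
    gravity_cos = m$cos_phi[1, j],
    flow_fraction = m$f_local[1, j]
  )
}

#' Sample one stochastic acinar path
#'
#' Draws the acinar generations appended after a terminal bronchiole. The
#' alveolar fraction increases monotonically with acinar depth.
#'
#' @inheritParams sample_conducting_path
#' @return A tibble with one row per acinar generation: `acinar_generation`,
#'   `length_cm`, `diameter_cm`, `alveolar_fraction`, `gravity_cos`.
#' @examples
#' sample_acinus(seed = 1)
#' @export
sample_acinus <- function(geom = airway_geometry(), seed = NULL) {
  if (is.null(geom$acinar)) bad_input("geometry has no acinar region.")
  with_seed(seed, {
    tab <- geom$acinar
    n <- nrow(tab)
    acv <- tab$cv * geom$cv_scale
    noise <- function() {
      out <- rep(1, n)
      pos <- acv > 0
      out[pos] <- rlnorm(sum(pos), -log1p(acv[pos]^2) / 2,
                         sqrt(log1p(acv[pos]^2)))
      out
    }
    tibble(
      acinar_generation = tab$acinar_generation,
      length_cm = tab$mean_length_cm * noise(),
      diameter_cm = tab$mean_diameter_cm * noise(),
      alveolar_fraction = tab$alveolar_fraction,
      gravity_cos = if (!is.null(geom$fixed_gravity_cos)) {
        rep(geom$fixed_gravity_cos, n)
      } else {
        runif(n, -1, 1)
      }
    )
  })
}
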