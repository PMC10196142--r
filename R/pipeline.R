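#' Default study configuration
#'
#' Nested configuration covering the four stages of the pipeline: cohort
#' generation (`cohort:`), device aerosols (`aerosol:`), deposition physics
#' (`physics:`), airway geometry (`geometry:`) and engine settings
#' (`engine:`). All values are the packaged defaults; a YAML file needs to
#' mention only the keys it overrides.
#'
#' @return A nested list of class `"study_config"`.
#' @examples
#' names(study_config())
#' @export
study_config <- function() {
  structure(list(
    cohort = list(
      n_per_group = NULL,
      intra_cv = 0.08,
      severity_cor = 0.6,
      tlc_ref_l = 6.0,
      rv_ref_l = 2.0,
      frc_ref_l = 3.0
    ),
    aerosol = stats::setNames(
      lapply(device_levels(), function(d) aerosol_to_list(device_preset(d))),
      device_levels()
    ),
    physics = unclass(physics_constants()),
    geometry = list(
      parent_cor = 0.5,
      branch_range = c(15, 60),
      terminal_range = c(12L, 17L),
      cv_scale = 1,
      v_ref_l = 4.8
    ),
    engine = list(
      n_particles = 10000L,
      exhale_mult = 1
    )
  ), class = "study_config")
}

# recursive unknown-key check; `where` accumulates the YAML path for the
# error message
check_keys <- function(user, defaults, where = character(0)) {
  if (!is.list(user)) return(invisible())
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    bad_input(sprintf("Unknown configuration key: %s",
                      paste(c(where, unknown[1]), collapse = ".")))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      check_keys(user[[nm]], defaults[[nm]], c(where, nm))
    }
  }
  invisible()
}

merge_config <- function(user, defaults) {
  if (!is.list(user)) return(user)
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) &&
                          !is.null(names(defaults[[nm]])) &&
                          is.list(user[[nm]])) {
      merge_config(user[[nm]], defaults[[nm]])
    } else {
      user[[nm]]
    }
  }
  defaults
}

#' Read and validate a study configuration from YAML
#'
#' Missing keys are filled from [study_config()]; unknown keys are rejected
#' with an error naming the offending key path. An empty file yields all
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `"study_config"` list.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) bad_input(sprintf("Config file not found: %s", path))
  user <- yaml::read_yaml(path)
  defaults <- study_config()
  if (is.null(user)) return(defaults)
  check_keys(user, defaults)
  structure(merge_config(user, unclass(defaults)), class = "study_config")
}

#' Write a study configuration to YAML
#'
#' @param config A `"study_config"` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# materialize the R objects the stages consume from a study_config list
config_objects <- function(config) {
  stopifnot(inherits(config, "study_config"))
  const <- do.call(physics_constants, config$physics)
  geom <- airway_geometry(
    parent_cor = config$geometry$parent_cor,
    branch_range = unlist(config$geometry$branch_range),
    terminal_range = unlist(config$geometry$terminal_range),
    cv_scale = config$geometry$cv_scale,
    v_ref_l = config$geometry$v_ref_l
  )
  aerosols <- lapply(config$aerosol, aerosol_from_list)
  cohort <- cohort_config(
    n_per_group = config$cohort$n_per_group,
    intra_cv = config$cohort$intra_cv,
    severity_cor = config$cohort$severity_cor,
    tlc_ref_l = config$cohort$tlc_ref_l,
    rv_ref_l = config$cohort$rv_ref_l,
    frc_ref_l = config$cohort$frc_ref_l
  )
  list(const = const, geom = geom, aerosols = aerosols, cohort = cohort,
       n_particles = config$engine$n_particles,
       exhale_mult = config$engine$exhale_mult)
}

#' Run the full pipeline from a study configuration
#'
#' Generate -> simulate -> analyze, optionally writing the long results CSV,
#' the repeatability grid, the rank counts and a JSON run manifest to an
#' output directory. A manifest (master seed, configuration hash, particle
#' count, package version) fully determines a reproducible rerun.
#'
#' @param config A `"study_config"` list (see [study_config()],
#'   [read_study_config()]).
#' @param seed Master seed for the whole pipeline.
#' @param out_dir Optional output directory; created if missing.
#' @return The [run_study()] result list, with a `manifest` element added.
#' @export
run_pipeline <- function(config = study_config(), seed = 1, out_dir = NULL) {
  obj <- config_objects(config)
  study <- run_study(
    config = obj$cohort, n_particles = obj$n_particles, seed = seed,
    aerosols = obj$aerosols, geom = obj$geom, const = obj$const,
    exhale_mult = obj$exhale_mult
  )
  study$manifest <- list(
    seed = seed,
    n_particles = obj$n_particles,
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("lungdepo")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(study$results,
                     file.path(out_dir, "deposition_results.csv"),
                     row.names = FALSE)
    utils::write.csv(study$repeatability,
                     file.path(out_dir, "repeatability.csv"),
                     row.names = FALSE)
    utils::write.csv(study$rank_counts,
                     file.path(out_dir, "rank_counts.csv"),
                     row.names = FALSE)
    jsonlite::write_json(study$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  study
}

#' Human-readable study report
#'
#' Renders the repeatability results as the familiar group x site grid (one
#' row per device with bias, p of the bias, limits of agreement and CR) plus
#' the per-group rank counts.
#'
#' @param study Result list of [run_study()] / [run_pipeline()].
#' @return A list of class `"study_report"` with elements `repeatability`
#'   (formatted grid tibble) and `rank_counts`.
#' @export
study_report <- function(study) {
  if (is.null(study$repeatability) || nrow(study$repeatability) == 0) {
    bad_input("Study contains no repeatability results to report.")
  }
  grid <- study$repeatability |>
    dplyr::mutate(
      loa = sprintf("%.2f to %.2f", .data$loa_low, .data$loa_high),
      bias = round(.data$bias, 2), p = signif(.data$p_value, 2),
      cr = round(.data$cr, 2)
    ) |>
    dplyr::select("group", "site", "device", "n", "bias", "p", "loa", "cr")
  structure(list(repeatability = grid, rank_counts = study$rank_counts),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Repeatability of deposition values (bias, p, LoA, CR):\n")
  print(as.data.frame(x$repeatability), row.names = FALSE)
  cat("\nDevice ranks per group (rank 1 = smallest difference):\n")
  print(as.data.frame(x$rank_counts), row.names = FALSE)
  invisible(x)
}

#' Deposition summary plot for a simulated cohort
#'
#' Boxplots of per-subject mean pulmonary and extrathoracic deposition by
#' group and device.
#'
#' @param results Output of [run_cohort()].
#' @return A ggplot object.
#' @export
plot_deposition_summary <- function(results) {
  dat <- average_repetitions(results) |>
    tidyr::pivot_longer(c("pd_mean", "etd_mean"), names_to = "site",
                        values_to = "pct") |>
    dplyr::mutate(site = ifelse(.data$site == "pd_mean",
                                "pulmonary", "extrathoracic"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$pct,
                                    fill = .data$device)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~site) +
    ggplot2::labs(x = NULL, y = "% of tracked dose", fill = NULL) +
    ggplot2::theme_minimal()
}
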