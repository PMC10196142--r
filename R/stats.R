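#' Bland-Altman repeatability analysis
#'
#' Agreement between two repeated measurements on the same subjects. With
#' differences `d_i = first_i - second_i`:
#' * bias = `mean(d)`;
#' * `sd_d` = sample SD of the differences (`n - 1` denominator);
#' * 95% limits of agreement = bias +/- `loa_mult * sd_d`;
#' * coefficient of repeatability `CR = loa_mult * sqrt(mean(d^2))` (root
#'   mean square difference, equivalently
#'   `loa_mult * sqrt(bias^2 + sd_d^2 (n-1)/n)`) -- lower CR means better
#'   repeatability;
#' * a two-sided one-sample t-test of the bias against zero (`df = n - 1`).
#'
#' @param first,second Numeric vectors of equal length `n >= 2` (first and
#'   second measurement per subject), or `first` may be a data frame with
#'   the two measurement columns named by `second` and `...` unused.
#' @param loa_mult Multiplier for the limits of agreement (1.96 for 95%).
#' @return An object of class `"bland_altman"`: list with `n`, `bias`,
#'   `sd_d`, `loa_low`, `loa_high`, `cr`, `t_stat`, `p_value`, and the
#'   per-subject `differences` and `means`.
#' @examples
#' ba <- bland_altman(c(10, 12, 11), c(9, 13, 10))
#' ba$cr
#' @export
bland_altman <- function(first, second, loa_mult = 1.96) {
  if (is.data.frame(first)) {
    bad_input("Pass two numeric vectors; for tables use `repeatability_table()`.")
  }
  if (length(first) != length(second)) {
    bad_input("`first` and `second` must have equal length.")
  }
  n <- length(first)
  if (n < 2) bad_input("Need at least 2 paired measurements.")
  if (anyNA(first) || anyNA(second) || any(!is.finite(c(first, second)))) {
    bad_input("Missing or non-finite measurements are not allowed.")
  }
  d <- first - second
  bias <- mean(d)
  sd_d <- sd(d)
  cr <- loa_mult * sqrt(mean(d^2))
  # one-sample t-test of the bias against zero, df = n - 1; computed
  # directly so that exactly repeated measurements (sd_d = 0) degrade
  # gracefully instead of erroring
  if (sd_d > 0) {
    t_stat <- bias / (sd_d / sqrt(n))
    p_value <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  } else {
    t_stat <- if (bias == 0) 0 else Inf * sign(bias)
    p_value <- if (bias == 0) 1 else 0
  }
  structure(list(
    n = n, bias = bias, sd_d = sd_d,
    loa_low = bias - loa_mult * sd_d,
    loa_high = bias + loa_mult * sd_d,
    cr = cr,
    t_stat = t_stat,
    p_value = p_value,
    loa_mult = loa_mult,
    differences = d,
    means = (first + second) / 2
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman: n=%d, bias %.3f, 95%% LoA %.3f to %.3f, CR %.3f, p=%.3g>\n",
    x$n, x$bias, x$loa_low, x$loa_high, x$cr, x$p_value))
  invisible(x)
}

#' Tidy per-subject Bland-Altman points
#'
#' @param x A [bland_altman()] object.
#' @param ... Unused.
#' @return Tibble with per-subject `mean` and `difference`.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(mean = x$means, difference = x$differences)
}

#' One-row Bland-Altman summary
#'
#' @param x A [bland_altman()] object.
#' @param ... Unused.
#' @return One-row tibble with `n`, `bias`, `sd_d`, `loa_low`, `loa_high`,
#'   `cr`, `t_stat`, `p_value`.
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(n = x$n, bias = x$bias, sd_d = x$sd_d, loa_low = x$loa_low,
         loa_high = x$loa_high, cr = x$cr, t_stat = x$t_stat,
         p_value = x$p_value)
}

#' @rdname tidy.bland_altman
#' @param object A [bland_altman()] object.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  dat <- tidy.bland_altman(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dotted") +
    ggplot2::labs(x = "mean of measurements 1 and 2",
                  y = "difference (meas 1 - meas 2)") +
    ggplot2::theme_minimal()
}

#' Coefficient of repeatability from bias, SD and n
#'
#' Second, independent code path for the CR identity
#' `CR = loa_mult * sqrt(bias^2 + sd_d^2 (n-1)/n)`; used to cross-check
#' [bland_altman()]'s root-mean-square form and to reconstruct printed CRs
#' from published bias and limits of agreement.
#'
#' @param bias Mean difference.
#' @param sd_d Sample SD of differences (`n - 1` denominator).
#' @param n Number of pairs.
#' @param loa_mult Limits-of-agreement multiplier.
#' @return CR on the scale of the measurements.
#' @examples
#' cr_from_moments(0.80, 1.2653, 17)
#' @export
cr_from_moments <- function(bias, sd_d, n, loa_mult = 1.96) {
  if (any(n < 2)) bad_input("`n` must be >= 2.")
  if (any(sd_d < 0)) bad_input("`sd_d` must be >= 0.")
  loa_mult * sqrt(bias^2 + sd_d^2 * (n - 1) / n)
}

#' Rank inhaler devices by repeatability for each subject
#'
#' Rank 1 goes to the device with the smallest absolute difference between
#' the two repeated deposition values, rank 3 to the largest. Ties are broken
#' deterministically by the fixed device order
#' `Foster_pMDI, Trimbow_pMDI, Spiriva_Respimat` and flagged.
#'
#' @param data Tibble with columns `subject_id`, `device` and a difference
#'   column (default `difference`; absolute values are taken).
#' @param diff_col Name of the difference column.
#' @return `data` grouped per subject with columns `abs_diff`, `rank`
#'   (1 = most repeatable) and `tied` appended.
#' @examples
#' d <- tibble::tibble(
#'   subject_id = rep("S1", 3),
#'   device = device_levels(),
#'   difference = c(2, -1, 0.5))
#' rank_devices(d)
#' @export
rank_devices <- function(data, diff_col = "difference") {
  req <- c("subject_id", "device", diff_col)
  if (!all(req %in% names(data))) {
    bad_input(paste0("`data` must have columns: ", paste(req, collapse = ", ")))
  }
  out <- data |>
    dplyr::mutate(abs_diff = abs(.data[[diff_col]]),
                  .device_ord = match(.data$device, device_levels())) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(
      rank = rank(.data$abs_diff, ties.method = "min"),
      tied = duplicated(.data$abs_diff) | duplicated(.data$abs_diff,
                                                     fromLast = TRUE)
    ) |>
    dplyr::arrange(.data$abs_diff, .data$.device_ord, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select(-".device_ord")
  n_dev <- out |>
    dplyr::count(.data$subject_id) |>
    dplyr::pull(.data$n)
  if (any(n_dev != 3)) {
    bad_input("Each subject must have exactly three devices to rank.")
  }
  if (any(out$tied)) {
    warn("Ties in absolute differences broken by fixed device order.")
  }
  out
}

#' Per-group counts of device ranks
#'
#' @param ranks Output of [rank_devices()] with a `group` column.
#' @return Tibble of counts by `group`, `device`, `rank`.
#' @export
rank_summary <- function(ranks) {
  if (!"group" %in% names(ranks)) {
    bad_input("`ranks` must have a `group` column.")
  }
  ranks |>
    dplyr::count(.data$group, .data$device, .data$rank, name = "n_subjects") |>
    tidyr::complete(.data$group, device = device_levels(), rank = 1:3,
                    fill = list(n_subjects = 0L))
}

# Dunn's rank-based post-hoc z-test for pairwise comparisons after a
# Kruskal-Wallis test, with tie correction and Bonferroni adjustment
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  combs <- utils::combn(levels(groups), 2, simplify = FALSE)
  purrr::map_dfr(combs, function(pair) {
    i <- pair[1]; j <- pair[2]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z <- (mean_rank[[i]] - mean_rank[[j]]) / se
    tibble(comparison = paste(i, "vs", j), statistic = z,
           p_raw = 2 * pnorm(-abs(z)))
  })
}

#' Compare deposition values across subject groups
#'
#' Group comparison as done for cohort summaries: per-group Shapiro-Wilk
#' normality at alpha = 0.05 selects one-way ANOVA with Bonferroni-adjusted
#' pairwise t-tests, otherwise Kruskal-Wallis with Dunn's multiple
#' comparison test (Bonferroni-adjusted). Any group with fewer than 3
#' observations forces the nonparametric branch with a warning.
#'
#' @param data Tibble with a value column and a group column.
#' @param value,group Column names (strings).
#' @param method `"auto"` (normality-based), `"anova"` or `"kruskal"`.
#' @return A list of class `"group_comparison"`: `method`, `omnibus_p`,
#'   `pairwise` (tibble with `comparison`, `p_raw`, `p_adj`).
#' @examples
#' d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 10),
#'                     y = rnorm(30))
#' group_compare(d, "y", "g")
#' @export
group_compare <- function(data, value, group,
                          method = c("auto", "anova", "kruskal")) {
  method <- match.arg(method)
  y <- data[[value]]
  gr <- factor(data[[group]])
  if (is.null(y) || is.null(gr)) bad_input("value/group columns not found.")
  keep <- !is.na(y) & !is.na(gr)
  y <- y[keep]; gr <- droplevels(gr[keep])
  n_g <- table(gr)
  if (length(n_g) < 2) bad_input("Need at least two groups.")

  if (any(n_g < 3) && method != "kruskal") {
    warn("Groups with n < 3 present; forcing the nonparametric test.")
    method <- "kruskal"
  }
  if (method == "auto") {
    normal <- all(vapply(levels(gr), function(l) {
      yy <- y[gr == l]
      if (length(unique(yy)) < 3) return(FALSE)
      stats::shapiro.test(yy)$p.value >= 0.05
    }, logical(1)))
    method <- if (normal) "anova" else "kruskal"
  }

  if (method == "anova") {
    fit <- stats::aov(y ~ gr)
    omnibus <- summary(fit)[[1]][["Pr(>F)"]][1]
    pw <- stats::pairwise.t.test(y, gr, p.adjust.method = "none",
                                 pool.sd = TRUE)
    tab <- as.data.frame(as.table(pw$p.value))
    tab <- tab[!is.na(tab$Freq), ]
    pairwise <- tibble(
      comparison = paste(tab$Var1, "vs", tab$Var2),
      p_raw = tab$Freq,
      p_adj = pmin(tab$Freq * nrow(tab), 1)
    )
  } else {
    omnibus <- stats::kruskal.test(y, gr)$p.value
    pw <- dunn_test(y, gr)
    pairwise <- dplyr::mutate(pw, p_adj = pmin(.data$p_raw * dplyr::n(), 1))
  }
  structure(list(method = method, omnibus_p = omnibus, pairwise = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison: %s, omnibus p=%.3g>\n", x$method,
              x$omnibus_p))
  print(x$pairwise)
  invisible(x)
}

#' Repeatability table for a simulated cohort
#'
#' Builds the group x site (lung / extrathoracic) x device grid of
#' Bland-Altman summaries (n, bias, p of the bias, limits of agreement, CR)
#' from a long results table with two repetitions per subject/device.
#'
#' @param results Output of [run_cohort()]: long table with `subject_id`,
#'   `group`, `device`, `repetition`, `pd_pct`, `etd_pct`.
#' @param loa_mult Limits-of-agreement multiplier.
#' @return Tibble with one row per group x site x device:
#'   `group`, `site`, `device`, `n`, `bias`, `sd_d`, `loa_low`, `loa_high`,
#'   `cr`, `t_stat`, `p_value`.
#' @export
repeatability_table <- function(results, loa_mult = 1.96) {
  wide <- results |>
    dplyr::filter(!is.na(.data$pd_pct)) |>
    dplyr::select("subject_id", "group", "device", "repetition",
                  "pd_pct", "etd_pct") |>
    tidyr::pivot_longer(c("pd_pct", "etd_pct"), names_to = "site",
                        values_to = "value") |>
    dplyr::mutate(site = ifelse(.data$site == "pd_pct", "lung",
                                "extrathoracic")) |>
    tidyr::pivot_wider(names_from = "repetition", values_from = "value",
                       names_prefix = "rep")
  if (!all(c("rep1", "rep2") %in% names(wide))) {
    bad_input("`results` must contain repetitions 1 and 2.")
  }
  wide |>
    dplyr::filter(!is.na(.data$rep1) & !is.na(.data$rep2)) |>
    dplyr::group_by(.data$group, .data$site, .data$device) |>
    dplyr::group_modify(function(df, key) {
      glance.bland_altman(bland_altman(df$rep1, df$rep2,
                                       loa_mult = loa_mult))
    }) |>
    dplyr::ungroup()
}

#' Per-subject PD differences for device ranking
#'
#' @param results Output of [run_cohort()].
#' @param site `"lung"` (PD) or `"extrathoracic"` (ETD).
#' @return Tibble with `subject_id`, `group`, `device`, `difference`
#'   (repetition 1 minus repetition 2).
#' @export
repetition_differences <- function(results, site = c("lung", "extrathoracic")) {
  site <- match.arg(site)
  col <- if (site == "lung") "pd_pct" else "etd_pct"
  results |>
    dplyr::select("subject_id", "group", "device", "repetition",
                  value = dplyr::all_of(col)) |>
    tidyr::pivot_wider(names_from = "repetition", values_from = "value",
                       names_prefix = "rep") |>
    dplyr::mutate(difference = .data$rep1 - .data$rep2) |>
    dplyr::select("subject_id", "group", "device", "difference")
}
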