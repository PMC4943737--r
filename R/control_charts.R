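#' Control-chart parameters
#'
#' Bundles the tuning constants of the combined Shewhart / decision-interval
#' CuSum scheme.  The allowance `k = 0.5` (in z units) is the standard
#' choice for detecting a one-standard-deviation shift in the process mean;
#' the decision interval `h = 5` gives an in-control average run length of
#' roughly 465 years for a two-sided scheme on standard-normal input.
#' Shewhart limits are `+/- 3` z units when the baseline is a
#' reference-condition window; for whole-series baselines the limit is the
#' two-sided 99% normal quantile (`+/- 2.576`), applied per observation.
#'
#' @param k Allowance (reference value), z units; deviations smaller than
#'   `k` are ignored by the CuSum.
#' @param h Decision interval, z units; an alarm requires `S+ > h` or
#'   `S- < -h` (strict).
#' @param shewhart_limit Shewhart limit in z units for reference-window
#'   baselines.
#' @param ci_level Confidence level defining the Shewhart limit for
#'   whole-series baselines.
#' @return A list of class `cusum_params`.
#' @export
cusum_params <- function(k = 0.5, h = 5, shewhart_limit = 3,
                         ci_level = 0.99) {
  if (k < 0) abort("allowance k must be non-negative")
  if (h <= 0) abort("decision interval h must be positive")
  if (shewhart_limit <= 0) abort("shewhart_limit must be positive")
  if (ci_level <= 0 || ci_level >= 1) abort("ci_level must be in (0, 1)")
  structure(list(k = k, h = h, shewhart_limit = shewhart_limit,
                 ci_level = ci_level), class = "cusum_params")
}

#' Decision-interval CuSum statistics
#'
#' Accumulates positive and negative deviations of a z-score series with
#' the one-sided recursions
#' `S+_i = max(0, S+_{i-1} + z_i - k)` and
#' `S-_i = min(0, S-_{i-1} + z_i + k)`, both started at 0.  `S+` tracks
#' persistent upward departures from the baseline, `S-` downward ones;
#' deviations smaller than the allowance `k` are absorbed.
#'
#' Missing values should not occur after imputation; if present, both
#' statistics carry their previous value forward and the year cannot raise
#' a flag (a message is logged).
#'
#' @param z Numeric z-score series in year order.
#' @param k Allowance, z units.
#' @return A tibble with columns `s_plus` and `s_minus`.
#' @export
#' @examples
#' di_cusum(c(1, 1, 1, 1, 1, 1), k = 0.5)
di_cusum <- function(z, k = 0.5) {
  n <- length(z)
  s_plus <- s_minus <- numeric(n)
  sp <- sm <- 0
  n_na <- 0L
  for (i in seq_len(n)) {
    if (is.na(z[i])) {
      n_na <- n_na + 1L
    } else {
      sp <- max(0, sp + z[i] - k)
      sm <- min(0, sm + z[i] + k)
    }
    s_plus[i] <- sp
    s_minus[i] <- sm
  }
  if (n_na > 0) {
    inform(paste0(n_na, " missing z value(s): CuSum carried forward"))
  }
  tibble::tibble(s_plus = s_plus, s_minus = s_minus)
}

#' Shewhart flags for a z-score series
#'
#' Flags single-year departures beyond the Shewhart limits: `+/- 3` z
#' units for reference-window baselines (`refcon_chl`, `refcon_fish`), or
#' the two-sided normal quantile of `ci_level` (2.576 for 99%) for
#' whole-series baselines.  Values exactly at the limit are in control
#' ("exceed" is strict).
#'
#' @param z Numeric z-score series.
#' @param params A [cusum_params()] object.
#' @param baseline_kind `"entire"`, `"refcon_chl"` or `"refcon_fish"`.
#' @return Character vector: `"ok"`, `"above_UCL"` or `"below_LCL"`
#'   (missing z gives `NA`).
#' @export
shewhart_flags <- function(z, params = cusum_params(),
                           baseline_kind = "entire") {
  limit <- if (baseline_kind == "entire") {
    qnorm(1 - (1 - params$ci_level) / 2)
  } else {
    params$shewhart_limit
  }
  dplyr::case_when(
    is.na(z) ~ NA_character_,
    z > limit ~ "above_UCL",
    z < -limit ~ "below_LCL",
    TRUE ~ "ok"
  )
}

cusum_flags <- function(s_plus, s_minus, h) {
  dplyr::case_when(
    s_plus > h ~ "upper",
    s_minus < -h ~ "lower",
    TRUE ~ "ok"
  )
}

#' Combined Shewhart and CuSum control charts for z-score tables
#'
#' Runs [di_cusum()] and [shewhart_flags()] over every dataset x indicator
#' series of a preprocessed z-score table and flags years whose CuSum
#' statistic exceeds the decision interval.  The CuSum is not reset after
#' an alarm, so persistent excursions stay visible.
#'
#' @param zscores A z-score tibble from [preprocess_indicators()] (columns
#'   `dataset`, `year`, `indicator`, `z`, `baseline_kind`).
#' @param params A [cusum_params()] object.
#' @return A tibble of class `control_chart`: the input plus `s_plus`,
#'   `s_minus`, `shewhart_flag`, `cusum_flag`.
#' @seealso [detect_out_of_control_periods()], [classify_years_by_refcon()],
#'   [autoplot.control_chart()]
#' @export
control_chart <- function(zscores, params = cusum_params()) {
  out <- zscores |>
    dplyr::group_by(.data$dataset, .data$indicator) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$year)
      if (anyDuplicated(d$year)) abort("duplicate years in z series")
      cs <- di_cusum(d$z, k = params$k)
      d$s_plus <- cs$s_plus
      d$s_minus <- cs$s_minus
      d$shewhart_flag <- shewhart_flags(d$z, params, d$baseline_kind[1])
      d$cusum_flag <- cusum_flags(cs$s_plus, cs$s_minus, params$h)
      d
    }) |>
    dplyr::ungroup()
  class(out) <- c("control_chart", class(out))
  attr(out, "params") <- params
  out
}

#' Out-of-control periods from CuSum flags
#'
#' Extracts maximal runs of same-direction CuSum violations lasting at
#' least `min_run` consecutive years (default 4, i.e. "more than 3").
#'
#' @param chart A [control_chart()] tibble, or any tibble with `dataset`,
#'   `indicator`, `year` and `cusum_flag`.
#' @param min_run Minimum run length in years.
#' @return A tibble `dataset`, `indicator`, `direction`, `start_year`,
#'   `end_year`, `length`.
#' @export
detect_out_of_control_periods <- function(chart, min_run = 4) {
  chart |>
    dplyr::as_tibble() |>
    dplyr::group_by(.data$dataset, .data$indicator) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$year)
      r <- rle(d$cusum_flag)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      keep <- r$values != "ok" & r$lengths >= min_run
      tibble::tibble(direction = r$values[keep],
                     start_year = d$year[starts[keep]],
                     end_year = d$year[ends[keep]],
                     length = r$lengths[keep])
    }) |>
    dplyr::ungroup()
}

#' Label years in or out of control across the indicator suite
#'
#' A year is out of control with respect to a reference state if any of
#' the indicators has its CuSum beyond the decision interval that year;
#' only years flagged by no indicator are in control.  Indicators with
#' different year coverage are restricted to the common years with a
#' warning.
#'
#' @param chart A [control_chart()] tibble computed against a single
#'   baseline kind.
#' @return A tibble `dataset`, `year`, `status`
#'   (`"in_control"`/`"out_of_control"`), `n_violating` (number of
#'   indicators flagging the year).
#' @export
classify_years_by_refcon <- function(chart) {
  if (length(unique(chart$baseline_kind)) > 1) {
    abort("classify_years_by_refcon needs charts for a single baseline kind")
  }
  chart |>
    dplyr::as_tibble() |>
    dplyr::group_by(.data$dataset) |>
    dplyr::group_modify(function(d, key) {
      n_ind <- dplyr::n_distinct(d$indicator)
      common <- d |>
        dplyr::count(.data$year) |>
        dplyr::filter(.data$n == n_ind)
      if (nrow(common) < dplyr::n_distinct(d$year)) {
        warn("indicators cover different years; restricting to intersection")
      }
      d |>
        dplyr::filter(.data$year %in% common$year) |>
        dplyr::group_by(.data$year) |>
        dplyr::summarise(
          n_violating = sum(.data$cusum_flag != "ok", na.rm = TRUE),
          .groups = "drop") |>
        dplyr::mutate(status = ifelse(.data$n_violating > 0,
                                      "out_of_control", "in_control")) |>
        dplyr::select("year", "status", "n_violating")
    }) |>
    dplyr::ungroup()
}

#' Plot combined control charts
#'
#' One panel per indicator: Shewhart z-scores (points, with the in-control
#' band) and the upper/lower decision-interval CuSum trajectories (lines,
#' with `+/- h` shown dashed).
#'
#' @param object A [control_chart()] tibble (one dataset; facet by
#'   indicator).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot control_chart
autoplot.control_chart <- function(object, ...) {
  params <- attr(object, "params") %||% cusum_params()
  limit <- if (object$baseline_kind[1] == "entire") {
    qnorm(1 - (1 - params$ci_level) / 2)
  } else {
    params$shewhart_limit
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = -limit,
                      ymax = limit, alpha = 0.12, fill = "grey50") +
    ggplot2::geom_hline(yintercept = c(-params$h, params$h),
                        linetype = "dashed", colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$s_plus), colour = "firebrick") +
    ggplot2::geom_line(ggplot2::aes(y = .data$s_minus),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$z,
                                     shape = .data$cusum_flag != "ok")) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16),
                                guide = "none") +
    ggplot2::facet_wrap(~indicator, scales = "free_y") +
    ggplot2::labs(x = "Year", y = "z / CuSum (z units)") +
    ggplot2::theme_minimal()
}
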