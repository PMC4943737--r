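#' Annual summer means per taxon and stage
#'
#' Restricts samples to the summer months (June-September by default, the
#' season all Baltic monitoring programs cover) and averages abundance and
#' biomass per dataset, year, taxon and life stage.  With
#' `average = "station"` (default) the mean is taken over sampling dates
#' within each station first and then over stations, so that heavily
#' sampled stations do not dominate the annual value; `average = "grand"`
#' pools all samples of a year.
#'
#' Years with no summer samples are absent from the output.
#'
#' @param samples A validated sample tibble ([read_samples()]).
#' @param months Integer months retained; must be non-empty.
#' @param average `"station"` or `"grand"`.
#' @return A tibble `dataset`, `year`, `taxon`, `stage`, `abundance`,
#'   `biomass` (canonical units).
#' @export
summer_annual_mean <- function(samples, months = 6:9,
                               average = c("station", "grand")) {
  average <- match.arg(average)
  if (length(months) == 0) abort("empty month set")
  dat <- samples |>
    dplyr::mutate(year = year_of(.data$date), month = month_of(.data$date)) |>
    dplyr::filter(.data$month %in% months)
  if (average == "station") {
    dat |>
      dplyr::group_by(.data$dataset, .data$year, .data$station,
                      .data$taxon, .data$stage) |>
      dplyr::summarise(abundance = mean(.data$abundance),
                       biomass = mean(.data$biomass), .groups = "drop") |>
      dplyr::group_by(.data$dataset, .data$year, .data$taxon, .data$stage) |>
      dplyr::summarise(abundance = mean(.data$abundance),
                       biomass = mean(.data$biomass), .groups = "drop")
  } else {
    dat |>
      dplyr::group_by(.data$dataset, .data$year, .data$taxon, .data$stage) |>
      dplyr::summarise(abundance = mean(.data$abundance),
                       biomass = mean(.data$biomass), .groups = "drop")
  }
}

#' Functional-group aggregates per dataset and year
#'
#' Pools the annual per-taxon means into the functional classes that the
#' community indicators are built from.  Predatory cladocerans
#' (onychopods such as *Cercopagis*, *Bythotrephes* and *Leptodora*) are
#' excluded from the total, cladoceran and microphagous pools throughout;
#' the copepod pool contains all copepods and pelagic harpacticoids (all
#' stages); the calanoid pool only taxa flagged `is_calanoid`.
#'
#' Copepod nauplii are microphagous feeders ecologically, but the default
#' keeps them out of the microphagous pool (which is defined through the
#' per-taxon `is_microphagous` flag); set `nauplii_microphagous = TRUE` to
#' add copepod-pool biomass of naupliar stages to the microphagous pool.
#'
#' @param annual Output of [summer_annual_mean()].
#' @param traits Trait registry covering every taxon in `annual`.
#' @param nauplii_microphagous Include copepod nauplii in the microphagous
#'   pool?
#' @return A tibble per `dataset` x `year` with columns `tz_abundance`
#'   (ind m^-3) and the biomass pools (mg WW m^-3): `tz_biomass`,
#'   `copepod_biomass`, `calanoid_biomass`, `cladoceran_biomass`
#'   (herbivorous only), `rotifer_biomass`, `microphagous_biomass`.
#' @export
compute_group_aggregates <- function(annual, traits,
                                     nauplii_microphagous = FALSE) {
  unmapped <- sort(setdiff(unique(annual$taxon), traits$taxon))
  if (length(unmapped) > 0) {
    abort(paste0("taxa missing from trait registry: ",
                 paste(unmapped, collapse = ", ")))
  }
  dat <- dplyr::left_join(annual, traits, by = "taxon") |>
    dplyr::mutate(
      predatory = .data$is_predatory_cladoceran,
      copepod_pool = .data$major_group %in% c("copepod", "harpacticoid"),
      micro = .data$is_microphagous |
        (nauplii_microphagous & .data$copepod_pool &
           .data$stage == "nauplius")
    )
  dat |>
    dplyr::group_by(.data$dataset, .data$year) |>
    dplyr::summarise(
      tz_abundance = sum(.data$abundance[!.data$predatory], na.rm = TRUE),
      tz_biomass = sum(.data$biomass[!.data$predatory]),
      copepod_biomass = sum(.data$biomass[.data$copepod_pool]),
      calanoid_biomass = sum(.data$biomass[.data$is_calanoid]),
      cladoceran_biomass = sum(.data$biomass[
        .data$major_group == "cladoceran" & !.data$predatory]),
      rotifer_biomass = sum(.data$biomass[.data$major_group == "rotifer"]),
      microphagous_biomass = sum(.data$biomass[.data$micro & !.data$predatory]),
      .groups = "drop"
    )
}

#' The nine community indicators
#'
#' Computes, per dataset and year, the indicator suite used for
#' status assessment:
#'
#' * `TZA` -- total zooplankton abundance, 10^3 ind m^-3;
#' * `TZB` -- total zooplankton biomass, mg WW m^-3;
#' * `CB`, `CB_pct` -- copepod biomass and its percentage of `TZB`;
#' * `MMB`, `MMB_pct` -- microphagous mesozooplankton biomass and its
#'   percentage of `TZB`;
#' * `MeanSize` -- mean individual wet weight `TZB`/`TZA`, ug WW ind^-1;
#' * `ClaCop` -- herbivorous cladoceran : calanoid copepod biomass ratio;
#' * `RotClaCop` -- (rotifer + herbivorous cladoceran) : calanoid copepod
#'   biomass ratio.
#'
#' Ratios (and `MeanSize`) with a zero denominator are returned as missing
#' values with a warning; they can be gap-filled downstream.
#'
#' @param aggregates Output of [compute_group_aggregates()].
#' @return A long tibble `dataset`, `year`, `indicator`, `value`.
#' @export
compute_indicator_suite <- function(aggregates) {
  if (nrow(aggregates) == 0) abort("no aggregates supplied")
  wide <- aggregates |>
    dplyr::mutate(
      TZA = .data$tz_abundance / 1e3,
      TZB = .data$tz_biomass,
      CB = .data$copepod_biomass,
      CB_pct = ratio_or_na(100 * .data$copepod_biomass, .data$tz_biomass),
      MMB = .data$microphagous_biomass,
      MMB_pct = ratio_or_na(100 * .data$microphagous_biomass,
                            .data$tz_biomass),
      MeanSize = ratio_or_na(.data$tz_biomass, .data$TZA),
      ClaCop = ratio_or_na(.data$cladoceran_biomass, .data$calanoid_biomass),
      RotClaCop = ratio_or_na(.data$rotifer_biomass +
                                .data$cladoceran_biomass,
                              .data$calanoid_biomass)
    )
  undef <- sum(wide$calanoid_biomass == 0) + sum(wide$tz_biomass == 0) +
    sum(wide$TZA == 0)
  if (undef > 0) {
    warn(paste0("zero denominators produced missing indicator values in ",
                undef, " place(s)"))
  }
  wide |>
    dplyr::select("dataset", "year", dplyr::all_of(INDICATOR_LEVELS)) |>
    tidyr::pivot_longer(dplyr::all_of(INDICATOR_LEVELS),
                        names_to = "indicator", values_to = "value") |>
    dplyr::mutate(indicator = factor(.data$indicator,
                                     levels = INDICATOR_LEVELS)) |>
    dplyr::arrange(.data$dataset, .data$indicator, .data$year)
}

ratio_or_na <- function(num, den) ifelse(den == 0, NA_real_, num / den)

#' Samples to indicator series in one step
#'
#' Convenience wrapper chaining [summer_annual_mean()],
#' [compute_group_aggregates()] and [compute_indicator_suite()].
#'
#' @inheritParams summer_annual_mean
#' @inheritParams compute_group_aggregates
#' @return A long indicator tibble; see [compute_indicator_suite()].
#' @export
compute_indicators <- function(samples, traits, months = 6:9,
                               average = c("station", "grand"),
                               nauplii_microphagous = FALSE) {
  samples |>
    summer_annual_mean(months = months, average = average) |>
    compute_group_aggregates(traits,
                             nauplii_microphagous = nauplii_microphagous) |>
    compute_indicator_suite()
}
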