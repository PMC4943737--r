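GEN_GROUPS <- c("calanoid", "copepod_other", "cladoceran_herb",
                "cladoceran_pred", "rotifer", "appendicularian")

#' Configuration for the synthetic community generator
#'
#' Describes a multi-decadal summer monitoring series with group-structured
#' biomass: per functional group a mean summer biomass and mean individual
#' wet weight, multiplicative lognormal noise, an optional monotonic drift
#' per year, an optional step regime shift, and a probability that a whole
#' year drops out of the series (as happens in the national monitoring
#' gap lists).  Station-to-station differences are persistent
#' multiplicative lognormal factors.
#'
#' The default community (calanoid copepods 60 mg WW m^-3 at 8 ug,
#' other copepods 20 at 2, herbivorous cladocerans 30 at 5, predatory
#' cladocerans 5 at 30, rotifers 8 at 0.3, appendicularians 4 at 2;
#' lognormal CV 0.4; 3 stations, monthly June-September sampling over 35
#' years) mimics a productive Baltic summer community with a total
#' non-predatory biomass around 120 mg WW m^-3.
#'
#' @param n_years Number of years in the series.
#' @param start_year First calendar year.
#' @param months Sampled months.
#' @param samples_per_month Sampling dates per month and station.
#' @param n_stations Stations per dataset.
#' @param group_means Named vector of mean summer biomass (mg WW m^-3) for
#'   the groups `calanoid`, `copepod_other`, `cladoceran_herb`,
#'   `cladoceran_pred`, `rotifer`, `appendicularian`.
#' @param ind_mass Named vector of mean individual wet weight (ug) per
#'   group.
#' @param noise_cv Lognormal coefficient of variation of biomass, scalar
#'   or per group.
#' @param trend Multiplicative drift per year (1 = none), scalar or per
#'   group.
#' @param shift_year Optional regime-shift year index (1-based within the
#'   series); `NULL` for none.
#' @param shift_factor Multiplier applied to group means from `shift_year`
#'   on, scalar or per group.
#' @param missing_year_prob Probability that a year has no samples (must
#'   be below 0.3).
#' @param station_cv Lognormal CV of the persistent station factors.
#' @param dataset_id Dataset identifier written into the samples.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A validated list of class `generator_config`.
#' @seealso [generate_dataset()], [synthetic_traits()]
#' @export
generator_config <- function(n_years = 35, start_year = 1980, months = 6:9,
                             samples_per_month = 1, n_stations = 3,
                             group_means = c(calanoid = 60,
                                             copepod_other = 20,
                                             cladoceran_herb = 30,
                                             cladoceran_pred = 5,
                                             rotifer = 8,
                                             appendicularian = 4),
                             ind_mass = c(calanoid = 8, copepod_other = 2,
                                          cladoceran_herb = 5,
                                          cladoceran_pred = 30,
                                          rotifer = 0.3,
                                          appendicularian = 2),
                             noise_cv = 0.4, trend = 1, shift_year = NULL,
                             shift_factor = 1, missing_year_prob = 0.05,
                             station_cv = 0.2, dataset_id = "SYN1",
                             seed = 42) {
  per_group <- function(x, nm) {
    if (length(x) == 1 && is.null(names(x))) {
      x <- setNames(rep(x, length(GEN_GROUPS)), GEN_GROUPS)
    }
    miss <- setdiff(GEN_GROUPS, names(x))
    if (length(miss) > 0) {
      abort(paste0(nm, " missing group(s): ", paste(miss, collapse = ", ")))
    }
    x[GEN_GROUPS]
  }
  group_means <- per_group(group_means, "group_means")
  ind_mass <- per_group(ind_mass, "ind_mass")
  noise_cv <- per_group(noise_cv, "noise_cv")
  trend <- per_group(trend, "trend")
  shift_factor <- per_group(shift_factor, "shift_factor")
  if (any(group_means <= 0) || any(ind_mass <= 0)) {
    abort("group means and individual masses must be positive")
  }
  if (any(noise_cv < 0)) abort("noise_cv must be non-negative")
  if (missing_year_prob < 0 || missing_year_prob >= 0.3) {
    abort("missing_year_prob must be in [0, 0.3)")
  }
  if (!is.null(shift_year) &&
      (shift_year < 2 || shift_year > n_years)) {
    abort("shift_year must fall within the series")
  }
  if (length(months) == 0) abort("months must be non-empty")
  if (n_years < 2 || n_stations < 1 || samples_per_month < 1) {
    abort("invalid series dimensions")
  }
  structure(list(n_years = n_years, start_year = start_year,
                 months = months, samples_per_month = samples_per_month,
                 n_stations = n_stations, group_means = group_means,
                 ind_mass = ind_mass, noise_cv = noise_cv, trend = trend,
                 shift_year = shift_year, shift_factor = shift_factor,
                 missing_year_prob = missing_year_prob,
                 station_cv = station_cv, dataset_id = dataset_id,
                 seed = seed),
            class = "generator_config")
}

#' Trait registry for the synthetic community
#'
#' @return A trait tibble matching the taxa produced by
#'   [generate_dataset()].
#' @export
synthetic_traits <- function() {
  tibble::tibble(
    taxon = c("Acartia", "Cyclops", "Bosmina", "Cercopagis", "Synchaeta",
              "Fritillaria"),
    major_group = c("copepod", "copepod", "cladoceran", "cladoceran",
                    "rotifer", "appendicularian"),
    is_calanoid = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    is_predatory_cladoceran = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    is_microphagous = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  )
}

gen_components <- function(config) {
  taxa <- c(calanoid = "Acartia", copepod_other = "Cyclops",
            cladoceran_herb = "Bosmina", cladoceran_pred = "Cercopagis",
            rotifer = "Synchaeta", appendicularian = "Fritillaria")
  # Other copepods are carried as copepodites plus a naupliar component so
  # that stage-dependent pooling (nauplii in/out of the microphagous set)
  # is exercised.
  tibble::tibble(
    group = c("calanoid", "copepod_other", "copepod_other",
              "cladoceran_herb", "cladoceran_pred", "rotifer",
              "appendicularian"),
    stage = c("adult", "copepodite", "nauplius", "adult", "adult",
              "unspecified", "unspecified"),
    share = c(1, 0.6, 0.4, 1, 1, 1, 1)
  ) |>
    dplyr::mutate(
      taxon = taxa[.data$group],
      mean_biomass = config$group_means[.data$group] * .data$share,
      ind_mass = ifelse(.data$stage == "nauplius",
                        config$ind_mass[.data$group] * 0.25,
                        config$ind_mass[.data$group]),
      noise_cv = config$noise_cv[.data$group],
      trend = config$trend[.data$group],
      shift_factor = config$shift_factor[.data$group]
    )
}

#' Generate a synthetic monitoring dataset with known structure
#'
#' Draws taxon x station x date sample records around the configured group
#' means: biomass is lognormal with the configured CV about a mean that
#' drifts by `trend` per year, jumps by `shift_factor` at the regime-shift
#' year, and carries a persistent station factor; abundance is derived
#' from biomass and the group's individual mass, so the
#' biomass/abundance/mass consistency holds exactly.  Years drop out
#' entirely with probability `missing_year_prob`.  Output is byte-identical
#' for a given configuration (seed included).
#'
#' @param config A [generator_config()].
#' @return A list with `samples` (a sample tibble in canonical form),
#'   `traits` ([synthetic_traits()]) and `truth` -- a record of the
#'   generating structure: `shift_year` (calendar year or `NULL`),
#'   `shifted_groups`, `trend`, `missing_years`, `years`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "generator_config")) {
    abort("config must be a generator_config")
  }
  comp <- gen_components(config)
  years <- config$start_year + seq_len(config$n_years) - 1
  shift_cal <- if (is.null(config$shift_year)) NULL else
    config$start_year + config$shift_year - 1
  out <- with_private_seed(config$seed, {
    station_factor <- rlnorm(config$n_stations,
                             -log(1 + config$station_cv^2) / 2,
                             sqrt(log(1 + config$station_cv^2)))
    missing <- runif(config$n_years) < config$missing_year_prob
    grid <- tidyr::expand_grid(
      year = years[!missing],
      month = config$months,
      rep = seq_len(config$samples_per_month),
      station = seq_len(config$n_stations),
      comp_i = seq_len(nrow(comp))
    )
    cc <- comp[grid$comp_i, ]
    year_index <- grid$year - config$start_year + 1
    shift_mult <- if (is.null(shift_cal)) 1 else
      ifelse(grid$year >= shift_cal, cc$shift_factor, 1)
    mean_b <- cc$mean_biomass * cc$trend^(year_index - 1) * shift_mult *
      station_factor[grid$station]
    sdlog <- sqrt(log(1 + cc$noise_cv^2))
    biomass <- rlnorm(nrow(grid), log(mean_b) - sdlog^2 / 2, sdlog)
    list(samples = tibble::tibble(
      dataset = config$dataset_id,
      station = paste0("ST", grid$station),
      date = as.Date(sprintf("%d-%02d-%02d", grid$year, grid$month,
                             5 + 10 * (grid$rep - 1))),
      taxon = cc$taxon,
      stage = cc$stage,
      abundance = biomass / cc$ind_mass * 1e3,
      ind_mass = cc$ind_mass,
      biomass = biomass
    ), missing_years = years[missing])
  })
  truth <- list(
    dataset_id = config$dataset_id,
    years = years,
    shift_year = shift_cal,
    shifted_groups = names(config$shift_factor)[config$shift_factor != 1],
    trend = config$trend,
    missing_years = out$missing_years
  )
  list(samples = out$samples, traits = synthetic_traits(), truth = truth)
}

#' Reference window and expected labels implied by the generator truth
#'
#' When the generator injected a regime shift, the pre-shift years form
#' the natural reference-condition window and post-shift years -- beyond a
#' detection-delay grace period -- are expected to be labelled
#' out-of-control by the chart pipeline.  Without a shift the whole series
#' is the window and every year is expected in-control.
#'
#' @param config The [generator_config()] used.
#' @param truth The `truth` element returned by [generate_dataset()].
#' @param kind Reference kind label for the window.
#' @param grace Detection-delay years after the shift with no expectation.
#' @return A list with `window` (a one-row refcon tibble) and `expected`
#'   (tibble `dataset`, `year`, `expected` in
#'   `in_control`/`out_of_control`/`NA` during the grace period).
#' @export
make_refcon_truth <- function(config, truth, kind = "refcon_chl",
                              grace = 5) {
  years <- truth$years
  if (is.null(truth$shift_year)) {
    window <- tibble::tibble(dataset = truth$dataset_id, kind = kind,
                             start_year = min(years),
                             end_year = max(years))
    expected <- tibble::tibble(dataset = truth$dataset_id, year = years,
                               expected = "in_control")
  } else {
    window <- tibble::tibble(dataset = truth$dataset_id, kind = kind,
                             start_year = min(years),
                             end_year = truth$shift_year - 1)
    expected <- tibble::tibble(
      dataset = truth$dataset_id, year = years,
      expected = dplyr::case_when(
        years < truth$shift_year ~ "in_control",
        years < truth$shift_year + grace ~ NA_character_,
        TRUE ~ "out_of_control"
      )
    )
  }
  list(window = window, expected = expected)
}

#' Matrices of independent standard-normal z-scores
#'
#' Null input for chart calibration (average run lengths, type-I error):
#' `n_series` independent series of `n_years` iid N(0, 1) draws.
#'
#' @param n_years Rows (years), at least 5.
#' @param n_series Columns (series).
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return A `n_years` x `n_series` numeric matrix.
#' @export
generate_null_zscores <- function(n_years, n_series, seed = 1) {
  if (n_years < 5) abort("n_years must be at least 5")
  with_private_seed(seed, {
    matrix(rnorm(n_years * n_series), n_years, n_series)
  })
}
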