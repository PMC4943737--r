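#' Read a taxon-resolved zooplankton sample table
#'
#' Reads a long-format monitoring table in which each row is one
#' taxon x station x date observation, validates it, and derives biomass
#' from abundance and individual mass where possible.
#'
#' The canonical columns are `dataset`, `station`, `date` (ISO 8601),
#' `taxon`, `stage` (`adult`, `copepodite`, `nauplius`, `unspecified`),
#' `abundance` (ind m^-3), `ind_mass` (ug WW ind^-1) and `biomass`
#' (mg WW m^-3); empty cells are missing values.  Files with different
#' headers are mapped through `schema`, and per-file unit declarations are
#' converted on ingest so that all downstream computation happens in the
#' canonical units.
#'
#' When abundance and individual mass are both present, biomass must equal
#' `abundance * ind_mass * 1e-3` (mg WW m^-3) to a relative tolerance of
#' 1e-6.  A stated biomass that disagrees beyond tolerance wins over the
#' product, with a warning: monitoring files often carry lab-computed
#' biomass that embeds stage-resolved weights.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(taxon = "species_name", abundance = "abund")`.  Unmapped canonical
#'   names are looked up verbatim.
#' @param units Optional named character vector declaring the file's units:
#'   `abundance` one of `"ind/m3"` (default) or `"ind/L"`; `ind_mass` one of
#'   `"ug"` (default) or `"mg"`; `biomass` one of `"mg/m3"` (default),
#'   `"ug/L"` (identical scale) or `"g/m3"`.
#' @return A tibble of validated sample records in canonical columns and
#'   units.
#' @seealso [read_taxon_traits()], [validate_dataset()], [write_samples()]
#' @export
read_samples <- function(path, schema = NULL, units = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    warn(paste0("no sample rows in ", path))
    return(empty_samples())
  }
  canonical <- c("dataset", "station", "date", "taxon", "stage",
                 "abundance", "ind_mass", "biomass")
  required <- c("dataset", "station", "date", "taxon")
  cols <- setNames(canonical, canonical)
  if (!is.null(schema)) cols[names(schema)] <- schema
  missing_req <- required[!cols[required] %in% names(raw)]
  if (length(missing_req) > 0) {
    abort(paste0("schema error: missing required column(s): ",
                 paste(cols[missing_req], collapse = ", ")))
  }
  pick <- function(nm) {
    if (cols[[nm]] %in% names(raw)) raw[[cols[[nm]]]] else NA_character_
  }
  out <- tibble::tibble(
    dataset = pick("dataset"),
    station = pick("station"),
    date = as.Date(pick("date")),
    taxon = pick("taxon"),
    stage = pick("stage"),
    abundance = as.numeric(pick("abundance")),
    ind_mass = as.numeric(pick("ind_mass")),
    biomass = as.numeric(pick("biomass"))
  )
  if (any(is.na(out$date))) {
    abort(paste0("unparseable date at row(s): ",
                 paste(head(which(is.na(out$date)), 5), collapse = ", ")))
  }
  out$stage[is.na(out$stage) | out$stage == ""] <- "unspecified"
  bad_stage <- setdiff(unique(out$stage), STAGE_LEVELS)
  if (length(bad_stage) > 0) {
    abort(paste0("unknown life stage(s): ", paste(bad_stage, collapse = ", ")))
  }
  out <- convert_units(out, units)
  validate_sample_records(out)
}

STAGE_LEVELS <- c("adult", "copepodite", "nauplius", "unspecified")

empty_samples <- function() {
  tibble::tibble(dataset = character(), station = character(),
                 date = as.Date(character()), taxon = character(),
                 stage = character(), abundance = numeric(),
                 ind_mass = numeric(), biomass = numeric())
}

convert_units <- function(samples, units) {
  if (is.null(units)) return(samples)
  conv <- list(
    abundance = c("ind/m3" = 1, "ind/L" = 1000),
    ind_mass = c("ug" = 1, "mg" = 1000),
    biomass = c("mg/m3" = 1, "ug/L" = 1, "g/m3" = 1000)
  )
  for (nm in names(units)) {
    if (!nm %in% names(conv)) abort(paste0("no unit declaration for: ", nm))
    f <- conv[[nm]][units[[nm]]]
    if (is.na(f)) abort(paste0("unsupported unit for ", nm, ": ", units[[nm]]))
    samples[[nm]] <- samples[[nm]] * unname(f)
  }
  samples
}

# Enforce the per-record invariants: non-negative densities, positive
# individual mass, at least one of abundance/biomass, and consistency of
# biomass with abundance x mass (stated biomass wins beyond tolerance).
validate_sample_records <- function(samples, rtol = 1e-6) {
  bad <- which(samples$abundance < 0 | samples$biomass < 0)
  if (length(bad) > 0) {
    abort(paste0("negative abundance/biomass at row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  bad <- which(samples$ind_mass <= 0)
  if (length(bad) > 0) {
    abort(paste0("non-positive individual mass at row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  neither <- which(is.na(samples$abundance) & is.na(samples$biomass))
  if (length(neither) > 0) {
    abort(paste0("rows with neither abundance nor biomass: ",
                 paste(head(neither, 5), collapse = ", ")))
  }
  derived <- samples$abundance * samples$ind_mass * 1e-3
  can_derive <- !is.na(derived)
  fill <- can_derive & is.na(samples$biomass)
  samples$biomass[fill] <- derived[fill]
  both <- can_derive & !fill
  if (any(both)) {
    rel <- abs(samples$biomass[both] - derived[both]) /
      pmax(abs(derived[both]), .Machine$double.xmin)
    if (any(rel > rtol)) {
      warn(paste0(sum(rel > rtol), " row(s) where stated biomass disagrees ",
                  "with abundance x mass beyond tolerance; keeping the ",
                  "stated biomass"))
    }
  }
  inform(paste0("read ", nrow(samples), " sample record(s)"))
  samples
}

#' Write a sample table in canonical format
#'
#' @param samples A sample tibble as returned by [read_samples()].
#' @param path Output CSV path.
#' @return `samples`, invisibly.
#' @export
write_samples <- function(samples, path) {
  readr::write_csv(samples, path, progress = FALSE)
  invisible(samples)
}

#' Read a taxon trait registry
#'
#' Reads the functional-group assignment used to pool taxa into the
#' indicator calculations: the major group, whether a copepod is calanoid,
#' whether a cladoceran is one of the predatory onychopods (e.g.
#' *Cercopagis*, *Bythotrephes*, *Leptodora* -- these are excluded from all
#' stock indicators), and whether the taxon belongs to the microphagous
#' mesozooplankton (rotifers, herbivorous cladocerans, tintinnids,
#' appendicularians, small ctenophores, pelagic harpacticoids).
#'
#' @param path Path to a CSV with columns `taxon`, `major_group`,
#'   `is_calanoid`, `is_predatory_cladoceran`, `is_microphagous`.
#' @return A tibble keyed by `taxon`.
#' @export
read_taxon_traits <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("taxon", "major_group", "is_calanoid",
            "is_predatory_cladoceran", "is_microphagous")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("schema error: missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  traits <- tibble::tibble(
    taxon = raw$taxon,
    major_group = raw$major_group,
    is_calanoid = parse_flag(raw$is_calanoid),
    is_predatory_cladoceran = parse_flag(raw$is_predatory_cladoceran),
    is_microphagous = parse_flag(raw$is_microphagous)
  )
  validate_taxon_traits(traits)
}

MAJOR_GROUPS <- c("copepod", "cladoceran", "rotifer", "tintinnid",
                  "appendicularian", "ctenophore", "harpacticoid", "other")

parse_flag <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
  if (any(is.na(out))) abort("unparseable logical flag in traits table")
  out
}

validate_taxon_traits <- function(traits) {
  dup <- traits$taxon[duplicated(traits$taxon)]
  if (length(dup) > 0) {
    abort(paste0("duplicate taxon in traits: ",
                 paste(unique(dup), collapse = ", ")))
  }
  bad <- setdiff(unique(traits$major_group), MAJOR_GROUPS)
  if (length(bad) > 0) {
    abort(paste0("unknown major_group value(s): ", paste(bad, collapse = ", ")))
  }
  off <- traits$is_calanoid & traits$major_group != "copepod"
  if (any(off)) {
    abort(paste0("is_calanoid set for non-copepod taxon: ",
                 paste(traits$taxon[off], collapse = ", ")))
  }
  off <- traits$is_predatory_cladoceran & traits$major_group != "cladoceran"
  if (any(off)) {
    abort(paste0("is_predatory_cladoceran set for non-cladoceran taxon: ",
                 paste(traits$taxon[off], collapse = ", ")))
  }
  off <- traits$is_predatory_cladoceran & traits$is_microphagous
  if (any(off)) {
    abort(paste0("predatory cladocerans cannot be microphagous: ",
                 paste(traits$taxon[off], collapse = ", ")))
  }
  traits
}

#' Read reference-period definitions
#'
#' Reference periods are year windows per dataset within which the
#' controlling mean and standard deviation of each indicator are estimated.
#' `kind` distinguishes windows derived from chlorophyll-a environmental
#' quality ratios (`refcon_chl`), from zooplanktivorous fish weight-at-age
#' (`refcon_fish`), and the degenerate whole-series window (`entire`).
#'
#' @param path Path to a CSV with columns `dataset`, `kind`, `start_year`,
#'   `end_year`.
#' @return A tibble of reference windows.
#' @export
read_refcon <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("dataset", "kind", "start_year", "end_year")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("schema error: missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  out <- tibble::tibble(
    dataset = raw$dataset,
    kind = raw$kind,
    start_year = as.integer(raw$start_year),
    end_year = as.integer(raw$end_year)
  )
  bad <- setdiff(unique(out$kind), c("refcon_chl", "refcon_fish", "entire"))
  if (length(bad) > 0) {
    abort(paste0("unknown reference kind(s): ", paste(bad, collapse = ", ")))
  }
  if (any(out$start_year > out$end_year)) {
    abort("reference window with start_year > end_year")
  }
  out
}

#' Cross-validate a sample table against a trait registry
#'
#' Produces a report-only summary of coverage problems: taxa present in the
#' samples but absent from the trait registry, dataset years with no summer
#' (June-September by default) samples, and the number of stations sampled
#' per dataset and year.  Running the check twice on the same inputs yields
#' identical reports.
#'
#' @param samples A sample tibble ([read_samples()]).
#' @param traits A trait registry ([read_taxon_traits()]).
#' @param months Months treated as the summer window.
#' @return A list of class `zoo_validation` with elements `issues` (tibble
#'   `type`, `dataset`, `detail`) and `stations_per_year` (tibble `dataset`,
#'   `year`, `n_stations`).
#' @export
validate_dataset <- function(samples, traits, months = 6:9) {
  unmapped <- sort(setdiff(unique(samples$taxon), traits$taxon))
  issues <- tibble::tibble(type = character(), dataset = character(),
                           detail = character())
  if (length(unmapped) > 0) {
    issues <- dplyr::bind_rows(issues, tibble::tibble(
      type = "unmapped_taxon", dataset = NA_character_, detail = unmapped))
  }
  if (nrow(samples) > 0) {
    cov <- samples |>
      dplyr::mutate(year = year_of(.data$date), month = month_of(.data$date)) |>
      dplyr::group_by(.data$dataset, .data$year) |>
      dplyr::summarise(summer = any(.data$month %in% months),
                       n_stations = dplyr::n_distinct(.data$station),
                       .groups = "drop")
    no_summer <- dplyr::filter(cov, !.data$summer)
    if (nrow(no_summer) > 0) {
      issues <- dplyr::bind_rows(issues, tibble::tibble(
        type = "no_summer_coverage", dataset = no_summer$dataset,
        detail = as.character(no_summer$year)))
    }
    spy <- dplyr::select(cov, "dataset", "year", "n_stations")
  } else {
    spy <- tibble::tibble(dataset = character(), year = integer(),
                          n_stations = integer())
  }
  structure(list(issues = issues, stations_per_year = spy),
            class = "zoo_validation")
}

#' @export
print.zoo_validation <- function(x, ...) {
  cat("<zoo_validation>\n")
  if (nrow(x$issues) == 0) {
    cat("  no issues found\n")
  } else {
    cat("  issues:\n")
    print(x$issues, n = 20)
  }
  invisible(x)
}

year_of <- function(date) as.integer(format(date, "%Y"))
month_of <- function(date) as.integer(format(date, "%m"))
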