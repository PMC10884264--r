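# Column order of the scenario CSV schema; units are part of the names.
.csv_columns <- c("scenario_id", "substance", "substance_mass_fraction",
                  "nonvolatile_volume_fraction", "solvent_vapor_pressure_pa",
                  "solvent_density_kg_m3", "substance_density_kg_m3",
                  "room_volume_m3", "air_exchange_per_h", "settling_height_m",
                  "personal_volume_m3", "exchange_flow_m3_min",
                  "spraying_time_min", "exposure_time_min", "mass_flow_g_min",
                  "mmd_um", "gsd", "application_type", "equipment",
                  "airborne_fraction_override")

.scenario_to_row <- function(scenario, id = "scenario_1") {
  liq <- scenario$liquid
  data.frame(
    scenario_id = id,
    substance = paste(names(liq$substance_mass_fractions), collapse = ";"),
    substance_mass_fraction = paste(liq$substance_mass_fractions,
                                    collapse = ";"),
    nonvolatile_volume_fraction = liq$nonvolatile_volume_fraction,
    solvent_vapor_pressure_pa = liq$solvent_vapor_pressure,
    solvent_density_kg_m3 = liq$solvent_density,
    substance_density_kg_m3 = liq$substance_density,
    room_volume_m3 = scenario$room$volume,
    air_exchange_per_h = scenario$room$air_exchange_rate,
    settling_height_m = scenario$room$settling_height,
    personal_volume_m3 = scenario$near_field$personal_volume,
    exchange_flow_m3_min = scenario$near_field$exchange_flow,
    spraying_time_min = scenario$timing$spraying_time,
    exposure_time_min = scenario$timing$exposure_time,
    mass_flow_g_min = scenario$mass_flow_rate,
    mmd_um = if (is.null(scenario$spectrum)) NA_real_ else scenario$spectrum$mmd,
    gsd = if (is.null(scenario$spectrum)) NA_real_ else scenario$spectrum$gsd,
    application_type = scenario$application_type,
    equipment = scenario$equipment,
    airborne_fraction_override =
      scenario$airborne_fraction_override %||% NA_real_,
    stringsAsFactors = FALSE
  )
}

.scenario_from_row <- function(row) {
  phis <- as.numeric(strsplit(as.character(row$substance_mass_fraction),
                              ";")[[1]])
  nm <- strsplit(as.character(row$substance %||% ""), ";")[[1]]
  if (length(nm) == length(phis)) names(phis) <- nm
  spec <- if (!is.null(row$mmd_um) && !is.na(row$mmd_um)) {
    droplet_spectrum(row$mmd_um, if (is.na(row$gsd)) 1.8 else row$gsd)
  }
  ov <- row$airborne_fraction_override
  spray_scenario(
    liquid = spray_liquid(phis,
                          solvent_vapor_pressure = row$solvent_vapor_pressure_pa,
                          nonvolatile_volume_fraction =
                            row$nonvolatile_volume_fraction,
                          solvent_density = row$solvent_density_kg_m3,
                          substance_density = row$substance_density_kg_m3),
    room = room(row$room_volume_m3, row$air_exchange_per_h,
                row$settling_height_m),
    timing = timing(row$spraying_time_min, row$exposure_time_min),
    near_field = near_field(row$personal_volume_m3, row$exchange_flow_m3_min),
    spectrum = spec,
    mass_flow_rate = row$mass_flow_g_min,
    application_type = as.character(row$application_type),
    equipment = as.character(row$equipment),
    airborne_fraction_override = if (is.null(ov) || is.na(ov)) NULL else ov
  )
}

.scenarios_from_table <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i) .scenario_from_row(tab[i, ]))
}

#' Read and write scenario tables (CSV)
#'
#' One row per scenario; column names carry the units
#' (`room_volume_m3`, `air_exchange_per_h`, ...). Multi-substance
#' formulations use semicolon-separated `substance` /
#' `substance_mass_fraction` entries. Extra columns (e.g.
#' `measured_twa_mg_m3`) are preserved by [read_scenario_csv()] as an
#' attribute `"extra"` and ignored by the scenario constructors.
#'
#' @param path File path.
#' @return `read_scenario_csv()`: a list of [spray_scenario()] objects,
#'   with the raw table in attribute `"table"`.
#' @export
read_scenario_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(.csv_columns, c("scenario_id", "substance")),
                     names(tab))
  if (length(missing) > 0) {
    stop("scenario CSV lacks columns: ", paste(missing, collapse = ", "))
  }
  out <- .scenarios_from_table(tab)
  names(out) <- tab$scenario_id %||% paste0("scenario_", seq_along(out))
  attr(out, "table") <- tab
  out
}

#' @rdname read_scenario_csv
#' @param scenarios A list of [spray_scenario()] objects (or a single one).
#' @export
write_scenario_csv <- function(scenarios, path) {
  if (inherits(scenarios, "spray_scenario")) scenarios <- list(scenarios)
  ids <- names(scenarios) %||% paste0("scenario_", seq_along(scenarios))
  if (is.null(names(scenarios))) names(scenarios) <- ids
  rows <- do.call(rbind, Map(.scenario_to_row, scenarios, names(scenarios)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write a single scenario configuration (YAML)
#'
#' A key/value tree mirroring the scenario constructors, with units in the
#' key names. Round-trips losslessly.
#'
#' @param path File path.
#' @return `read_scenario_config()`: a [spray_scenario()].
#' @examples
#' sc <- spray_scenario(
#'   liquid = spray_liquid(0.01, solvent_vapor_pressure = 2330),
#'   room = room(100, 0.6), timing = timing(10, 60), mass_flow_rate = 50,
#'   spectrum = droplet_spectrum(40)
#' )
#' f <- tempfile(fileext = ".yaml")
#' write_scenario_config(sc, f)
#' identical(read_scenario_config(f), sc)
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  phis <- unlist(cfg$liquid$substance_mass_fractions)
  spec <- if (!is.null(cfg$spectrum)) {
    droplet_spectrum(cfg$spectrum$mmd_um, cfg$spectrum$gsd)
  }
  spray_scenario(
    liquid = spray_liquid(phis,
                          solvent_vapor_pressure = cfg$liquid$solvent_vapor_pressure_pa,
                          nonvolatile_volume_fraction =
                            cfg$liquid$nonvolatile_volume_fraction,
                          solvent_density = cfg$liquid$solvent_density_kg_m3,
                          substance_density = cfg$liquid$substance_density_kg_m3),
    room = room(cfg$room$volume_m3, cfg$room$air_exchange_per_h,
                cfg$room$settling_height_m),
    timing = timing(cfg$timing$spraying_time_min, cfg$timing$exposure_time_min),
    near_field = near_field(cfg$near_field$personal_volume_m3,
                            cfg$near_field$exchange_flow_m3_min),
    spectrum = spec,
    mass_flow_rate = cfg$mass_flow_g_min,
    application_type = cfg$application_type,
    equipment = cfg$equipment,
    airborne_fraction_override = cfg$airborne_fraction_override
  )
}

#' @rdname read_scenario_config
#' @param scenario A [spray_scenario()].
#' @export
write_scenario_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "spray_scenario"))
  liq <- scenario$liquid
  cfg <- list(
    liquid = list(
      substance_mass_fractions = as.list(liq$substance_mass_fractions),
      solvent_vapor_pressure_pa = liq$solvent_vapor_pressure,
      nonvolatile_volume_fraction = liq$nonvolatile_volume_fraction,
      solvent_density_kg_m3 = liq$solvent_density,
      substance_density_kg_m3 = liq$substance_density
    ),
    room = list(volume_m3 = scenario$room$volume,
                air_exchange_per_h = scenario$room$air_exchange_rate,
                settling_height_m = scenario$room$settling_height),
    near_field = list(personal_volume_m3 = scenario$near_field$personal_volume,
                      exchange_flow_m3_min = scenario$near_field$exchange_flow),
    timing = list(spraying_time_min = scenario$timing$spraying_time,
                  exposure_time_min = scenario$timing$exposure_time),
    mass_flow_g_min = scenario$mass_flow_rate,
    application_type = scenario$application_type,
    equipment = scenario$equipment
  )
  if (!is.null(scenario$spectrum)) {
    cfg$spectrum <- list(mmd_um = scenario$spectrum$mmd,
                         gsd = scenario$spectrum$gsd)
  }
  if (!is.null(scenario$airborne_fraction_override)) {
    cfg$airborne_fraction_override <- scenario$airborne_fraction_override
  }
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
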