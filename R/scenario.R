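#' Spray liquid description
#'
#' @param substance_mass_fractions Numeric vector of mass fractions (0, 1]
#'   of the non-volatile substances of interest, optionally named.
#' @param nonvolatile_volume_fraction Total volume fraction of all
#'   non-volatile material in the liquid (phihat); controls the residual
#'   droplet size after solvent evaporation. Default 0.01 (conservative:
#'   smaller residues settle less).
#' @param solvent_vapor_pressure Saturation vapor pressure of the solvent,
#'   Pa (water at 20 degrees C: ~2330 Pa).
#' @param solvent_density,substance_density Densities, kg/m3 (default 1000).
#' @return An object of class `"spray_liquid"`.
#' @examples
#' spray_liquid(0.05, solvent_vapor_pressure = 2330)
#' @export
spray_liquid <- function(substance_mass_fractions,
                         solvent_vapor_pressure,
                         nonvolatile_volume_fraction = 0.01,
                         solvent_density = 1000,
                         substance_density = 1000) {
  stopifnot(is.numeric(substance_mass_fractions),
            length(substance_mass_fractions) >= 1,
            all(substance_mass_fractions > 0),
            all(substance_mass_fractions <= 1),
            sum(substance_mass_fractions) <= 1,
            solvent_vapor_pressure >= 0,
            nonvolatile_volume_fraction > 0, nonvolatile_volume_fraction < 1,
            solvent_density > 0, substance_density > 0)
  if (is.null(names(substance_mass_fractions))) {
    names(substance_mass_fractions) <-
      paste0("substance_", seq_along(substance_mass_fractions))
  }
  structure(list(
    substance_mass_fractions = substance_mass_fractions,
    total_nonvolatile_mass_fraction = sum(substance_mass_fractions),
    nonvolatile_volume_fraction = nonvolatile_volume_fraction,
    solvent_vapor_pressure = solvent_vapor_pressure,
    solvent_density = solvent_density,
    substance_density = substance_density
  ), class = "spray_liquid")
}

#' Room description
#'
#' @param volume Room volume Vr, m3.
#' @param air_exchange_rate Air exchange rate Gamma, 1/h (0 = unventilated).
#' @param settling_height Effective settling height Hs, m (default 3, a
#'   typical room height).
#' @return An object of class `"spray_room"`.
#' @export
room <- function(volume, air_exchange_rate, settling_height = 3) {
  stopifnot(volume > 0, air_exchange_rate >= 0, settling_height > 0)
  structure(list(volume = volume, air_exchange_rate = air_exchange_rate,
                 settling_height = settling_height), class = "spray_room")
}

#' Near-field (personal volume) description
#'
#' The residence time is always `Tp = Vp / Qp`; the defaults (10 m3 and
#' 100 m3/min) give 0.1 min.
#'
#' @param personal_volume Personal volume Vp, m3.
#' @param exchange_flow Exchange air flow Qp through the personal volume,
#'   m3/min.
#' @return An object of class `"spray_near_field"` with a `residence_time`
#'   field in minutes.
#' @examples
#' near_field()$residence_time  # 0.1 min
#' @export
near_field <- function(personal_volume = 10, exchange_flow = 100) {
  stopifnot(personal_volume > 0, exchange_flow > 0)
  structure(list(personal_volume = personal_volume,
                 exchange_flow = exchange_flow,
                 residence_time = personal_volume / exchange_flow),
            class = "spray_near_field")
}

#' Spraying and exposure times
#'
#' @param spraying_time Ts, min.
#' @param exposure_time T (spraying plus post-spraying), min.
#' @return An object of class `"spray_timing"`.
#' @export
timing <- function(spraying_time, exposure_time = spraying_time) {
  stopifnot(spraying_time > 0, exposure_time >= spraying_time)
  structure(list(spraying_time = spraying_time, exposure_time = exposure_time),
            class = "spray_timing")
}

#' Lognormal spray droplet spectrum
#'
#' @param mmd Mass median diameter, um.
#' @param gsd Geometric standard deviation (default 1.8).
#' @param size_class `"fine"` or `"coarse"`; derived from `mmd` via
#'   [classify_droplet_size()] when not given.
#' @return An object of class `"droplet_spectrum"`.
#' @export
droplet_spectrum <- function(mmd, gsd = 1.8, size_class = NULL) {
  stopifnot(mmd > 0, gsd > 1)
  if (is.null(size_class)) size_class <- classify_droplet_size(mmd)
  size_class <- match.arg(size_class, c("fine", "coarse"))
  structure(list(mmd = mmd, gsd = gsd, size_class = size_class),
            class = "droplet_spectrum")
}

.application_types <- c("surface_spraying", "room_spraying")
.equipment_types <- c("none", "flat_fan_or_hollow_cone", "handheld_pump",
                      "fogger")

#' Full spray scenario
#'
#' Collects everything the two-box model and its refinements need to
#' describe a single spray event.
#'
#' @param liquid A [spray_liquid()].
#' @param room A [room()].
#' @param timing A [timing()].
#' @param mass_flow_rate Mass flow rate of sprayed liquid, g/min.
#' @param near_field A [near_field()]; defaults give a 0.1 min residence.
#' @param spectrum Optional [droplet_spectrum()]; required by the refined
#'   (correction-factor) model.
#' @param application_type `"surface_spraying"` or `"room_spraying"`. Room
#'   spraying releases the full spray to air (airborne fraction 1).
#' @param equipment Spraying equipment; used by the release-fraction
#'   refinement to pick a measured airborne fraction.
#' @param airborne_fraction_override Optional airborne fraction in (0, 1]
#'   that overrides all defaults.
#' @return An object of class `"spray_scenario"`.
#' @examples
#' sc <- spray_scenario(
#'   liquid = spray_liquid(0.01, solvent_vapor_pressure = 2330),
#'   room = room(100, 0.6),
#'   timing = timing(10, 60),
#'   mass_flow_rate = 50,
#'   spectrum = droplet_spectrum(80)
#' )
#' sc
#' @export
spray_scenario <- function(liquid, room, timing, mass_flow_rate,
                           near_field = sprayscreen::near_field(),
                           spectrum = NULL,
                           application_type = c("surface_spraying",
                                                "room_spraying"),
                           equipment = c("none", "flat_fan_or_hollow_cone",
                                         "handheld_pump", "fogger"),
                           airborne_fraction_override = NULL) {
  stopifnot(inherits(liquid, "spray_liquid"), inherits(room, "spray_room"),
            inherits(timing, "spray_timing"),
            inherits(near_field, "spray_near_field"),
            is.null(spectrum) || inherits(spectrum, "droplet_spectrum"),
            mass_flow_rate >= 0)
  application_type <- match.arg(application_type)
  equipment <- match.arg(equipment)
  if (!is.null(airborne_fraction_override)) {
    if (!(airborne_fraction_override > 0 && airborne_fraction_override <= 1)) {
      stop("airborne_fraction_override must lie in (0, 1]")
    }
  }
  structure(list(liquid = liquid, room = room, timing = timing,
                 near_field = near_field, spectrum = spectrum,
                 mass_flow_rate = mass_flow_rate,
                 application_type = application_type, equipment = equipment,
                 airborne_fraction_override = airborne_fraction_override),
            class = "spray_scenario")
}

#' @export
print.spray_scenario <- function(x, ...) {
  cat("Spray scenario\n")
  cat(sprintf("  liquid: %d substance(s), phi = %.4g, phihat = %.3g, vapor pressure %.4g Pa (class %d)\n",
              length(x$liquid$substance_mass_fractions),
              x$liquid$total_nonvolatile_mass_fraction,
              x$liquid$nonvolatile_volume_fraction,
              x$liquid$solvent_vapor_pressure,
              classify_vapor_pressure(x$liquid$solvent_vapor_pressure)))
  cat(sprintf("  room: %.5g m3, %.3g / h air exchange, Hs = %.3g m\n",
              x$room$volume, x$room$air_exchange_rate, x$room$settling_height))
  cat(sprintf("  near field: Vp = %.3g m3, Qp = %.3g m3/min (Tp = %.3g min)\n",
              x$near_field$personal_volume, x$near_field$exchange_flow,
              x$near_field$residence_time))
  cat(sprintf("  timing: Ts = %.4g min of T = %.4g min\n",
              x$timing$spraying_time, x$timing$exposure_time))
  cat(sprintf("  source: %.4g g/min, %s, equipment %s\n",
              x$mass_flow_rate, x$application_type, x$equipment))
  if (!is.null(x$spectrum)) {
    cat(sprintf("  spectrum: MMD %.4g um, GSD %.3g (%s)\n",
                x$spectrum$mmd, x$spectrum$gsd, x$spectrum$size_class))
  }
  cat(sprintf("  airborne fraction: %.3g (%s)\n",
              select_airborne_fraction(x), attr(select_airborne_fraction(x),
                                                "provenance")))
  invisible(x)
}

#' Vapor pressure class of a solvent
#'
#' Class 1: p <= 10 Pa; class 2: 10 < p < 1000 Pa; class 3: p >= 1000 Pa.
#' The boundaries are inclusive towards the outer classes, so 10 Pa is
#' class 1 and 1000 Pa is class 3.
#'
#' @param p Vapor pressure(s), Pa.
#' @return Integer class(es) in 1:3.
#' @examples
#' classify_vapor_pressure(c(5, 10, 100, 2330))
#' @export
classify_vapor_pressure <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0)) stop("vapor pressure must be non-negative")
  ifelse(p <= 10, 1L, ifelse(p < 1000, 2L, 3L))
}

#' Droplet size class of a spray spectrum
#'
#' Fine sprays have MMD below 80 um (propellant cans, foggers, high
#' pressure nozzles); coarse sprays (MMD >= 80 um) come from nozzles at low
#' pressure.
#'
#' @param mmd Mass median diameter(s), um.
#' @return `"fine"` or `"coarse"`.
#' @export
classify_droplet_size <- function(mmd) {
  stopifnot(is.numeric(mmd))
  if (any(mmd <= 0)) stop("mmd must be positive")
  ifelse(mmd < 80, "fine", "coarse")
}

#' Airborne release fraction of a scenario
#'
#' Room spraying releases everything to air (`F_A = 1`). For surface
#' spraying, equipment-specific chamber measurements give 0.01 for flat fan
#' or hollow cone nozzles and 0.1 for handheld pump sprays; other equipment
#' falls back to the conservative 0.3 default. An explicit override always
#' wins.
#'
#' @param scenario A [spray_scenario()].
#' @return The airborne fraction in (0, 1], with a `"provenance"` attribute
#'   (`"override"`, `"room"`, `"equipment"` or `"default"`).
#' @export
select_airborne_fraction <- function(scenario) {
  stopifnot(inherits(scenario, "spray_scenario"))
  if (!is.null(scenario$airborne_fraction_override)) {
    return(structure(scenario$airborne_fraction_override,
                     provenance = "override"))
  }
  if (scenario$application_type == "room_spraying") {
    return(structure(1, provenance = "room"))
  }
  fa <- switch(scenario$equipment,
               flat_fan_or_hollow_cone = structure(0.01, provenance = "equipment"),
               handheld_pump = structure(0.1, provenance = "equipment"),
               structure(0.3, provenance = "default"))
  fa
}

#' Residence times of the two boxes
#'
#' `residence_time()` returns the near-field residence `Tp = Vp/Qp` in
#' minutes; `ventilation_residence_time()` the mean far-field residence
#' `1/Gamma` in minutes (e.g. 3 min at 20/h).
#'
#' @param near_field A [near_field()].
#' @return Minutes.
#' @export
residence_time <- function(near_field = sprayscreen::near_field()) {
  stopifnot(inherits(near_field, "spray_near_field"))
  near_field$residence_time
}

#' @rdname residence_time
#' @param air_exchange_rate Air exchange rate, 1/h.
#' @export
ventilation_residence_time <- function(air_exchange_rate) {
  stopifnot(air_exchange_rate > 0)
  60 / air_exchange_rate
}
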