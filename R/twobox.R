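#' Near-field concentration during spraying
#'
#' The personal volume is fed at `Mdot * phi` and flushed at `Qp`, giving a
#' constant plateau concentration `Mdot * phi / Qp` while spraying.
#'
#' @param mass_flow_rate Liquid mass flow rate, g/min.
#' @param mass_fraction Substance mass fraction in the liquid.
#' @param exchange_flow Near-field exchange flow Qp, m3/min.
#' @return Concentration, mg/m3.
#' @examples
#' near_field_concentration(100, 0.1, 100)  # 100 mg/m3
#' @export
near_field_concentration <- function(mass_flow_rate, mass_fraction,
                                     exchange_flow = 100) {
  stopifnot(mass_flow_rate >= 0, mass_fraction >= 0)
  if (any(exchange_flow <= 0)) stop("exchange_flow must be positive")
  1000 * mass_flow_rate * mass_fraction / exchange_flow
}

#' Far-field concentration profile
#'
#' Well-mixed room mass balance: the concentration rises as
#' `(1 - exp(-Gamma t))` towards `Mdot phi / (Vr Gamma)` while spraying and
#' decays exponentially afterwards. The unventilated limit (`Gamma = 0`) is
#' handled analytically (linear rise, constant decay plateau).
#'
#' @param t Time(s) since the start of spraying, min.
#' @param mass_flow_rate Liquid mass flow rate, g/min.
#' @param mass_fraction Substance mass fraction.
#' @param volume Room volume, m3.
#' @param air_exchange_rate Gamma, 1/h.
#' @param spraying_time Ts, min.
#' @return Concentration(s), mg/m3.
#' @export
far_field_profile <- function(t, mass_flow_rate, mass_fraction, volume,
                              air_exchange_rate, spraying_time) {
  stopifnot(volume > 0, air_exchange_rate >= 0, spraying_time > 0)
  if (any(t < 0)) stop("t must be non-negative")
  g <- air_exchange_rate / 60  # 1/min
  src <- 1000 * mass_flow_rate * mass_fraction / volume  # mg/(m3 min)
  ts <- pmin(t, spraying_time)
  if (g * max(t, spraying_time) < 1e-10) {
    rise <- src * ts
    return(rise)  # no decay without ventilation
  }
  peak_t <- src / g * (1 - exp(-g * ts))
  decay <- exp(-g * pmax(t - spraying_time, 0))
  peak_t * decay
}

# integral of exp(-g a) * min(Ts, T - a) over a in [0, T], minutes^2;
# the series branch avoids 0/0 for small Gamma * T.
.twa_kernel <- function(g, Ts, T) {
  if (g * T < 1e-5) {
    D <- T - Ts
    Ts * (T - Ts / 2) - g * (Ts^3 / 6 + Ts^2 * D / 2 + Ts * D^2 / 2)
  } else {
    Ts / g + exp(-g * (T - Ts)) * expm1(-g * Ts) / g^2
  }
}

#' Time-weighted average near-field concentration
#'
#' The plateau concentration weighted by the spraying duty cycle `Ts/T`.
#'
#' @inheritParams near_field_concentration
#' @param spraying_time Ts, min.
#' @param exposure_time T, min.
#' @return TWA concentration, mg/m3.
#' @export
twa_near_field <- function(mass_flow_rate, mass_fraction, exchange_flow = 100,
                           spraying_time, exposure_time) {
  if (any(exposure_time <= 0)) stop("exposure_time must be positive")
  stopifnot(all(spraying_time > 0), all(spraying_time <= exposure_time))
  near_field_concentration(mass_flow_rate, mass_fraction, exchange_flow) *
    spraying_time / exposure_time
}

#' Time-weighted average far-field concentration
#'
#' Closed-form time integral of the far-field profile over the exposure
#' time, `Mdot phi / (Vr T) * [Ts/Gamma - exp(-Gamma (T-Ts)) (1 -
#' exp(-Gamma Ts)) / Gamma^2]`, with a series expansion below
#' `Gamma T < 1e-6` that converges to `Mdot phi Ts (T - Ts/2) / (Vr T)`.
#'
#' @inheritParams far_field_profile
#' @param exposure_time T, min.
#' @return TWA concentration, mg/m3.
#' @export
twa_far_field <- function(mass_flow_rate, mass_fraction, volume,
                          air_exchange_rate, spraying_time, exposure_time) {
  if (any(volume <= 0)) stop("volume must be positive")
  stopifnot(all(air_exchange_rate >= 0), all(spraying_time > 0),
            all(spraying_time <= exposure_time))
  src <- 1000 * mass_flow_rate * mass_fraction / volume
  n <- max(length(src), length(air_exchange_rate), length(spraying_time),
           length(exposure_time))
  src <- rep_len(src, n)
  g <- rep_len(air_exchange_rate / 60, n)
  Ts <- rep_len(spraying_time, n)
  T <- rep_len(exposure_time, n)
  A <- vapply(seq_len(n), function(i) .twa_kernel(g[i], Ts[i], T[i]),
              numeric(1))
  src * A / T
}

#' Corrected TWA according to the refined two-box model
#'
#' `C_corr = C_nf * xi + C_ff * kappa * F_A`.
#'
#' @param twa_nf,twa_ff Near- and far-field TWA contributions, mg/m3.
#' @param xi,kappa Near- and far-field correction factors in (0, 1].
#' @param fa Airborne release fraction in (0, 1].
#' @return Corrected TWA, mg/m3.
#' @export
twa_corrected <- function(twa_nf, twa_ff, xi = 1, kappa = 1, fa = 1) {
  for (f in list(xi, kappa, fa)) {
    if (any(f <= 0) || any(f > 1)) stop("correction factors must lie in (0, 1]")
  }
  stopifnot(all(twa_nf >= 0), all(twa_ff >= 0))
  twa_nf * xi + twa_ff * kappa * fa
}

#' Two-box screening estimate for a spray scenario
#'
#' The main entry point: computes, per substance, the near-field, far-field
#' and total TWA concentrations of the generic two-box model, and the
#' corrected TWA of the selected refinement.
#'
#' Model variants:
#' \describe{
#'   \item{`generic`}{all sprayed mass is treated as airborne
#'     (`xi = kappa = F_A = 1`).}
#'   \item{`refined`}{mean correction factors for droplet evaporation and
#'     settling are looked up from `grid` by spraying/exposure time, air
#'     exchange rate, vapor pressure class and droplet size class, and the
#'     airborne fraction defaults to 0.3 for surface spraying (1 for room
#'     spraying).}
#'   \item{`release_fraction`}{no aerosol-dynamics correction, but the
#'     airborne fraction is taken from equipment-specific measurements via
#'     [select_airborne_fraction()].}
#' }
#'
#' @param scenario A [spray_scenario()].
#' @param model Model variant, see Details.
#' @param grid Correction-factor table for the refined variant; defaults to
#'   the packaged table ([reference_correction_factors()]).
#' @param physics A [physics_params()] object (only used when
#'   `recompute_factors = TRUE`).
#' @param recompute_factors If `TRUE`, the refined variant computes the
#'   scenario-specific factors from the aerosol physics via
#'   [correction_factor()] instead of the table lookup.
#' @return An object of class `"spray_twobox"`: a list with the per
#'   substance results table (`$twa`, mg/m3), the factors used
#'   (`$factors`), and the scenario.
#' @examples
#' sc <- spray_scenario(
#'   liquid = spray_liquid(c(biocide = 0.01), solvent_vapor_pressure = 2330),
#'   room = room(100, 0.6), timing = timing(10, 60), mass_flow_rate = 50,
#'   spectrum = droplet_spectrum(80)
#' )
#' spray_twobox(sc, model = "refined")
#' @export
spray_twobox <- function(scenario,
                         model = c("generic", "refined", "release_fraction"),
                         grid = NULL, physics = physics_params(),
                         recompute_factors = FALSE) {
  stopifnot(inherits(scenario, "spray_scenario"))
  model <- match.arg(model)
  liq <- scenario$liquid
  phis <- liq$substance_mass_fractions
  tm <- scenario$timing
  nf_twa <- twa_near_field(scenario$mass_flow_rate, phis,
                           scenario$near_field$exchange_flow,
                           tm$spraying_time, tm$exposure_time)
  ff_twa <- twa_far_field(scenario$mass_flow_rate, phis,
                          scenario$room$volume, scenario$room$air_exchange_rate,
                          tm$spraying_time, tm$exposure_time)

  xi <- 1; kappa <- 1; fa <- 1
  prov <- c(xi = "identity", kappa = "identity", fa = "identity")
  if (model == "refined") {
    if (scenario$application_type == "room_spraying") {
      fa <- 1; prov["fa"] <- "room"
    } else if (!is.null(scenario$airborne_fraction_override)) {
      fa <- scenario$airborne_fraction_override; prov["fa"] <- "override"
    } else {
      fa <- 0.3; prov["fa"] <- "default"
    }
    if (is.null(scenario$spectrum)) {
      stop("the refined model needs a droplet spectrum in the scenario")
    }
    if (recompute_factors) {
      xi <- correction_factor(scenario$spectrum$mmd,
                              liq$solvent_vapor_pressure,
                              tm$spraying_time, tm$exposure_time,
                              scenario$room$air_exchange_rate,
                              compartment = "near_field", physics = physics,
                              nonvolatile_volume_fraction =
                                liq$nonvolatile_volume_fraction,
                              settling_height = scenario$room$settling_height,
                              residence_time = scenario$near_field$residence_time)
      kappa <- correction_factor(scenario$spectrum$mmd,
                                 liq$solvent_vapor_pressure,
                                 tm$spraying_time, tm$exposure_time,
                                 scenario$room$air_exchange_rate,
                                 compartment = "far_field", physics = physics,
                                 nonvolatile_volume_fraction =
                                   liq$nonvolatile_volume_fraction,
                                 settling_height = scenario$room$settling_height,
                                 residence_time = scenario$near_field$residence_time)
      prov[c("xi", "kappa")] <- "computed"
    } else {
      if (is.null(grid)) grid <- reference_correction_factors()
      lk <- lookup_correction_factors(
        tm$spraying_time, tm$exposure_time, scenario$room$air_exchange_rate,
        classify_vapor_pressure(liq$solvent_vapor_pressure),
        scenario$spectrum$size_class, grid)
      xi <- lk$xi_bar; kappa <- lk$kappa_bar
      prov[c("xi", "kappa")] <- "table"
    }
  } else if (model == "release_fraction") {
    fa <- select_airborne_fraction(scenario)
    prov["fa"] <- attr(fa, "provenance")
    fa <- as.numeric(fa)
  }

  corr <- twa_corrected(nf_twa, ff_twa, xi, kappa, fa)
  res <- data.frame(substance = names(phis), mass_fraction = as.numeric(phis),
                    twa_near_field = as.numeric(nf_twa),
                    twa_far_field = as.numeric(ff_twa),
                    twa_total = as.numeric(nf_twa + ff_twa),
                    twa_corrected = as.numeric(corr),
                    row.names = NULL)
  structure(list(twa = res,
                 factors = data.frame(xi = xi, kappa = kappa, fa = fa,
                                      xi_provenance = prov[["xi"]],
                                      kappa_provenance = prov[["kappa"]],
                                      fa_provenance = prov[["fa"]]),
                 model = model, scenario = scenario),
            class = "spray_twobox")
}

#' @export
print.spray_twobox <- function(x, digits = 4, ...) {
  cat(sprintf("Two-box spray exposure estimate (%s model), mg/m3\n", x$model))
  print(format(x$twa, digits = digits), row.names = FALSE)
  f <- x$factors
  cat(sprintf("factors: xi = %.3g (%s), kappa = %.3g (%s), F_A = %.3g (%s)\n",
              f$xi, f$xi_provenance, f$kappa, f$kappa_provenance,
              f$fa, f$fa_provenance))
  invisible(x)
}

#' @export
summary.spray_twobox <- function(object, ...) {
  x <- object
  print(x)
  tm <- x$scenario$timing
  cat(sprintf("exposure: Ts = %.4g min of T = %.4g min; room %.5g m3 at %.3g / h\n",
              tm$spraying_time, tm$exposure_time, x$scenario$room$volume,
              x$scenario$room$air_exchange_rate))
  share <- x$twa$twa_near_field / pmax(x$twa$twa_total, .Machine$double.xmin)
  cat(sprintf("near-field share of the uncorrected TWA: %s\n",
              paste(sprintf("%.1f%%", 100 * share), collapse = ", ")))
  invisible(x)
}

#' Concentration-time plot for a two-box estimate
#'
#' Draws the far-field profile and the near-field plateau (during spraying)
#' for the substance with the highest mass fraction.
#'
#' @param x A `"spray_twobox"` object.
#' @param n Number of time points.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the data frame of plotted values.
#' @export
plot.spray_twobox <- function(x, n = 400, ...) {
  sc <- x$scenario
  i <- which.max(sc$liquid$substance_mass_fractions)
  phi <- sc$liquid$substance_mass_fractions[i]
  t <- seq(0, sc$timing$exposure_time, length.out = n)
  ff <- far_field_profile(t, sc$mass_flow_rate, phi, sc$room$volume,
                          sc$room$air_exchange_rate, sc$timing$spraying_time)
  nf <- ifelse(t <= sc$timing$spraying_time,
               near_field_concentration(sc$mass_flow_rate, phi,
                                        sc$near_field$exchange_flow), 0)
  graphics::plot(t, nf + ff, type = "l", xlab = "time [min]",
                 ylab = "concentration [mg/m3]",
                 main = sprintf("Two-box profile (%s)",
                                names(sc$liquid$substance_mass_fractions)[i]),
                 ...)
  graphics::lines(t, ff, lty = 2)
  graphics::legend("topright", legend = c("near field (total)", "far field"),
                   lty = 1:2, bty = "n")
  invisible(data.frame(t = t, near_field = nf + ff, far_field = ff))
}
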