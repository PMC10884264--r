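#' Physical constants and numerical controls for the aerosol model
#'
#' Bundles the physical constants and numerical settings used by the
#' droplet evaporation/settling compartment model. The defaults were fixed
#' once by calibrating the reconstructed compartment model against the
#' packaged mean correction-factor table (see
#' `vignette("spray-model", package = "sprayscreen")`) and should normally
#' be left alone.
#'
#' @param air_viscosity Dynamic viscosity of air, Pa s (default 1.81e-5 at
#'   20 degrees C).
#' @param air_temperature Air temperature, K.
#' @param air_density Air density, kg/m3.
#' @param air_mean_free_path Mean free path of air molecules, m; enters the
#'   Cunningham slip correction for micrometre-sized particles.
#' @param gravity Gravitational acceleration, m/s2.
#' @param solvent_molar_mass Molar mass of the solvent, kg/mol (default:
#'   water).
#' @param solvent_vapor_diffusivity Diffusion coefficient of solvent vapor
#'   in air, m2/s.
#' @param evaporative_cooling_factor Dimensionless factor (0, 1] scaling the
#'   d-squared-law evaporation constant to account for the wet-bulb
#'   temperature depression of an evaporating droplet; 1 means isothermal
#'   evaporation at `air_temperature`.
#' @param drag_regime `"transition_corrected"` applies the Schiller-Naumann
#'   drag correction to the terminal settling velocity (it reduces smoothly
#'   to Stokes' law for small droplets); `"stokes"` uses pure Stokes
#'   settling for all sizes.
#' @param slip_correction Logical; apply the Cunningham slip correction
#'   (matters below ~10 um).
#' @param near_field_deposition_efficiency Fraction of the quiescent-air
#'   settling flux that is effective as a deposition loss during the short,
#'   strongly stirred transit of spray through the personal volume
#'   (calibrated, default 0.45).
#' @param inhalable_sampling Logical; weight the near-field breathing-zone
#'   concentration by the EN 481 inhalable sampling convention. The
#'   far-field concentration is never filtered.
#' @param n_bins Number of mass-weighted droplet-size bins used to
#'   discretize the lognormal spray spectrum.
#' @param span_sd Half-width of the discretized spectrum, in units of
#'   ln(geometric standard deviation).
#' @param n_ages Number of nodes of the droplet-age grid used in the
#'   compartment time integrals.
#'
#' @return An object of class `"physics_params"` (a named list).
#' @examples
#' p <- physics_params()
#' settling_velocity(10, physics = p)  # ~3e-3 m/s for a 10 um unit-density droplet
#' @export
physics_params <- function(air_viscosity = 1.81e-5,
                           air_temperature = 293.15,
                           air_density = 1.204,
                           air_mean_free_path = 66.5e-9,
                           gravity = 9.81,
                           solvent_molar_mass = 0.018,
                           solvent_vapor_diffusivity = 2.4e-5,
                           evaporative_cooling_factor = 0.8,
                           drag_regime = c("transition_corrected", "stokes"),
                           slip_correction = TRUE,
                           near_field_deposition_efficiency = 0.45,
                           inhalable_sampling = TRUE,
                           n_bins = 120,
                           span_sd = 4,
                           n_ages = 1600) {
  drag_regime <- match.arg(drag_regime)
  p <- list(
    air_viscosity = air_viscosity,
    air_temperature = air_temperature,
    air_density = air_density,
    air_mean_free_path = air_mean_free_path,
    gravity = gravity,
    solvent_molar_mass = solvent_molar_mass,
    solvent_vapor_diffusivity = solvent_vapor_diffusivity,
    evaporative_cooling_factor = evaporative_cooling_factor,
    drag_regime = drag_regime,
    slip_correction = slip_correction,
    near_field_deposition_efficiency = near_field_deposition_efficiency,
    inhalable_sampling = inhalable_sampling,
    n_bins = as.integer(n_bins),
    span_sd = span_sd,
    n_ages = as.integer(n_ages)
  )
  num <- p[!(names(p) %in% c("drag_regime", "slip_correction",
                             "inhalable_sampling"))]
  stopifnot(all(vapply(num, function(x) is.numeric(x) && all(x > 0), logical(1))))
  stopifnot(evaporative_cooling_factor <= 1,
            near_field_deposition_efficiency <= 1)
  class(p) <- "physics_params"
  p
}

#' @export
print.physics_params <- function(x, ...) {
  cat("Aerosol physics parameters\n")
  cat(sprintf("  air: eta = %.3g Pa s, T = %.2f K, rho = %.3g kg/m3\n",
              x$air_viscosity, x$air_temperature, x$air_density))
  cat(sprintf("  solvent: M = %.3g kg/mol, D = %.3g m2/s, cooling factor = %.2f\n",
              x$solvent_molar_mass, x$solvent_vapor_diffusivity,
              x$evaporative_cooling_factor))
  cat(sprintf("  drag: %s, slip correction: %s\n", x$drag_regime, x$slip_correction))
  cat(sprintf("  near field: deposition efficiency = %.2f, inhalable sampling: %s\n",
              x$near_field_deposition_efficiency, x$inhalable_sampling))
  cat(sprintf("  discretization: %d bins over +-%g ln(GSD), %d age nodes\n",
              x$n_bins, x$span_sd, x$n_ages))
  invisible(x)
}

GAS_CONSTANT <- 8.314462  # J/(mol K)

.cunningham <- function(d_m, physics) {
  kn <- 2 * physics$air_mean_free_path / d_m
  1 + kn * (1.165 + 0.483 * exp(-0.997 / kn))
}

.v_stokes <- function(d_m, particle_density, physics) {
  v <- particle_density * physics$gravity * d_m^2 / (18 * physics$air_viscosity)
  if (physics$slip_correction) v <- v * .cunningham(d_m, physics)
  v
}

# Terminal velocity interpolator on a log-log grid; solving the
# Schiller-Naumann fixed point once per call chain keeps the per-bin
# evaluation cheap inside the compartment integrals.
.settling_interpolator <- function(particle_density, physics) {
  if (physics$drag_regime == "stokes") {
    return(function(d_um) .v_stokes(d_um * 1e-6, particle_density, physics))
  }
  dg <- exp(seq(log(1e-8), log(5e-3), length.out = 400))
  vs <- .v_stokes(dg, particle_density, physics)
  v <- vs
  for (i in 1:200) {
    re <- physics$air_density * v * dg / physics$air_viscosity
    v <- 0.5 * v + 0.5 * vs / (1 + 0.15 * re^0.687)
  }
  ld <- log(dg); lv <- log(v)
  function(d_um) {
    d <- pmax(d_um, 1e-6) * 1e-6
    out <- exp(approx(ld, lv, xout = log(d), rule = 2)$y)
    out[d_um <= 0] <- 0
    dim(out) <- dim(d_um)
    out
  }
}

#' Terminal settling velocity of a droplet
#'
#' Stokes' law with optional Cunningham slip correction, and (by default) the
#' Schiller-Naumann drag correction which becomes important above roughly
#' 80 um where droplets leave the Stokes regime.
#'
#' @param d Droplet diameter(s), um.
#' @param particle_density Droplet density, kg/m3.
#' @param physics A [physics_params()] object.
#' @return Terminal velocity, m/s (0 for `d = 0`).
#' @examples
#' settling_velocity(c(1, 10, 100, 320))
#' @export
settling_velocity <- function(d, particle_density = 1000,
                              physics = physics_params()) {
  stopifnot(is.numeric(d), all(d >= 0))
  .settling_interpolator(particle_density, physics)(d)
}

#' d-squared-law evaporation constant
#'
#' Quasi-steady diffusion-limited evaporation into vapor-free air:
#' `K = f_cool * 8 D M p / (rho_l R T)` so that `d^2(t) = d0^2 - K t`.
#'
#' @param vapor_pressure Solvent saturation vapor pressure, Pa.
#' @param liquid_density Droplet liquid density, kg/m3.
#' @param physics A [physics_params()] object.
#' @return Evaporation constant, m2/s.
#' @export
evaporation_constant <- function(vapor_pressure, liquid_density = 1000,
                                 physics = physics_params()) {
  stopifnot(vapor_pressure >= 0)
  physics$evaporative_cooling_factor * 8 * physics$solvent_vapor_diffusivity *
    physics$solvent_molar_mass * vapor_pressure /
    (liquid_density * GAS_CONSTANT * physics$air_temperature)
}

#' Droplet diameter after partial solvent evaporation
#'
#' Applies the clamped d-squared law: the squared diameter shrinks linearly
#' in time and is clamped at the non-volatile residual diameter
#' `d_res = d0 * phihat^(1/3)`.
#'
#' @param d0 Initial diameter(s), um.
#' @param vapor_pressure Solvent vapor pressure, Pa.
#' @param elapsed Elapsed time(s), s.
#' @param nonvolatile_volume_fraction Volume fraction of non-volatile
#'   material in the droplet (phihat).
#' @param liquid_density Droplet density, kg/m3.
#' @param physics A [physics_params()] object.
#' @return Diameter(s), um.
#' @examples
#' evaporate_diameter(320, 1000, Inf)  # residual: 320 * 0.01^(1/3) ~ 68.97 um
#' @export
evaporate_diameter <- function(d0, vapor_pressure, elapsed,
                               nonvolatile_volume_fraction = 0.01,
                               liquid_density = 1000,
                               physics = physics_params()) {
  stopifnot(all(elapsed >= 0), nonvolatile_volume_fraction > 0,
            nonvolatile_volume_fraction < 1)
  K <- evaporation_constant(vapor_pressure, liquid_density, physics) * 1e12  # um2/s
  dres2 <- (d0 * nonvolatile_volume_fraction^(1 / 3))^2
  sqrt(pmax(d0^2 - K * elapsed, dres2))
}

#' EN 481 inhalable sampling convention
#'
#' Mass fraction of airborne particles of aerodynamic diameter `d` that is
#' inhalable: `I(d) = 0.5 (1 + exp(-0.06 d))`, with `d` capped at 100 um
#' where the convention is defined.
#'
#' @param d Aerodynamic diameter(s), um.
#' @return Inhalable fraction in (0.5, 1].
#' @export
inhalable_fraction <- function(d) {
  stopifnot(all(d >= 0))
  0.5 * (1 + exp(-0.06 * pmin(d, 100)))
}
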