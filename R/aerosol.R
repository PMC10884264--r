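#' Mass-weighted discretization of a lognormal droplet spectrum
#'
#' Splits the lognormal mass distribution into `n_bins` bins equally spaced
#' in `ln d` over `+- span_sd * ln(gsd)`, each carrying the mass fraction
#' between its edges (renormalized to sum to 1). `n_bins = 1` degenerates
#' to a monodisperse spray at the MMD.
#'
#' @param spectrum A [droplet_spectrum()].
#' @param n_bins Number of bins (>= 1).
#' @param span_sd Half-width in units of `ln(gsd)`.
#' @param nonvolatile_volume_fraction Phihat, used for the residual
#'   diameters reported alongside.
#' @return A data frame with `initial_diameter` (um, geometric bin
#'   midpoints), `residual_diameter` (um) and `mass_weight`.
#' @examples
#' b <- discretize_spectrum(droplet_spectrum(80), n_bins = 200)
#' sum(b$mass_weight)                      # 1
#' sum(b$mass_weight[b$initial_diameter < 80])  # ~0.5 (median property)
#' @export
discretize_spectrum <- function(spectrum, n_bins = 120, span_sd = 4,
                                nonvolatile_volume_fraction = 0.01) {
  stopifnot(inherits(spectrum, "droplet_spectrum"), n_bins >= 1)
  mu <- log(spectrum$mmd)
  s <- log(spectrum$gsd)
  if (n_bins == 1) {
    d <- spectrum$mmd
    w <- 1
  } else {
    edges <- exp(seq(mu - span_sd * s, mu + span_sd * s,
                     length.out = n_bins + 1))
    cdf <- stats::pnorm(log(edges), mu, s)
    w <- diff(cdf)
    w <- w / sum(w)
    d <- sqrt(edges[-1] * edges[-(n_bins + 1)])
  }
  data.frame(initial_diameter = d,
             residual_diameter = d * nonvolatile_volume_fraction^(1 / 3),
             mass_weight = w)
}

# Age grid in seconds: log-spaced nodes resolve the first seconds where
# coarse droplets are lost, linear nodes control the trapezoid error over
# the full exposure; breakpoints of the TWA weight are included exactly.
.age_grid <- function(T_s, Ts_s, n_ages) {
  n_log <- ceiling(0.6 * n_ages)
  n_lin <- n_ages - n_log
  g <- c(0, exp(seq(log(1e-3), log(T_s), length.out = n_log)),
         seq(0, T_s, length.out = n_lin), max(T_s - Ts_s, 0))
  sort(unique(g))
}

# Diameter history matrix (bins x ages), um, clamped d-squared law.
.diameter_history <- function(bins, vapor_pressure, ages_s, liquid_density,
                              physics, age_offset = 0) {
  K <- evaporation_constant(vapor_pressure, liquid_density, physics) * 1e12
  d2 <- outer(bins$initial_diameter^2, K * (ages_s + age_offset), `-`)
  d2 <- pmax(d2, bins$residual_diameter^2)
  sqrt(d2)
}

# Row-wise cumulative trapezoid of a bins x ages matrix.
.cumtrapz_rows <- function(m, x) {
  dx <- diff(x)
  inc <- 0.5 * (m[, -1, drop = FALSE] + m[, -ncol(m), drop = FALSE]) *
    rep(dx, each = nrow(m))
  cbind(0, t(apply(inc, 1, cumsum)))
}

# Near-field transit: returns per-bin exit survival (mass reaching the far
# field) and the time-averaged inhalable concentration ratio xi_b inside
# the personal volume (plug-flow residence Tp).
.near_field_transit <- function(bins, vapor_pressure, Tp_s, settling_height,
                                liquid_density, physics, losses = TRUE) {
  ages <- sort(unique(c(0, exp(seq(log(1e-4), log(Tp_s), length.out = 400)))))
  d <- .diameter_history(bins, vapor_pressure, ages, liquid_density, physics)
  if (losses) {
    vt <- .settling_interpolator(liquid_density, physics)
    lam <- physics$near_field_deposition_efficiency * vt(d) / settling_height
    L <- .cumtrapz_rows(lam, ages)
  } else {
    L <- matrix(0, nrow(d), ncol(d))
  }
  S <- exp(-L)
  IF <- if (losses && physics$inhalable_sampling) inhalable_fraction(d) else 1
  integrand <- S * IF
  xi_b <- as.numeric((integrand[, -1, drop = FALSE] +
                        integrand[, -ncol(S), drop = FALSE]) %*%
                       (0.5 * diff(ages))) / Tp_s
  list(exit_survival = S[, ncol(S)], xi_b = pmin(xi_b, 1))
}

#' Compartment TWA with evaporation and settling losses
#'
#' Solves the well-stirred compartment mass balance for the airborne
#' non-volatile material of a spray released at constant rate over the
#' spraying time: every mass parcel ages individually, its diameter follows
#' the clamped d-squared law and it is lost to ventilation (rate `Gamma`)
#' and gravitational settling (rate `v(d)/Hs`). The far-field TWA is the
#' exact superposition integral over injection times; the near-field TWA is
#' the plateau concentration of the personal volume reduced by deposition
#' during the plug-flow residence `Tp` and weighted by the inhalable
#' sampling convention. The far field is fed mass-conservingly by what
#' survives the near-field transit.
#'
#' With `losses = FALSE` (no evaporation, no settling, no sampling
#' convention) the result reduces exactly to the loss-free two-box TWA
#' ([twa_far_field()] / [twa_near_field()]).
#'
#' @param scenario A [spray_scenario()] with a droplet spectrum.
#' @param compartment `"far_field"` or `"near_field"`.
#' @param physics A [physics_params()] object.
#' @param losses Set `FALSE` to disable all loss mechanisms (degeneration
#'   check).
#' @return A list of class `"compartment_twa"` with `twa_with_losses`
#'   (mg/m3, named per substance), the loss-free `twa_loss_free`, and the
#'   implied correction factor `ratio`.
#' @export
simulate_twa_with_losses <- function(scenario,
                                     compartment = c("far_field",
                                                     "near_field"),
                                     physics = physics_params(),
                                     losses = TRUE) {
  stopifnot(inherits(scenario, "spray_scenario"))
  if (is.null(scenario$spectrum)) {
    stop("scenario must carry a droplet spectrum")
  }
  compartment <- match.arg(compartment)
  liq <- scenario$liquid
  tmg <- scenario$timing
  phis <- liq$substance_mass_fractions
  bins <- discretize_spectrum(scenario$spectrum, physics$n_bins,
                              physics$span_sd,
                              liq$nonvolatile_volume_fraction)
  Tp_s <- scenario$near_field$residence_time * 60
  Hs <- scenario$room$settling_height
  nf <- .near_field_transit(bins, liq$solvent_vapor_pressure, Tp_s, Hs,
                            liq$solvent_density, physics, losses)

  if (compartment == "near_field") {
    xi <- sum(bins$mass_weight * nf$xi_b)
    base <- twa_near_field(scenario$mass_flow_rate, phis,
                           scenario$near_field$exchange_flow,
                           tmg$spraying_time, tmg$exposure_time)
    out <- list(twa_with_losses = base * xi, twa_loss_free = base,
                ratio = xi, compartment = compartment)
    class(out) <- "compartment_twa"
    return(out)
  }

  Ts_s <- tmg$spraying_time * 60
  T_s <- tmg$exposure_time * 60
  gamma_s <- scenario$room$air_exchange_rate / 3600
  ages <- .age_grid(T_s, Ts_s, physics$n_ages)
  d <- .diameter_history(bins, liq$solvent_vapor_pressure, ages,
                         liq$solvent_density, physics, age_offset = Tp_s)
  if (losses) {
    vt <- .settling_interpolator(liq$solvent_density, physics)
    L <- .cumtrapz_rows(vt(d) / Hs, ages)
  } else {
    L <- matrix(0, nrow(d), ncol(d))
  }
  S <- exp(-L - rep(gamma_s * ages, each = nrow(L)))
  wt <- pmax(pmin(Ts_s, T_s - ages), 0)
  N_b <- as.numeric((S[, -1, drop = FALSE] * rep(wt[-1], each = nrow(S)) +
                       S[, -ncol(S), drop = FALSE] *
                       rep(wt[-length(wt)], each = nrow(S))) %*%
                      (0.5 * diff(ages)))
  feed <- bins$mass_weight * (if (losses) nf$exit_survival else 1)
  N <- sum(feed * N_b)  # s^2
  src <- 1000 * scenario$mass_flow_rate / 60 * phis / scenario$room$volume
  twa <- src * N / T_s
  base <- twa_far_field(scenario$mass_flow_rate, phis, scenario$room$volume,
                        scenario$room$air_exchange_rate, tmg$spraying_time,
                        tmg$exposure_time)
  out <- list(twa_with_losses = twa, twa_loss_free = base,
              ratio = unname(twa[1] / base[1]), compartment = compartment)
  class(out) <- "compartment_twa"
  out
}

#' @export
print.compartment_twa <- function(x, ...) {
  cat(sprintf("%s TWA with aerosol losses [mg/m3]:\n", x$compartment))
  print(x$twa_with_losses)
  cat(sprintf("loss-free two-box TWA: %s\n",
              paste(signif(x$twa_loss_free, 4), collapse = ", ")))
  cat(sprintf("correction factor (ratio): %.4g\n", x$ratio))
  invisible(x)
}

#' Time-resolved far-field concentration with losses
#'
#' Evaluates the far-field airborne concentration of the lead substance on
#' a time grid, by the same superposition of aging parcels used for the
#' TWA. Used by the command line `simulate` subcommand and for plotting.
#'
#' @inheritParams simulate_twa_with_losses
#' @param n Number of output time points.
#' @return Data frame with `t_min` and `far_field_mg_m3`.
#' @export
simulate_far_field_profile <- function(scenario, physics = physics_params(),
                                       n = 200) {
  stopifnot(inherits(scenario, "spray_scenario"), !is.null(scenario$spectrum))
  liq <- scenario$liquid
  phi <- max(liq$substance_mass_fractions)
  Ts_s <- scenario$timing$spraying_time * 60
  T_s <- scenario$timing$exposure_time * 60
  gamma_s <- scenario$room$air_exchange_rate / 3600
  bins <- discretize_spectrum(scenario$spectrum, physics$n_bins,
                              physics$span_sd,
                              liq$nonvolatile_volume_fraction)
  Tp_s <- scenario$near_field$residence_time * 60
  nf <- .near_field_transit(bins, liq$solvent_vapor_pressure, Tp_s,
                            scenario$room$settling_height,
                            liq$solvent_density, physics)
  ages <- .age_grid(T_s, Ts_s, physics$n_ages)
  d <- .diameter_history(bins, liq$solvent_vapor_pressure, ages,
                         liq$solvent_density, physics, age_offset = Tp_s)
  vt <- .settling_interpolator(liq$solvent_density, physics)
  L <- .cumtrapz_rows(vt(d) / scenario$room$settling_height, ages)
  S <- exp(-L - rep(gamma_s * ages, each = nrow(L)))
  # cumulative G_b(x) = int_0^x S_b, interpolated per bin
  G <- .cumtrapz_rows(S, ages)
  feed <- bins$mass_weight * nf$exit_survival
  src <- 1000 * scenario$mass_flow_rate / 60 * phi / scenario$room$volume
  tt <- seq(0, T_s, length.out = n)
  conc <- vapply(tt, function(t) {
    lo <- max(t - Ts_s, 0)
    gt <- vapply(seq_len(nrow(G)), function(b) {
      gb <- stats::approx(ages, G[b, ], xout = c(lo, t), rule = 2)$y
      # parcels injected at tau have age t - tau; survival relative to
      # injection needs exp(+gamma tau) * S(age); using stationarity of S in
      # age, m(t) = sum_b feed_b * int_{t-min(t,Ts)}^{t} S_b(a) da with the
      # gamma factor already inside S.
      gb[2] - gb[1]
    }, numeric(1))
    src * sum(feed * gt)
  }, numeric(1))
  data.frame(t_min = tt / 60, far_field_mg_m3 = conc)
}
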