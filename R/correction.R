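# Grid-point memberships used for the class means of the packaged table.
# The printed class boundaries overlap at 10 and 1000 Pa; this membership is
# the calibration winner (see the methods vignette). The user-facing
# classifier (classify_vapor_pressure) keeps 10 Pa in class 1.
.vp_grid <- c(0.01, 0.1, 1, 10, 100, 1000, 10000)
.vp_members <- list(`1` = c(0.01, 0.1, 1), `2` = c(10, 100),
                    `3` = c(1000, 10000))
.mmd_grid <- c(10, 20, 40, 80, 160, 320, 640)
.mmd_members <- list(fine = c(10, 20, 40, 80), coarse = c(80, 160, 320, 640))
.table1 <- data.frame(
  ts_min = c(1, 1, 1, 10, 10, 10, 10, 10, 10, 10, 60, 60, 60, 60),
  t_min = c(6, 6, 6, 15, 15, 15, 60, 60, 60, 60, 65, 65, 65, 65),
  gamma_per_h = c(0, 10, 20, 0, 10, 20, 0, 5, 10, 20, 0, 5, 10, 20)
)

.scenario_for_factor <- function(mmd, vapor_pressure, spraying_time,
                                 exposure_time, air_exchange_rate,
                                 nonvolatile_volume_fraction, settling_height,
                                 residence_time, gsd) {
  spray_scenario(
    liquid = spray_liquid(0.01,
                          solvent_vapor_pressure = vapor_pressure,
                          nonvolatile_volume_fraction =
                            nonvolatile_volume_fraction),
    room = room(100, air_exchange_rate, settling_height),
    timing = timing(spraying_time, exposure_time),
    near_field = near_field(100 * residence_time, 100),
    spectrum = droplet_spectrum(mmd, gsd),
    mass_flow_rate = 100
  )
}

#' Aerosol-dynamics correction factor for one scenario
#'
#' Ratio of the TWA concentration with droplet evaporation and settling
#' losses ([simulate_twa_with_losses()]) to the loss-free two-box TWA, for
#' the far field (`kappa`) or the near field (`xi`). The ratio is
#' independent of the room volume and of the mass flow rate, because both
#' concentrations scale identically with them.
#'
#' @param mmd Mass median diameter of the spray, um.
#' @param vapor_pressure Solvent vapor pressure, Pa.
#' @param spraying_time,exposure_time Ts and T, min.
#' @param air_exchange_rate Gamma, 1/h.
#' @param compartment `"far_field"` (kappa) or `"near_field"` (xi).
#' @param physics A [physics_params()].
#' @param nonvolatile_volume_fraction Phihat (default 0.01).
#' @param settling_height Hs, m (default 3).
#' @param residence_time Near-field residence Tp, min (default 0.1).
#' @param gsd Geometric standard deviation of the spectrum (default 1.8).
#' @return The correction factor in (0, 1].
#' @examples
#' \donttest{
#' correction_factor(320, 1000, 10, 60, 20)  # ~0.042
#' }
#' @export
correction_factor <- function(mmd, vapor_pressure, spraying_time,
                              exposure_time, air_exchange_rate,
                              compartment = c("far_field", "near_field"),
                              physics = physics_params(),
                              nonvolatile_volume_fraction = 0.01,
                              settling_height = 3, residence_time = 0.1,
                              gsd = 1.8) {
  compartment <- match.arg(compartment)
  sc <- .scenario_for_factor(mmd, vapor_pressure, spraying_time,
                             exposure_time, air_exchange_rate,
                             nonvolatile_volume_fraction, settling_height,
                             residence_time, gsd)
  sim <- simulate_twa_with_losses(sc, compartment, physics)
  min(sim$ratio, 1)
}

#' Scale invariance of the far-field correction factor
#'
#' Recomputes kappa after multiplying the room volume and/or the liquid
#' mass flow rate and checks that it is unchanged to a relative tolerance
#' (default 1e-9); both concentrations in the ratio depend identically on
#' these parameters.
#'
#' @param scenario A [spray_scenario()] with spectrum.
#' @param scale_volume,scale_mass_flow Positive scale factors.
#' @param physics A [physics_params()].
#' @param tol Relative tolerance.
#' @return `TRUE` or `FALSE`, with attribute `"relative_difference"`.
#' @export
correction_factor_invariance <- function(scenario, scale_volume = 1,
                                         scale_mass_flow = 1,
                                         physics = physics_params(),
                                         tol = 1e-9) {
  stopifnot(scale_volume > 0, scale_mass_flow > 0)
  k0 <- simulate_twa_with_losses(scenario, "far_field", physics)$ratio
  sc2 <- scenario
  sc2$room$volume <- sc2$room$volume * scale_volume
  sc2$mass_flow_rate <- sc2$mass_flow_rate * scale_mass_flow
  k1 <- simulate_twa_with_losses(sc2, "far_field", physics)$ratio
  rel <- abs(k1 - k0) / k0
  structure(rel <= tol, relative_difference = rel)
}

# Survival-curve reuse across the 14 (Ts, T, Gamma) rows makes the full
# grid regeneration a ~50-curve computation instead of ~800.
.kappa_rows <- function(mmd, vp, rows, physics, phihat = 0.01, hs = 3,
                        Tp_min = 0.1, gsd = 1.8) {
  spectrum <- droplet_spectrum(mmd, gsd)
  bins <- discretize_spectrum(spectrum, physics$n_bins, physics$span_sd,
                              phihat)
  Tp_s <- Tp_min * 60
  nf <- .near_field_transit(bins, vp, Tp_s, hs, 1000, physics)
  T_max <- max(rows$t_min) * 60
  ages <- .age_grid(T_max, min(rows$ts_min) * 60, physics$n_ages)
  ages <- sort(unique(c(ages, (rows$t_min - rows$ts_min) * 60,
                        rows$t_min * 60)))
  d <- .diameter_history(bins, vp, ages, 1000, physics, age_offset = Tp_s)
  vt <- .settling_interpolator(1000, physics)
  L <- .cumtrapz_rows(vt(d) / hs, ages)
  feed <- bins$mass_weight * nf$exit_survival
  vapply(seq_len(nrow(rows)), function(i) {
    Ts_s <- rows$ts_min[i] * 60
    T_s <- rows$t_min[i] * 60
    g_s <- rows$gamma_per_h[i] / 3600
    keep <- ages <= T_s
    a <- ages[keep]
    S <- exp(-L[, keep, drop = FALSE] - rep(g_s * a, each = nrow(L)))
    wt <- pmax(pmin(Ts_s, T_s - a), 0)
    N_b <- as.numeric((S[, -1, drop = FALSE] * rep(wt[-1], each = nrow(S)) +
                         S[, -ncol(S), drop = FALSE] *
                         rep(wt[-length(wt)], each = nrow(S))) %*%
                        (0.5 * diff(a)))
    sum(feed * N_b) / .twa_kernel(g_s, Ts_s, T_s)
  }, numeric(1))
}

.xi_value <- function(mmd, vp, physics, phihat = 0.01, hs = 3, Tp_min = 0.1,
                      gsd = 1.8) {
  bins <- discretize_spectrum(droplet_spectrum(mmd, gsd), physics$n_bins,
                              physics$span_sd, phihat)
  nf <- .near_field_transit(bins, vp, Tp_min * 60, hs, 1000, physics)
  sum(bins$mass_weight * nf$xi_b)
}

#' Regenerate the mean correction-factor table from the aerosol physics
#'
#' Computes the per-scenario correction factors for every combination of
#' the vapor-pressure grid (0.01 to 10000 Pa) and MMD grid (10 to 640 um)
#' and averages them over the class memberships, for the 14 standard
#' (Ts, T, Gamma) rows: 84 far-field means `kappa_bar` (3 vapor classes x 2
#' size classes x 14 rows) and 6 near-field means `xi_bar` (for the single
#' Tp = 0.1 min near-field scenario, repeated down the rows).
#'
#' @param physics A [physics_params()].
#' @param rows Data frame of `ts_min`, `t_min`, `gamma_per_h` rows
#'   (defaults to the standard 14).
#' @return A data frame of class `"correction_grid"` with columns
#'   `ts_min`, `t_min`, `gamma_per_h`, `vp_class`, `size_class`,
#'   `kappa_bar`, `xi_bar` (84 rows).
#' @seealso [reference_correction_factors()] for the packaged table,
#'   [compare_correction_grids()] for the deviation report.
#' @export
regenerate_correction_factors <- function(physics = physics_params(),
                                          rows = NULL) {
  if (is.null(rows)) rows <- .table1
  stopifnot(all(c("ts_min", "t_min", "gamma_per_h") %in% names(rows)))
  combos <- expand.grid(vp = .vp_grid, mmd = .mmd_grid)
  kap <- array(NA_real_, dim = c(length(.vp_grid), length(.mmd_grid),
                                 nrow(rows)))
  xim <- matrix(NA_real_, length(.vp_grid), length(.mmd_grid))
  for (i in seq_along(.vp_grid)) {
    for (j in seq_along(.mmd_grid)) {
      kap[i, j, ] <- .kappa_rows(.mmd_grid[j], .vp_grid[i], rows, physics)
      xim[i, j] <- .xi_value(.mmd_grid[j], .vp_grid[i], physics)
    }
  }
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(r) {
    do.call(rbind, lapply(names(.vp_members), function(cl) {
      do.call(rbind, lapply(names(.mmd_members), function(sz) {
        iv <- match(.vp_members[[cl]], .vp_grid)
        jm <- match(.mmd_members[[sz]], .mmd_grid)
        data.frame(ts_min = rows$ts_min[r], t_min = rows$t_min[r],
                   gamma_per_h = rows$gamma_per_h[r],
                   vp_class = as.integer(cl), size_class = sz,
                   kappa_bar = mean(kap[iv, jm, r]),
                   xi_bar = mean(xim[iv, jm]))
      }))
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("correction_grid", "data.frame")
  out
}

#' Packaged mean correction factors
#'
#' The published table of mean near- and far-field correction factors
#' (`xi_bar`, `kappa_bar`) indexed by spraying time, exposure time, air
#' exchange rate, vapor pressure class (1-3) and droplet size class
#' (fine/coarse). This transcription is the runtime default of the refined
#' model; [regenerate_correction_factors()] recomputes it from physics.
#'
#' @return A data frame of class `"correction_grid"` (84 rows).
#' @export
reference_correction_factors <- function() {
  path <- system.file("extdata", "correction_factors.tsv",
                      package = "sprayscreen", mustWork = TRUE)
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("correction_grid", "data.frame")
  out
}

#' @export
print.correction_grid <- function(x, ...) {
  cat(sprintf("Correction-factor grid: %d rows (%d scenario rows x %d classes)\n",
              nrow(x), length(unique(interaction(x$ts_min, x$t_min,
                                                 x$gamma_per_h))),
              length(unique(interaction(x$vp_class, x$size_class)))))
  print.data.frame(utils::head(as.data.frame(x), 12))
  if (nrow(x) > 12) cat(sprintf("... %d more rows\n", nrow(x) - 12))
  invisible(x)
}

#' Compare a regenerated grid against the packaged table
#'
#' @param regenerated,reference Two `"correction_grid"` data frames.
#' @return A list with the merged table (columns `kappa_dev`, `xi_dev`) and
#'   the maximum absolute deviations.
#' @export
compare_correction_grids <- function(regenerated,
                                     reference = reference_correction_factors()) {
  key <- c("ts_min", "t_min", "gamma_per_h", "vp_class", "size_class")
  m <- merge(regenerated, reference, by = key,
             suffixes = c("_regen", "_ref"))
  if (nrow(m) != nrow(reference)) stop("grids do not cover the same cells")
  m$kappa_dev <- m$kappa_bar_regen - m$kappa_bar_ref
  m$xi_dev <- m$xi_bar_regen - m$xi_bar_ref
  list(table = m,
       max_abs_kappa_dev = max(abs(m$kappa_dev)),
       max_abs_xi_dev = max(abs(m$xi_dev)))
}

#' Look up mean correction factors for a scenario
#'
#' Matches the (Ts, T) pair to the nearest tabulated row (Euclidean in log
#' time; on ties the row with the larger, i.e. more conservative,
#' `kappa_bar` wins) and the air exchange rate to the next tabulated value
#' upwards (conservative, since `kappa_bar` is nondecreasing in Gamma).
#' Requests outside the tabulated envelope get the nearest row and a
#' warning, never an extrapolation.
#'
#' @param spraying_time,exposure_time Ts and T, min.
#' @param air_exchange_rate Gamma, 1/h.
#' @param vp_class Vapor pressure class (1, 2 or 3).
#' @param size_class `"fine"` or `"coarse"`.
#' @param grid A `"correction_grid"`; defaults to the packaged table.
#' @return A list with `xi_bar`, `kappa_bar` and the matched `row`.
#' @export
lookup_correction_factors <- function(spraying_time, exposure_time,
                                      air_exchange_rate, vp_class, size_class,
                                      grid = reference_correction_factors()) {
  if (is.null(grid) || nrow(grid) == 0) stop("empty correction-factor grid")
  stopifnot(vp_class %in% 1:3, size_class %in% c("fine", "coarse"))
  sub <- grid[grid$vp_class == vp_class & grid$size_class == size_class, ]
  if (nrow(sub) == 0) stop("empty grid for the requested class")
  dts <- (log(sub$ts_min) - log(spraying_time))^2 +
    (log(sub$t_min) - log(exposure_time))^2
  best <- min(dts)
  cand <- sub[dts <= best + 1e-12, ]
  if (best > 1e-12 &&
      (spraying_time < min(grid$ts_min) || spraying_time > max(grid$ts_min) ||
       exposure_time < min(grid$t_min) || exposure_time > max(grid$t_min))) {
    warning("scenario outside the tabulated (Ts, T) envelope; ",
            "using the nearest tabulated row")
  }
  gam <- sort(unique(cand$gamma_per_h))
  gsel <- if (air_exchange_rate > max(gam)) {
    warning("air exchange rate above the tabulated range; using ",
            max(gam), " per h")
    max(gam)
  } else {
    min(gam[gam >= air_exchange_rate])
  }
  cand <- cand[cand$gamma_per_h == gsel, ]
  cand <- cand[which.max(cand$kappa_bar), ]
  list(xi_bar = cand$xi_bar, kappa_bar = cand$kappa_bar, row = cand)
}

#' Mean correction factor for one table cell, from physics
#'
#' Averages the per-scenario correction factor over the vapor-pressure and
#' MMD grid points belonging to a (vapor class, size class) cell, the way
#' the packaged table means are defined.
#'
#' @inheritParams lookup_correction_factors
#' @param compartment `"far_field"` or `"near_field"`.
#' @param physics A [physics_params()].
#' @return The mean factor.
#' @export
mean_correction_factor <- function(spraying_time, exposure_time,
                                   air_exchange_rate, vp_class, size_class,
                                   compartment = c("far_field", "near_field"),
                                   physics = physics_params()) {
  compartment <- match.arg(compartment)
  vps <- .vp_members[[as.character(vp_class)]]
  mmds <- .mmd_members[[size_class]]
  if (compartment == "near_field") {
    vals <- vapply(vps, function(p) {
      vapply(mmds, function(m) .xi_value(m, p, physics), numeric(1))
    }, numeric(length(mmds)))
  } else {
    rows <- data.frame(ts_min = spraying_time, t_min = exposure_time,
                       gamma_per_h = air_exchange_rate)
    vals <- vapply(vps, function(p) {
      vapply(mmds, function(m) .kappa_rows(m, p, rows, physics), numeric(1))
    }, numeric(length(mmds)))
  }
  mean(vals)
}
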