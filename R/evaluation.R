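#' Impute an air exchange rate for an under-documented workplace
#'
#' Coding convention for workplace measurement reports that omit the
#' ventilation rate: a qualitative ventilation statement maps to 0 (none),
#' 0.6 (natural) or 10 (mechanical) per hour; otherwise the use area picks
#' the rate (antifouling 10/h, animal housing 1/h because of open doors)
#' and everything else falls back to a conservative 0.6/h.
#'
#' @param use_area Optional use-area tag, e.g. `"antifouling"`,
#'   `"animal_housing"`, `"disinfection"`, ...
#' @param ventilation Optional qualitative ventilation statement:
#'   `"none"`, `"natural"` or `"mechanical"`.
#' @return Air exchange rate, 1/h, with a `"rule"` attribute naming the
#'   convention applied.
#' @examples
#' impute_ventilation("antifouling")
#' impute_ventilation(ventilation = "mechanical")
#' impute_ventilation()
#' @export
impute_ventilation <- function(use_area = NULL, ventilation = NULL) {
  if (!is.null(ventilation) && !is.na(ventilation)) {
    ventilation <- match.arg(ventilation, c("none", "natural", "mechanical"))
    g <- switch(ventilation, none = 0, natural = 0.6, mechanical = 10)
    return(structure(g, rule = paste0("qualitative:", ventilation)))
  }
  if (!is.null(use_area) && !is.na(use_area)) {
    ua <- tolower(use_area)
    if (grepl("antifouling", ua)) {
      return(structure(10, rule = "use_area:antifouling"))
    }
    if (grepl("animal", ua) || grepl("stable", ua)) {
      return(structure(1, rule = "use_area:animal_housing"))
    }
  }
  structure(0.6, rule = "default")
}

.ratio_bins <- c(underestimation = 0.5, accurate = 10, overestimation = 100,
                 high_overestimation = Inf)

#' Classify modeled/measured concentration ratios into performance bins
#'
#' Screening-model performance bins for the ratio modeled/measured:
#' underestimation below 0.5, accurate in \[0.5, 10), overestimation in
#' \[10, 100), high overestimation at or above 100 (boundaries are
#' left-closed).
#'
#' @param modeled,measured Vectors of modeled and measured TWA
#'   concentrations, mg/m3. Pairs with non-positive measurements are
#'   dropped with a warning.
#' @return An object of class `"ratio_evaluation"` with the ratios, bin
#'   counts and percentages.
#' @examples
#' evaluate_ratios(c(0.4, 2, 50, 500), rep(1, 4))
#' @export
evaluate_ratios <- function(modeled, measured) {
  stopifnot(is.numeric(modeled), is.numeric(measured),
            length(modeled) == length(measured))
  if (length(modeled) == 0) stop("no scenarios to evaluate")
  bad <- !(measured > 0) | is.na(measured) | is.na(modeled)
  if (any(bad)) {
    warning(sum(bad), " scenario(s) without a positive measured TWA excluded")
  }
  ratios <- modeled[!bad] / measured[!bad]
  if (length(ratios) == 0) stop("no scenarios with positive measurements")
  cuts <- cut(ratios, breaks = c(0, 0.5, 10, 100, Inf), right = FALSE,
              labels = names(.ratio_bins))
  counts <- table(cuts)
  structure(list(ratios = ratios, n = length(ratios),
                 counts = as.vector(counts),
                 bin = names(.ratio_bins),
                 percentages = 100 * as.vector(counts) / length(ratios),
                 n_excluded = sum(bad)),
            class = "ratio_evaluation")
}

#' @export
print.ratio_evaluation <- function(x, ...) {
  cat(sprintf("Model-vs-measurement ratio evaluation (n = %d", x$n))
  if (x$n_excluded > 0) cat(sprintf(", %d excluded", x$n_excluded))
  cat(")\n")
  lab <- c("ratio < 0.5 (underestimation)", "0.5 - 10 (accurate)",
           "10 - 100 (overestimation)", "> 100 (high overestimation)")
  for (i in seq_along(lab)) {
    cat(sprintf("  %-30s %5d  %6.1f%%\n", lab[i], x$counts[i],
                x$percentages[i]))
  }
  invisible(x)
}

#' @export
as.data.frame.ratio_evaluation <- function(x, ...) {
  data.frame(bin = x$bin, count = x$counts, percentage = x$percentages)
}

#' Generate a reproducible batch of synthetic measured scenarios
#'
#' Emits pseudo-random but physically plausible workplace spray scenarios
#' spanning the ranges seen in workplace reports (room volumes 13.3 to
#' 10700 m3, spraying times 4 to 103 min, surface and room spraying, fine
#' and coarse spectra, the usual imputed ventilation rates), and equips
#' each with a synthetic "measured" TWA constructed as the modeled generic
#' TWA of the lead substance divided by a lognormal bias factor. The
#' modeled/measured ratio of the batch is therefore exactly the bias
#' factor, so the expected occupancy of the evaluation bins is known in
#' closed form ([stats::plnorm()] at 0.5, 10 and 100).
#'
#' The default bias (median 10, geometric standard deviation 10) mimics the
#' conservatism typically observed for screening models, which mostly
#' overestimate workplace measurements.
#'
#' @param n Number of scenarios.
#' @param seed Integer seed; identical seeds give identical batches.
#' @param bias_median Median of the lognormal bias factor.
#' @param bias_gsd Geometric standard deviation of the bias factor (> 1 for
#'   scatter; exactly 1 makes every ratio equal `bias_median`).
#' @return A data frame in the scenario CSV schema (see
#'   [read_scenario_csv()]) with `measured_twa_mg_m3`, `modeled_twa_mg_m3`
#'   and `source_label` columns.
#' @examples
#' fx <- generate_fixture_scenarios(5, seed = 1)
#' fx$modeled_twa_mg_m3 / fx$measured_twa_mg_m3
#' @export
generate_fixture_scenarios <- function(n, seed, bias_median = 10,
                                       bias_gsd = 10) {
  stopifnot(n >= 1, bias_median > 0, bias_gsd >= 1)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vr <- exp(stats::runif(n, log(13.3), log(10700)))
  ts <- stats::runif(n, 4, 103)
  post <- ifelse(stats::runif(n) < 0.7, 0, stats::runif(n, 0, 60))
  gamma <- sample(c(0, 0.6, 1, 10), n, replace = TRUE,
                  prob = c(0.1, 0.55, 0.15, 0.2))
  app <- sample(c("surface_spraying", "room_spraying"), n, replace = TRUE,
                prob = c(0.7, 0.3))
  mmd <- ifelse(app == "room_spraying",
                exp(stats::runif(n, log(10), log(79))),
                exp(stats::runif(n, log(20), log(640))))
  phi <- exp(stats::runif(n, log(0.001), log(0.2)))
  mdot <- exp(stats::runif(n, log(5), log(500)))
  vp <- exp(stats::runif(n, log(0.01), log(10000)))
  equipment <- ifelse(app == "room_spraying", "none",
                      sample(c("none", "flat_fan_or_hollow_cone",
                               "handheld_pump"), n, replace = TRUE))
  modeled <- twa_near_field(mdot, phi, 100, ts, ts + post) +
    twa_far_field(mdot, phi, vr, gamma, ts, ts + post)
  bias <- stats::rlnorm(n, meanlog = log(bias_median),
                        sdlog = log(bias_gsd))
  out <- data.frame(
    scenario_id = sprintf("synthetic_%04d", seq_len(n)),
    substance = "substance_1",
    substance_mass_fraction = phi,
    nonvolatile_volume_fraction = 0.01,
    solvent_vapor_pressure_pa = vp,
    solvent_density_kg_m3 = 1000,
    substance_density_kg_m3 = 1000,
    room_volume_m3 = vr,
    air_exchange_per_h = gamma,
    settling_height_m = 3,
    personal_volume_m3 = 10,
    exchange_flow_m3_min = 100,
    spraying_time_min = ts,
    exposure_time_min = ts + post,
    mass_flow_g_min = mdot,
    mmd_um = mmd,
    gsd = 1.8,
    application_type = app,
    equipment = equipment,
    airborne_fraction_override = NA_real_,
    modeled_twa_mg_m3 = modeled,
    measured_twa_mg_m3 = modeled / bias,
    source_label = "synthetic",
    stringsAsFactors = FALSE
  )
  out
}

#' Evaluate a scenario table against its measurements
#'
#' Runs the selected model variant on every row of a scenario table (the
#' CSV schema of [read_scenario_csv()], or the output of
#' [generate_fixture_scenarios()]) and bins the modeled/measured ratios.
#'
#' @param scenarios Scenario data frame with a `measured_twa_mg_m3` column.
#' @param model Model variant passed to [spray_twobox()].
#' @param grid Correction-factor table for the refined variant.
#' @param verbose Log every imputed default to the console.
#' @return A list with the per-scenario results (`$table`, including the
#'   modeled TWA and ratio) and the `"ratio_evaluation"` (`$bins`).
#' @export
evaluate_scenarios <- function(scenarios,
                               model = c("generic", "refined",
                                         "release_fraction"),
                               grid = NULL, verbose = FALSE) {
  model <- match.arg(model)
  stopifnot(is.data.frame(scenarios),
            "measured_twa_mg_m3" %in% names(scenarios))
  scs <- .scenarios_from_table(scenarios)
  modeled <- vapply(seq_along(scs), function(i) {
    fit <- spray_twobox(scs[[i]], model = model, grid = grid)
    j <- which.max(fit$twa$mass_fraction)
    if (verbose) {
      f <- fit$factors
      message(sprintf("%s: xi=%.3g (%s) kappa=%.3g (%s) F_A=%.3g (%s)",
                      scenarios$scenario_id[i] %||% i, f$xi, f$xi_provenance,
                      f$kappa, f$kappa_provenance, f$fa, f$fa_provenance))
    }
    if (model == "generic") fit$twa$twa_total[j] else fit$twa$twa_corrected[j]
  }, numeric(1))
  tab <- scenarios
  tab$modeled_twa_mg_m3 <- modeled
  tab$ratio <- modeled / tab$measured_twa_mg_m3
  list(table = tab, bins = evaluate_ratios(modeled,
                                           tab$measured_twa_mg_m3))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
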