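test_that("spectrum discretization reproduces the lognormal mass distribution", {
  sp <- droplet_spectrum(80, 1.8)
  b <- discretize_spectrum(sp, n_bins = 200)
  expect_equal(sum(b$mass_weight), 1, tolerance = 1e-9)
  expect_equal(sum(b$mass_weight[b$initial_diameter < 80]), 0.5,
               tolerance = 5e-3)  # median property
  expect_equal(sum(b$mass_weight[b$initial_diameter < 80 / 1.8]),
               pnorm(-1), tolerance = 5e-3)  # one geometric SD below
  expect_equal(b$residual_diameter, b$initial_diameter * 0.01^(1 / 3))
  mono <- discretize_spectrum(sp, n_bins = 1)
  expect_equal(mono$initial_diameter, 80)
  expect_equal(mono$mass_weight, 1)
  # median converges with refinement
  med_of <- function(n) {
    bb <- discretize_spectrum(sp, n)
    o <- order(bb$initial_diameter)
    approx(cumsum(bb$mass_weight[o]), bb$initial_diameter[o], 0.5)$y
  }
  expect_lt(abs(med_of(400) - 80), abs(med_of(20) - 80) + 1e-9)
})

test_that("settling velocity behaves like Stokes below and drag-corrected above the transition", {
  expect_equal(settling_velocity(0), 0)
  expect_equal(settling_velocity(10), 3.0e-3, tolerance = 0.05)
  d <- c(0.5, 1, 2, 5, 10, 20, 50, 100, 200, 320, 640)
  v <- settling_velocity(d)
  expect_true(all(diff(v) > 0))  # strictly increasing
  # Schiller-Naumann reduces large-droplet velocities below Stokes
  stokes <- settling_velocity(d, physics = physics_params(
    drag_regime = "stokes"))
  expect_lt(v[d == 320] / stokes[d == 320], 0.6)
  expect_equal(v[d == 1] / stokes[d == 1], 1, tolerance = 1e-3)
  # 320 um water-like droplet falls at roughly 1.25 m/s (literature value)
  expect_equal(settling_velocity(320), 1.25, tolerance = 0.1)
})

test_that("droplet evaporation follows the clamped d-squared law", {
  expect_equal(evaporate_diameter(100, 0, 1e6), 100)  # no vapor pressure
  expect_equal(evaporate_diameter(320, 1000, Inf), 320 * 0.01^(1 / 3))
  expect_equal(evaporate_diameter(320, 1000, Inf), 68.97, tolerance = 1e-3)
  tt <- seq(0, 300, by = 1)
  d <- evaporate_diameter(80, 1000, tt)
  expect_true(all(diff(d) <= 0))
  expect_true(all(d >= 80 * 0.01^(1 / 3) - 1e-12))
  # time to residue scales with 1/K, i.e. 1/vapor pressure
  t_res <- function(vp) {
    f <- function(t) evaporate_diameter(40, vp, t) - 40 * 0.01^(1 / 3) - 1e-9
    uniroot(f, c(1e-6, 1e7))$root
  }
  expect_equal(t_res(100) / t_res(1000), 10, tolerance = 1e-2)
})

test_that("with losses disabled the compartment model degenerates to the generic two-box", {
  for (sc in random_scenarios(20, seed = 5)) {
    sim <- simulate_twa_with_losses(sc, "far_field", lossless_physics(),
                                    losses = FALSE)
    expect_equal(unname(sim$twa_with_losses[1]), unname(sim$twa_loss_free[1]),
                 tolerance = 1e-3)
    expect_equal(sim$ratio, 1, tolerance = 1e-3)
  }
  nf <- simulate_twa_with_losses(base_scenario(), "near_field",
                                 losses = FALSE)
  expect_equal(nf$ratio, 1, tolerance = 1e-6)
})

test_that("settling losses are negligible for a slow 1-um spray", {
  sc <- base_scenario(mmd = 1, vp = 0, gamma = 0, ts = 10, t = 10)
  sc$spectrum <- droplet_spectrum(1, gsd = 1.0001)  # essentially monodisperse
  sim <- simulate_twa_with_losses(sc, "far_field",
                                  physics_params(inhalable_sampling = FALSE))
  expect_equal(unname(sim$twa_with_losses[1]), unname(sim$twa_loss_free[1]),
               tolerance = 0.01)
})

test_that("losses increase with droplet size and decrease after maturation", {
  # non-volatile solvent: far-field TWA falls monotonically with MMD
  tws <- vapply(c(10, 40, 160, 640), function(m) {
    sc <- base_scenario(mmd = m, vp = 0, gamma = 0, ts = 10, t = 60)
    unname(simulate_twa_with_losses(sc, "far_field")$twa_with_losses[1])
  }, numeric(1))
  expect_true(all(diff(tws) < 0))
  # a volatile solvent shrinks coarse droplets and raises the TWA
  coarse_wet <- base_scenario(mmd = 320, vp = 0, gamma = 0, ts = 10, t = 60)
  coarse_dry <- base_scenario(mmd = 320, vp = 10000, gamma = 0, ts = 10,
                              t = 60)
  expect_gt(simulate_twa_with_losses(coarse_dry, "far_field")$ratio,
            simulate_twa_with_losses(coarse_wet, "far_field")$ratio)
  # lower settling height means faster losses
  low <- base_scenario(mmd = 160, vp = 0, hs = 1.5)
  high <- base_scenario(mmd = 160, vp = 0, hs = 3)
  expect_lt(simulate_twa_with_losses(low, "far_field")$ratio,
            simulate_twa_with_losses(high, "far_field")$ratio)
})

test_that("grid refinement changes the correction factor by less than 1 percent", {
  cases <- list(c(320, 1000, 10, 60, 0), c(40, 100, 10, 15, 10),
                c(80, 0.1, 1, 6, 20))
  for (cs in cases) {
    k1 <- correction_factor(cs[1], cs[2], cs[3], cs[4], cs[5])
    k2 <- correction_factor(cs[1], cs[2], cs[3], cs[4], cs[5],
                            physics = physics_params(n_bins = 240,
                                                     n_ages = 3200))
    expect_equal(k1, k2, tolerance = 0.01)
  }
})

test_that("the production integrator matches a brute-force explicit time march", {
  # independent oracle: survival by first-order explicit Euler on a uniform
  # 1e4-step age grid, TWA by Riemann superposition over injection times
  brute_kappa <- function(sc, n_steps = 1e4) {
    ph <- physics_params(n_bins = 40)
    liq <- sc$liquid
    bins <- discretize_spectrum(sc$spectrum, 40, 4,
                                liq$nonvolatile_volume_fraction)
    Ts <- sc$timing$spraying_time * 60
    T_ <- sc$timing$exposure_time * 60
    g <- sc$room$air_exchange_rate / 3600
    Tp <- sc$near_field$residence_time * 60
    dt <- T_ / n_steps
    ages <- seq(0, T_, by = dt)
    hs <- sc$room$settling_height
    num <- 0
    for (b in seq_len(nrow(bins))) {
      d0 <- bins$initial_diameter[b]
      # near-field exit survival, Euler over the transit
      dtp <- Tp / 200
      anf <- seq(0, Tp, by = dtp)
      dnf <- evaporate_diameter(d0, liq$solvent_vapor_pressure, anf,
                                liq$nonvolatile_volume_fraction)
      snf <- exp(-sum(0.45 * settling_velocity(dnf[-length(dnf)]) / hs) * dtp)
      d <- evaporate_diameter(d0, liq$solvent_vapor_pressure, ages + Tp,
                              liq$nonvolatile_volume_fraction)
      lam <- settling_velocity(d) / hs + g
      S <- cumprod(c(1, pmax(1 - lam[-length(lam)] * dt, 0)))
      num <- num + bins$mass_weight[b] * snf *
        sum(S * pmax(pmin(Ts, T_ - ages), 0)) * dt
    }
    A <- twa_far_field(1, 1, 1, sc$room$air_exchange_rate,
                       sc$timing$spraying_time, sc$timing$exposure_time) *
      sc$timing$exposure_time / 1000 * 3600  # back to the raw kernel, s^2
    num / A
  }
  set.seed(9)
  scs <- random_scenarios(6, seed = 9)
  for (sc in scs) {
    prod <- simulate_twa_with_losses(sc, "far_field",
                                     physics_params(n_bins = 40))$ratio
    expect_equal(prod, brute_kappa(sc), tolerance = 5e-3)
  }
})

test_that("near-field correction reflects inhalability and settling during the transit", {
  xi_of <- function(mmd, vp, ...) {
    sc <- base_scenario(mmd = mmd, vp = vp)
    simulate_twa_with_losses(sc, "near_field", physics_params(...))$ratio
  }
  expect_lt(xi_of(640, 0.01), xi_of(20, 0.01))  # coarse sprays lose more
  expect_gt(xi_of(80, 10000), xi_of(80, 0.01))  # evaporation reduces losses
  # without the inhalable convention fine sprays pass almost unhindered
  expect_gt(xi_of(10, 0.01, inhalable_sampling = FALSE), 0.98)
  expect_lt(xi_of(10, 0.01), 0.85)
  for (m in c(10, 80, 640)) expect_lte(xi_of(m, 100), 1)
})

test_that("the simulated far-field profile integrates to the TWA with losses", {
  sc <- base_scenario(mmd = 160, vp = 100, gamma = 5, ts = 10, t = 30)
  prof <- simulate_far_field_profile(sc, n = 600)
  twa_prof <- pracma::trapz(prof$t_min, prof$far_field_mg_m3) /
    max(prof$t_min)
  sim <- unname(simulate_twa_with_losses(sc, "far_field")$twa_with_losses[1])
  expect_equal(twa_prof, sim, tolerance = 0.02)
  expect_equal(prof$far_field_mg_m3[1], 0)
  expect_true(all(prof$far_field_mg_m3 >= 0))
})
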