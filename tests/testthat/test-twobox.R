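test_that("near-field plateau concentration is Mdot phi / Qp", {
  expect_equal(near_field_concentration(100, 0.1, 100), 100)
  expect_equal(near_field_concentration(0, 0.1, 100), 0)
  expect_equal(near_field_concentration(60, 0.05, 100), 30)
  expect_error(near_field_concentration(10, 0.1, 0), "positive")
})

test_that("near-field TWA scales with the spraying duty cycle", {
  expect_equal(twa_near_field(80, 0.2, 100, 30, 30),
               near_field_concentration(80, 0.2, 100))
  expect_equal(twa_near_field(100, 0.01, 100, 10, 60), 10 / 6)
  a <- twa_near_field(100, 0.01, 100, 10, 60)
  b <- twa_near_field(100, 0.01, 100, 5, 60)
  expect_equal(a, 2 * b)
  expect_error(twa_near_field(100, 0.01, 100, 10, 0), "positive")
})

test_that("far-field profile rises, decays, and is continuous at Ts", {
  expect_equal(far_field_profile(0, 100, 0.01, 100, 5, 10), 0)
  # unventilated limit: linear accumulation, then a constant plateau
  expect_equal(far_field_profile(4, 100, 0.01, 100, 0, 10),
               1000 * 100 * 0.01 * 4 / 100)
  expect_equal(far_field_profile(4, 100, 0.01, 100, 1e-9, 10),
               far_field_profile(4, 100, 0.01, 100, 0, 10), tolerance = 1e-6)
  expect_equal(far_field_profile(50, 100, 0.01, 100, 0, 10),
               far_field_profile(10, 100, 0.01, 100, 0, 10))
  # steady state under continued spraying: source / (Vr Gamma)
  expect_equal(far_field_profile(1e4, 100, 0.01, 100, 6, 2e4),
               1000 * 100 * 0.01 / (100 * 6 / 60), tolerance = 1e-6)
  eps <- 1e-9
  expect_equal(far_field_profile(10 - eps, 100, 0.01, 100, 5, 10),
               far_field_profile(10 + eps, 100, 0.01, 100, 5, 10),
               tolerance = 1e-6)
  expect_error(far_field_profile(-1, 100, 0.01, 100, 5, 10))
})

test_that("far-field TWA matches the zero-ventilation closed form", {
  # Mdot phi Ts (T - Ts/2) / (Vr T), approached smoothly as Gamma -> 0
  closed <- function(md, phi, vr, ts, t) 1000 * md * phi * ts * (t - ts / 2) /
    (vr * t)
  expect_equal(twa_far_field(100, 0.01, 100, 0, 10, 60),
               closed(100, 0.01, 100, 10, 60), tolerance = 1e-12)
  for (g in c(1e-9, 1e-7, 1e-5)) {
    expect_equal(twa_far_field(100, 0.01, 100, g, 10, 60),
                 closed(100, 0.01, 100, 10, 60), tolerance = 1e-4)
  }
  set.seed(7)
  for (i in 1:20) {
    ts <- runif(1, 1, 50); t <- ts + runif(1, 0, 60)
    expect_equal(twa_far_field(100, 0.01, 100, 1e-7, ts, t),
                 closed(100, 0.01, 100, ts, t), tolerance = 1e-6)
  }
})

test_that("far-field TWA equals the time integral of the profile", {
  set.seed(11)
  for (i in 1:25) {
    md <- runif(1, 1, 500); phi <- runif(1, 1e-3, 0.5)
    vr <- runif(1, 20, 5000); g <- runif(1, 0, 30)
    ts <- runif(1, 0.5, 60); t <- ts + runif(1, 0, 120)
    tt <- sort(unique(c(seq(0, t, length.out = 20001), ts)))
    prof <- far_field_profile(tt, md, phi, vr, g, ts)
    oracle <- pracma::trapz(tt, prof) / t
    expect_equal(twa_far_field(md, phi, vr, g, ts, t), oracle,
                 tolerance = 1e-6)
  }
})

test_that("far-field TWA obeys its limits and scale invariances", {
  # high ventilation asymptote Mdot phi Ts / (Vr Gamma T)
  g <- 1e4
  expect_equal(twa_far_field(100, 0.01, 100, g, 10, 60),
               1000 * 100 * 0.01 * 10 / (100 * g / 60 * 60),
               tolerance = 1e-3)
  # depends on Mdot / Vr only
  expect_equal(twa_far_field(100, 0.01, 100, 5, 10, 60),
               twa_far_field(200, 0.01, 200, 5, 10, 60))
  # monotone nonincreasing and continuous in Gamma
  gs <- c(0, 10^seq(-8, 1.5, length.out = 60))
  tw <- vapply(gs, function(g) twa_far_field(100, 0.01, 100, g, 10, 60),
               numeric(1))
  expect_true(all(diff(tw) <= 1e-8 * tw[1]))
  expect_lt(abs(tw[2] - tw[1]) / tw[1], 1e-6)
  expect_error(twa_far_field(100, 0.01, 0, 5, 10, 60), "positive")
})

test_that("corrected TWA combines the factors linearly", {
  expect_equal(twa_corrected(10, 10, 0.65, 0.38, 0.3), 6.5 + 1.14)
  expect_equal(twa_corrected(3, 7), 10)  # identity factors: plain sum
  expect_equal(twa_corrected(10, 10, 0.5, 1e-12, 1e-12), 5,
               tolerance = 1e-6)
  expect_error(twa_corrected(10, 10, xi = 0), "0, 1")
  expect_error(twa_corrected(10, 10, kappa = 1.2), "0, 1")
  set.seed(3)
  for (i in 1:20) {
    f <- runif(3)
    expect_lte(twa_corrected(5, 8, f[1], f[2], f[3]), 13)
  }
})

test_that("the two-box estimate is additive in substances and collapses to the near field for huge rooms", {
  liq2 <- spray_liquid(c(a = 0.01, b = 0.03), solvent_vapor_pressure = 50)
  sc2 <- spray_scenario(liquid = liq2, room = room(100, 0.6),
                        timing = timing(10, 60), mass_flow_rate = 50)
  fit <- spray_twobox(sc2)
  liq_sum <- spray_liquid(0.04, solvent_vapor_pressure = 50)
  sc_sum <- spray_scenario(liquid = liq_sum, room = room(100, 0.6),
                           timing = timing(10, 60), mass_flow_rate = 50)
  expect_equal(sum(fit$twa$twa_total), spray_twobox(sc_sum)$twa$twa_total)
  expect_equal(fit$twa$twa_total, fit$twa$twa_near_field +
                 fit$twa$twa_far_field)
  big <- base_scenario(vr = 1e12)
  fit_big <- spray_twobox(big)
  expect_equal(fit_big$twa$twa_total, fit_big$twa$twa_near_field,
               tolerance = 1e-6)
  none <- base_scenario(mdot = 0)
  expect_equal(spray_twobox(none)$twa$twa_total, 0)
})

test_that("model variants pick their factors and provenance", {
  sc <- base_scenario(mmd = 40, vp = 2330, gamma = 10, ts = 10, t = 15,
                      equipment = "handheld_pump")
  gen <- spray_twobox(sc, "generic")
  expect_equal(gen$factors$xi, 1)
  expect_equal(gen$twa$twa_corrected, gen$twa$twa_total)

  ref <- spray_twobox(sc, "refined")
  expect_identical(ref$factors$kappa_provenance, "table")
  # class 3 (water), fine, Ts=10, T=15, Gamma=10 row of the packaged table
  expect_equal(ref$factors$kappa, 0.68)
  expect_equal(ref$factors$xi, 0.84)
  expect_equal(ref$factors$fa, 0.3)
  expect_lte(ref$twa$twa_corrected, ref$twa$twa_total)

  rel <- spray_twobox(sc, "release_fraction")
  expect_equal(rel$factors$fa, 0.1)
  expect_identical(rel$factors$fa_provenance, "equipment")
  expect_equal(rel$factors$kappa, 1)

  nospec <- spray_scenario(liquid = sc$liquid, room = sc$room,
                           timing = sc$timing, mass_flow_rate = 50)
  expect_error(spray_twobox(nospec, "refined"), "spectrum")
})
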