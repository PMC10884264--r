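# Shared scenario builders for the test suite; fixtures are constructed in
# code, never stored.

base_scenario <- function(mmd = 80, vp = 2330, vr = 100, gamma = 0.6,
                          ts = 10, t = 60, mdot = 50, phi = 0.01,
                          application = "surface_spraying",
                          equipment = "none", hs = 3, ...) {
  spray_scenario(
    liquid = spray_liquid(phi, solvent_vapor_pressure = vp),
    room = room(vr, gamma, hs),
    timing = timing(ts, t),
    spectrum = droplet_spectrum(mmd),
    mass_flow_rate = mdot,
    application_type = application,
    equipment = equipment,
    ...
  )
}

# reproducible random scenarios spanning the plausible workplace ranges
random_scenarios <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    ts <- runif(1, 1, 60)
    base_scenario(
      mmd = exp(runif(1, log(10), log(640))),
      vp = 10^runif(1, -2, 4),
      vr = exp(runif(1, log(20), log(5000))),
      gamma = sample(c(0, 0.6, 5, 20), 1),
      ts = ts, t = ts + runif(1, 0, 60),
      mdot = runif(1, 5, 500),
      phi = runif(1, 0.001, 0.2)
    )
  })
}

# physics with every loss mechanism switched off
lossless_physics <- function(...) {
  physics_params(inhalable_sampling = FALSE, ...)
}
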