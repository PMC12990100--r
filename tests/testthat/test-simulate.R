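test_that("the stepped ramp enumerates the standard field magnitudes", {
  p <- stepped_field_protocol()
  mags <- p$fields[, 3]
  expect_equal(p$n_stages, 21)
  expect_equal(length(unique(mags)), 21)
  expect_equal(mags[1], 2.57e-3)
  expect_equal(mags[p$n_stages], 2.06e-1, tolerance = 2e-3)
  # three arithmetic sub-ramps with the stated increments
  expect_equal(mags[1:10], seq(2.57e-3, 2.57e-2, by = 2.57e-3))
  expect_equal(diff(mags[10:15]), rep(5.14e-3, 5), tolerance = 1e-12)
  expect_equal(diff(mags[15:21]), rep(2.57e-2, 6), tolerance = 1e-12)
  expect_true(all(p$durations == 2e5) && all(p$discards == 2e4))
})

test_that("protocol and config invariants are enforced", {
  expect_error(field_protocol(c(0, 0, 0.01), durations = 10, discards = 20))
  expect_error(sim_config(n_solvent = 5, box = 4), "too small")
  expect_error(sim_config(temperature = -1))
  cfg <- sim_config(n_solvent = 30)
  expect_error(simulate_electrolyte(cfg, field = c(0, 0, 0.9),
                                    duration = 10, discard = 0,
                                    equilibrate = 0),
               "exceeds")
})

test_that("identical seed and config reproduce the trajectory bit for bit", {
  cfg <- sim_config(n_solvent = 30, ion = "na", seed = 99)
  s1 <- simulate_electrolyte(cfg, field = c(0, 0, 0.02), duration = 300,
                             discard = 0, equilibrate = 50)
  s2 <- simulate_electrolyte(cfg, field = c(0, 0, 0.02), duration = 300,
                             discard = 0, equilibrate = 50)
  expect_identical(s1$stages[[1]]$ion$vel, s2$stages[[1]]$ion$vel)
  expect_identical(s1$stages[[1]]$frames$positions,
                   s2$stages[[1]]$frames$positions)
  # a different seed decorrelates
  cfg2 <- sim_config(n_solvent = 30, ion = "na", seed = 100)
  s3 <- simulate_electrolyte(cfg2, field = c(0, 0, 0.02), duration = 300,
                             discard = 0, equilibrate = 50)
  expect_false(identical(s1$stages[[1]]$ion$vel, s3$stages[[1]]$ion$vel))
})

test_that("zero-field runs thermalize and show no systematic drift", {
  cfg <- sim_config(n_solvent = 50, ion = "na", seed = 7)
  sim <- simulate_electrolyte(cfg, field = c(0, 0, 0), duration = 20000,
                              discard = 5000, equilibrate = 2000)
  ser <- stage_ion_series(sim$stages[[1]])
  # kinetic temperature within 3% of target after the discard
  expect_equal(mean(ser$temperature), 300, tolerance = 0.03)
  # ion equipartition: VACF(0) = 3 kBT/m within a few percent
  const <- transport_constants()
  v0 <- vacf(ser$vel, ser$dt, max_lag = 10)$vacf[1]
  expect_equal(v0, 3 * const$kB * 300 / (cfg$ion$mass * const$mass_unit),
               tolerance = 0.05)
  # drift statistically indistinguishable from zero (|mean| < 3 SE)
  for (k in 1:3) {
    ms <- mean_with_blocked_sem(ser$vel[, k], discard = 0, dt = ser$dt)
    expect_lt(abs(ms$mean), 3 * max(ms$sem, 1e-12))
  }
  # dipole orientations stay unit norm through the rotational integrator
  dip <- sim$stages[[1]]$frames$dipoles
  nrm <- sqrt(colSums(aperm(dip[-1, , , drop = FALSE], c(2, 1, 3))^2))
  expect_equal(as.vector(nrm), rep(1, length(nrm)), tolerance = 1e-8)
})

test_that("solvent dipoles align with an applied field", {
  # strong field, weak ion coupling: mean cos(theta) approaches the Langevin
  # function L(mu E / kBT)
  cfg <- sim_config(n_solvent = 50, ion = "na", seed = 8, q_ion = 0)
  E <- 0.15
  sim <- simulate_electrolyte(cfg, field = c(0, 0, E), duration = 6000,
                              discard = 2000, equilibrate = 500,
                              frame_stride = 20)
  dip <- sim$stages[[1]]$frames$dipoles
  keep <- sim$stages[[1]]$frames$times - sim$stages[[1]]$frames$times[1] >=
    2000
  ct <- as.vector(dip[-1, 3, keep])
  x <- cfg$mu_dip * E / (transport_constants()$kB * 300)
  langevin <- 1 / tanh(x) - 1 / x
  expect_equal(mean(ct), langevin, tolerance = 0.15)
})

test_that("a single free Langevin particle obeys the OU closed forms", {
  const <- transport_constants()
  gamma <- 0.02
  cfg <- sim_config(n_solvent = 1, ion = "na", box = 40, gamma_t = gamma,
                    eps_ss = 0, mu_dip = 0, seed = 12)
  cfg$eps_is <- 0 # no pair interactions: pure Ornstein-Uhlenbeck
  sim <- simulate_electrolyte(cfg, field = c(0, 0, 0), duration = 2e5,
                              discard = 0, equilibrate = 0,
                              frame_stride = 1e5)
  ser <- stage_ion_series(sim$stages[[1]])
  kBT_m <- const$kB * 300 / (cfg$ion$mass * const$mass_unit)
  res <- vacf(ser$vel, ser$dt, max_lag = 3 / gamma)
  expect_equal(res$vacf[1], 3 * kBT_m, tolerance = 0.02)
  # normalized VACF decays as exp(-gamma tau)
  theory <- exp(-gamma * res$lag)
  expect_lt(max(abs(res$vacf / res$vacf[1] - theory)), 0.05)
  D <- green_kubo_diffusion(vacf(ser$vel, ser$dt, max_lag = 2600), 2500)
  expect_equal(as.numeric(D), kBT_m / gamma, tolerance = 0.05)
})

test_that("Markov coordination series honours its generating parameters", {
  # one state: constant series, survival C == 1
  m1 <- markov_cn_series(1000, cn_states = 5L, seed = 61)
  expect_true(all(m1$cn == 5))
  s <- survival_correlation(as_shell_series(m1), max_lag = 400)
  expect_true(all(s$C == 1))

  # two states: empirical mean dwell within 5% of 1/k
  k <- 1e-2
  m2 <- markov_cn_series(1e5, cn_states = c(4L, 6L), dwell_rates = k,
                         seed = 62)
  runs <- rle(m2$cn)
  expect_equal(mean(runs$lengths), 1 / k, tolerance = 0.05)

  # identity-set size always equals the CN state
  expect_true(all(lengths(m2$members) == m2$cn))

  # per-state drifts with known occupancies: time-weighted mixture to ~1%
  m3 <- markov_cn_series(2e5, cn_states = c(4L, 6L),
                         dwell_rates = c(2e-2, 1e-2),
                         drifts = c(0, 1), seed = 63)
  occ6 <- mean(m3$cn == 6)
  expect_equal(mean(m3$drift), occ6, tolerance = 1e-9) # exact by construction
  # occupancy matches the chain's stationary distribution (2/3 for state 6)
  expect_equal(occ6, 2 / 3, tolerance = 0.02)
})

test_that("deeper ion-solvent wells strictly lengthen the shell lifetime", {
  tau_for <- function(mult) {
    cfg <- sim_config(n_solvent = 80, ion = "na", well_depth_mult = mult,
                      seed = 21)
    sim <- simulate_electrolyte(cfg, field = c(0, 0, 0), duration = 40000,
                                discard = 8000, equilibrate = 2000,
                                frame_stride = 10)
    st <- sim$stages[[1]]
    rdf <- compute_rdf(st$frames, discard = st$discard)
    rdf <- tryCatch(detect_first_minimum(rdf), error = function(e) {
      rdf$R0 <- 1.4 * rdf$r[which.max(rdf$g)]
      rdf
    })
    sh <- shell_series(st$frames, rdf$R0, discard = st$discard)
    continuous_lifetime(survival_correlation(sh))
  }
  # multipliers spanning the weak ("cs-like") to strong ("li-like") regimes
  taus <- vapply(c(0.3, 1, 3), tau_for, 0)
  expect_true(all(diff(taus) > 0))
})
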