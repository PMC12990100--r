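test_that("survival correlation handles constant and instant-exit shells", {
  # membership never changes: C == 1 at every lag
  sh <- manual_shell_series(rep(list(1:4), 50))
  s <- survival_correlation(sh, max_lag = 20)
  expect_equal(s$C, rep(1, 21))
  expect_equal(continuous_lifetime(s), 20) # C == 1 integrates to the range

  # every member exits at the first step and never returns
  members <- lapply(seq_len(40), function(i) (10 * i):(10 * i + 2))
  s2 <- survival_correlation(manual_shell_series(members), max_lag = 10)
  expect_equal(s2$C[1], 1)
  expect_true(all(s2$C[-1] == 0))
  expect_lte(continuous_lifetime(s2), s2$dt)

  expect_error(survival_correlation(manual_shell_series(rep(list(integer(0)),
                                                            20))),
               "empty")
})

test_that("survival correlation matches Poisson exchange decay", {
  k <- 2e-3 # per fs
  m <- markov_cn_series(1e5, dt = 1, cn_states = 6L, exchange_rate = k,
                        seed = 31)
  s <- survival_correlation(as_shell_series(m), max_lag = 3 / k)
  expect_true(all(diff(s$C) <= 0)) # exactly non-increasing
  theory <- exp(-k * s$lag)
  expect_lt(max(abs(s$C - theory)), 0.05)
  # relative agreement over the first decade of decay
  early <- s$lag <= 1 / k
  expect_lt(max(abs(s$C[early] - theory[early]) / theory[early]), 0.05)
})

test_that("continuous lifetime integrates an exponential to its time scale", {
  tau0 <- 500
  lag <- seq(0, 20 * tau0, by = 10)
  s <- structure(list(lag = lag, C = exp(-lag / tau0), n_origins = 1,
                      dt = 10), class = "survival_result")
  expect_equal(continuous_lifetime(s), tau0 * (1 - exp(-20)),
               tolerance = 0.01)
})

test_that("VACF of a constant velocity is its squared norm at every lag", {
  v <- matrix(rep(c(1e-3, -2e-3, 0.5e-3), each = 200), 200, 3)
  res <- vacf(v, dt = 1, max_lag = 50)
  expect_equal(res$vacf, rep(sum(c(1e-3, -2e-3, 0.5e-3)^2), 51),
               tolerance = 1e-12)
})

test_that("VACF and Green-Kubo recover the Ornstein-Uhlenbeck closed forms", {
  # exact discrete OU: v_{n+1} = a v_n + s xi, a = exp(-gamma dt)
  const <- transport_constants()
  gamma <- 0.01; m <- 20; temp <- 300; dt <- 1
  kBT_m <- const$kB * temp / (m * const$mass_unit)
  a <- exp(-gamma * dt); s <- sqrt(kBT_m * (1 - a^2))
  set.seed(32)
  n <- 4e5
  v <- matrix(0, n, 3)
  for (k in 1:3) {
    xi <- rnorm(n)
    v[, k] <- as.vector(stats::filter(s * xi, a, method = "recursive"))
  }
  res <- vacf(v, dt = dt, max_lag = 3 / gamma)
  expect_equal(res$vacf[1], 3 * kBT_m, tolerance = 0.02) # equipartition
  theory <- 3 * kBT_m * exp(-gamma * res$lag)
  expect_lt(max(abs(res$vacf - theory) / theory[1]), 0.05)

  # D = VACF(0)/(3 gamma) for exponential decay; analytic integral check
  lag <- seq(0, 5000, by = 1)
  vr <- structure(list(lag = lag, vacf = 3 * kBT_m * exp(-gamma * lag),
                       dt = 1, n = length(lag)), class = "vacf_result")
  D <- green_kubo_diffusion(vr, 2500)
  expect_equal(as.numeric(D), kBT_m / gamma, tolerance = 0.005)

  # zero VACF integrates to zero; short grids are range errors
  vr0 <- structure(list(lag = lag, vacf = lag * 0, dt = 1, n = length(lag)),
                   class = "vacf_result")
  expect_equal(as.numeric(green_kubo_diffusion(vr0, 2500)), 0)
  expect_error(green_kubo_diffusion(res, 1e6), "short")
})

test_that("Green-Kubo and Einstein MSD routes agree on the same series", {
  const <- transport_constants()
  gamma <- 0.02; m <- 20; temp <- 300; dt <- 1
  kBT_m <- const$kB * temp / (m * const$mass_unit)
  a <- exp(-gamma * dt); s <- sqrt(kBT_m * (1 - a^2))
  set.seed(33)
  n <- 2e5
  v <- matrix(0, n, 3)
  for (k in 1:3) {
    v[, k] <- as.vector(stats::filter(s * rnorm(n), a, method = "recursive"))
  }
  pos <- apply(v, 2, cumsum) * dt
  D_gk <- green_kubo_diffusion(vacf(v, dt, max_lag = 2600), 2500)
  D_ms <- einstein_msd_diffusion(pos, dt, fit_range = c(500, 3000))
  expect_equal(as.numeric(D_gk), kBT_m / gamma, tolerance = 0.05)
  expect_equal(D_ms / as.numeric(D_gk), 1, tolerance = 0.10)
})

test_that("bootstrap of segment estimates matches closed forms and is seeded", {
  b0 <- bootstrap_diffusion(rep(3.5, 10), 500, seed = 1)
  expect_equal(b0$mean, 3.5)
  expect_equal(b0$sd, 0)

  # two values {0, 1}: SD of the resampled mean is exactly 0.5/sqrt(2)
  b1 <- bootstrap_diffusion(c(0, 1), 2e5, seed = 2)
  expect_equal(b1$sd, 0.5 / sqrt(2), tolerance = 0.03)

  b2 <- bootstrap_diffusion(c(0, 1), 2e5, seed = 2)
  expect_identical(b1, b2) # seeded determinism

  # mean converges to the sample mean for large resample counts
  set.seed(3)
  est <- rnorm(50)
  b3 <- bootstrap_diffusion(est, 1e5, seed = 4)
  expect_lt(abs(b3$mean - mean(est)), 0.005 * sd(est))
})

test_that("finite-size extrapolation recovers intercepts", {
  # exact line: intercept recovered to round-off
  L <- c(10, 12, 15, 20, 30)
  D <- 2e-4 + 3e-3 / L
  fit <- finite_size_extrapolation(L, D, SD = rep(1e-6, 5))
  expect_equal(fit$D_inf, 2e-4, tolerance = 1e-12)
  expect_equal(fit$slope, 3e-3, tolerance = 1e-9)

  # two points: exact interpolation
  fit2 <- finite_size_extrapolation(c(10, 20), 2e-4 + 3e-3 / c(10, 20))
  expect_equal(fit2$D_inf, 2e-4, tolerance = 1e-12)

  expect_error(finite_size_extrapolation(c(10, 10), c(1, 2)), "singular")

  # Monte-Carlo coverage: intercept within 2 SE of truth in ~95% of repeats
  set.seed(34)
  hits <- 0; reps <- 200
  for (r in seq_len(reps)) {
    Dn <- 2e-4 + 3e-3 / L + rnorm(5, sd = 2e-5)
    f <- finite_size_extrapolation(L, Dn, SD = rep(2e-5, 5))
    if (abs(f$D_inf - 2e-4) < 2 * f$D_inf_se) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.85)
})

test_that("Nernst-Einstein conversion reproduces the constants arithmetic", {
  expect_equal(nernst_einstein(0), 0)
  expect_equal(nernst_einstein(1e-9, 300, unit = "m2s"), 37.32,
               tolerance = 1e-3)
  expect_equal(nernst_einstein(2e-4), 2 * nernst_einstein(1e-4))
  # internal-unit route: 1e-4 A^2/fs = 1e-9 m^2/s
  expect_equal(nernst_einstein(1e-4), nernst_einstein(1e-9, unit = "m2s"))
})

test_that("VDOS finds a pure-tone peak and flags featureless spectra", {
  dt <- 1; n <- 48000; nu0 <- 0.01
  t <- (seq_len(n) - 1) * dt
  v <- cbind(1e-3 * cos(2 * pi * nu0 * t), 0, 0)
  vd <- vdos(v, dt, block_counts = c(8, 16))
  rat <- rattling_period(vd)
  expect_equal(rat$freq, nu0, tolerance = 0.05)
  expect_equal(rat$period, 1 / nu0, tolerance = 0.05 * 100)
  # peak stable across block counts
  expect_lt(diff(range(rat$peak_by_blocks)) / rat$freq, 0.1)
  expect_true(all(vd$spectra[[1]]$intensity >= 0))

  # wavenumber conversion: a 50 cm^-1 peak corresponds to ~667 fs
  expect_equal(1 / (transport_constants()$c_cm_fs * 50), 667, tolerance = 1)

  # white-noise velocities: flat spectrum, no qualifying interior peak
  set.seed(35)
  vw <- matrix(rnorm(3 * n, sd = 1e-3), n, 3)
  expect_error(rattling_period(vdos(vw, dt, block_counts = c(16))),
               "monotone|no caged", ignore.case = TRUE)

  expect_error(vdos(v[1:10, ], dt, block_counts = c(8)), "fewer than 2")
})

test_that("VDOS peak of a damped oscillator sits near its natural frequency", {
  # underdamped Langevin in a harmonic well, gamma << omega0
  const <- transport_constants()
  m <- 20 * const$mass_unit
  omega0 <- 0.05; gamma <- 0.005; dt <- 1; temp <- 300
  kBT <- const$kB * temp
  set.seed(36)
  n <- 60000
  x <- 0; vv <- sqrt(kBT / m)
  vs <- numeric(n)
  c1 <- exp(-gamma * dt); c2 <- sqrt((1 - c1^2) * kBT / m)
  for (i in seq_len(n)) {
    vv <- vv - 0.5 * dt * omega0^2 * x
    x <- x + 0.5 * dt * vv
    vv <- c1 * vv + c2 * rnorm(1)
    x <- x + 0.5 * dt * vv
    vv <- vv - 0.5 * dt * omega0^2 * x
    vs[i] <- vv
  }
  vd <- vdos(cbind(vs, 0, 0), dt, block_counts = c(12, 24))
  rat <- rattling_period(vd)
  expect_equal(rat$freq, omega0 / (2 * pi), tolerance = 0.05)
})

test_that("two spectral peaks: the lower frequency one defines the period", {
  dt <- 1; n <- 48000
  t <- (seq_len(n) - 1) * dt
  v <- cbind(1e-3 * cos(2 * pi * 0.01 * t) + 0.8e-3 * cos(2 * pi * 0.05 * t),
             0, 0)
  rat <- rattling_period(vdos(v, dt, block_counts = c(16)))
  expect_equal(rat$freq, 0.01, tolerance = 0.05)
})
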