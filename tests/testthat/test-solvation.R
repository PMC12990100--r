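test_that("RDF of an ideal gas is flat and its running CN integrates volume", {
  set.seed(21)
  box <- 12; n_atoms <- 101; n_frames <- 60
  pos <- array(runif(n_atoms * 3 * n_frames, 0, box),
               c(n_atoms, 3, n_frames))
  traj <- trajectory(pos, c("I", rep("S", 100)), box,
                     (seq_len(n_frames) - 1) * 1.0)
  rdf <- compute_rdf(traj, bin_width = 0.2)
  # beyond contact (here: everywhere), g ~ 1 within Poisson error per bin
  keep <- rdf$r > 1 & rdf$r < box / 2
  expected_counts <- rdf$n_frames * rdf$rho * 4 * pi * rdf$r^2 * 0.2
  tol <- 3 / sqrt(expected_counts[keep])
  expect_true(all(abs(rdf$g[keep] - 1) < pmax(tol, 0.2)))
  # n(r -> box/2) approaches (4/3) pi rho (L/2)^3
  n_half <- rdf$running_cn[max(which(rdf$r < box / 2))]
  expect_equal(n_half, 4 / 3 * pi * rdf$rho * (box / 2)^3, tolerance = 0.05)
})

test_that("two fixed atoms give a single occupied RDF bin at their distance", {
  pos <- array(0, c(2, 3, 5))
  pos[2, 1, ] <- 3.14
  traj <- trajectory(pos, c("I", "S"), 40, 0:4)
  rdf <- compute_rdf(traj, bin_width = 0.03, r_max = 10)
  hit <- which(rdf$counts > 0)
  expect_length(hit, 1)
  expect_lt(abs(rdf$r[hit] - 3.14), 0.03)
  expect_error(compute_rdf(traj, partner = "Q"), "empty partner")
})

test_that("first-minimum detection finds a constructed valley", {
  r <- seq(0.015, 8, by = 0.03)
  valley <- 3.2
  g_clean <- 3 * exp(-(r - 2.4)^2 / 0.08) + 1.2 * exp(-(r - 4.2)^2 / 0.3)
  rdf <- structure(list(r = r, g = g_clean, running_cn = cumsum(g_clean),
                        rho = 0.03, counts = round(g_clean * 50),
                        n_frames = 1, bin_width = 0.03, R0 = NA_real_),
                   class = "rdf_result")
  R0 <- detect_first_minimum(rdf)$R0
  g_at <- function(x) 3 * exp(-(x - 2.4)^2 / 0.08) + 1.2 * exp(-(x - 4.2)^2 / 0.3)
  true_min <- optimize(g_at, c(2.4, 4.2))$minimum
  expect_lt(abs(R0 - true_min), 0.03 + 1e-9)

  # noisy valley, smoothing on: within 2 bins of the noiseless minimum
  set.seed(22)
  rdf_noisy <- rdf
  rdf_noisy$g <- g_clean + rnorm(length(r), sd = 0.04)
  R0n <- detect_first_minimum(rdf_noisy)$R0
  expect_lt(abs(R0n - true_min), 2 * 0.03 + 1e-9)

  # monotone g(r): detection error
  rdf_mono <- rdf
  rdf_mono$g <- seq(0, 2, length.out = length(r))
  expect_error(detect_first_minimum(rdf_mono), "minimum")
})

test_that("smooth CN switching function obeys its limits", {
  expect_equal(smooth_cn(1.0, R0 = 1), 0.5) # NN/ND limit at r = R0
  expect_equal(smooth_cn(1e-12, R0 = 1), 1.0)
  expect_equal(smooth_cn(1.2, R0 = 1), 0.02542, tolerance = 2e-4)
  expect_equal(smooth_cn(1.2, R0 = 1), (1 - 1.2^20) / (1 - 1.2^40))
  expect_equal(smooth_cn(100, R0 = 1), 0) # far outside: no overflow
  # monotone non-increasing in each distance
  r <- seq(0.01, 3, by = 0.01)
  vals <- vapply(r, smooth_cn, 0, R0 = 1)
  expect_true(all(diff(vals) <= 1e-12))
  # additivity over distances
  expect_equal(smooth_cn(c(0.5, 1.0, 1.5), R0 = 1),
               sum(vapply(c(0.5, 1.0, 1.5), smooth_cn, 0, R0 = 1)))
})

test_that("PMF reproduces Boltzmann ratios and fixes its constant at 0", {
  # two equally populated bins: delta PMF = 0
  p1 <- pmf_from_cn(rep(c(4, 5), 500), bin_width = 1)
  occupied <- which(p1$counts > 0)
  expect_equal(p1$pmf[occupied], c(0, 0))

  # populations in ratio e:1 differ by exactly 1 kBT
  n2 <- 40000
  cn <- rep(c(4, 5), round(c(n2 * exp(1) / (1 + exp(1)), n2 / (1 + exp(1)))))
  p2 <- pmf_from_cn(cn, bin_width = 1)
  occ <- which(p2$counts > 0)
  expect_equal(diff(p2$pmf[occ]), 1.0, tolerance = 1e-3)

  expect_warning(pmf_from_cn(rep(4, 200), bin_width = 0.1), "identical")
  expect_warning(pmf_from_cn(c(4, 5), bin_width = 1), "100 samples")
  # empty interior bins are NA, not zero
  p3 <- pmf_from_cn(rep(c(1, 3), 100), bin_width = 1)
  expect_true(anyNA(p3$pmf))
})

test_that("PMF is a shape statistic, invariant under sample-count rescaling", {
  set.seed(23)
  x <- seq(2, 8, length.out = 400)
  u <- 2 * (x - 5)^2 * ((x - 5)^2 - 1.2) # double well, kBT units
  u <- u - min(u)
  p <- exp(-u)
  s1 <- sample_from_density(x, p, 2e4, seed = 1)
  pm1 <- pmf_from_cn(s1, bin_width = 0.25)
  pm2 <- pmf_from_cn(rep(s1, 3), bin_width = 0.25)
  expect_equal(pm1$pmf, pm2$pmf, tolerance = 1e-12)
})

test_that("integer CN histogram counts every frame", {
  sh <- manual_shell_series(list(1:4, 1:4, 1:4))
  h <- integer_cn_histogram(sh)
  expect_equal(as.integer(names(h)), 4)
  expect_equal(unname(h), 3L)
  expect_identical(integer_cn_histogram(manual_shell_series(list())),
                   integer(0))

  m <- markov_cn_series(50000, cn_states = c(4L, 6L), dwell_rates = 0.01,
                        seed = 24)
  h2 <- integer_cn_histogram(as_shell_series(m))
  expect_equal(sum(h2), 50000)
  # symmetric two-state chain: occupancies near 1/2 each
  expect_equal(unname(h2["4"] / sum(h2)), 0.5, tolerance = 0.05)
})

test_that("tilt-angle density is isotropic without a field and normalized", {
  set.seed(25)
  box <- 20; n_atoms <- 31; n_frames <- 40
  pos <- array(runif(n_atoms * 3 * n_frames, 0, box), c(n_atoms, 3, n_frames))
  pos[1, , ] <- box / 2 # ion fixed at the center
  dip <- array(rnorm(n_atoms * 3 * n_frames), c(n_atoms, 3, n_frames))
  for (k in seq_len(n_frames)) {
    dip[, , k] <- dip[, , k] / sqrt(rowSums(dip[, , k]^2))
  }
  traj <- trajectory(pos, c("I", rep("S", 30)), box,
                     (seq_len(n_frames) - 1) * 1.0, dipoles = dip)
  sh <- shell_series(traj, R0 = 9)
  td <- tilt_angle_density(traj, sh, field_direction = c(0, 0, 1), nbins = 10)
  cell <- (2 / 10)^2
  expect_equal(sum(td$density) * cell, 1, tolerance = 1e-10)
  expect_true(all(td$density >= 0))
  expect_lt(abs(td$correlation), 3 / sqrt(td$n_samples))
  # leading and trailing mean cos(theta) agree within combined standard error
  se <- sqrt(1 / 3) * sqrt(1 / sum(td$cos_alpha < 0) +
                           1 / sum(td$cos_alpha > 0))
  expect_lt(abs(td$mean_cos_theta_leading - td$mean_cos_theta_trailing),
            3 * se)

  # all dipoles parallel to the field: all mass on the cos(theta) = 1 edge
  dip1 <- dip; dip1[, 1, ] <- 0; dip1[, 2, ] <- 0; dip1[, 3, ] <- 1
  traj1 <- trajectory(pos, c("I", rep("S", 30)), box,
                      (seq_len(n_frames) - 1) * 1.0, dipoles = dip1)
  td1 <- tilt_angle_density(traj1, sh, field_direction = c(0, 0, 1),
                            nbins = 10)
  expect_true(all(td1$density[, 1:9] == 0))
  expect_equal(td1$mean_cos_theta_trailing, 1)

  # zero field without a reference axis is an error
  expect_error(tilt_angle_density(traj, sh), "reference")
})

test_that("printed trailing cosines convert to the expected tilt angles", {
  expect_equal(round(cos_to_degrees(0.49), 1), 60.7)
  expect_equal(round(cos_to_degrees(0.30), 1), 72.5)
  expect_equal(round(cos_to_degrees(0.05), 1), 87.1)
})
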