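# Shared fixtures, built in code at test time.

random_apt_set <- function(n, q_tot = 1, sd = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  apt_set(array(rnorm(n * 9, sd = sd), c(n, 3, 3)), q_tot = q_tot)
}

# a tiny hand-made trajectory: n_atoms on a line, optionally drifting
toy_trajectory <- function(n_atoms = 4, n_frames = 3, box = 10, dt = 1,
                           velocities = TRUE, dipoles = FALSE,
                           fields = NULL, seed = 42) {
  set.seed(seed)
  pos <- array(runif(n_atoms * 3 * n_frames, 0, box),
               c(n_atoms, 3, n_frames))
  vel <- if (velocities) {
    array(rnorm(n_atoms * 3 * n_frames, sd = 1e-3), c(n_atoms, 3, n_frames))
  } else NULL
  dip <- NULL
  if (dipoles) {
    dip <- array(rnorm(n_atoms * 3 * n_frames), c(n_atoms, 3, n_frames))
    for (k in seq_len(n_frames)) {
      nrm <- sqrt(rowSums(dip[, , k]^2))
      dip[, , k] <- dip[, , k] / nrm
    }
  }
  trajectory(pos, c("NA", rep("S", n_atoms - 1)), box,
             times = (seq_len(n_frames) - 1) * dt,
             velocities = vel, dipoles = dip, fields = fields)
}

# membership list -> shell_series (bypasses geometry)
manual_shell_series <- function(members, dt = 1, R0 = 3) {
  structure(list(members = members,
                 cn = lengths(members),
                 smooth_cn = as.numeric(lengths(members)),
                 times = (seq_along(members) - 1) * dt,
                 dt = dt, R0 = R0, NN = 20, ND = 40),
            class = "shell_series")
}

# inverse-CDF sampler for a density known on a grid
sample_from_density <- function(x, p, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cdf <- cumsum(p) / sum(p)
  x[findInterval(runif(n), cdf) + 1L]
}
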