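#' Ion presets for the toy electrolyte
#'
#' Three cation archetypes differing in mass, size and ion-solvent well depth.
#' The well depth controls first-shell stability: the "li" preset binds its
#' shell strongly (slow ligand exchange, vehicular transport), "cs" weakly
#' (fast exchange, structural transport), "na" is intermediate.
#'
#' @param name One of `"li"`, `"na"`, `"cs"`.
#' @return List with `label`, `mass` (amu), `sigma_is` (A), `eps_is` (eV).
#' @export
ion_preset <- function(name = c("na", "li", "cs")) {
  name <- match.arg(name)
  switch(name,
    li = list(label = "li", mass = 6.94,  sigma_is = 2.0, eps_is = 0.400),
    na = list(label = "na", mass = 22.99, sigma_is = 2.6, eps_is = 0.105),
    cs = list(label = "cs", mass = 132.9, sigma_is = 3.2, eps_is = 0.022))
}

#' Configuration of the toy finite-field electrolyte simulator
#'
#' One cation (atom 1) in a bath of single-site Lennard-Jones solvent
#' particles, each carrying a rigid point dipole with overdamped rotational
#' Brownian dynamics. Translations follow Langevin (BAOAB) dynamics whose
#' friction doubles as the heat sink for the Joule heat injected by the field.
#'
#' @param n_solvent Number of solvent particles.
#' @param ion Ion preset name (see [ion_preset()]) or a list with the same
#'   fields.
#' @param box Cubic box edge (A). Default sized to water-like number density
#'   0.0334 1/A^3 for `n_solvent + 1` particles.
#' @param solvent_mass Solvent mass (amu), default water-like 18.015.
#' @param sigma_ss,eps_ss Solvent-solvent LJ parameters (A, eV), default
#'   SPC/E-like 3.166 A, 0.00674 eV.
#' @param well_depth_mult Multiplier on the preset's ion-solvent well depth;
#'   >1 deepens the first-shell well (longer ligand lifetimes).
#' @param q_ion Ion Born charge (e); its Born-charge tensor is `q_ion * I`.
#' @param mu_dip Solvent dipole magnitude (e.A), default water-like 0.489.
#' @param gamma_t,gamma_r Translational/rotational friction (1/fs).
#' @param rot_inertia Effective moment of inertia for rotational diffusion
#'   (amu A^2), water-like 0.64.
#' @param temperature Thermostat target (K).
#' @param dt Timestep (fs).
#' @param dipole_cutoff Cutoff for the ion charge-dipole torque (A); default
#'   half the box.
#' @param max_field Maximum allowed field magnitude (V/A).
#' @param seed Master seed; per-stage child seeds are derived from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_solvent = 200, ion = "na", box = NULL,
                       solvent_mass = 18.015,
                       sigma_ss = 3.166, eps_ss = 0.00674,
                       well_depth_mult = 1, q_ion = 1, mu_dip = 0.489,
                       gamma_t = 0.01, gamma_r = 0.1, rot_inertia = 0.64,
                       temperature = 300, dt = 1,
                       dipole_cutoff = NULL, max_field = 0.3, seed = 1L) {
  if (is.character(ion)) ion <- ion_preset(ion)
  stopifnot(n_solvent >= 1, temperature > 0, dt > 0, well_depth_mult > 0)
  if (is.null(box)) box <- ((n_solvent + 1) / 0.0334)^(1 / 3)
  # interaction cutoffs: 2.5 sigma, capped just below half the box so the
  # minimum-image convention stays valid in small cells
  rc_ss <- min(2.5 * sigma_ss, 0.49 * box)
  rc_is <- min(2.5 * ion$sigma_is, 0.49 * box)
  if (box < 2.2 * max(sigma_ss, ion$sigma_is)) {
    stop(sprintf("box %.2f A too small for sigma %.2f A interactions",
                 box, max(sigma_ss, ion$sigma_is)))
  }
  if (is.null(dipole_cutoff)) dipole_cutoff <- box / 2
  structure(list(
    n_solvent = n_solvent, ion = ion, box = box,
    solvent_mass = solvent_mass, sigma_ss = sigma_ss, eps_ss = eps_ss,
    eps_is = ion$eps_is * well_depth_mult, sigma_is = ion$sigma_is,
    well_depth_mult = well_depth_mult,
    q_ion = q_ion, mu_dip = mu_dip,
    gamma_t = gamma_t, gamma_r = gamma_r, rot_inertia = rot_inertia,
    temperature = temperature, dt = dt,
    rc_ss = rc_ss, rc_is = rc_is,
    dipole_cutoff = dipole_cutoff, max_field = max_field,
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d solvent + 1 '%s' ion, box %.2f A, T %g K, dt %g fs\n",
              x$n_solvent, x$ion$label, x$box, x$temperature, x$dt))
  cat(sprintf("  eps_is %.4g eV (mult %.2g), sigma_is %.3g A, q_ion %+g e\n",
              x$eps_is, x$well_depth_mult, x$sigma_is, x$q_ion))
  invisible(x)
}

#' Field protocol: ordered finite-field stages
#'
#' @param fields Matrix (n_stages x 3) or list of length-3 field vectors (V/A).
#' @param durations Stage durations (fs), scalar or vector.
#' @param discards Equilibration discard at the start of each stage (fs).
#' @return Object of class `field_protocol` (data.frame-like stage table).
#' @export
field_protocol <- function(fields, durations, discards = 0) {
  if (is.list(fields)) fields <- do.call(rbind, fields)
  fields <- matrix(fields, ncol = 3)
  n <- nrow(fields)
  durations <- rep_len(durations, n)
  discards <- rep_len(discards, n)
  stopifnot(all(durations > discards), all(discards >= 0))
  structure(list(fields = fields, durations = durations, discards = discards,
                 n_stages = n), class = "field_protocol")
}

#' @export
print.field_protocol <- function(x, ...) {
  mags <- sqrt(rowSums(x$fields^2))
  cat(sprintf("field_protocol: %d stages, |E| in [%.4g, %.4g] V/A\n",
              x$n_stages, min(mags), max(mags)))
  cat(sprintf("  durations %s fs, discards %s fs\n",
              paste(unique(x$durations), collapse = "/"),
              paste(unique(x$discards), collapse = "/")))
  invisible(x)
}

#' Stepped field-ramp protocol
#'
#' The standard finite-field ramp along z: fields stepped in increments of
#' 2.57e-3 V/A from 2.57e-3 to 2.57e-2 V/A, then in increments of 5.14e-3 V/A
#' up to 5.14e-2 V/A, and finally in increments of 2.57e-2 V/A up to
#' 2.06e-1 V/A - 21 distinct nonzero magnitudes. Each stage starts from the
#' final configuration of the previous one.
#'
#' @param duration Per-stage duration (fs), default 200 ps.
#' @param discard Per-stage equilibration discard (fs), default 20 ps.
#' @param magnitudes Optional explicit magnitudes (V/A) replacing the preset
#'   ramp.
#' @return A [field_protocol()] with fields along +z.
#' @export
#' @examples
#' p <- stepped_field_protocol()
#' p$n_stages # 21
stepped_field_protocol <- function(duration = 2e5, discard = 2e4,
                                   magnitudes = NULL) {
  if (is.null(magnitudes)) {
    magnitudes <- c(seq(2.57e-3, 2.57e-2, by = 2.57e-3),
                    seq(2.57e-2 + 5.14e-3, 5.14e-2, by = 5.14e-3),
                    seq(5.14e-2 + 2.57e-2, 2.06e-1, by = 2.57e-2))
  }
  fields <- cbind(0, 0, magnitudes)
  field_protocol(fields, duration, discard)
}

init_configuration <- function(config, max_attempts = 200) {
  n <- config$n_solvent + 1
  box <- config$box
  # simple-cubic lattice, ion on the central site
  per_side <- ceiling(n^(1 / 3))
  g <- (seq_len(per_side) - 0.5) * box / per_side
  grid <- as.matrix(expand.grid(x = g, y = g, z = g))[seq_len(n), , drop = FALSE]
  mid <- which.min(rowSums((grid - box / 2)^2))
  pos <- rbind(grid[mid, ], grid[-mid, , drop = FALSE])
  # jittered retry if any pair is closer than 60% of sigma (cannot happen on
  # the pristine lattice, but guards tight user-supplied boxes)
  min_ok <- 0.6 * min(config$sigma_ss, config$sigma_is)
  for (attempt in seq_len(max_attempts)) {
    d <- stats::dist(pos)
    if (min(d) >= min_ok) break
    if (attempt == max_attempts) {
      stop("could not place particles without overlap; box too small?")
    }
    pos <- pos + matrix(stats::rnorm(3 * n, sd = 0.05), n, 3)
  }
  const <- transport_constants()
  masses <- c(config$ion$mass, rep(config$solvent_mass, config$n_solvent))
  vsd <- sqrt(const$kB * config$temperature / (masses * const$mass_unit))
  vel <- matrix(stats::rnorm(3 * n), n, 3) * vsd
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  u[1, ] <- c(0, 0, 1) # ion carries no dipole; placeholder orientation
  list(pos = pos, vel = vel, dip = u, masses = masses)
}

run_stage <- function(config, state, field, nsteps, ion_stride, frame_stride,
                      stage_seed) {
  set.seed(stage_seed)
  field <- check_field(field, config$max_field)
  res <- ff_langevin_run(
    state$pos, state$vel, state$dip,
    box = config$box, mass = state$masses,
    q_ion = config$q_ion, mu_dip = config$mu_dip,
    sig_ss = config$sigma_ss, eps_ss = config$eps_ss,
    sig_is = config$sigma_is, eps_is = config$eps_is,
    rc_ss = config$rc_ss, rc_is = config$rc_is,
    gamma_t = config$gamma_t, gamma_r = config$gamma_r,
    rot_inertia = config$rot_inertia,
    temperature = config$temperature, dt = config$dt,
    field = field, nsteps = as.integer(nsteps),
    ion_stride = as.integer(ion_stride),
    frame_stride = as.integer(frame_stride),
    vmax = 1.0, dipole_cutoff = config$dipole_cutoff)
  res
}

stage_trajectory <- function(res, config, field, t_offset = 0) {
  n <- config$n_solvent + 1
  nf <- length(res$frame_t)
  lab <- config$ion$label
  species <- c(paste0(toupper(substring(lab, 1, 1)), substring(lab, 2)),
               rep("S", config$n_solvent))
  dim(res$frame_pos) <- c(n, 3, nf)
  dim(res$frame_vel) <- c(n, 3, nf)
  dim(res$frame_dip) <- c(n, 3, nf)
  dip <- res$frame_dip
  dip[1, , ] <- NA_real_
  trajectory(res$frame_pos, species, config$box, t_offset + res$frame_t,
             velocities = res$frame_vel, dipoles = dip,
             fields = field,
             metadata = list(source = "toy_electrolyte_sim"))
}

#' Run the toy finite-field electrolyte simulation
#'
#' Simulates one cation in a dipolar solvent bath under an ordered protocol of
#' homogeneous field stages. Each stage continues from the final configuration
#' of the previous one; per-stage seeds are derived deterministically from the
#' config's master seed, so identical config + protocol reproduce the
#' trajectory bit for bit.
#'
#' @param config A [sim_config()].
#' @param protocol A [field_protocol()], or NULL for a single stage.
#' @param field,duration,discard Single-stage shortcut used when `protocol` is
#'   NULL: one field vector (V/A), duration and discard (fs).
#' @param ion_stride Steps between ion position/velocity samples (fine series
#'   for current density and VACF).
#' @param frame_stride Steps between full frames (all atoms; used by the
#'   structural analyses).
#' @param equilibrate Extra zero-field equilibration (fs) run before the first
#'   stage and not recorded (default 5000 fs).
#' @return Object of class `ff_simulation`: list of per-stage results, each
#'   with elements `field`, `discard`, `ion` (times/pos/vel/temperature after
#'   no discard; discard is metadata for analyses), and `frames`
#'   (a [trajectory()]).
#' @export
simulate_electrolyte <- function(config, protocol = NULL,
                                 field = c(0, 0, 0), duration = 5e4,
                                 discard = 2e4,
                                 ion_stride = 1, frame_stride = 25,
                                 equilibrate = 5000) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(protocol)) {
    protocol <- field_protocol(matrix(field, 1, 3), duration, discard)
  }
  set.seed(config$seed)
  state <- init_configuration(config)
  stage_seeds <- sample.int(.Machine$integer.max - 1, protocol$n_stages + 1)
  if (equilibrate > 0) {
    res <- run_stage(config, state, c(0, 0, 0),
                     nsteps = max(1, round(equilibrate / config$dt)),
                     ion_stride = 1e9, frame_stride = 1e9,
                     stage_seed = stage_seeds[protocol$n_stages + 1])
    state$pos <- res$final_pos; state$vel <- res$final_vel
    state$dip <- res$final_dip
  }
  stages <- vector("list", protocol$n_stages)
  t_offset <- 0
  for (s in seq_len(protocol$n_stages)) {
    fld <- protocol$fields[s, ]
    nsteps <- max(1, round(protocol$durations[s] / config$dt))
    res <- run_stage(config, state, fld, nsteps, ion_stride, frame_stride,
                     stage_seeds[s])
    state$pos <- res$final_pos; state$vel <- res$final_vel
    state$dip <- res$final_dip
    stages[[s]] <- list(
      field = fld,
      duration = protocol$durations[s],
      discard = protocol$discards[s],
      ion = list(times = t_offset + res$ion_t,
                 pos = res$ion_pos, vel = res$ion_vel,
                 temperature = res$temperature,
                 dt = config$dt * ion_stride),
      frames = stage_trajectory(res, config, fld, t_offset))
    t_offset <- t_offset + protocol$durations[s]
  }
  structure(list(stages = stages, config = config, protocol = protocol),
            class = "ff_simulation")
}

#' @export
print.ff_simulation <- function(x, ...) {
  cat(sprintf("ff_simulation: %d stage(s), '%s' ion, %d solvent, seed %d\n",
              length(x$stages), x$config$ion$label, x$config$n_solvent,
              x$config$seed))
  for (s in seq_along(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  stage %d: E=(%.3g, %.3g, %.3g) V/A, %g fs (discard %g)\n",
                s, st$field[1], st$field[2], st$field[3], st$duration,
                st$discard))
  }
  invisible(x)
}

#' Retained ion velocity series of a simulation stage
#'
#' Drops the equilibration discard and returns the ion velocity samples of a
#' stage, for current-density and VACF analyses.
#'
#' @param stage One element of `ff_simulation$stages`.
#' @return List with `vel` (n x 3), `times`, `dt`, `temperature`.
#' @export
stage_ion_series <- function(stage) {
  keep <- stage$ion$times - stage$ion$times[1] >= stage$discard
  list(vel = stage$ion$vel[keep, , drop = FALSE],
       pos = stage$ion$pos[keep, , drop = FALSE],
       times = stage$ion$times[keep],
       temperature = stage$ion$temperature[keep],
       dt = stage$ion$dt)
}
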