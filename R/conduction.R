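# Ionic current density from the ion's atomic polar tensor and velocity,
# blocked steady-state statistics, conductivity regression, molar conversion.

#' Instantaneous ionic current density along z
#'
#' `J_ion,z(t) = (1/V) * sum_eta P_ion[eta, z] * v_ion[eta](t)`: only the
#' z-column of the ion's polar tensor enters. The per-frame tensor is taken as
#' a static table value by default; a `per_frame_apt` hook accepts an
#' n x 3 x 3 array of per-frame tensors when available.
#'
#' @param vel n x 3 ion velocity matrix (A/fs), or a [trajectory()] (+`atom`).
#' @param ion_apt 3 x 3 ion polar tensor (e), e.g. `q * diag(3)`.
#' @param volume Cell volume (A^3).
#' @param dt Sample spacing (fs); from the trajectory if omitted.
#' @param atom Ion index when `vel` is a trajectory.
#' @param per_frame_apt Optional n x 3 x 3 array overriding `ion_apt` frame by
#'   frame.
#' @return Object of class `current_density_series`: `J` (e A^-2 fs^-1), `dt`,
#'   `volume`; `attr(, "J_si_factor")` converts to A m^-2.
#' @export
#' @examples
#' cds <- current_density_series(cbind(0, 0, 1:3), diag(3), volume = 1000,
#'                               dt = 1)
#' cds$J # (1:3)/1000
current_density_series <- function(vel, ion_apt, volume, dt = NULL,
                                   atom = 1, per_frame_apt = NULL) {
  if (inherits(vel, "trajectory")) {
    if (!has_velocities(vel)) {
      stop("trajectory carries no velocities; current density undefined")
    }
    dt <- trajectory_timestep(vel)
    vel <- t(vel$velocities[atom, , ])
  }
  vel <- as.matrix(vel)
  stopifnot(ncol(vel) == 3, volume > 0)
  if (is.null(per_frame_apt)) {
    ion_apt <- as.matrix(ion_apt)
    stopifnot(identical(dim(ion_apt), c(3L, 3L)))
    J <- as.vector(vel %*% ion_apt[, 3]) / volume
  } else {
    stopifnot(dim(per_frame_apt)[1] == nrow(vel))
    J <- rowSums(vel * per_frame_apt[, , 3]) / volume
  }
  structure(list(J = J, dt = dt, volume = volume,
                 J_si_factor = transport_constants()$J_to_si),
            class = "current_density_series")
}

#' @export
print.current_density_series <- function(x, ...) {
  cat(sprintf("current_density_series: %d frames, <J> = %.4g e A^-2 fs^-1\n",
              length(x$J), mean(x$J)))
  invisible(x)
}

#' Blocked standard error of the mean of a time series
#'
#' Block averaging accounts for the statistical inefficiency of correlated
#' series: the block length is grown (doubled) until the blocked SEM changes
#' by less than 5% over two successive doublings (plateau). If no plateau is
#' reached before fewer than 8 blocks remain, the largest-block SEM is
#' returned with a warning.
#'
#' @param x Numeric series.
#' @return List with `sem`, `block_length`, `plateau` (logical).
#' @export
blocked_sem <- function(x) {
  n <- length(x)
  stopifnot(n >= 2)
  if (stats::sd(x) == 0) {
    return(list(sem = 0, block_length = 1, plateau = TRUE))
  }
  sems <- c(); lens <- c()
  len <- 1
  while (n %/% len >= 8) {
    nb <- n %/% len
    bm <- colMeans(matrix(x[seq_len(nb * len)], nrow = len))
    sems <- c(sems, stats::sd(bm) / sqrt(nb))
    lens <- c(lens, len)
    k <- length(sems)
    if (k >= 3 &&
        abs(sems[k] - sems[k - 1]) < 0.05 * sems[k] &&
        abs(sems[k - 1] - sems[k - 2]) < 0.05 * sems[k - 1]) {
      return(list(sem = sems[k], block_length = len, plateau = TRUE))
    }
    len <- len * 2
  }
  warning("blocked SEM did not plateau; reporting the largest-block estimate")
  list(sem = sems[length(sems)], block_length = lens[length(lens)],
       plateau = FALSE)
}

#' Steady-state mean current density with blocked SEM
#'
#' Discards the leading equilibration window, then reports the mean and the
#' block-averaged standard error of the mean.
#'
#' @param series A `current_density_series` (or numeric vector with `dt`).
#' @param discard Equilibration time to drop (fs), default 20 ps.
#' @param dt Sample spacing, required if `series` is a bare vector.
#' @return List with `mean`, `sem`, `n`, `block_length`, `plateau`.
#' @export
mean_with_blocked_sem <- function(series, discard = 2e4, dt = NULL) {
  if (inherits(series, "current_density_series")) {
    dt <- series$dt
    series <- series$J
  }
  stopifnot(!is.null(dt), dt > 0)
  drop_n <- floor(discard / dt)
  if (drop_n >= length(series)) stop("discard removes the entire series")
  x <- series[(drop_n + 1):length(series)]
  b <- blocked_sem(x)
  list(mean = mean(x), sem = b$sem, n = length(x),
       block_length = b$block_length, plateau = b$plateau)
}

#' Ionic conductivity from the field dependence of the mean current density
#'
#' Weighted (1/SEM^2) zero-intercept least squares of the per-field mean
#' current densities against the field strengths, restricted to the linear
#' regime `fields <= linear_cutoff`. The slope is the ionic conductivity.
#'
#' @param fields Applied field strengths E_z (V/A).
#' @param J_means Mean current densities (e A^-2 fs^-1).
#' @param sems Blocked SEMs (same units); NULL for equal weights.
#' @param linear_cutoff Upper edge of the linear regime (V/A, default 0.0514).
#' @param concentration Ion concentration (mol/L) for the molar conversion;
#'   optional.
#' @return Object of class `conductivity_fit`: `sigma` (internal units),
#'   `sigma_si` (S/m), `sigma_se_si`, `r_squared`, `used` (logical per input
#'   point), `molar_conductivity` (S cm^2/mol, if concentration given).
#' @export
conductivity_fit <- function(fields, J_means, sems = NULL,
                             linear_cutoff = 0.0514, concentration = NULL) {
  stopifnot(length(fields) == length(J_means))
  used <- fields <= linear_cutoff
  if (!any(used)) stop("no field points inside the linear regime")
  x <- fields[used]; y <- J_means[used]
  w <- if (is.null(sems)) rep(1, length(x)) else {
    s <- sems[used]
    if (any(s <= 0)) rep(1, length(x)) else 1 / s^2
  }
  # zero-intercept weighted least squares
  sigma <- sum(w * x * y) / sum(w * x^2)
  resid <- y - sigma * x
  r2 <- if (length(x) > 1 && sum(w * y^2) > 0) {
    1 - sum(w * resid^2) / sum(w * y^2)
  } else 1
  se <- if (length(x) > 1) {
    sqrt(sum(w * resid^2) / ((length(x) - 1) * sum(w * x^2)))
  } else NA_real_
  const <- transport_constants()
  sigma_si <- sigma * const$sigma_to_si
  lam <- if (!is.null(concentration)) {
    molar_conductivity(sigma_si, concentration)
  } else NA_real_
  structure(list(sigma = sigma, sigma_si = sigma_si,
                 sigma_se_si = se * const$sigma_to_si,
                 r_squared = r2, used = used,
                 linear_cutoff = linear_cutoff,
                 fields = fields, J_means = J_means, sems = sems,
                 molar_conductivity = lam),
            class = "conductivity_fit")
}

#' @export
print.conductivity_fit <- function(x, ...) {
  cat(sprintf("conductivity_fit: %d/%d points <= %.4g V/A, sigma = %.4g S/m (R^2 %.3f)\n",
              sum(x$used), length(x$used), x$linear_cutoff, x$sigma_si,
              x$r_squared))
  if (!is.na(x$molar_conductivity)) {
    cat(sprintf("  molar conductivity = %.4g S cm^2/mol\n",
                x$molar_conductivity))
  }
  invisible(x)
}

#' Nominal ion concentration of a periodic cell
#'
#' @param n_ions Number of ions in the cell.
#' @param volume Cell volume (A^3).
#' @return Concentration in mol/L.
#' @export
#' @examples
#' # one ion in the volume of 128 waters at 0.99659 kg/L
#' v <- 128 * 18.01528 / 0.99659 / 6.02214076e23 * 1e24 # A^3
#' concentration_from_box(1, v) # 0.43 M
concentration_from_box <- function(n_ions, volume) {
  stopifnot(volume > 0, n_ions >= 0)
  n_ions / (transport_constants()$avogadro * volume * 1e-27)
}

#' Molar conductivity from conductivity and concentration
#'
#' `Lambda_m = sigma / c`, reported in S cm^2/mol.
#'
#' @param sigma Ionic conductivity (S/m).
#' @param concentration Ion concentration (mol/L).
#' @return Molar conductivity (S cm^2/mol).
#' @export
#' @examples
#' molar_conductivity(1, 1) # 10
molar_conductivity <- function(sigma, concentration) {
  if (concentration <= 0) stop("concentration must be positive")
  # sigma [S/m] -> S/cm: /100; c [mol/L] -> mol/cm^3: *1e-3
  (sigma / 100) / (concentration * 1e-3)
}
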