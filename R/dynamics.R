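# Time-correlation analyses: survival correlation and continuous lifetimes,
# VACF, Green-Kubo diffusion with bootstrap and finite-size extrapolation,
# Nernst-Einstein conversion, VDOS and the cage-rattling period.

#' Continuous survival correlation of first-shell members
#'
#' `C(tau)` is the probability that a ligand counted in the first shell at an
#' origin remains continuously inside the shell cutoff at every intermediate
#' frame up to lag tau. Per origin t0, `S/N` is formed (members surviving over
#' members present) and then averaged over origins; origins are restricted to
#' those with the full `max_lag` window available so that the origin set is
#' identical at every lag, which makes C exactly non-increasing with C(0)=1.
#' No intermittent-return allowance is made (t* = 0): a single frame outside
#' the cutoff terminates a ligand's survival.
#'
#' @param shell A `shell_series` (from [shell_series()] or
#'   [as_shell_series()]).
#' @param max_lag Maximum lag in fs; default half the series length.
#' @return Object of class `survival_result`: `lag` (fs), `C`, `n_origins`,
#'   `dt`.
#' @export
survival_correlation <- function(shell, max_lag = NULL) {
  stopifnot(inherits(shell, "shell_series"))
  n <- length(shell$members)
  if (n < 2) stop("survival correlation needs at least 2 frames")
  dt <- shell$dt
  L <- if (is.null(max_lag)) (n - 1) %/% 2 else {
    stopifnot(max_lag > 0)
    min(n - 1, as.integer(floor(max_lag / dt)))
  }
  if (L < 1) stop("max_lag shorter than one frame")
  n_members <- lengths(shell$members)
  origin_ok <- seq_len(n - L) # origins with a full window
  valid <- origin_ok[n_members[origin_ok] > 0]
  if (length(valid) == 0) {
    stop("shell is empty at every usable origin; survival correlation undefined")
  }
  frames <- rep.int(seq_len(n), n_members)
  ids <- unlist(shell$members, use.names = FALSE)
  if (length(ids) == 0) stop("shell is empty everywhere")
  o <- order(ids, frames)
  ids <- ids[o]; frames <- frames[o]
  new_run <- c(TRUE, ids[-1] != ids[-length(ids)] |
                     diff(frames) != 1L)
  run <- cumsum(new_run)
  run_end <- stats::ave(frames, run, FUN = max)
  rem <- run_end - frames # surviving frames beyond the origin
  sel <- frames <= (n - L) & n_members[frames] > 0
  rem <- pmin(rem[sel], L)
  w <- 1 / n_members[frames[sel]]
  hist_w <- vapply(split(w, rem), sum, 0)
  W <- numeric(L + 1)
  W[as.integer(names(hist_w)) + 1L] <- hist_w
  num <- rev(cumsum(rev(W)))
  C <- num / length(valid)
  structure(list(lag = (0:L) * dt, C = C, n_origins = length(valid), dt = dt),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("survival_result: %d lags up to %g fs, %d origins\n",
              length(x$lag), max(x$lag), x$n_origins))
  invisible(x)
}

#' Continuous lifetime from a survival correlation
#'
#' Trapezoidal integral of C(tau) over the full available lag range.
#'
#' @param surv A `survival_result`.
#' @return Lifetime tau_c in fs.
#' @export
continuous_lifetime <- function(surv) {
  stopifnot(inherits(surv, "survival_result"))
  trapz(surv$lag, surv$C)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# unnormalized multi-origin autocorrelation sum_t x[t] x[t+tau] via FFT
acf_sum_fft <- function(x, max_lag) {
  n <- length(x)
  m <- 2^ceiling(log2(2 * n))
  X <- stats::fft(c(x, rep(0, m - n)))
  s <- Re(stats::fft(X * Conj(X), inverse = TRUE)) / m
  s[seq_len(max_lag + 1)]
}

#' Velocity autocorrelation function
#'
#' Multi-origin average of the dot product of the 3-vector velocity,
#' `VACF(tau) = <v(t0) . v(t0 + tau)>`, computed with FFT-based
#' autocorrelation over all origins.
#'
#' @param v An n x 3 velocity matrix (A/fs), or a [trajectory()] (then `atom`
#'   selects the particle and velocities must be present).
#' @param dt Sample spacing in fs (taken from the trajectory if omitted).
#' @param max_lag Maximum lag (fs); default half the series.
#' @param atom Atom index when `v` is a trajectory.
#' @return Object of class `vacf_result`: `lag` (fs), `vacf` (A^2/fs^2), `dt`.
#' @export
vacf <- function(v, dt = NULL, max_lag = NULL, atom = 1) {
  if (inherits(v, "trajectory")) {
    if (!has_velocities(v)) {
      stop("trajectory carries no velocities; dynamics analyses refuse to run")
    }
    dt <- trajectory_timestep(v)
    v <- t(v$velocities[atom, , ])
  }
  v <- as.matrix(v)
  stopifnot(ncol(v) == 3, !is.null(dt), dt > 0)
  n <- nrow(v)
  L <- if (is.null(max_lag)) (n - 1) %/% 2 else min(n - 1, floor(max_lag / dt))
  s <- acf_sum_fft(v[, 1], L) + acf_sum_fft(v[, 2], L) + acf_sum_fft(v[, 3], L)
  vv <- s / (n - 0:L)
  structure(list(lag = (0:L) * dt, vacf = vv, dt = dt, n = n),
            class = "vacf_result")
}

#' @export
print.vacf_result <- function(x, ...) {
  cat(sprintf("vacf_result: %d lags up to %g fs, VACF(0) = %.4g A^2/fs^2\n",
              length(x$lag), max(x$lag), x$vacf[1]))
  invisible(x)
}

#' Green-Kubo diffusion constant from a VACF
#'
#' `D = 1/3 * integral of VACF(tau) dtau` up to `upper_limit` (trapezoidal),
#' after which the integral is assumed converged.
#'
#' @param vacf_res A `vacf_result`.
#' @param upper_limit Integration limit in fs (default 2500 fs = 2.5 ps).
#' @return Diffusion constant in A^2/fs; attribute `"D_si"` in m^2/s.
#' @export
green_kubo_diffusion <- function(vacf_res, upper_limit = 2500) {
  stopifnot(inherits(vacf_res, "vacf_result"))
  if (max(vacf_res$lag) < upper_limit) {
    stop(sprintf("VACF grid ends at %g fs, short of the %g fs integration limit",
                 max(vacf_res$lag), upper_limit))
  }
  keep <- vacf_res$lag <= upper_limit
  D <- trapz(vacf_res$lag[keep], vacf_res$vacf[keep]) / 3
  attr(D, "D_si") <- D * transport_constants()$D_to_si
  D
}

#' Diffusion constant from the Einstein mean-squared-displacement slope
#'
#' Independent route to D used to cross-check the Green-Kubo estimate:
#' multi-origin MSD computed by the FFT decomposition, then a least-squares
#' slope over the stated lag window gives `D = slope/6`.
#'
#' @param pos n x 3 matrix of unwrapped positions (A).
#' @param dt Sample spacing (fs).
#' @param fit_range Length-2 lag window (fs) for the linear fit; default the
#'   2nd to 10th percent of the series length.
#' @return D in A^2/fs.
#' @export
einstein_msd_diffusion <- function(pos, dt, fit_range = NULL) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  stopifnot(ncol(pos) == 3, n > 10)
  max_lag <- (n - 1) %/% 2
  # MSD(tau) = S1(tau) - 2 S2(tau), per component
  msd <- numeric(max_lag + 1)
  for (k in 1:3) {
    x <- pos[, k]
    s2 <- acf_sum_fft(x, max_lag) / (n - 0:max_lag)
    x2 <- x^2
    css <- cumsum(x2)
    # sum_{t} x_t^2 over valid origins for lag tau, forward + backward
    s1 <- (rev(cumsum(rev(x2)))[1:(max_lag + 1)] +
           css[n:(n - max_lag)]) / (n - 0:max_lag)
    msd <- msd + s1 - 2 * s2
  }
  lag <- (0:max_lag) * dt
  if (is.null(fit_range)) fit_range <- c(0.02, 0.10) * max(lag)
  keep <- lag >= fit_range[1] & lag <= fit_range[2]
  if (sum(keep) < 2) stop("fit_range selects fewer than 2 MSD points")
  fit <- stats::lm(msd[keep] ~ lag[keep])
  unname(stats::coef(fit)[2]) / 6
}

#' Bootstrap mean and SD of segment diffusion estimates
#'
#' Draws `n_resamples` resamples (with replacement, same size as the input)
#' of the per-segment estimates and returns the mean and SD of the resampled
#' means.
#'
#' @param estimates Numeric vector of per-segment D estimates (>= 2).
#' @param n_resamples Number of bootstrap resamples (default 10000).
#' @param seed Optional seed for reproducibility.
#' @return List with `mean`, `sd`, `n_resamples`.
#' @export
bootstrap_diffusion <- function(estimates, n_resamples = 10000, seed = NULL) {
  stopifnot(length(estimates) >= 2, all(is.finite(estimates)))
  if (!is.null(seed)) set.seed(seed)
  n <- length(estimates)
  means <- vapply(seq_len(n_resamples), function(i) {
    mean(estimates[sample.int(n, n, replace = TRUE)])
  }, 0)
  list(mean = mean(means), sd = stats::sd(means), n_resamples = n_resamples)
}

#' Finite-size extrapolation of diffusion constants
#'
#' Weighted linear fit of per-box-size diffusion constants against 1/L
#' (weights 1/SD^2); the intercept estimates the infinite-dilution diffusion
#' constant D_inf.
#'
#' @param L Box edge lengths (A).
#' @param D Diffusion constants per box.
#' @param SD Their uncertainties; default equal weights.
#' @return List with `D_inf`, `D_inf_se`, `slope`, `fit` (the lm object).
#' @export
finite_size_extrapolation <- function(L, D, SD = NULL) {
  stopifnot(length(L) == length(D), length(L) >= 2)
  if (length(unique(L)) < 2) stop("all box sizes equal; fit is singular")
  w <- if (is.null(SD)) rep(1, length(L)) else 1 / SD^2
  x <- 1 / L
  fit <- stats::lm(D ~ x, weights = w)
  co <- summary(fit)$coefficients
  list(D_inf = unname(co[1, 1]),
       D_inf_se = if (length(L) > 2) unname(co[1, 2]) else NA_real_,
       slope = unname(co[2, 1]), fit = fit)
}

#' Molar conductivity by the Nernst-Einstein relation
#'
#' `Lambda_m = F^2 D_inf / (R T)`, neglecting ion-ion correlations.
#'
#' @param D_inf Diffusion constant.
#' @param temperature Temperature (K), default 300.
#' @param unit Unit of `D_inf`: `"A2fs"` (internal, default) or `"m2s"`.
#' @return Molar conductivity in S cm^2/mol.
#' @export
#' @examples
#' nernst_einstein(1e-9, unit = "m2s") # 37.32
nernst_einstein <- function(D_inf, temperature = 300,
                            unit = c("A2fs", "m2s")) {
  unit <- match.arg(unit)
  stopifnot(D_inf >= 0, temperature > 0)
  const <- transport_constants()
  D_si <- if (unit == "A2fs") D_inf * const$D_to_si else D_inf
  lambda_si <- const$faraday^2 * D_si / (const$gas_R * temperature) # S m^2/mol
  lambda_si * 1e4 # S cm^2/mol
}

#' Velocity density of states with block averaging
#'
#' Splits the velocity series into each requested number of blocks
#' (truncating the remainder), computes a Hann-windowed VACF spectrum per
#' block, and averages within each block count. Comparing the detected peak
#' across block counts shows whether it is an artifact of the blocking.
#'
#' @param v n x 3 velocity matrix (A/fs) or a [trajectory()] (+ `atom`).
#' @param dt Sample spacing (fs); from the trajectory if omitted.
#' @param block_counts Numbers of blocks (default c(24, 48, 96, 192, 384)).
#' @param atom Atom index when `v` is a trajectory.
#' @return Object of class `vdos_result`: `spectra` (per block count: `freq`
#'   in fs^-1, `wavenumber` in cm^-1, `intensity`), `reference` (index of the
#'   block count used by [rattling_period()], the largest), `block_counts`.
#' @export
vdos <- function(v, dt = NULL, block_counts = c(24, 48, 96, 192, 384),
                 atom = 1) {
  if (inherits(v, "trajectory")) {
    if (!has_velocities(v)) stop("trajectory carries no velocities")
    dt <- trajectory_timestep(v)
    v <- t(v$velocities[atom, , ])
  }
  v <- as.matrix(v)
  stopifnot(ncol(v) == 3, !is.null(dt), dt > 0)
  n <- nrow(v)
  const <- transport_constants()
  spectra <- vector("list", length(block_counts))
  for (bi in seq_along(block_counts)) {
    B <- block_counts[bi]
    Lb <- n %/% B
    if (Lb < 2) stop(sprintf("%d blocks leave fewer than 2 frames per block", B))
    nf <- Lb %/% 2 + 1
    acc <- numeric(nf)
    win <- 0.5 * (1 - cos(2 * pi * (0:(Lb - 1)) / (Lb - 1))) # Hann
    wnorm <- sum(win^2)
    for (b in seq_len(B)) {
      rows <- ((b - 1) * Lb + 1):(b * Lb)
      # Hann-windowed periodogram summed over components (Wiener-Khinchin
      # pair of the block VACF; manifestly non-negative)
      sp <- numeric(nf)
      for (k in 1:3) {
        sp <- sp + Mod(stats::fft(v[rows, k] * win))[seq_len(nf)]^2
      }
      acc <- acc + sp / wnorm
    }
    freq <- (seq_len(nf) - 1) / (Lb * dt)
    spectra[[bi]] <- list(blocks = B, freq = freq,
                          wavenumber = freq / const$c_cm_fs,
                          intensity = acc / B)
  }
  structure(list(spectra = spectra, block_counts = block_counts,
                 reference = which.max(block_counts), dt = dt),
            class = "vdos_result")
}

#' @export
print.vdos_result <- function(x, ...) {
  cat(sprintf("vdos_result: block counts {%s}, dt %g fs\n",
              paste(x$block_counts, collapse = ", "), x$dt))
  invisible(x)
}

lowest_interior_peak <- function(freq, intensity, min_prominence = 0.2) {
  # zero-frequency bin excluded (drift/diffusion contaminates nu = 0).
  # Residual block-averaged noise still leaves spurious local maxima, so the
  # spectrum is lightly smoothed and a peak must rise above its surrounding
  # minima by min_prominence of the spectral range to count.
  n <- length(intensity)
  if (n < 5) return(NA_real_)
  w <- min(11, if (n %/% 5 %% 2 == 1) n %/% 5 else n %/% 5 + 1)
  s <- if (w >= 5 && n > w) signal::sgolayfilt(intensity, p = 2, n = w)
       else intensity
  ref <- max(s[-1])
  med <- stats::median(s[-1])
  if (ref <= 0) return(NA_real_)
  for (i in 3:(n - 1)) {
    if (s[i] >= s[i - 1] && s[i] >= s[i + 1]) {
      left_min <- min(s[2:(i - 1)])
      right_min <- if (i + 1 <= n) min(s[(i + 1):min(n, i + max(3, n %/% 5))])
                   else s[n]
      prom <- s[i] - max(left_min, right_min)
      # a genuine cage peak must also stand clear of the typical spectral
      # level; near-flat (free-particle or white) spectra are rejected
      if (prom >= min_prominence * ref && s[i] >= 1.5 * med) return(freq[i])
    }
  }
  NA_real_
}

#' Rattling period of the ion in its solvent cage
#'
#' The rattling frequency is the lowest-frequency interior local maximum of
#' the VDOS (the zero-frequency bin is excluded); its reciprocal is the
#' rattling period, used as the minimum lifetime for an n-fold coordination
#' state to count as stable.
#'
#' @param vdos_res A `vdos_result`.
#' @param which_blocks Index into `vdos_res$spectra` (default the reference,
#'   i.e. the most-averaged spectrum).
#' @return List with `freq` (fs^-1), `wavenumber` (cm^-1), `period` (fs), and
#'   `peak_by_blocks` (detected peak per block count, the stability report).
#' @export
rattling_period <- function(vdos_res, which_blocks = NULL) {
  stopifnot(inherits(vdos_res, "vdos_result"))
  if (is.null(which_blocks)) which_blocks <- vdos_res$reference
  peaks <- vapply(vdos_res$spectra, function(s) {
    lowest_interior_peak(s$freq, s$intensity)
  }, 0)
  nu <- peaks[which_blocks]
  if (is.na(nu) || nu <= 0) {
    stop(paste("VDOS is monotone from zero: no caged rattling motion found;",
               "supply a manual period"))
  }
  list(freq = nu, wavenumber = nu / transport_constants()$c_cm_fs,
       period = 1 / nu,
       peak_by_blocks = stats::setNames(peaks,
                                        paste0("blocks_",
                                               vdos_res$block_counts)))
}
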