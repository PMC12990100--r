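#' Ion-solvent radial distribution function
#'
#' Pair distribution of one central atom (the ion) against partner atoms,
#' averaged over frames, with standard shell-volume x partner-density
#' normalization and the running coordination number obtained by integrating
#' the same binned counts.
#'
#' @param traj A [trajectory()].
#' @param center Index of the central atom (default 1, the ion).
#' @param partner Species label(s) selecting partner atoms, or NULL for all
#'   atoms except the center.
#' @param bin_width Bin width in A (default 0.03).
#' @param r_max Maximum radius (default half the box).
#' @param discard Equilibration time (fs) dropped from the start.
#' @return Object of class `rdf_result`: `r` (bin centers), `g`, `running_cn`,
#'   `rho` (partner number density, 1/A^3), `counts`, `n_frames`, and `R0`
#'   (NA until [detect_first_minimum()] assigns it).
#' @export
compute_rdf <- function(traj, center = 1, partner = NULL, bin_width = 0.03,
                        r_max = NULL, discard = 0) {
  stopifnot(inherits(traj, "trajectory"), bin_width > 0)
  if (is.null(r_max)) r_max <- traj$box / 2
  idx <- if (is.null(partner)) setdiff(seq_len(traj$n_atoms), center)
         else which(traj$species %in% partner & seq_len(traj$n_atoms) != center)
  if (length(idx) == 0) stop("empty partner selection")
  keep <- which(traj$times - traj$times[1] >= discard)
  if (length(keep) == 0) stop("discard removes every frame")
  edges <- seq(0, r_max + bin_width, by = bin_width)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  for (k in keep) {
    d <- minimum_image_distance(
      matrix(traj$positions[center, , k], length(idx), 3, byrow = TRUE),
      traj$positions[idx, , k, drop = TRUE], traj$box)
    h <- findInterval(d[d < edges[nb + 1]], edges, rightmost.closed = TRUE)
    counts <- counts + tabulate(h, nbins = nb)
  }
  nf <- length(keep)
  r_mid <- edges[-1] - bin_width / 2
  rho <- length(idx) / traj$box^3
  shell_vol <- 4 * pi * r_mid^2 * bin_width
  g <- counts / (nf * rho * shell_vol)
  running_cn <- cumsum(counts) / nf
  structure(list(r = r_mid, g = g, running_cn = running_cn, rho = rho,
                 counts = counts, n_frames = nf, bin_width = bin_width,
                 R0 = NA_real_),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  ip <- which.max(x$g)
  cat(sprintf("rdf_result: %d bins of %.3g A, %d frames\n",
              length(x$r), x$bin_width, x$n_frames))
  cat(sprintf("  g(r) peak %.3g at r = %.3g A; R0 = %s\n", x$g[ip], x$r[ip],
              if (is.na(x$R0)) "undetected" else sprintf("%.3g A", x$R0)))
  invisible(x)
}

#' First-shell radius from the first RDF minimum
#'
#' Smooths g(r) with a Savitzky-Golay local polynomial filter (the raw-bin
#' argmin is noise-dominated when the minimum flattens, as for weakly bound
#' shells), then returns the abscissa of the first local minimum after the
#' first peak, searching up to 1.8x the peak position. The zero-field R0 is
#' conventionally reused at all field strengths.
#'
#' @param rdf An `rdf_result` from [compute_rdf()].
#' @param window Savitzky-Golay window in bins (odd, default 11).
#' @param order Polynomial order (default 3).
#' @return The input `rdf_result` with `R0` set; `attr(, "R0")` also holds it.
#' @export
detect_first_minimum <- function(rdf, window = 11, order = 3) {
  stopifnot(inherits(rdf, "rdf_result"))
  g <- rdf$g
  gs <- if (length(g) > window) {
    signal::sgolayfilt(g, p = order, n = window)
  } else g
  ip <- which.max(gs)
  if (ip <= 1 || ip >= length(gs)) {
    stop("no RDF peak found; cannot detect a first minimum")
  }
  hi <- max(which(rdf$r <= 1.8 * rdf$r[ip]))
  found <- NA_integer_
  for (i in seq(ip + 1, hi - 1)) {
    if (i < 2 || i >= length(gs)) break
    if (gs[i] <= gs[i - 1] && gs[i] <= gs[i + 1]) { found <- i; break }
  }
  if (is.na(found)) {
    stop(paste("no first minimum detected after the RDF peak;",
               "the minimum may be too flat - supply a manual cutoff"))
  }
  rdf$R0 <- rdf$r[found]
  rdf
}

#' Smooth coordination number switching function
#'
#' Rational switching function of ion-partner distances:
#' `CN = sum_j (1 - (r_j/R0)^NN) / (1 - (r_j/R0)^ND)`, with the removable
#' singularity at `r_j = R0` evaluated by its limit `NN/ND`. Each term decays
#' monotonically from 1 (r -> 0) through NN/ND (r = R0) to 0 (r >> R0), so
#' the sum is a differentiable count of first-shell partners.
#'
#' @param distances Numeric vector of distances r_j >= 0 (A).
#' @param R0 First-shell radius (A).
#' @param NN,ND Switching exponents (defaults 20 and 40).
#' @return Scalar smooth coordination number.
#' @export
#' @examples
#' smooth_cn(1.0, R0 = 1.0) # 0.5
smooth_cn <- function(distances, R0, NN = 20, ND = 40) {
  stopifnot(all(distances >= 0), R0 > 0, NN > 0, ND > NN)
  x <- distances / R0
  term <- ifelse(abs(x - 1) < 1e-9, NN / ND,
                 (1 - x^NN) / (1 - x^ND))
  # guard overflow at large x: limit is 0
  term[!is.finite(term)] <- 0
  sum(term)
}

#' Per-frame first-shell membership series
#'
#' For every retained frame, identifies the partner atoms strictly inside the
#' first-shell radius R0 (ties at exactly R0 are excluded), and records the
#' integer coordination number together with the smooth coordination number
#' over all partners.
#'
#' @param traj A [trajectory()].
#' @param R0 First-shell radius (A), e.g. from [detect_first_minimum()].
#' @param center Central atom index (default 1).
#' @param partner Species selection as in [compute_rdf()].
#' @param discard Equilibration time (fs) dropped from the start.
#' @param NN,ND Smooth-CN exponents.
#' @return Object of class `shell_series`: `members` (list of partner indices
#'   per frame), `cn`, `smooth_cn`, `times`, `dt`, `R0`.
#' @export
shell_series <- function(traj, R0, center = 1, partner = NULL, discard = 0,
                         NN = 20, ND = 40) {
  stopifnot(inherits(traj, "trajectory"), R0 > 0)
  idx <- if (is.null(partner)) setdiff(seq_len(traj$n_atoms), center)
         else which(traj$species %in% partner & seq_len(traj$n_atoms) != center)
  if (length(idx) == 0) stop("empty partner selection")
  keep <- which(traj$times - traj$times[1] >= discard)
  members <- vector("list", length(keep))
  cn <- integer(length(keep))
  scn <- numeric(length(keep))
  for (j in seq_along(keep)) {
    k <- keep[j]
    d <- minimum_image_distance(
      matrix(traj$positions[center, , k], length(idx), 3, byrow = TRUE),
      traj$positions[idx, , k, drop = TRUE], traj$box)
    inside <- idx[d < R0]
    members[[j]] <- inside
    cn[j] <- length(inside)
    scn[j] <- smooth_cn(d, R0, NN, ND)
  }
  times <- traj$times[keep]
  structure(list(members = members, cn = cn, smooth_cn = scn,
                 times = times,
                 dt = if (length(times) > 1) diff(times)[1] else NA_real_,
                 R0 = R0, NN = NN, ND = ND),
            class = "shell_series")
}

#' @export
print.shell_series <- function(x, ...) {
  cat(sprintf("shell_series: %d frames, R0 = %.3g A, mean CN %.3g (smooth %.3g)\n",
              length(x$cn), x$R0, mean(x$cn), mean(x$smooth_cn)))
  invisible(x)
}

#' Potential of mean force along the coordination number
#'
#' `PMF(CN) = -kB T ln p(CN) + const`, with the additive constant fixed by
#' the convention min(PMF) = 0 and empty bins reported as NA (undefined), not
#' zero.
#'
#' @param cn Numeric vector of (smooth) coordination numbers.
#' @param temperature Temperature (K).
#' @param bin_width Histogram bin width in CN units (default 0.1).
#' @param units `"kBT"` (default) or `"eV"`.
#' @return Object of class `pmf_result`: `cn` (bin centers), `pmf`, `p`,
#'   `counts`, `temperature`, `units`.
#' @export
pmf_from_cn <- function(cn, temperature = 300, bin_width = 0.1,
                        units = c("kBT", "eV")) {
  units <- match.arg(units)
  stopifnot(length(cn) >= 1, all(is.finite(cn)), bin_width > 0)
  if (length(cn) < 100) {
    warning("fewer than 100 samples; the PMF will be poorly resolved")
  }
  if (diff(range(cn)) < .Machine$double.eps) {
    warning("all samples identical; returning a single-point PMF")
    return(structure(list(cn = cn[1], pmf = 0, p = 1, counts = length(cn),
                          temperature = temperature, units = units,
                          bin_width = bin_width), class = "pmf_result"))
  }
  edges <- seq(floor(min(cn) / bin_width) * bin_width,
               max(cn) + bin_width, by = bin_width)
  h <- findInterval(cn, edges, rightmost.closed = TRUE)
  counts <- tabulate(h, nbins = length(edges) - 1)
  p <- counts / sum(counts)
  pmf <- ifelse(p > 0, -log(p), NA_real_)
  pmf <- pmf - min(pmf, na.rm = TRUE)
  if (units == "eV") pmf <- pmf * transport_constants()$kB * temperature
  structure(list(cn = edges[-1] - bin_width / 2, pmf = pmf, p = p,
                 counts = counts, temperature = temperature, units = units,
                 bin_width = bin_width),
            class = "pmf_result")
}

#' @export
print.pmf_result <- function(x, ...) {
  im <- which.min(x$pmf)
  cat(sprintf("pmf_result: %d bins of %.3g CN, minimum at CN = %.3g (%s units)\n",
              length(x$cn), x$bin_width, x$cn[im], x$units))
  invisible(x)
}

#' Histogram of integer coordination numbers
#'
#' @param shell A `shell_series`.
#' @return Named integer vector of counts per observed CN (contiguous range);
#'   counts sum to the frame count. An empty series gives an empty histogram.
#' @export
integer_cn_histogram <- function(shell) {
  stopifnot(inherits(shell, "shell_series"))
  if (length(shell$cn) == 0) return(integer(0))
  rng <- range(shell$cn)
  counts <- tabulate(shell$cn - rng[1] + 1L, nbins = rng[2] - rng[1] + 1L)
  names(counts) <- seq(rng[1], rng[2])
  counts
}

#' Joint density of shell-member direction and dipole tilt cosines
#'
#' For every first-shell member in every frame, accumulates the pair
#' (cos alpha, cos theta): alpha is the angle between the vector pointing
#' from the shell partner to the ion and the field direction, theta the tilt
#' angle of the partner's dipole with respect to the field. Members with
#' cos(alpha) < 0 lead the migrating ion, cos(alpha) > 0 trail it. The
#' density is conditional on first-shell membership and normalized to
#' integrate to 1 over \[-1, 1\]^2.
#'
#' @param traj A [trajectory()] with dipole orientations.
#' @param shell A `shell_series` computed from the same frames.
#' @param field_direction Length-3 reference direction; defaults to the
#'   trajectory's field metadata. Required (as an arbitrary axis) at zero
#'   field.
#' @param nbins Bins per axis (default 40).
#' @param center Ion atom index.
#' @return Object of class `tilt_density`: `density` (nbins x nbins,
#'   cos alpha by cos theta), `breaks`, `n_samples`, `mean_cos_theta_leading`,
#'   `mean_cos_theta_trailing`, `correlation`.
#' @export
tilt_angle_density <- function(traj, shell, field_direction = NULL,
                               nbins = 40, center = 1) {
  stopifnot(inherits(traj, "trajectory"), inherits(shell, "shell_series"))
  if (is.null(traj$dipoles)) stop("trajectory has no dipole orientations")
  if (is.null(field_direction)) {
    if (is.null(traj$fields) || sqrt(sum(traj$fields[, 1]^2)) == 0) {
      stop("zero or absent field: supply a reference field_direction")
    }
    field_direction <- traj$fields[, 1]
  }
  e_hat <- field_direction / sqrt(sum(field_direction^2))
  frame_of <- match(round(shell$times, 6), round(traj$times, 6))
  if (anyNA(frame_of)) stop("shell series times not aligned with trajectory")
  ca <- numeric(0); ct <- numeric(0)
  for (j in seq_along(shell$members)) {
    mem <- shell$members[[j]]
    if (length(mem) == 0) next
    k <- frame_of[j]
    rvec <- minimum_image_displacement(
      traj$positions[mem, , k, drop = TRUE],
      matrix(traj$positions[center, , k], length(mem), 3, byrow = TRUE),
      traj$box) # partner -> ion
    rvec <- rvec / sqrt(rowSums(rvec^2))
    ca <- c(ca, as.vector(rvec %*% e_hat))
    dip <- matrix(traj$dipoles[mem, , k], length(mem), 3)
    ct <- c(ct, as.vector(dip %*% e_hat))
  }
  if (length(ca) == 0) stop("no first-shell occupancy anywhere in the series")
  breaks <- seq(-1, 1, length.out = nbins + 1)
  ia <- findInterval(ca, breaks, rightmost.closed = TRUE)
  it <- findInterval(ct, breaks, rightmost.closed = TRUE)
  dens <- matrix(0, nbins, nbins)
  for (s in seq_along(ia)) dens[ia[s], it[s]] <- dens[ia[s], it[s]] + 1
  cell <- (2 / nbins)^2
  dens <- dens / (sum(dens) * cell)
  structure(list(density = dens, breaks = breaks, n_samples = length(ca),
                 mean_cos_theta_leading = mean(ct[ca < 0]),
                 mean_cos_theta_trailing = mean(ct[ca > 0]),
                 mean_cos_theta = mean(ct),
                 correlation = stats::cor(ca, ct),
                 cos_alpha = ca, cos_theta = ct),
            class = "tilt_density")
}

#' @export
print.tilt_density <- function(x, ...) {
  cat(sprintf("tilt_density: %d samples, corr(cos a, cos t) = %.3f\n",
              x$n_samples, x$correlation))
  cat(sprintf("  mean cos(theta): leading %.3f (%.1f deg), trailing %.3f (%.1f deg)\n",
              x$mean_cos_theta_leading,
              cos_to_degrees(x$mean_cos_theta_leading),
              x$mean_cos_theta_trailing,
              cos_to_degrees(x$mean_cos_theta_trailing)))
  invisible(x)
}
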