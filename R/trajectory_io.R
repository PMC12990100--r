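#' Trajectory container
#'
#' Time-ordered atomic configurations in a cubic periodic box. Positions are
#' stored unwrapped (continuous across box boundaries) so that displacements
#' and velocities stay consistent for diffusion analyses; periodic wrapping is
#' applied on demand by the geometry helpers.
#'
#' @param positions Array `c(n_atoms, 3, n_frames)`, Angstrom.
#' @param species Character vector of length n_atoms.
#' @param box Cubic box edge length, Angstrom.
#' @param times Frame times in fs (strictly increasing, uniform spacing).
#' @param velocities Optional array like `positions`, A/fs.
#' @param dipoles Optional array like `positions` of unit dipole orientation
#'   vectors (rows for atoms without a dipole may be NA).
#' @param fields Optional `3 x n_frames` matrix of applied field vectors (V/A),
#'   or a single length-3 vector recycled to all frames.
#' @param metadata Optional named list (source, seed, protocol reference ...).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(positions, species, box, times,
                       velocities = NULL, dipoles = NULL, fields = NULL,
                       metadata = list()) {
  stopifnot(is.array(positions), length(dim(positions)) == 3,
            dim(positions)[2] == 3)
  n_atoms <- dim(positions)[1]
  n_frames <- dim(positions)[3]
  stopifnot(length(species) == n_atoms, box > 0,
            length(times) == n_frames)
  if (n_frames > 1) {
    dtv <- diff(times)
    if (any(dtv <= 0)) stop("frame times must be strictly increasing")
    if (max(dtv) - min(dtv) > 1e-6 * max(dtv)) {
      stop("trajectory requires a uniform timestep")
    }
  }
  if (!is.null(velocities)) {
    stopifnot(identical(dim(velocities), dim(positions)))
  }
  if (!is.null(dipoles)) {
    stopifnot(identical(dim(dipoles), dim(positions)))
    nrm <- sqrt(colSums(aperm(dipoles, c(2, 1, 3))^2))
    ok <- is.na(nrm) | abs(nrm - 1) < 1e-8
    if (!all(ok)) stop("dipole orientation vectors must be unit-norm")
  }
  if (!is.null(fields)) {
    if (is.vector(fields) && length(fields) == 3) {
      fields <- matrix(fields, 3, n_frames)
    }
    stopifnot(nrow(fields) == 3, ncol(fields) == n_frames)
  }
  structure(list(positions = positions, species = species, box = box,
                 times = times, velocities = velocities, dipoles = dipoles,
                 fields = fields, metadata = metadata,
                 n_atoms = n_atoms, n_frames = n_frames),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  dt <- if (x$n_frames > 1) diff(x$times)[1] else NA_real_
  cat(sprintf("trajectory: %d frames x %d atoms, box %.3f A, dt %.4g fs\n",
              x$n_frames, x$n_atoms, x$box, dt))
  cat(sprintf("  species: %s\n",
              paste(sprintf("%s(%d)", names(table(x$species)),
                            table(x$species)), collapse = " ")))
  cat(sprintf("  velocities: %s, dipoles: %s, field metadata: %s\n",
              !is.null(x$velocities), !is.null(x$dipoles),
              !is.null(x$fields)))
  invisible(x)
}

#' Timestep of a trajectory
#' @param traj A [trajectory()].
#' @return Frame spacing in fs.
#' @export
trajectory_timestep <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$n_frames < 2) stop("timestep undefined for a single frame")
  diff(traj$times)[1]
}

#' Whether dynamics analyses may run on a trajectory
#'
#' Dynamics analyses (VACF, current density, Green-Kubo) require velocities;
#' trajectories read from files without velocity columns are flagged.
#'
#' @param traj A [trajectory()].
#' @return Logical.
#' @export
has_velocities <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  !is.null(traj$velocities)
}

#' Minimum-image distances and displacements in a cubic box
#'
#' `minimum_image_displacement()` returns the shortest displacement vector(s)
#' b - a under periodic images; `minimum_image_distance()` its norm.
#'
#' @param a,b Length-3 vectors or n x 3 matrices of positions (A).
#' @param box Cubic box edge length (A).
#' @return Displacement matrix (n x 3) or distance vector.
#' @export
#' @examples
#' minimum_image_distance(c(1, 0, 0), c(9, 0, 0), 10) # 2
minimum_image_displacement <- function(a, b, box) {
  stopifnot(box > 0)
  if (is.vector(a)) a <- matrix(a, ncol = 3)
  if (is.vector(b)) b <- matrix(b, ncol = 3)
  d <- b - a
  d - box * round(d / box)
}

#' @rdname minimum_image_displacement
#' @export
minimum_image_distance <- function(a, b, box) {
  d <- minimum_image_displacement(a, b, box)
  sqrt(rowSums(d^2))
}

fmt_num <- function(x) sprintf("%.10g", x)

#' Write a trajectory as extended XYZ
#'
#' Dialect: the comment line carries `key=value` pairs `Lattice="..."`,
#' `Time=...` (fs), `Field="ex ey ez"` (V/A) and `Properties=...`; per-atom
#' columns are species, position, then velocity and dipole orientation when
#' present. All numerics use 10 significant digits.
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  has_v <- !is.null(traj$velocities)
  has_d <- !is.null(traj$dipoles)
  props <- "species:S:1:pos:R:3"
  if (has_v) props <- paste0(props, ":vel:R:3")
  if (has_d) props <- paste0(props, ":dipole:R:3")
  for (k in seq_len(traj$n_frames)) {
    writeLines(as.character(traj$n_atoms), con)
    lat <- sprintf('Lattice="%s 0 0 0 %s 0 0 0 %s"',
                   fmt_num(traj$box), fmt_num(traj$box), fmt_num(traj$box))
    comment <- sprintf('%s Properties=%s Time=%s', lat, props,
                       fmt_num(traj$times[k]))
    if (!is.null(traj$fields)) {
      comment <- sprintf('%s Field="%s %s %s"', comment,
                         fmt_num(traj$fields[1, k]), fmt_num(traj$fields[2, k]),
                         fmt_num(traj$fields[3, k]))
    }
    writeLines(comment, con)
    dip_k <- if (has_d) {
      d <- traj$dipoles[, , k]
      d[!is.finite(d)] <- 0 # atoms without a dipole: zero vector on disk
      d
    }
    block <- cbind(traj$positions[, , k],
                   if (has_v) traj$velocities[, , k],
                   dip_k)
    lines <- paste(traj$species,
                   apply(block, 1, function(r) paste(fmt_num(r),
                                                     collapse = " ")))
    writeLines(lines, con)
  }
  invisible(path)
}

parse_kv_comment <- function(line) {
  # key=value pairs; values may be double-quoted strings with spaces
  out <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|\\S+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  for (i in seq_along(m)) {
    tok <- substr(line, m[i], m[i] + attr(m, "match.length")[i] - 1)
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1, eq - 1)
    val <- substr(tok, eq + 1, nchar(tok))
    out[[key]] <- gsub('^"|"$', "", val)
  }
  out
}

#' Read an extended-XYZ trajectory
#'
#' Counterpart of [write_xyz()]. Frames must share one atom count and species
#' ordering; the comment line must provide a cubic `Lattice`. Missing velocity
#' columns are tolerated and flagged via [has_velocities()].
#'
#' @param path Input file.
#' @return A [trajectory()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  pos_list <- list(); vel_list <- list(); dip_list <- list()
  times <- c(); fields <- NULL; field_list <- list()
  species <- NULL; box <- NULL
  i <- 1; k <- 0
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i])) {
      stop(sprintf("malformed frame header at line %d: expected atom count", i))
    }
    n <- as.integer(lines[i])
    k <- k + 1
    kv <- parse_kv_comment(lines[i + 1])
    if (is.null(kv$Lattice)) {
      stop(sprintf("malformed comment at line %d: missing Lattice", i + 1))
    }
    lat <- as.numeric(strsplit(trimws(kv$Lattice), "\\s+")[[1]])
    bk <- lat[1]
    if (!isTRUE(all.equal(lat, c(bk, 0, 0, 0, bk, 0, 0, 0, bk)))) {
      stop("only cubic lattices are supported")
    }
    if (is.null(box)) box <- bk
    times <- c(times, if (!is.null(kv$Time)) as.numeric(kv$Time) else k - 1)
    if (!is.null(kv$Field)) {
      field_list[[k]] <- as.numeric(strsplit(trimws(kv$Field), "\\s+")[[1]])
    }
    body <- lines[(i + 2):(i + 1 + n)]
    toks <- strsplit(trimws(body), "\\s+")
    ncols <- unique(lengths(toks))
    if (length(ncols) != 1) {
      stop(sprintf("ragged atom lines in frame %d", k))
    }
    sp <- vapply(toks, `[[`, "", 1)
    if (is.null(species)) {
      species <- sp
    } else if (length(sp) != length(species) || any(sp != species)) {
      stop(sprintf("inconsistent atom count or species ordering in frame %d",
                   k))
    }
    num <- matrix(as.numeric(unlist(lapply(toks, `[`, -1))),
                  nrow = n, byrow = TRUE)
    pos_list[[k]] <- num[, 1:3, drop = FALSE]
    if (ncols >= 7) vel_list[[k]] <- num[, 4:6, drop = FALSE]
    if (ncols >= 10) dip_list[[k]] <- num[, 7:9, drop = FALSE]
    i <- i + 2 + n
  }
  n_atoms <- length(species)
  stack <- function(lst) {
    if (length(lst) < k || is.null(lst[[1]])) return(NULL)
    array(unlist(lst), c(n_atoms, 3, k))
  }
  dip_arr <- stack(dip_list)
  if (!is.null(dip_arr)) {
    # zero vectors on disk mean "no dipole": restore NA
    for (kk in seq_len(k)) {
      zero <- rowSums(dip_arr[, , kk, drop = FALSE]^2) == 0
      if (any(zero)) dip_arr[zero, , kk] <- NA_real_
    }
  }
  fields <- if (length(field_list) == k) {
    matrix(unlist(field_list), nrow = 3)
  } else NULL
  trajectory(stack(pos_list), species, box, times,
             velocities = stack(vel_list), dipoles = dip_arr,
             fields = fields, metadata = list(source = path))
}

#' Write an APT table
#'
#' Plain-text format: a header line `# q_tot=<charge> n=<atoms>`, then one row
#' per atom: index, species label, and the 9 tensor components row-major
#' (P_xx P_xy P_xz P_yx ... P_zz).
#'
#' @param apts An [apt_set].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_apt_table <- function(apts, path) {
  stopifnot(inherits(apts, "apt_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# q_tot=%s n=%d", fmt_num(apts$q_tot), apts$n), con)
  sp <- if (is.null(apts$species)) rep("X", apts$n) else apts$species
  for (i in seq_len(apts$n)) {
    comps <- as.vector(t(apts$tensors[i, , ])) # row-major
    writeLines(paste(i, sp[i], paste(fmt_num(comps), collapse = " ")), con)
  }
  invisible(path)
}

#' Read an APT table
#'
#' Reads the format written by [write_apt_table()], applies the acoustic
#' sum-rule correction once at load time, and records the pre-correction
#' deviation in the returned object's `"deviation"` attribute (the load
#' report).
#'
#' @param path Input file.
#' @param correct Apply [apply_sum_rule()] (default TRUE).
#' @return An [apt_set]; attribute `"deviation"` holds the raw 3x3 deviation.
#' @export
read_apt_table <- function(path, correct = TRUE) {
  lines <- readLines(path)
  hdr <- lines[1]
  if (!grepl("^#", hdr)) stop("APT table must start with a '# q_tot=...' header")
  kv <- parse_kv_comment(sub("^#\\s*", "", hdr))
  if (is.null(kv$q_tot)) stop("APT table header missing q_tot")
  q_tot <- as.numeric(kv$q_tot)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  toks <- strsplit(trimws(body), "\\s+")
  if (any(lengths(toks) != 11)) {
    bad <- which(lengths(toks) != 11)[1]
    stop(sprintf(
      "APT table row %d has %d fields; expected index, species, 9 components",
      bad, lengths(toks)[bad]))
  }
  n <- length(toks)
  tensors <- array(0, c(n, 3, 3))
  species <- character(n)
  for (i in seq_len(n)) {
    species[i] <- toks[[i]][2]
    tensors[i, , ] <- matrix(as.numeric(toks[[i]][3:11]), 3, 3, byrow = TRUE)
  }
  raw <- apt_set(tensors, q_tot = q_tot, species = species)
  dev <- sum_rule_deviation(raw)
  out <- if (correct) apply_sum_rule(raw) else raw
  attr(out, "deviation") <- dev
  out
}
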