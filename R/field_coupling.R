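#' Atomic polar tensor set
#'
#' Container for per-atom atomic polar tensors (APTs). The APT of atom i is
#' the derivative of the system dipole moment with respect to the atom's
#' position, equivalently the derivative of the force on the atom with respect
#' to a homogeneous external electric field. Its components are dimensionless
#' (units of elementary charge e); one third of the trace is the atom's Born
#' effective charge.
#'
#' @param tensors A numeric array of dimension `c(n, 3, 3)` (atom, row eta,
#'   column zeta), or a list of n 3x3 matrices.
#' @param q_tot Total system charge in e (default +1, a single-cation system).
#' @param species Optional character vector of species labels, length n.
#' @return An object of class `apt_set`: list with elements `tensors`
#'   (n x 3 x 3 array), `q_tot`, `species`, `n`.
#' @export
#' @examples
#' a <- apt_set(list(diag(3)), q_tot = 1)
#' born_charges(a)
apt_set <- function(tensors, q_tot = 1, species = NULL) {
  if (is.list(tensors)) {
    n <- length(tensors)
    arr <- array(0, c(n, 3, 3))
    for (i in seq_len(n)) {
      ti <- as.matrix(tensors[[i]])
      stopifnot(identical(dim(ti), c(3L, 3L)))
      arr[i, , ] <- ti
    }
    tensors <- arr
  }
  stopifnot(is.array(tensors), length(dim(tensors)) == 3,
            dim(tensors)[2] == 3, dim(tensors)[3] == 3)
  n <- dim(tensors)[1]
  if (n < 1) stop("empty system: an apt_set needs at least one atom")
  if (!all(is.finite(tensors))) stop("non-finite APT components")
  if (!is.null(species)) stopifnot(length(species) == n)
  structure(list(tensors = tensors, q_tot = q_tot, species = species, n = n),
            class = "apt_set")
}

#' @export
print.apt_set <- function(x, ...) {
  dev <- sum_rule_deviation(x)
  cat(sprintf("apt_set: %d atoms, q_tot = %+g e\n", x$n, x$q_tot))
  cat(sprintf("  Born charges: [%.4g, %.4g]\n",
              min(born_charges(x)), max(born_charges(x))))
  cat(sprintf("  max |sum-rule deviation| = %.3g e\n", max(abs(dev))))
  invisible(x)
}

#' Validate an electric field vector
#'
#' Fields are 3-vectors in V/A. Magnitudes above `max_magnitude` are rejected
#' as unphysical inputs (the perturbative first-order treatment of the field
#' breaks down well below 1 V/A).
#'
#' @param field Numeric length-3 vector, V/A.
#' @param max_magnitude Maximum allowed |field| (default 0.3 V/A).
#' @return The validated field vector, invisibly usable.
#' @export
check_field <- function(field, max_magnitude = 0.3) {
  field <- as.numeric(field)
  stopifnot(length(field) == 3, all(is.finite(field)))
  if (sqrt(sum(field^2)) > max_magnitude) {
    stop(sprintf("field magnitude %.4g V/A exceeds maximum %.4g V/A",
                 sqrt(sum(field^2)), max_magnitude))
  }
  field
}

#' Born effective charges
#'
#' `born_charge()` returns trace/3 of a single 3x3 tensor; `born_charges()`
#' maps over an [apt_set].
#'
#' @param apt A 3x3 numeric matrix.
#' @return Scalar charge in e.
#' @export
#' @examples
#' born_charge(diag(3)) # 1
born_charge <- function(apt) {
  apt <- as.matrix(apt)
  stopifnot(identical(dim(apt), c(3L, 3L)))
  sum(diag(apt)) / 3
}

#' @rdname born_charge
#' @param apts An [apt_set].
#' @export
born_charges <- function(apts) {
  stopifnot(inherits(apts, "apt_set"))
  apply(apts$tensors, 1, function(p) sum(diag(p)) / 3)
}

#' Deviation of an APT set from the acoustic sum rule
#'
#' The acoustic sum rule requires the atom-summed APT to equal the total
#' system charge times the identity. Returns the 3x3 deviation matrix
#' `sum_i P_i - q_tot * I`.
#'
#' @param apts An [apt_set].
#' @return 3x3 deviation matrix (e).
#' @export
sum_rule_deviation <- function(apts) {
  stopifnot(inherits(apts, "apt_set"))
  apply(apts$tensors, c(2, 3), sum) - diag(3) * apts$q_tot
}

#' Enforce the acoustic sum rule on an APT set
#'
#' Any deviation from the sum rule is corrected by subtracting an equal share
#' of the deviation matrix from every atom's tensor, so that the corrected
#' tensors sum exactly to `q_tot * I`. This guarantees that the net
#' field-induced force on the system equals `q_tot * field`, i.e. total charge
#' is conserved when field forces are applied.
#'
#' @param apts An [apt_set].
#' @return A corrected `apt_set`; attribute `"deviation"` records the 3x3
#'   pre-correction deviation matrix.
#' @export
#' @examples
#' a <- apt_set(list(diag(3) * 2), q_tot = 1)
#' b <- apply_sum_rule(a)
#' sum_rule_deviation(b) # ~ 0
apply_sum_rule <- function(apts) {
  stopifnot(inherits(apts, "apt_set"))
  dev <- sum_rule_deviation(apts)
  share <- dev / apts$n
  corrected <- apts$tensors
  for (i in seq_len(apts$n)) corrected[i, , ] <- corrected[i, , ] - share
  out <- apt_set(corrected, q_tot = apts$q_tot, species = apts$species)
  attr(out, "deviation") <- dev
  out
}

#' Per-atom force set
#'
#' Forces are stored in e.V/A (numerically identical to eV/A). The `tag`
#' records whether the set is the unperturbed (zero-field) force, the
#' field-induced perturbation, or their total; [total_forces()] refuses to add
#' two totals.
#'
#' @param forces n x 3 numeric matrix.
#' @param tag One of `"unperturbed"`, `"perturbed"`, `"total"`.
#' @return Object of class `force_set`.
#' @export
force_set <- function(forces, tag = c("unperturbed", "perturbed", "total")) {
  tag <- match.arg(tag)
  forces <- as.matrix(forces)
  stopifnot(ncol(forces) == 3)
  if (!all(is.finite(forces))) stop("non-finite force components")
  structure(list(forces = forces, tag = tag, n = nrow(forces)),
            class = "force_set")
}

#' @export
print.force_set <- function(x, ...) {
  cat(sprintf("force_set (%s): %d atoms, max |F| = %.4g eV/A\n",
              x$tag, x$n, max(abs(x$forces))))
  invisible(x)
}

#' Field-induced forces from atomic polar tensors
#'
#' The force perturbation on atom i along Cartesian direction eta is the
#' contraction of the atom's polar tensor with the field:
#' `F_p[i, eta] = sum_zeta P[i, eta, zeta] * field[zeta]`.
#'
#' @param apts An [apt_set].
#' @param field Length-3 field vector in V/A (validated by [check_field()]).
#' @param n_atoms Optional expected atom count; a mismatch with `apts$n` is an
#'   error.
#' @return A [force_set()] with tag `"perturbed"`, units e.V/A.
#' @export
#' @examples
#' a <- apt_set(list(diag(3)))
#' perturbed_forces(a, c(0, 0, 0.1))$forces # (0, 0, 0.1)
perturbed_forces <- function(apts, field, n_atoms = NULL) {
  stopifnot(inherits(apts, "apt_set"))
  field <- check_field(field)
  if (!is.null(n_atoms) && n_atoms != apts$n) {
    stop(sprintf("APT set has %d atoms but system has %d", apts$n, n_atoms))
  }
  # contract over zeta: F[i, eta] = sum_z P[i, eta, z] field[z]
  f <- apts$tensors[, , 1, drop = FALSE] * field[1] +
       apts$tensors[, , 2, drop = FALSE] * field[2] +
       apts$tensors[, , 3, drop = FALSE] * field[3]
  force_set(matrix(f, nrow = apts$n, ncol = 3), tag = "perturbed")
}

#' Total forces from unperturbed and perturbed contributions
#'
#' @param base A [force_set()] tagged `"unperturbed"`.
#' @param perturbed A [force_set()] tagged `"perturbed"`.
#' @return A `force_set` tagged `"total"` with the element-wise sum.
#' @export
total_forces <- function(base, perturbed) {
  stopifnot(inherits(base, "force_set"), inherits(perturbed, "force_set"))
  if (base$tag == "total" || perturbed$tag == "total") {
    stop("cannot combine force sets already tagged 'total'")
  }
  if (base$tag == perturbed$tag) {
    stop("expected one unperturbed and one perturbed force set")
  }
  if (base$n != perturbed$n) stop("atom-count mismatch between force sets")
  force_set(base$forces + perturbed$forces, tag = "total")
}

#' Atomic polar tensors by finite differences of field forces
#'
#' Exploits the exact identity between the dipole position-derivative and the
#' force field-derivative: each tensor column zeta is estimated by a central
#' difference of the atomic forces under fields +/- increment along axis zeta.
#'
#' @param force_model Function mapping a length-3 field vector (V/A) to an
#'   n x 3 force matrix or a [force_set()].
#' @param increment Field increment in V/A (default 0.0257).
#' @param q_tot Total charge assigned to the returned [apt_set].
#' @return An [apt_set] with the central-difference tensor estimates.
#' @export
finite_difference_apt <- function(force_model, increment = 0.0257, q_tot = 1) {
  stopifnot(is.function(force_model), increment > 0)
  eval_forces <- function(field) {
    f <- force_model(field)
    if (inherits(f, "force_set")) f <- f$forces
    f <- as.matrix(f)
    if (!all(is.finite(f))) stop("force model returned non-finite forces")
    f
  }
  cols <- vector("list", 3)
  n <- NULL
  for (z in 1:3) {
    e <- c(0, 0, 0); e[z] <- increment
    fp <- eval_forces(e)
    fm <- eval_forces(-e)
    if (is.null(n)) n <- nrow(fp)
    stopifnot(nrow(fp) == n, nrow(fm) == n)
    cols[[z]] <- (fp - fm) / (2 * increment) # n x 3: rows atoms, cols eta
  }
  tensors <- array(0, c(n, 3, 3))
  for (z in 1:3) tensors[, , z] <- cols[[z]]
  apt_set(tensors, q_tot = q_tot)
}
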