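#' Physical constants and unit conversions
#'
#' Internal unit system: length in Angstrom (A), time in femtoseconds (fs),
#' mass in unified atomic mass units (amu), energy in electronvolts (eV),
#' charge in elementary charges (e), electric field in V/A. In these units a
#' force of 1 e.V/A is numerically identical to 1 eV/A, which is why field
#' forces (charge times field) need no conversion factor.
#'
#' @return Named list of constants:
#' \describe{
#'   \item{kB}{Boltzmann constant, eV/K.}
#'   \item{mass_unit}{Conversion amu -> eV fs^2/A^2, so that
#'     `a = F / (m * mass_unit)` gives acceleration in A/fs^2.}
#'   \item{coulomb_k}{Coulomb constant, eV A / e^2.}
#'   \item{faraday}{Faraday constant, C/mol.}
#'   \item{gas_R}{Molar gas constant, J/(mol K).}
#'   \item{avogadro}{Avogadro constant, 1/mol.}
#'   \item{e_charge}{Elementary charge, C.}
#'   \item{c_cm_fs}{Speed of light in cm/fs (converts wavenumbers in cm^-1 to
#'     frequencies in fs^-1).}
#'   \item{D_to_si}{Conversion A^2/fs -> m^2/s.}
#'   \item{J_to_si}{Conversion e A^-2 fs^-1 -> A m^-2.}
#'   \item{sigma_to_si}{Conversion (e A^-2 fs^-1)/(V/A) -> S/m.}
#' }
#' @export
#' @examples
#' transport_constants()$kB
transport_constants <- function() {
  e_charge <- 1.602176634e-19
  list(
    kB        = 8.617333262e-5,
    mass_unit = 1.66053906660e-27 / e_charge * 1e10, # = 103.6427
    coulomb_k = 14.399645,
    faraday   = 96485.332,
    gas_R     = 8.31446,
    avogadro  = 6.02214076e23,
    e_charge  = e_charge,
    c_cm_fs   = 2.99792458e-5,
    D_to_si   = 1e-5,
    # e / (A^2 fs) -> C / (m^2 s)
    J_to_si   = e_charge / (1e-20 * 1e-15),
    # slope (e A^-2 fs^-1 per V/A) -> S/m: multiply J by J_to_si, divide E by
    # 1e10 (V/A -> V/m)
    sigma_to_si = e_charge / (1e-20 * 1e-15) / 1e10
  )
}

#' Convert a direction cosine to an angle in degrees
#'
#' Helper for reporting mean dipole tilt cosines as tilt angles.
#'
#' @param cosine Numeric vector of cosines in \[-1, 1\].
#' @return Angle(s) in degrees.
#' @export
#' @examples
#' cos_to_degrees(0.49) # 60.66
cos_to_degrees <- function(cosine) {
  stopifnot(all(is.finite(cosine)), all(abs(cosine) <= 1 + 1e-12))
  acos(pmin(1, pmax(-1, cosine))) * 180 / pi
}
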