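#' Sauerbrey areal mass from a frequency shift
#'
#' For a rigid film the areal mass added to the crystal is proportional to
#' the (overtone-normalized, baseline-referenced) frequency shift:
#' `m_f = -C * dF`. A negative shift means mass gained; a positive shift
#' yields a negative mass, signalling mass loss.
#'
#' @param dF Normalized frequency shift, Hz. May be a vector.
#' @param constants A [qcmd_constants()] object.
#' @return Areal mass, ng/cm^2.
#' @examples
#' sauerbrey_mass(-30)    # 534 ng/cm^2, a complete bilayer plus hydration layer
#' @export
sauerbrey_mass <- function(dF, constants = qcmd_constants()) {
  -constants$sauerbrey_c * dF
}

#' Sauerbrey film thickness from a frequency shift
#'
#' Treats the adsorbed layer as a uniform film of density `rho` and converts
#' the Sauerbrey mass to a thickness: `h = -C * dF / rho`, reported in nm.
#' Only meaningful when the film is rigid (overtones converged, dissipation
#' near zero); for soft layers use [deformed_height()] which restores
#' Sauerbrey validity by extrapolation.
#'
#' @param dF Normalized frequency shift, Hz.
#' @param rho Film density, g/cm^3 (> 0).
#' @inheritParams sauerbrey_mass
#' @return Thickness, nm.
#' @examples
#' sauerbrey_thickness(-113)  # 20.1 nm
#' @export
sauerbrey_thickness <- function(dF, rho = 1.0, constants = qcmd_constants()) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0)
    stop("rho must be a single positive number")
  m <- sauerbrey_mass(dF, constants)          # ng/cm^2
  # (ng/cm^2) / (g/cm^3) = 1e-9 cm = 1e-2 nm
  (m / rho) * 1e-2
}

#' Bilayer thickness corrected for the substrate hydration layer
#'
#' The Sauerbrey mass at the SLB asymptote includes the thin water layer
#' between the substrate and the bilayer. Subtracting its previously reported
#' areal mass (102 ng/cm^2, about 1 nm) isolates the lipid bilayer itself:
#' `h = (-C * dF_asymp - hydration_mass) / rho` in nm.
#'
#' @param dF_asymp Asymptotic normalized frequency shift, Hz.
#' @param hydration_mass Areal mass of the hydration layer, ng/cm^2.
#' @param rho Film density, g/cm^3.
#' @inheritParams sauerbrey_mass
#' @return Thickness in nm. If the hydration mass exceeds the Sauerbrey mass
#'   the function returns 0 with attribute `clamped = TRUE` and a warning.
#' @examples
#' bilayer_thickness_corrected(-30)  # 4.3 nm
#' @export
bilayer_thickness_corrected <- function(dF_asymp, hydration_mass = 102,
                                        rho = 1.0,
                                        constants = qcmd_constants()) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0)
    stop("rho must be a single positive number")
  m <- sauerbrey_mass(dF_asymp, constants) - hydration_mass
  clamped <- m < -1e-9
  if (any(clamped))
    warning("hydration mass exceeds Sauerbrey mass; thickness clamped to 0")
  m[m < 0] <- 0
  h <- (m / rho) * 1e-2
  if (any(clamped)) attr(h, "clamped") <- TRUE
  h
}

#' Acoustic decay length in the liquid
#'
#' Penetration depth of the shear acoustic wave into the liquid at overtone
#' `n`: `delta = sqrt(eta_L / (pi * n * F0 * rho_L))`. Higher overtones probe
#' closer to the crystal surface (delta decreases as n^(-1/2)).
#'
#' @param n Overtone (harmonic) number, an odd integer >= 1. May be a vector.
#' @inheritParams sauerbrey_mass
#' @return Decay length, nm.
#' @examples
#' decay_length(1, qcmd_constants(eta_l = 8.9e-4, rho_l = 0.997))  # ~238 nm
#' @export
decay_length <- function(n, constants = qcmd_constants()) {
  .check_overtone(n)
  si <- .qcmd_si(constants)
  sqrt(si$eta / (pi * n * constants$f0_hz * si$rho_l)) * 1e9
}

.check_overtone <- function(n) {
  if (!is.numeric(n) || any(n < 1) || any(n != round(n)))
    stop("overtone number n must be an integer >= 1")
  invisible(TRUE)
}

#' Response of a rigid film
#'
#' A rigid film obeys the Sauerbrey relation at every overtone: the
#' normalized frequency shift is `-m_f / C`, identical across overtones, and
#' the dissipation shift is zero. (The solvent loading terms cancel because
#' traces are referenced to a baseline in the same liquid.)
#'
#' @param m_f Areal film mass, ng/cm^2 (>= 0). May be a vector.
#' @param n Overtone number (kept in the signature for interface symmetry
#'   with [viscoelastic_film_response()]; the result does not depend on it).
#' @inheritParams sauerbrey_mass
#' @return A list with components `dF` (Hz) and `dD` (dissipation, in units
#'   of 1e-6).
#' @examples
#' rigid_film_response(534)$dF  # -30 Hz
#' @export
rigid_film_response <- function(m_f, n = 7, constants = qcmd_constants()) {
  if (any(m_f < 0)) stop("m_f must be >= 0")
  .check_overtone(n)
  list(dF = -m_f / constants$sauerbrey_c, dD = rep(0, length(m_f)))
}

#' Response of a viscoelastic film
#'
#' Thin-film (small-load) response of a viscoelastic layer in liquid, with
#' the solvent terms differenced away by baseline referencing:
#' \deqn{\Delta F = -\frac{m_f}{C}\left[1 -
#'   \frac{2}{\rho_f}\left(\frac{\eta_L}{\delta_L}\right)^2
#'   \frac{G''}{G'^2+G''^2}\right]}
#' \deqn{\Delta D = \frac{m_f}{m_q}\,\frac{4}{\rho_f}
#'   \left(\frac{\eta_L}{\delta_L}\right)^2 \frac{G'}{G'^2+G''^2}}
#' with the decay length \eqn{\delta_L} evaluated per overtone. As G' grows
#' the pair converges to the rigid (Sauerbrey) response with dD -> 0; soft
#' films respond differently at different overtones because delta_L depends
#' on n.
#'
#' @param film A [viscoelastic_film()] object.
#' @param n Overtone number(s), odd integer(s) >= 1.
#' @inheritParams sauerbrey_mass
#' @return A list with `dF` (Hz) and `dD` (units of 1e-6), one element per
#'   overtone in `n`, plus `softness`, the dimensionless viscoelastic
#'   correction factor applied to the Sauerbrey term.
#' @examples
#' f <- viscoelastic_film(m_f = 2000, g_storage = 1e5, g_loss = 3e4)
#' viscoelastic_film_response(f, n = 3,
#'   constants = qcmd_constants(eta_l = 8.9e-4, rho_l = 0.997))
#' @export
viscoelastic_film_response <- function(film, n = c(3, 7, 11),
                                       constants = qcmd_constants()) {
  stopifnot(inherits(film, "qcmd_film"))
  .check_overtone(n)
  if (film$g_storage == 0 && film$g_loss == 0)
    stop("G' and G'' cannot both be zero")
  si <- .qcmd_si(constants)
  rho_f <- film$rho_f * 1000                     # kg/m^3
  delta <- sqrt(si$eta / (pi * n * constants$f0_hz * si$rho_l))  # m
  afac <- (si$eta / delta)^2                     # Pa^2 s^2 / m^2 -> Pa*kg/m^3
  denom <- film$g_storage^2 + film$g_loss^2
  softness <- 2 * afac * film$g_loss / (denom * rho_f)
  dF <- -(film$m_f / constants$sauerbrey_c) * (1 - softness)
  dD <- (.ngcm2_to_si(film$m_f) / si$mq) * 4 * afac * film$g_storage /
    (denom * rho_f)
  list(dF = dF, dD = dD * 1e6, softness = softness)
}

#' Dissipation factor from shear moduli
#'
#' The dissipation of a viscoelastic film is the ratio of energy lost to
#' energy stored per oscillation cycle, `D = G'' / (2 pi G')`.
#'
#' @param g_storage Storage modulus G', Pa (> 0).
#' @param g_loss Loss modulus G'', Pa.
#' @return Dimensionless dissipation.
#' @examples
#' dissipation_from_moduli(1e5, 3e4)  # 0.0477
#' @export
dissipation_from_moduli <- function(g_storage, g_loss) {
  if (any(g_storage <= 0)) stop("g_storage must be > 0")
  g_loss / (2 * pi * g_storage)
}
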