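#' Physical constants for QCM-D film calculations
#'
#' Bundles the instrument and liquid properties every film-model calculation
#' needs: the fundamental resonance frequency of the quartz crystal, the
#' Sauerbrey mass-sensitivity coefficient, and the viscosity and density of
#' the liquid the crystal is immersed in. The areal mass of the quartz
#' crystal, `m_q = C * F0` (after unit conversion), is derived and stored for
#' consistency.
#'
#' Defaults describe a 5 MHz crystal in water at 23 degrees C
#' (eta = 9.32e-4 Pa s, rho = 0.9975 g/cm^3); override the liquid properties
#' for runs at other temperatures.
#'
#' @param f0_hz Fundamental resonance frequency of the crystal, Hz.
#' @param sauerbrey_c Sauerbrey coefficient C, ng/cm^2/Hz.
#' @param eta_l Liquid viscosity, Pa s.
#' @param rho_l Liquid density, g/cm^3.
#' @param rho_film Default film density, g/cm^3.
#' @return An object of class `qcmd_constants`: a list with the fields above
#'   plus `m_q_g_cm2`, the areal mass of the crystal in g/cm^2.
#' @examples
#' k <- qcmd_constants()
#' k$m_q_g_cm2  # 0.089 g/cm^2 for the 5 MHz crystal
#' @export
qcmd_constants <- function(f0_hz = 5e6, sauerbrey_c = 17.8,
                           eta_l = 9.32e-4, rho_l = 0.9975,
                           rho_film = 1.0) {
  stopifnot(is.numeric(f0_hz), is.numeric(sauerbrey_c), is.numeric(eta_l),
            is.numeric(rho_l), is.numeric(rho_film))
  if (f0_hz <= 0) stop("f0_hz must be > 0")
  if (sauerbrey_c <= 0) stop("sauerbrey_c must be > 0")
  if (eta_l <= 0) stop("eta_l must be > 0")
  if (rho_l <= 0) stop("rho_l must be > 0")
  if (rho_film <= 0) stop("rho_film must be > 0")
  out <- list(
    f0_hz = f0_hz,
    sauerbrey_c = sauerbrey_c,
    eta_l = eta_l,
    rho_l = rho_l,
    rho_film = rho_film,
    # C [ng/cm^2/Hz] * F0 [Hz] -> ng/cm^2 -> g/cm^2
    m_q_g_cm2 = sauerbrey_c * 1e-9 * f0_hz
  )
  class(out) <- "qcmd_constants"
  out
}

#' @export
print.qcmd_constants <- function(x, ...) {
  cat("QCM-D constants\n")
  cat(sprintf("  F0          : %.4g Hz\n", x$f0_hz))
  cat(sprintf("  C           : %.4g ng/cm^2/Hz\n", x$sauerbrey_c))
  cat(sprintf("  m_q         : %.4g g/cm^2\n", x$m_q_g_cm2))
  cat(sprintf("  liquid      : eta = %.4g Pa s, rho = %.4g g/cm^3\n",
              x$eta_l, x$rho_l))
  cat(sprintf("  film density: %.4g g/cm^3\n", x$rho_film))
  invisible(x)
}

#' Viscoelastic film description
#'
#' A thin adsorbed film characterised by its areal mass, density and complex
#' shear modulus. The storage modulus G' measures elastic rigidity, the loss
#' modulus G'' viscous losses; water-filled vesicle layers are loss-dominated
#' (G'' > G'), a finished bilayer is effectively rigid (large G').
#'
#' @param m_f Areal film mass, ng/cm^2 (>= 0).
#' @param rho_f Film density, g/cm^3 (> 0).
#' @param g_storage Storage modulus G', Pa (> 0).
#' @param g_loss Loss modulus G'', Pa (>= 0).
#' @return An object of class `qcmd_film`.
#' @examples
#' viscoelastic_film(m_f = 2000, g_storage = 1e5, g_loss = 3e4)
#' @export
viscoelastic_film <- function(m_f, rho_f = 1.0, g_storage, g_loss) {
  stopifnot(is.numeric(m_f), is.numeric(rho_f),
            is.numeric(g_storage), is.numeric(g_loss))
  if (m_f < 0) stop("m_f must be >= 0")
  if (rho_f <= 0) stop("rho_f must be > 0")
  if (g_storage <= 0) stop("g_storage must be > 0")
  if (g_loss < 0) stop("g_loss must be >= 0")
  structure(list(m_f = m_f, rho_f = rho_f,
                 g_storage = g_storage, g_loss = g_loss),
            class = "qcmd_film")
}

# internal: SI conversions used by the film response functions
.qcmd_si <- function(constants) {
  list(
    mq = constants$m_q_g_cm2 * 10,   # g/cm^2 -> kg/m^2
    rho_l = constants$rho_l * 1000,  # g/cm^3 -> kg/m^3
    eta = constants$eta_l
  )
}

# ng/cm^2 -> kg/m^2
.ngcm2_to_si <- function(m) m * 1e-8
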