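#' Apparent vesicle adsorption rate
#'
#' `R_ads = -dF_min / t_ads`, in Hz/min: how fast mass accumulated up to
#' the critical coverage.
#'
#' @param dF_min Frequency shift at the minimum, Hz.
#' @param t_ads Time from lipid start to the minimum, min (> 0).
#' @return Rate in Hz/min (positive when `dF_min < 0`).
#' @examples
#' adsorption_rate(-56.5, 2.1)  # 26.9 Hz/min
#' @export
adsorption_rate <- function(dF_min, t_ads) {
  if (any(t_ads <= 0)) stop("t_ads must be > 0")
  -dF_min / t_ads
}

#' Apparent vesicle rupture rate
#'
#' `R_rup = -(dF_min - dF_asymp) / t_rup`, in Hz/min: how fast the trapped
#' water was released between the frequency minimum and the asymptote.
#' Unruptured traces (`t_rup = Inf`) return exactly 0.
#'
#' @param dF_min Frequency shift at the minimum, Hz.
#' @param dF_asymp Asymptotic frequency shift, Hz (must be >= `dF_min`).
#' @param t_rup Rupture duration, min (> 0, possibly `Inf`).
#' @return Rate in Hz/min.
#' @examples
#' rupture_rate(-56.5, -25.1, 1.4)  # 22.4 Hz/min
#' rupture_rate(-56.6, -56.6, Inf)  # 0
#' @export
rupture_rate <- function(dF_min, dF_asymp, t_rup) {
  if (any(t_rup <= 0)) stop("t_rup must be > 0 (or Inf)")
  if (any(dF_asymp < dF_min - 1e-9))
    stop("inconsistent features: dF_asymp below dF_min")
  r <- -(dF_min - dF_asymp) / t_rup
  r[!is.finite(t_rup)] <- 0
  r
}

#' Classify the final film on the crystal
#'
#' Applies the asymptote-based boundary rule: small frequency and
#' dissipation changes mean a complete rigid SLB; very large frequency
#' changes mean an intact supported vesicle layer (SLV); in between lies a
#' partial bilayer with embedded vesicles. The default boundaries (36 Hz,
#' 50 Hz, dissipation 1.0e-6) are midpoints between the observed bands
#' (~26-30 Hz SLB, 42-46 Hz partial, >= 55 Hz SLV) and are configurable.
#'
#' @param dF_asymp Asymptotic frequency shift, Hz.
#' @param dD_asymp Asymptotic dissipation shift, 1e-6 units.
#' @param ruptured Optional logical from [extract_features()]; accepted for
#'   interface completeness (the boundary rule alone decides the class).
#' @param slb_max_hz SLB boundary on |dF_asymp|, Hz.
#' @param slv_min_hz SLV boundary on |dF_asymp|, Hz.
#' @param slb_max_dd SLB boundary on dD_asymp, 1e-6 units.
#' @return One of `"SLB"`, `"PARTIAL_SLB_SLV"`, `"SLV"` (vectorised).
#' @examples
#' classify_outcome(-25.1, 0.1)   # "SLB"
#' classify_outcome(-94.4, 17.2)  # "SLV"
#' classify_outcome(-42.8, 2.4)   # "PARTIAL_SLB_SLV"
#' @export
classify_outcome <- function(dF_asymp, dD_asymp, ruptured = NULL,
                             slb_max_hz = 36, slv_min_hz = 50,
                             slb_max_dd = 1.0) {
  if (any(!is.finite(dF_asymp)) || any(!is.finite(dD_asymp)))
    stop("asymptotic values must be finite")
  out <- ifelse(abs(dF_asymp) <= slb_max_hz & dD_asymp <= slb_max_dd, "SLB",
                ifelse(abs(dF_asymp) >= slv_min_hz, "SLV", "PARTIAL_SLB_SLV"))
  out
}

#' Buffer composition
#'
#' @param name Identifier (e.g. `"B1"`).
#' @param species Named numeric vector of solute concentrations in mM
#'   (names such as `NaCl`, `CaCl2`, `MgCl2`, `phosphate`, `Tris`).
#' @param pH Buffer pH.
#' @return An object of class `qcmd_buffer`.
#' @export
qcmd_buffer <- function(name, species, pH = 7) {
  if (is.null(names(species)) || any(!nzchar(names(species))))
    stop("species must be a named numeric vector (mM)")
  if (any(species < 0)) stop("concentrations must be >= 0")
  structure(list(name = name, species = species, pH = pH),
            class = "qcmd_buffer")
}

#' The six standard buffers
#'
#' Phosphate- and Tris-based buffers differing in added salt, used as
#' hydration (vesicle interior), dilution (exterior during adsorption) and
#' rinse buffers in the osmotic-stress experiment designs.
#'
#' @return A named list of [qcmd_buffer()] objects `B1`..`B6`.
#' @export
qcmd_buffers <- function() {
  list(
    B1 = qcmd_buffer("B1", c(phosphate = 20, NaCl = 100), pH = 7.8),
    B2 = qcmd_buffer("B2", c(phosphate = 20, NaCl = 100), pH = 7.0),
    B3 = qcmd_buffer("B3", c(Tris = 10, NaCl = 150, CaCl2 = 2), pH = 7.4),
    B4 = qcmd_buffer("B4", c(phosphate = 20, NaCl = 100, MgCl2 = 2.5), pH = 7),
    B5 = qcmd_buffer("B5", c(phosphate = 20, NaCl = 250, MgCl2 = 2.5), pH = 7),
    B6 = qcmd_buffer("B6", c(phosphate = 20), pH = 7)
  )
}

# dissociation particle counts per mM nominal (ideal van't Hoff);
# phosphate approximated as a 1:1 salt since buffer-species contributions
# cancel between every compared buffer pair
.osmotic_registry <- c(NaCl = 2, CaCl2 = 3, MgCl2 = 3, phosphate = 2, Tris = 1)

# internal: ideal osmolarity of a buffer, mOsm
.osmolarity <- function(buffer, registry) {
  nm <- names(buffer$species)
  unknown <- setdiff(nm, names(registry))
  if (length(unknown))
    stop("unknown solute species: ", paste(unknown, collapse = ", "),
         " (extend the registry argument)")
  sum(buffer$species * registry[nm])
}

#' Osmotic condition across the vesicle membrane
#'
#' Compares the ideal van't Hoff osmolarity of the buffer inside the vesicle
#' (the hydration buffer) with the exterior buffer. A higher salt
#' concentration outside deflates the vesicle (hyperosmotic, promotes
#' rupture); a lower one swells it (hypoosmotic).
#'
#' @param interior Interior (hydration) [qcmd_buffer()], or a name from
#'   [qcmd_buffers()].
#' @param exterior Exterior (dilution or rinse) buffer, likewise.
#' @param threshold Band in mOsm within which the pair is called isosmotic.
#' @param registry Named vector of dissociation counts per species; extend
#'   it to register new solutes.
#' @return A list with `label` (`"hypoosmotic"`, `"isosmotic"`,
#'   `"hyperosmotic"`), `delta_mosm` (exterior minus interior) and
#'   `nacl_equiv_mm` (`delta_mosm / 2`).
#' @examples
#' osmotic_condition("B2", "B5")  # hyperosmotic, ~150 mM NaCl equivalent
#' @export
osmotic_condition <- function(interior, exterior, threshold = 10,
                              registry = NULL) {
  reg <- .osmotic_registry
  if (!is.null(registry)) reg[names(registry)] <- registry
  if (is.character(interior)) interior <- qcmd_buffers()[[interior]]
  if (is.character(exterior)) exterior <- qcmd_buffers()[[exterior]]
  stopifnot(inherits(interior, "qcmd_buffer"), inherits(exterior, "qcmd_buffer"))
  delta <- .osmolarity(exterior, reg) - .osmolarity(interior, reg)
  label <- if (delta > threshold) "hyperosmotic"
           else if (delta < -threshold) "hypoosmotic" else "isosmotic"
  list(label = label, delta_mosm = delta, nacl_equiv_mm = delta / 2)
}

#' Experimental conditions for one QCM-D run
#'
#' @param vesicle_diameter Vesicle diameter, nm (> 0).
#' @param hydration,dilution,rinse Buffers ([qcmd_buffer()] objects or names
#'   from [qcmd_buffers()]).
#' @param temperature Temperature, degrees C.
#' @param flow Named numeric vector of event times in minutes
#'   (`lipid_start`, `lipid_end`, `rinse`, ...), non-decreasing.
#' @return An object of class `qcmd_conditions`.
#' @export
experiment_conditions <- function(vesicle_diameter, hydration, dilution,
                                  rinse, temperature = 23,
                                  flow = c(lipid_start = 0)) {
  if (vesicle_diameter <= 0) stop("vesicle_diameter must be > 0")
  as_buf <- function(b) if (is.character(b)) qcmd_buffers()[[b]] else b
  hydration <- as_buf(hydration); dilution <- as_buf(dilution)
  rinse <- as_buf(rinse)
  stopifnot(inherits(hydration, "qcmd_buffer"),
            inherits(dilution, "qcmd_buffer"),
            inherits(rinse, "qcmd_buffer"))
  if (is.unsorted(flow)) stop("flow schedule times must be non-decreasing")
  structure(list(vesicle_diameter = vesicle_diameter, hydration = hydration,
                 dilution = dilution, rinse = rinse,
                 temperature = temperature, flow = flow),
            class = "qcmd_conditions")
}
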