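#' Summarize one QCM-D experiment into a flat record
#'
#' Runs the full analysis pipeline on a trace — baseline correction (if not
#' already applied), feature extraction, adsorption and rupture rates,
#' Sauerbrey mass at the asymptote, deformed-layer height by multi-overtone
#' extrapolation, outcome classification, and (when conditions are given)
#' the osmotic labels of the adsorption step (hydration vs dilution buffer)
#' and the rinse step (dilution vs rinse buffer) — and returns everything
#' as a single one-row data frame in the reference table's column order.
#'
#' Stage failures are rethrown with the failing stage named. The
#' deformed-height stage is optional in the sense that a trace with a
#' degenerate extrapolation (e.g. rigid from the start) yields `NA` with a
#' warning rather than aborting the record.
#'
#' @param trace A [qcmd_trace()].
#' @param conditions Optional [experiment_conditions()].
#' @param overtone Analysis overtone.
#' @param params A [feature_params()].
#' @param constants A [qcmd_constants()].
#' @param ... Boundary overrides passed to [classify_outcome()].
#' @return A one-row data frame of class `qcmd_record`.
#' @examples
#' rec <- summarize_experiment(simulate_trace("slv"))
#' rec$outcome   # "SLV"
#' rec$R_rup     # 0
#' @export
summarize_experiment <- function(trace, conditions = NULL, overtone = 7,
                                 params = feature_params(),
                                 constants = qcmd_constants(), ...) {
  stopifnot(inherits(trace, "qcmd_trace"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  if (is.null(trace$baseline_window))
    trace <- stage("baseline", baseline_correct(trace))
  fe <- stage("features", extract_features(trace, overtone, params))
  r_ads <- stage("rates", adsorption_rate(fe$dF_min, fe$t_ads))
  r_rup <- stage("rates", rupture_rate(fe$dF_min, fe$dF_asymp, fe$t_rup))
  h <- tryCatch(deformed_height(trace, constants = constants)$h_nm,
                error = function(e) {
                  warning("deformed height unavailable: ",
                          conditionMessage(e))
                  NA_real_
                })
  mass <- sauerbrey_mass(fe$dF_asymp, constants)
  outcome <- stage("classify",
                   classify_outcome(fe$dF_asymp, fe$dD_asymp, fe$ruptured, ...))
  bil_h <- if (outcome == "SLB")
    as.numeric(bilayer_thickness_corrected(fe$dF_asymp,
                                           constants = constants))
    else NA_real_

  osm_ads <- osm_rinse <- NA_character_
  nacl_ads <- NA_real_
  if (!is.null(conditions)) {
    stopifnot(inherits(conditions, "qcmd_conditions"))
    oa <- stage("osmotic",
                osmotic_condition(conditions$hydration, conditions$dilution))
    or <- stage("osmotic",
                osmotic_condition(conditions$dilution, conditions$rinse))
    osm_ads <- oa$label; osm_rinse <- or$label
    nacl_ads <- oa$nacl_equiv_mm
  }

  out <- data.frame(
    t_ads = fe$t_ads, dF_min = fe$dF_min, dD_max = fe$dD_max,
    t_rup = fe$t_rup, dF_asymp = fe$dF_asymp, dD_asymp = fe$dD_asymp,
    R_ads = r_ads, R_rup = r_rup, h_nm = h,
    sauerbrey_mass = mass, bilayer_thickness_nm = bil_h,
    outcome = outcome, ruptured = fe$ruptured,
    overtone = fe$overtone_used,
    osmotic_adsorption = osm_ads, osmotic_rinse = osm_rinse,
    nacl_equiv_mm = nacl_ads,
    stringsAsFactors = FALSE)
  class(out) <- c("qcmd_record", "data.frame")
  out
}

#' @export
print.qcmd_record <- function(x, ...) {
  cat("QCM-D experiment record\n")
  cat(sprintf("  outcome: %s (dF_asymp = %.4g Hz, dD_asymp = %.3g)\n",
              x$outcome, x$dF_asymp, x$dD_asymp))
  cat(sprintf("  t_ads = %.3g min, dF_min = %.4g Hz, t_rup = %s\n",
              x$t_ads, x$dF_min,
              if (is.finite(x$t_rup)) sprintf("%.3g min", x$t_rup) else "Inf"))
  cat(sprintf("  R_ads = %.3g Hz/min, R_rup = %.3g Hz/min, h = %.3g nm\n",
              x$R_ads, x$R_rup, x$h_nm))
  if (!is.na(x$osmotic_adsorption))
    cat(sprintf("  osmotic: adsorption %s, rinse %s\n",
                x$osmotic_adsorption, x$osmotic_rinse))
  invisible(x)
}
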