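#' Tuning parameters for trace feature extraction
#'
#' @param smooth_window Centered moving-median window, samples (odd; robust
#'   to spikes without biasing the minimum location).
#' @param plateau_slope Maximum absolute slope of the smoothed frequency
#'   shift inside the terminal plateau, Hz/min.
#' @param plateau_span Minimum plateau duration, min.
#' @param no_rupture_tol If the asymptote is within this many Hz of the
#'   minimum, the trace is called unruptured and t_rup is +Inf.
#' @param entry_frac,entry_min_hz The rupture time ends when the smoothed
#'   frequency shift first comes within `max(entry_min_hz,
#'   entry_frac * |dF_min - dF_asymp|)` of the asymptote.
#' @return A list of class `qcmd_feature_params`.
#' @export
feature_params <- function(smooth_window = 5, plateau_slope = 0.5,
                           plateau_span = 2, no_rupture_tol = 2,
                           entry_frac = 0.05, entry_min_hz = 0.5) {
  if (smooth_window %% 2 == 0) smooth_window <- smooth_window + 1
  structure(list(smooth_window = smooth_window,
                 plateau_slope = plateau_slope,
                 plateau_span = plateau_span,
                 no_rupture_tol = no_rupture_tol,
                 entry_frac = entry_frac, entry_min_hz = entry_min_hz),
            class = "qcmd_feature_params")
}

# internal: centered rolling least-squares slope of y(t) over +/- halfwin
# samples (regression over the whole window, far less noise-sensitive than a
# two-point difference)
.local_slope <- function(t, y, halfwin) {
  n <- length(y)
  cs1 <- cumsum(c(0, t)); cs2 <- cumsum(c(0, t^2))
  csy <- cumsum(c(0, y)); csty <- cumsum(c(0, t * y))
  lo <- pmax(seq_len(n) - halfwin, 1L)
  hi <- pmin(seq_len(n) + halfwin, n)
  m <- hi - lo + 1
  S1 <- cs1[hi + 1L] - cs1[lo]
  S2 <- cs2[hi + 1L] - cs2[lo]
  Sy <- csy[hi + 1L] - csy[lo]
  Sty <- csty[hi + 1L] - csty[lo]
  (m * Sty - S1 * Sy) / (m * S2 - S1^2)
}

#' Extract the characteristic scalars from a QCM-D trace
#'
#' Locates, on one overtone of a baseline-corrected trace, the six standard
#' features of the vesicle-to-bilayer transition: the adsorption time
#' `t_ads` (lipid start to the global minimum of the smoothed frequency
#' shift, which marks the critical vesicle coverage), the frequency minimum
#' `dF_min`, the dissipation maximum `dD_max` (reached near, but not
#' exactly at, the frequency minimum), the rupture time `t_rup` (minimum to
#' entry into the terminal plateau), and the plateau means `dF_asymp` and
#' `dD_asymp`. Traces whose asymptote stays within `no_rupture_tol` of the
#' minimum are flagged unruptured with `t_rup = Inf`.
#'
#' @param trace A baseline-corrected [qcmd_trace()].
#' @param overtone Overtone to analyse (default 7).
#' @param params A [feature_params()] object.
#' @return An object of class `qcmd_features`: a list with `t_ads`,
#'   `dF_min`, `dD_max`, `t_rup`, `dF_asymp`, `dD_asymp`, `overtone_used`,
#'   `ruptured`, plus `t_min` (absolute time of the minimum).
#' @export
extract_features <- function(trace, overtone = 7, params = feature_params()) {
  stopifnot(inherits(trace, "qcmd_trace"))
  if (is.null(trace$baseline_window))
    stop("trace must be baseline-corrected first (see baseline_correct())")
  j <- .ov_index(trace, overtone)
  lipid_start <- if (!is.null(trace$annotations) &&
                     "lipid_start" %in% names(trace$annotations))
    trace$annotations[["lipid_start"]] else 0

  tm <- trace$time
  keep <- tm >= lipid_start
  t <- tm[keep]
  f <- stats::runmed(trace$dF[keep, j], params$smooth_window)
  d <- stats::runmed(trace$dD[keep, j], params$smooth_window)
  n <- length(t)
  if (n < params$smooth_window + 2L) stop("trace too short past lipid_start")

  # locate the minimum region on the smoothed series (robust to spikes),
  # then refine to the raw minimum inside it so the median window does not
  # bias the location at an asymmetric kink
  i0 <- which.min(f)
  w <- params$smooth_window
  nb <- max(1L, i0 - w):min(n, i0 + w)
  raw <- trace$dF[keep, j]
  i_min <- nb[which.min(raw[nb])]
  dF_min <- raw[i_min]
  t_ads <- t[i_min] - lipid_start
  dD_max <- max(d)

  dt_med <- stats::median(diff(t))
  halfwin <- max(1L, round(0.5 / dt_med))
  slope <- .local_slope(t, f, halfwin)
  flat <- abs(slope) < params$plateau_slope
  # terminal plateau: longest tail in which at least 98% of the local slopes
  # are below the threshold (a strict all-flat run is brittle under noise)
  frac_flat <- rev(cumsum(rev(flat))) / (n - seq_len(n) + 1)
  ok <- which(frac_flat >= 0.98)
  s <- if (length(ok)) ok[1] else n
  if (length(ok) == 0L || (t[n] - t[s]) < params$plateau_span)
    stop("no terminal plateau detected before trace end ",
         "(extend the duration or relax plateau parameters)")
  plateau <- s:n
  dF_asymp <- mean(f[plateau])
  dD_asymp <- mean(d[plateau])

  ruptured <- abs(dF_asymp - dF_min) >= params$no_rupture_tol
  if (ruptured) {
    band <- max(params$entry_min_hz,
                params$entry_frac * abs(dF_min - dF_asymp))
    after <- which(seq_len(n) > i_min & abs(f - dF_asymp) <= band)
    i_rup <- if (length(after)) after[1] else s
    t_rup <- t[i_rup] - t[i_min]
  } else {
    t_rup <- Inf
    dF_asymp <- dF_asymp  # equals dF_min within tolerance by definition
  }

  structure(list(t_ads = t_ads, dF_min = dF_min, dD_max = dD_max,
                 t_rup = t_rup, dF_asymp = dF_asymp, dD_asymp = dD_asymp,
                 overtone_used = trace$overtones[j], ruptured = ruptured,
                 t_min = t[i_min]),
            class = "qcmd_features")
}

#' @export
print.qcmd_features <- function(x, ...) {
  cat(sprintf("QCM-D trace features (overtone %d)\n", x$overtone_used))
  cat(sprintf("  t_ads    = %.3g min\n", x$t_ads))
  cat(sprintf("  dF_min   = %.4g Hz\n", x$dF_min))
  cat(sprintf("  dD_max   = %.3g x1e-6\n", x$dD_max))
  cat(sprintf("  t_rup    = %s\n",
              if (is.finite(x$t_rup)) sprintf("%.3g min", x$t_rup) else "Inf (no rupture)"))
  cat(sprintf("  dF_asymp = %.4g Hz\n", x$dF_asymp))
  cat(sprintf("  dD_asymp = %.3g x1e-6\n", x$dD_asymp))
  invisible(x)
}

#' Dissipation-frequency phase trajectory
#'
#' Returns (dF, dD) pairs at evenly spaced time intervals for the classic
#' dD-vs-dF fingerprint plot: vesicle adsorption moves northeast (mass and
#' softness grow), rupture turns the trajectory southwest (water release and
#' stiffening). The spacing between consecutive points encodes rate.
#'
#' @param trace A [qcmd_trace()].
#' @param overtone Overtone to use.
#' @param stride Keep every `stride`-th sample (>= 1).
#' @return A data frame of class `qcmd_phase` with columns `time`, `dF`,
#'   `dD`, in time order.
#' @export
phase_plot <- function(trace, overtone = 7, stride = 1L) {
  stopifnot(inherits(trace, "qcmd_trace"))
  if (stride < 1) stop("stride must be >= 1")
  j <- .ov_index(trace, overtone)
  idx <- seq(1L, length(trace$time), by = as.integer(stride))
  out <- data.frame(time = trace$time[idx], dF = trace$dF[idx, j],
                    dD = trace$dD[idx, j])
  class(out) <- c("qcmd_phase", "data.frame")
  out
}

#' @export
plot.qcmd_phase <- function(x, ...) {
  graphics::plot(x$dF, x$dD, type = "o", pch = 20, cex = 0.5,
                 xlab = expression(Delta * F ~ "(Hz)"),
                 ylab = expression(Delta * D ~ "(x" * 10^-6 * ")"), ...)
  invisible(x)
}

#' Deformed-vesicle layer height by multi-overtone extrapolation
#'
#' The Sauerbrey relation does not hold for the soft layer of adsorbed,
#' water-filled vesicles (overtones diverge, dissipation is large). The
#' extrapolation of Reviakine and co-workers restores it: over the
#' adsorption phase, the ratio dD/dF plotted against dF is close to linear
#' for every overtone, and the fitted lines extrapolate to a common
#' intercept on the frequency axis where the dissipation would be zero.
#' At that intercept the Sauerbrey conditions hold, so the layer height is
#' `h = -C * dF_intercept / rho`.
#'
#' Per overtone a least-squares line is fitted to (dF, dD/dF) over the
#' window, excluding samples with |dF| below `dF_floor` (the ratio blows up
#' near zero); the intercepts are aggregated by unweighted mean.
#'
#' @param trace A baseline-corrected [qcmd_trace()].
#' @param overtones Overtones to fit (default: all present; at least 2).
#' @param window Length-2 time window (min) covering the adsorption phase
#'   only; default is lipid start to the frequency minimum of the analysis
#'   overtone.
#' @param rho Film density, g/cm^3.
#' @param constants A [qcmd_constants()] object.
#' @param dF_floor Exclude samples with |dF| below this many Hz.
#' @param min_points Minimum usable samples per overtone.
#' @return An object of class `qcmd_height`: list with `h_nm`, the
#'   per-overtone `intercepts_hz`, their `spread_hz` (range), `window`, and
#'   `n_points`.
#' @examples
#' tr <- baseline_correct(simulate_trace("dopc_fig2", noise = FALSE))
#' deformed_height(tr)$h_nm
#' @export
deformed_height <- function(trace, overtones = NULL, window = NULL,
                            rho = NULL, constants = qcmd_constants(),
                            dF_floor = 5, min_points = 10L) {
  stopifnot(inherits(trace, "qcmd_trace"))
  if (is.null(trace$baseline_window))
    stop("trace must be baseline-corrected first (see baseline_correct())")
  if (is.null(rho)) rho <- constants$rho_film
  if (rho <= 0) stop("rho must be > 0")
  if (is.null(overtones)) overtones <- trace$overtones
  if (length(overtones) < 2L)
    stop("at least two overtones are required for the extrapolation")
  lipid_start <- if (!is.null(trace$annotations) &&
                     "lipid_start" %in% names(trace$annotations))
    trace$annotations[["lipid_start"]] else 0
  if (is.null(window)) {
    ja <- if (7 %in% trace$overtones) .ov_index(trace, 7) else 1L
    keep <- trace$time >= lipid_start
    fs <- stats::runmed(trace$dF[keep, ja], 5)
    t_min <- trace$time[keep][which.min(fs)]
    window <- c(lipid_start, t_min)
  }
  if (diff(window) <= 0) stop("invalid extrapolation window")

  sel_t <- trace$time >= window[1] & trace$time <= window[2]
  intercepts <- numeric(length(overtones))
  npts <- integer(length(overtones))
  for (i in seq_along(overtones)) {
    j <- .ov_index(trace, overtones[i])
    fF <- trace$dF[sel_t, j]
    fD <- trace$dD[sel_t, j]
    use <- abs(fF) >= dF_floor & is.finite(fD)
    if (sum(use) < min_points)
      stop("extrapolation failure: fewer than ", min_points,
           " usable samples for overtone ", overtones[i])
    ratio <- fD[use] / fF[use]
    fit <- stats::lm.fit(cbind(1, fF[use]), ratio)
    b <- fit$coefficients
    if (!is.finite(b[2]) || abs(b[2]) < 1e-7)
      stop("extrapolation failure: dD/dF vs dF slope is ~0 for overtone ",
           overtones[i], " (intercept unstable)")
    intercepts[i] <- -b[1] / b[2]
    npts[i] <- sum(use)
  }
  names(intercepts) <- paste0("n", overtones)
  h <- (-constants$sauerbrey_c * mean(intercepts) / rho) * 1e-2
  structure(list(h_nm = h, intercepts_hz = intercepts,
                 spread_hz = diff(range(intercepts)), window = window,
                 n_points = npts),
            class = "qcmd_height")
}

#' @export
print.qcmd_height <- function(x, ...) {
  cat(sprintf("Deformed-layer height: %.3g nm\n", x$h_nm))
  cat("  per-overtone intercepts (Hz):",
      paste(sprintf("%s=%.4g", names(x$intercepts_hz), x$intercepts_hz),
            collapse = ", "), "\n")
  cat(sprintf("  intercept spread: %.3g Hz; window [%.3g, %.3g] min\n",
              x$spread_hz, x$window[1], x$window[2]))
  invisible(x)
}
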