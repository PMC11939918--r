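#' Multi-overtone QCM-D trace
#'
#' Container for a time-indexed, baseline-referenced QCM-D measurement:
#' normalized frequency shifts (Fn/n, Hz) and dissipation shifts (units of
#' 1e-6) for a set of odd overtones on a shared, strictly increasing time
#' grid (minutes). Flow events (lipid start/end, rinse) are carried as named
#' annotations in minutes.
#'
#' @param time Strictly increasing numeric vector, minutes.
#' @param dF Numeric matrix, one column per overtone, of normalized frequency
#'   shifts in Hz (a vector is accepted for a single overtone).
#' @param dD Numeric matrix matching `dF`, dissipation shifts in 1e-6 units.
#' @param overtones Ordered vector of odd integers, one per column.
#' @param annotations Named numeric vector of event times in minutes
#'   (recognised names: `lipid_start`, `lipid_end`, `rinse`).
#' @param baseline_window Length-2 numeric `(t_start, t_end)` of the window
#'   the trace was baseline-referenced to, or `NULL` if not yet corrected.
#' @param normalized Logical; `TRUE` if `dF` is already Fn/n.
#' @return An object of class `qcmd_trace`.
#' @seealso [baseline_correct()], [normalize_overtones()], [read_qcmd_trace()]
#' @export
qcmd_trace <- function(time, dF, dD, overtones,
                       annotations = c(lipid_start = 0),
                       baseline_window = NULL, normalized = TRUE) {
  time <- as.numeric(time)
  if (length(time) < 2L) stop("trace needs at least two time points")
  if (any(!is.finite(time)) || any(diff(time) <= 0))
    stop("time must be finite and strictly increasing")
  dF <- as.matrix(dF); dD <- as.matrix(dD)
  overtones <- as.integer(overtones)
  if (length(overtones) < 1L) stop("at least one overtone is required")
  if (any(overtones < 1L) || any(overtones %% 2L == 0L))
    stop("overtones must be odd integers >= 1")
  if (nrow(dF) != length(time) || nrow(dD) != length(time))
    stop("dF/dD must have one row per time point")
  if (ncol(dF) != length(overtones) || ncol(dD) != length(overtones))
    stop("dF/dD must have one column per overtone")
  colnames(dF) <- paste0("f", overtones)
  colnames(dD) <- paste0("d", overtones)
  if (!is.null(annotations)) {
    if (is.null(names(annotations)) || any(!nzchar(names(annotations))))
      stop("annotations must be a named numeric vector")
    annotations <- vapply(annotations, as.numeric, numeric(1))
  }
  if (!is.null(baseline_window)) {
    baseline_window <- as.numeric(baseline_window)
    if (length(baseline_window) != 2L || diff(baseline_window) <= 0)
      stop("baseline_window must be (t_start, t_end) with t_start < t_end")
  }
  structure(list(time = time, overtones = overtones, dF = dF, dD = dD,
                 annotations = annotations,
                 baseline_window = baseline_window,
                 normalized = isTRUE(normalized)),
            class = "qcmd_trace")
}

#' @export
print.qcmd_trace <- function(x, ...) {
  cat(sprintf("QCM-D trace: %d samples, t = [%.3g, %.3g] min, overtones %s\n",
              length(x$time), min(x$time), max(x$time),
              paste(x$overtones, collapse = ",")))
  if (!is.null(x$annotations))
    cat("  events:", paste(sprintf("%s=%.3g", names(x$annotations),
                                   x$annotations), collapse = ", "), "\n")
  cat(sprintf("  normalized: %s; baseline window: %s\n", x$normalized,
              if (is.null(x$baseline_window)) "none"
              else sprintf("[%.3g, %.3g]", x$baseline_window[1],
                           x$baseline_window[2])))
  rng <- range(x$dF)
  cat(sprintf("  dF range [%.4g, %.4g] Hz; dD max %.3g x1e-6\n",
              rng[1], rng[2], max(x$dD)))
  invisible(x)
}

#' Plot a QCM-D trace
#'
#' Frequency shifts (solid) on the left axis and dissipation shifts (dashed,
#' right axis) against time, one colour per overtone; flow events are marked
#' with vertical dotted lines.
#'
#' @param x A `qcmd_trace`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.qcmd_trace <- function(x, ...) {
  op <- graphics::par(mar = c(4.5, 4.5, 2, 4.5))
  on.exit(graphics::par(op))
  cols <- seq_along(x$overtones)
  graphics::matplot(x$time, x$dF, type = "l", lty = 1, col = cols,
                    xlab = "time (min)", ylab = expression(Delta * F ~ "(Hz)"),
                    ...)
  if (!is.null(x$annotations))
    graphics::abline(v = x$annotations, lty = 3, col = "grey40")
  graphics::par(new = TRUE)
  graphics::matplot(x$time, x$dD, type = "l", lty = 2, col = cols,
                    axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext(expression(Delta * D ~ "(x" * 10^-6 * ")"), side = 4,
                  line = 3)
  graphics::legend("bottomright", bty = "n", lty = 1, col = cols,
                   legend = paste0("n=", x$overtones), cex = 0.8)
  invisible(x)
}

# internal: column index of an overtone, with a lookup error
.ov_index <- function(trace, overtone) {
  i <- match(overtone, trace$overtones)
  if (is.na(i))
    stop(sprintf("overtone %s not present (available: %s)", overtone,
                 paste(trace$overtones, collapse = ", ")))
  i
}

#' Baseline-correct a trace
#'
#' Shifts every frequency and dissipation series by its mean over the
#' baseline window, so that the trace is referenced to the lipid-free state.
#' The default window is the minute preceding the `lipid_start` annotation
#' (the baseline is set in the dilution buffer before injection). The
#' operation is idempotent.
#'
#' @param trace A [qcmd_trace()].
#' @param window Length-2 numeric `(t_start, t_end)` in minutes; must lie
#'   within the time range and not extend past `lipid_start`.
#' @return The corrected `qcmd_trace`, with `baseline_window` recorded.
#' @export
baseline_correct <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "qcmd_trace"))
  lipid_start <- if (!is.null(trace$annotations) &&
                     "lipid_start" %in% names(trace$annotations))
    trace$annotations[["lipid_start"]] else NA_real_
  if (is.null(window)) {
    if (is.na(lipid_start))
      stop("no baseline window given and no lipid_start annotation to derive one")
    window <- c(max(lipid_start - 1, trace$time[1]), lipid_start)
  }
  window <- as.numeric(window)
  if (length(window) != 2L || diff(window) <= 0)
    stop("invalid baseline window")
  if (window[1] < trace$time[1] - 1e-9 ||
      window[2] > trace$time[length(trace$time)] + 1e-9)
    stop("baseline window outside the trace time range")
  if (!is.na(lipid_start) && window[2] > lipid_start + 1e-9)
    stop("baseline window must end at or before lipid_start")
  sel <- trace$time >= window[1] - 1e-9 & trace$time <= window[2] + 1e-9
  if (!any(sel)) stop("baseline window contains no samples")
  trace$dF <- sweep(trace$dF, 2, colMeans(trace$dF[sel, , drop = FALSE]))
  trace$dD <- sweep(trace$dD, 2, colMeans(trace$dD[sel, , drop = FALSE]))
  trace$baseline_window <- window
  trace
}

#' Normalize raw overtone frequency shifts
#'
#' Divides raw frequency shifts by the harmonic number so that dF is the
#' change in Fn/n; applied to a whole trace it normalizes every overtone
#' column and flips the `normalized` flag, refusing to normalize twice.
#'
#' @param x A `qcmd_trace`, or a numeric vector of raw shifts.
#' @param n Overtone number (only for the vector form).
#' @return Object of the same type with normalized frequency shifts.
#' @examples
#' normalize_overtones(-75, n = 3)  # -25 Hz
#' @export
normalize_overtones <- function(x, n = NULL) {
  if (inherits(x, "qcmd_trace")) {
    if (x$normalized)
      stop("trace is already overtone-normalized")
    x$dF <- sweep(x$dF, 2, x$overtones, "/")
    x$normalized <- TRUE
    return(x)
  }
  .check_overtone(n)
  x / n
}
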