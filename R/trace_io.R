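#' Read a QCM-D trace from its CSV dialect
#'
#' The dialect is comma-separated UTF-8 with '.' decimals and a mandatory
#' header naming a `time_min` column plus paired per-overtone columns
#' `f<n>`, `d<n>` (e.g. `f3,d3,f7,d7,f11,d11`; any subset with at least one
#' overtone is accepted). Lines starting with `#` carry metadata:
#' `# event: <name>=<min>` flow annotations, `# baseline_window: a,b`, and
#' `# normalized: TRUE/FALSE`. Rows containing non-finite values are dropped
#' with a warning reporting their indices.
#'
#' @param path Path to the CSV file.
#' @return A [qcmd_trace()].
#' @seealso [write_qcmd_trace()]
#' @export
read_qcmd_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) < 2L) stop("no data rows in ", path)

  annotations <- NULL
  ev <- regmatches(meta, regexec("^#\\s*event:\\s*([A-Za-z_0-9]+)\\s*=\\s*(\\S+)", meta))
  ev <- ev[lengths(ev) == 3L]
  if (length(ev)) {
    annotations <- vapply(ev, function(m) as.numeric(m[3]), numeric(1))
    names(annotations) <- vapply(ev, `[`, character(1), 2L)
  }
  bw <- NULL
  bwl <- grep("^#\\s*baseline_window:", meta, value = TRUE)
  if (length(bwl))
    bw <- as.numeric(strsplit(sub("^#\\s*baseline_window:\\s*", "", bwl[1]),
                              ",")[[1]])
  normalized <- TRUE
  nl <- grep("^#\\s*normalized:", meta, value = TRUE)
  if (length(nl))
    normalized <- toupper(trimws(sub("^#\\s*normalized:\\s*", "", nl[1]))) == "TRUE"

  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE)
  if (!"time_min" %in% names(df))
    stop("parse error: missing 'time_min' column in ", path)
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  dcols <- grep("^d[0-9]+$", names(df), value = TRUE)
  ov <- sort(as.integer(sub("^f", "", fcols)))
  if (length(ov) == 0L)
    stop("parse error: no overtone columns (f<n>) in ", path)
  if (!setequal(as.integer(sub("^d", "", dcols)), ov))
    stop("parse error: dissipation columns do not match frequency columns in ",
         path)

  mat <- as.matrix(df[, c("time_min", paste0("f", ov), paste0("d", ov))])
  bad <- which(!apply(is.finite(mat), 1, all))
  if (length(bad)) {
    warning("dropping ", length(bad), " row(s) with non-finite values at indices: ",
            paste(bad, collapse = ", "))
    mat <- mat[-bad, , drop = FALSE]
  }
  tm <- mat[, "time_min"]
  if (any(diff(tm) <= 0)) {
    i <- which(diff(tm) <= 0)[1] + 1L
    stop("parse error: time not strictly increasing at data row ", i,
         " of ", path)
  }
  qcmd_trace(time = tm,
             dF = mat[, paste0("f", ov), drop = FALSE],
             dD = mat[, paste0("d", ov), drop = FALSE],
             overtones = ov, annotations = annotations,
             baseline_window = bw, normalized = normalized)
}

#' Write a QCM-D trace in the package's CSV dialect
#'
#' Emits full double precision (`%.17g`, so a read round-trips to the exact
#' values) and writes annotations, baseline window and the normalization
#' flag as `#` metadata lines. Output is byte-deterministic for a given
#' trace.
#'
#' @param trace A [qcmd_trace()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_qcmd_trace <- function(trace, path) {
  stopifnot(inherits(trace, "qcmd_trace"))
  ov <- trace$overtones
  hdr <- c("# qcmd-trace v1",
           "# units: time=min, dF=Hz (Fn/n), dD=1e-6")
  if (!is.null(trace$annotations))
    hdr <- c(hdr, sprintf("# event: %s=%.17g", names(trace$annotations),
                          trace$annotations))
  if (!is.null(trace$baseline_window))
    hdr <- c(hdr, sprintf("# baseline_window: %.17g,%.17g",
                          trace$baseline_window[1], trace$baseline_window[2]))
  hdr <- c(hdr, sprintf("# normalized: %s", trace$normalized))
  cols <- character(2L * length(ov))
  cols[seq(1, by = 2, length.out = length(ov))] <- paste0("f", ov)
  cols[seq(2, by = 2, length.out = length(ov))] <- paste0("d", ov)
  header <- paste(c("time_min", cols), collapse = ",")
  mat <- cbind(trace$time,
               do.call(cbind, lapply(seq_along(ov), function(i)
                 cbind(trace$dF[, i], trace$dD[, i]))))
  rows <- apply(mat, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
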