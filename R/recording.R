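# Stabilogram recordings: container, text reader/writer.

#' Construct a stabilogram recording
#'
#' One subject's two-direction center-of-pressure time series: medial-lateral
#' (ML, right/left) and anterior-posterior (AP, forward/backward)
#' displacements in millimetres, sampled uniformly.
#'
#' @param subject_id Identifier string.
#' @param ml,ap Numeric displacement vectors (mm), equal length, finite.
#' @param sampling_rate Sampling rate in Hz.
#' @param label `"Healthy"`, `"PD"` or `NA` when unknown.
#' @return Object of class `stabilogram_recording`.
#' @export
stabilogram_recording <- function(subject_id, ml, ap, sampling_rate,
                                  label = NA_character_) {
  stopifnot(is.numeric(ml), is.numeric(ap), length(ml) == length(ap),
            all(is.finite(ml)), all(is.finite(ap)), sampling_rate > 0)
  if (!is.na(label) && !label %in% c("Healthy", "PD")) {
    stop("label must be 'Healthy', 'PD' or NA")
  }
  structure(
    list(subject_id = as.character(subject_id), label = label,
         sampling_rate = sampling_rate, ml = as.numeric(ml),
         ap = as.numeric(ap), duration = length(ml) / sampling_rate),
    class = "stabilogram_recording"
  )
}

#' @export
print.stabilogram_recording <- function(x, ...) {
  cat(sprintf("<stabilogram_recording> %s [%s]: %.1f s at %g Hz (%d samples/direction)\n",
              x$subject_id, ifelse(is.na(x$label), "unlabelled", x$label),
              x$duration, x$sampling_rate, length(x$ml)))
  invisible(x)
}

#' Read a recording from delimited text
#'
#' Accepts whitespace-, tab- or comma-delimited files with either three
#' numeric columns (time in seconds, ML, AP) or two (ML, AP). With a time
#' column the sampling rate is inferred from the median time step; otherwise
#' `sampling_rate` must be supplied. Lines starting with `#` and blank lines
#' are skipped. Malformed input (ragged rows, non-numeric cells) raises an
#' error naming the offending line.
#'
#' @param path File path.
#' @param sampling_rate Sampling rate hint in Hz, required for 2-column files.
#' @param subject_id Identifier; defaults to the file name without extension.
#' @param label Optional class label.
#' @return A `stabilogram_recording`.
#' @export
read_recording <- function(path, sampling_rate = NULL, subject_id = NULL,
                           label = NA_character_) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  body <- trimws(lines[keep])
  if (length(body) == 0L) stop(sprintf("%s: no data lines", path))
  parts <- strsplit(body, "[,\t ]+")
  ncols <- lengths(parts)
  if (length(unique(ncols)) != 1L) {
    bad <- lineno[which(ncols != ncols[1L])[1L]]
    stop(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                 path, bad, ncols[which(ncols != ncols[1L])[1L]], ncols[1L]))
  }
  nc <- ncols[1L]
  if (!nc %in% c(2L, 3L)) {
    stop(sprintf("%s: expected 2 (ML, AP) or 3 (time, ML, AP) columns, found %d",
                 path, nc))
  }
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(parts)), ncol = nc, byrow = TRUE))
  if (anyNA(mat)) {
    bad <- lineno[which(rowSums(is.na(mat)) > 0)[1L]]
    stop(sprintf("%s: non-numeric cell at line %d", path, bad))
  }
  if (nc == 3L) {
    dt <- stats::median(diff(mat[, 1L]))
    if (!is.finite(dt) || dt <= 0) {
      stop(sprintf("%s: time column is not increasing", path))
    }
    rate <- 1 / dt
    ml <- mat[, 2L]; ap <- mat[, 3L]
  } else {
    if (is.null(sampling_rate)) {
      stop(sprintf("%s: 2-column file needs an explicit sampling_rate", path))
    }
    rate <- sampling_rate
    ml <- mat[, 1L]; ap <- mat[, 2L]
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  stabilogram_recording(subject_id, ml, ap, rate, label)
}

#' Write a recording as delimited text
#'
#' Three tab-separated columns `time_s`, `ml_mm`, `ap_mm` with a `#` comment
#' header documenting units; round-trips through [read_recording()].
#'
#' @param rec A `stabilogram_recording`.
#' @param path Output file path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "stabilogram_recording"))
  n <- length(rec$ml)
  t <- (seq_len(n) - 1L) / rec$sampling_rate
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# subject_id: %s", rec$subject_id),
    sprintf("# label: %s", ifelse(is.na(rec$label), "unknown", rec$label)),
    sprintf("# sampling_rate_hz: %g", rec$sampling_rate),
    "# columns: time_s ml_mm ap_mm (displacement in millimetres)"
  ), con)
  utils::write.table(
    data.frame(time_s = t, ml_mm = rec$ml, ap_mm = rec$ap),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
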