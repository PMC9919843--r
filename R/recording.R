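#' A raw triaxial accelerometer recording
#'
#' One labeled recording from one subject: a `T x 3` sample matrix plus the
#' sampling frequency and provenance. Recordings are the unit that sliding
#' windows are cut from and that subject-wise splitting assigns.
#'
#' @param samples Numeric `T x 3` matrix of acceleration samples (row order
#'   is time order).
#' @param fs Sampling frequency in Hz.
#' @param label Activity class label.
#' @param subject Subject identifier.
#' @param source File path the data came from, or `"synthetic"`.
#' @return An object of class `"accel_recording"`.
#' @export
accel_recording <- function(samples, fs, label, subject,
                            source = "synthetic") {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L)
    stop("a recording must have exactly 3 acceleration axes")
  if (nrow(samples) < 1L) stop("a recording must contain at least one sample")
  if (any(!is.finite(samples))) stop("recording contains non-finite values")
  stopifnot(is.finite(fs), fs > 0)
  structure(
    list(samples = samples, fs = as.numeric(fs),
         label = as.character(label), subject = as.character(subject),
         source = as.character(source)),
    class = "accel_recording"
  )
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf(
    "<accel_recording> %d samples @ %g Hz | label = %s, subject = %s (%s)\n",
    nrow(x$samples), x$fs, x$label, x$subject, x$source
  ))
  invisible(x)
}

#' Read a triaxial accelerometer CSV
#'
#' Reads a HASC-style CSV with four numeric columns per row --
#' `time, x, y, z` -- into an [accel_recording()]. No header is expected;
#' a first line that does not parse as numbers is treated as a header and
#' skipped. Timestamps must be strictly increasing; any later malformed row
#' is an error naming the offending line.
#'
#' @param path CSV file path.
#' @param fs Sampling frequency in Hz (HASC-style files carry timestamps but
#'   no rate declaration).
#' @param label Activity class label attached to the whole recording.
#' @param subject Subject identifier.
#' @return An [accel_recording()].
#' @export
read_accel_csv <- function(path, fs, label, subject) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty recording file: %s", path))
  first_offset <- 0L
  parse_row <- function(line) suppressWarnings(
    as.numeric(strsplit(trimws(line), ",", fixed = TRUE)[[1L]])
  )
  if (any(is.na(parse_row(lines[1L])))) {     # header line
    lines <- lines[-1L]
    first_offset <- 1L
    if (length(lines) == 0L)
      stop(sprintf("no data rows in %s", path))
  }
  rows <- lapply(lines, parse_row)
  nfield <- lengths(rows)
  bad <- which(nfield < 4L | vapply(rows, anyNA, logical(1L)))
  if (length(bad) > 0L)
    stop(sprintf("cannot parse line %d of %s as time,x,y,z",
                 bad[1L] + first_offset, path))
  m <- do.call(rbind, rows)[, 1:4, drop = FALSE]
  if (is.unsorted(m[, 1L], strictly = FALSE))
    stop(sprintf("timestamps in %s are not monotone increasing", path))
  accel_recording(m[, 2:4, drop = FALSE], fs, label, subject, source = path)
}

#' Write a recording as a HASC-style CSV
#'
#' Writes `time, x, y, z` rows (no header), timestamps `0, 1/fs, 2/fs, ...`.
#' The inverse of [read_accel_csv()] up to floating-point formatting (15
#' significant digits, exact for round-trip tests).
#'
#' @param rec An [accel_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(rec, path) {
  stopifnot(inherits(rec, "accel_recording"))
  t <- (seq_len(nrow(rec$samples)) - 1L) / rec$fs
  df <- cbind(t, rec$samples)
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
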