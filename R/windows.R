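#' Segmented accelerometer windows
#'
#' A `window_set` holds `n` fixed-length triaxial windows as a `3 x w x n`
#' array (axis, sample, window) together with per-window activity labels and
#' subject IDs and the sampling frequency. All pipeline stages (filtering,
#' training, prediction, the mask sweep) operate on window sets; a single
#' window is just a set with `n = 1`.
#'
#' @param values Numeric array `3 x w x n` (or a `3 x w` matrix for one
#'   window) of acceleration values, axis-major.
#' @param labels Character vector of activity labels, length `n`.
#' @param subjects Character vector of subject IDs, length `n`.
#' @param fs Sampling frequency in Hz.
#'
#' @return An object of class `"window_set"`.
#' @export
window_set <- function(values, labels, subjects, fs) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (dim(values)[1L] != 3L)
    stop("windows must have exactly 3 axes (first array dimension)")
  if (any(!is.finite(values)))
    stop("window values must all be finite")
  n <- dim(values)[3L]
  labels <- as.character(labels)
  subjects <- as.character(subjects)
  if (length(labels) == 1L) labels <- rep(labels, n)
  if (length(subjects) == 1L) subjects <- rep(subjects, n)
  stopifnot(length(labels) == n, length(subjects) == n,
            is.finite(fs), fs > 0)
  structure(
    list(values = values, labels = labels, subjects = subjects,
         fs = as.numeric(fs)),
    class = "window_set"
  )
}

#' @rdname window_set
#' @param x A `window_set`.
#' @export
n_windows <- function(x) {
  stopifnot(inherits(x, "window_set"))
  dim(x$values)[3L]
}

#' @rdname window_set
#' @export
window_length <- function(x) {
  stopifnot(inherits(x, "window_set"))
  dim(x$values)[2L]
}

#' @export
`[.window_set` <- function(x, i) {
  window_set(x$values[, , i, drop = FALSE], x$labels[i], x$subjects[i], x$fs)
}

#' Concatenate window sets
#'
#' @param ... `window_set` objects with identical window length and `fs`.
#' @return A single `window_set`.
#' @export
bind_windows <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) &&
      !inherits(sets[[1L]], "window_set"))
    sets <- sets[[1L]]
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1L), "window_set")))
  w  <- unique(vapply(sets, window_length, integer(1L)))
  fs <- unique(vapply(sets, function(s) s$fs, numeric(1L)))
  if (length(w) != 1L || length(fs) != 1L)
    stop("window sets differ in window length or sampling frequency")
  vals <- array(
    unlist(lapply(sets, function(s) s$values), use.names = FALSE),
    dim = c(3L, w, sum(vapply(sets, n_windows, integer(1L))))
  )
  window_set(vals,
             unlist(lapply(sets, function(s) s$labels), use.names = FALSE),
             unlist(lapply(sets, function(s) s$subjects), use.names = FALSE),
             fs)
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf(
    "<window_set> %d windows of %d samples x 3 axes @ %g Hz; %d class(es), %d subject(s)\n",
    n_windows(x), window_length(x), x$fs,
    length(unique(x$labels)), length(unique(x$subjects))
  ))
  invisible(x)
}

#' The spectrum grid of a window set
#'
#' @param windows A [window_set()].
#' @return The [spectrum_grid()] with the set's window length and `fs`.
#' @export
window_grid <- function(windows) {
  stopifnot(inherits(windows, "window_set"))
  spectrum_grid(window_length(windows), windows$fs)
}
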