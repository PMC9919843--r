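#' One-sided spectrum grid of a fixed-length window
#'
#' Describes the discrete one-sided frequency grid of a real signal of
#' `n_samples` samples recorded at `fs` Hz: bins `0 .. floor(n_samples/2)`,
#' where bin `k` sits at `k * fs / n_samples` Hz. Bin 0 is the DC component
#' (the signal mean); the highest bin is at or below the Nyquist frequency
#' `fs/2`. All gain profiles and mask sweeps are defined on this grid, so the
#' bin/Hz bookkeeping lives in one place.
#'
#' @param n_samples Window length `w` in samples (positive integer).
#' @param fs Sampling frequency in Hz (positive).
#'
#' @return An object of class `"spectrum_grid"`: a list with `n_samples`,
#'   `fs`, `n_bins` (`floor(w/2) + 1` one-sided bins) and `bin_hz`
#'   (resolution `fs / w` in Hz per bin).
#'
#' @examples
#' g <- spectrum_grid(256, 100)
#' g$n_bins            # 129 one-sided bins
#' bin_frequency(g, 2) # 0.78125 Hz
#' @export
spectrum_grid <- function(n_samples, fs) {
  stopifnot(length(n_samples) == 1L, length(fs) == 1L)
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2L)
    stop("`n_samples` must be an integer >= 2")
  if (!is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive sampling frequency in Hz")
  structure(
    list(
      n_samples = n_samples,
      fs        = as.numeric(fs),
      n_bins    = n_samples %/% 2L + 1L,
      bin_hz    = fs / n_samples
    ),
    class = "spectrum_grid"
  )
}

#' Frequency (Hz) of one-sided spectrum bins
#'
#' @param grid A [spectrum_grid()].
#' @param bins Integer vector of bin indices in `0 .. n_bins - 1`.
#' @return Numeric vector of frequencies `bins * fs / n_samples` (Hz).
#' @export
bin_frequency <- function(grid, bins) {
  stopifnot(inherits(grid, "spectrum_grid"))
  bins <- as.integer(bins)
  if (any(is.na(bins)) || any(bins < 0L) || any(bins > grid$n_bins - 1L))
    stop("bin indices must lie in 0 .. n_bins - 1")
  bins * grid$bin_hz
}

#' Nearest grid bin to a frequency in Hz
#'
#' @param grid A [spectrum_grid()].
#' @param hz Frequencies in Hz, each in `[0, fs/2]`.
#' @return Integer vector of bin indices.
#' @export
nearest_bin <- function(grid, hz) {
  stopifnot(inherits(grid, "spectrum_grid"))
  if (any(!is.finite(hz)) || any(hz < 0) || any(hz > grid$fs / 2 + 1e-9))
    stop("frequencies must lie in [0, fs/2]")
  k <- as.integer(round(hz / grid$bin_hz))
  pmin(k, grid$n_bins - 1L)
}

#' @export
print.spectrum_grid <- function(x, ...) {
  cat(sprintf(
    "<spectrum_grid> w = %d samples @ %g Hz: %d one-sided bins, %.4g Hz/bin (Nyquist %.4g Hz)\n",
    x$n_samples, x$fs, x$n_bins, x$bin_hz, x$fs / 2
  ))
  invisible(x)
}
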