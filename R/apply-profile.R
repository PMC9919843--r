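#' Filter windows in the frequency domain
#'
#' Applies a [gain_profile] to every window of a set, per axis independently:
#' forward FFT, multiply each one-sided complex coefficient by its real gain
#' (the conjugate half gets the mirrored gain so the inverse transform is
#' real), inverse FFT. This realizes `x' = ifft(P(fft(x), f))` with `P` a
#' phase-preserving amplitude rescaling: masks zero out a band, emphasis
#' filters scale the off-peak spectrum toward the floor. Labels, subjects and
#' shapes are preserved.
#'
#' The transform length is the window length itself (no zero padding), so
#' profile bins line up exactly with the window's DFT bins.
#'
#' @param windows A [window_set()] (or a bare `3 x w` numeric matrix, in
#'   which case a matrix is returned).
#' @param profile A [gain_profile] built on the matching [spectrum_grid()].
#' @return Filtered windows of the same class and shape as `windows`.
#' @export
apply_profile <- function(windows, profile) {
  stopifnot(inherits(profile, "gain_profile"))
  if (is.matrix(windows)) {
    ws <- window_set(windows, "", "", profile$grid$fs)
    return(apply_profile(ws, profile)$values[, , 1L])
  }
  stopifnot(inherits(windows, "window_set"))
  w <- window_length(windows)
  if (w != profile$grid$n_samples)
    stop(sprintf("window length %d does not match profile grid (%d samples)",
                 w, profile$grid$n_samples))
  n <- n_windows(windows)
  g <- full_gain_vector(profile)

  # One mvfft over all axes of all windows: columns are (axis, window) series.
  m <- matrix(aperm(windows$values, c(2L, 1L, 3L)), nrow = w, ncol = 3L * n)
  spec <- stats::mvfft(m) * g            # g recycles down each column
  out  <- stats::mvfft(spec, inverse = TRUE) / w
  resid <- max(abs(Im(out)))
  if (resid > 1e-9)
    stop(sprintf("imaginary residue %.3g after inverse transform", resid))
  vals <- aperm(array(Re(out), dim = c(w, 3L, n)), c(2L, 1L, 3L))
  window_set(vals, windows$labels, windows$subjects, windows$fs)
}

# Two-sided gain vector (length w): one-sided gains extended by conjugate
# symmetry, g[w - k] = g[k], so real signals stay real.
full_gain_vector <- function(profile) {
  w  <- profile$grid$n_samples
  nb <- profile$grid$n_bins
  g  <- numeric(w)
  g[seq_len(nb)] <- profile$gains
  if (w > 2L) {
    mirror <- (nb + 1L):w                 # bins nb .. w-1 mirror w-k
    g[mirror] <- profile$gains[w - mirror + 2L]
  }
  g
}
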