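#' @title Gain profiles over the one-sided spectrum
#'
#' @description A gain profile is a real multiplier in `[0, 1]` per one-sided
#' FFT bin. Applied to a window (see [apply_profile()]) it scales the
#' amplitude spectrum bin-by-bin while preserving phase: masks set bins to
#' zero, emphasis filters hold the important bin at 1 and attenuate the rest
#' toward a floor (0.5 by default). The DC bin (bin 0, the signal mean) is
#' never attenuated by the emphasis filters and can never be masked.
#'
#' @name gain_profile
NULL

new_gain_profile <- function(grid, gains, kind, center_bin = NA_integer_) {
  stopifnot(inherits(grid, "spectrum_grid"), length(gains) == grid$n_bins)
  if (any(!is.finite(gains)) || any(gains < 0) || any(gains > 1))
    stop("all gains must be finite and lie in [0, 1]")
  structure(
    list(grid = grid, gains = as.numeric(gains), kind = kind,
         center_bin = as.integer(center_bin)),
    class = "gain_profile"
  )
}

#' Band-stop mask profile (single bin or bin range)
#'
#' Builds the masking operator used in the importance sweep: gain 0 on the
#' masked bin(s), gain 1 everywhere else. Bin 0 is the DC component and is
#' never masked; the highest maskable bin is the Nyquist bin `n_bins - 1`.
#'
#' @param grid A [spectrum_grid()].
#' @param band A single bin index, or an inclusive `c(lo, hi)` bin range,
#'   with `1 <= lo <= hi <= n_bins - 1`.
#' @return A `gain_profile` of kind `"mask"`.
#' @examples
#' g <- spectrum_grid(8, 8)
#' make_mask_profile(g, 1)$gains  # 1 0 1 1 1
#' @export
make_mask_profile <- function(grid, band) {
  stopifnot(inherits(grid, "spectrum_grid"))
  band <- as.integer(band)
  if (length(band) == 1L) band <- c(band, band)
  if (length(band) != 2L || any(is.na(band)) || band[1L] > band[2L])
    stop("`band` must be a bin index or an inclusive c(lo, hi) range")
  if (band[1L] <= 0L)
    stop("bin 0 is the DC component and is never masked")
  if (band[2L] > grid$n_bins - 1L)
    stop(sprintf("band exceeds the one-sided spectrum (max bin %d)",
                 grid$n_bins - 1L))
  gains <- rep(1, grid$n_bins)
  gains[(band[1L]:band[2L]) + 1L] <- 0
  new_gain_profile(grid, gains, "mask", band[1L])
}

check_center_floor <- function(grid, center_bin, floor) {
  center_bin <- as.integer(center_bin)
  if (is.na(center_bin) || center_bin < 0L || center_bin > grid$n_bins - 1L)
    stop("`center_bin` must lie in 0 .. n_bins - 1")
  if (!is.finite(floor) || floor <= 0 || floor > 1)
    stop("`floor` must lie in (0, 1]")
  center_bin
}

#' Peak emphasis profile
#'
#' Keeps the amplitude spectrum untouched at the important bin and halves it
#' (multiplies by `floor`, default 1/2) at every other frequency. DC (bin 0)
#' always keeps gain 1.
#'
#' @inheritParams make_mask_profile
#' @param center_bin Emphasized bin index, `0 .. n_bins - 1`.
#' @param floor Gain applied away from the peak, in `(0, 1]` (default 0.5).
#' @return A `gain_profile` of kind `"peak"`.
#' @export
make_peak_profile <- function(grid, center_bin, floor = 0.5) {
  stopifnot(inherits(grid, "spectrum_grid"))
  center_bin <- check_center_floor(grid, center_bin, floor)
  gains <- rep(floor, grid$n_bins)
  gains[center_bin + 1L] <- 1
  gains[1L] <- 1
  new_gain_profile(grid, gains, "peak", center_bin)
}

#' Gaussian emphasis profile
#'
#' A Gaussian window over bins, centered on the important bin, rescaled so
#' the maximum gain is 1 (at the center) and the gain approaches `floor`
#' (default 0.5) far from it:
#' `gain[k] = floor + (1 - floor) * exp(-(k - center)^2 / (2 sigma^2))`.
#' The standard deviation is measured in bins (default 10). DC keeps gain 1.
#'
#' @inheritParams make_peak_profile
#' @param sigma_bins Standard deviation of the Gaussian, in bins (> 0).
#' @return A `gain_profile` of kind `"gaussian"`.
#' @export
make_gaussian_profile <- function(grid, center_bin, sigma_bins = 10,
                                  floor = 0.5) {
  stopifnot(inherits(grid, "spectrum_grid"))
  center_bin <- check_center_floor(grid, center_bin, floor)
  if (!is.finite(sigma_bins) || sigma_bins <= 0)
    stop("`sigma_bins` must be positive")
  k <- 0:(grid$n_bins - 1L)
  gains <- floor + (1 - floor) * exp(-(k - center_bin)^2 / (2 * sigma_bins^2))
  gains[1L] <- 1
  new_gain_profile(grid, gains, "gaussian", center_bin)
}

#' Triangular emphasis profile
#'
#' A triangular window with its vertex (gain 1) at the important bin, falling
#' off linearly and clamped at `floor` (default 0.5) beyond `half_width_bins`
#' bins from the center. When `half_width_bins` is `NULL` the ramp spans the
#' distance from the center to the farther edge of the spectrum, so the whole
#' band is inside the ramp before clamping. DC keeps gain 1.
#'
#' @inheritParams make_peak_profile
#' @param half_width_bins Bins from vertex to where the ramp reaches `floor`
#'   (>= 1), or `NULL` for the farther-edge default.
#' @return A `gain_profile` of kind `"triangular"`.
#' @export
make_triangular_profile <- function(grid, center_bin, half_width_bins = NULL,
                                    floor = 0.5) {
  stopifnot(inherits(grid, "spectrum_grid"))
  center_bin <- check_center_floor(grid, center_bin, floor)
  if (is.null(half_width_bins))
    half_width_bins <- max(center_bin, grid$n_bins - 1L - center_bin)
  if (!is.finite(half_width_bins) || half_width_bins < 1)
    stop("`half_width_bins` must be >= 1")
  k <- 0:(grid$n_bins - 1L)
  gains <- pmax(floor, 1 - (1 - floor) * abs(k - center_bin) / half_width_bins)
  gains[1L] <- 1
  new_gain_profile(grid, gains, "triangular", center_bin)
}

#' Random emphasis profile (control filter)
#'
#' Draws an independent uniform gain on `[0.5, 1]` for every bin whose
#' frequency lies in `(0, cutoff_hz]` (default cutoff 7.8 Hz). Bin 0 and bins
#' above the cutoff keep `outside_gain` (default 1; set 0.5 for a
#' floor-consistent variant). Used as the control that carries no information
#' about any class's important frequency.
#'
#' @inheritParams make_mask_profile
#' @param cutoff_hz Upper edge (Hz) of the randomized band, in `(0, fs/2]`.
#' @param rng_seed Integer seed; the profile is reproducible under it.
#' @param outside_gain Gain outside `(0, cutoff_hz]`, in `[0.5, 1]`.
#' @return A `gain_profile` of kind `"random"`.
#' @export
make_random_profile <- function(grid, cutoff_hz = 7.8, rng_seed,
                                outside_gain = 1) {
  stopifnot(inherits(grid, "spectrum_grid"))
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz > grid$fs / 2)
    stop("`cutoff_hz` must lie in (0, fs/2]")
  if (!is.finite(outside_gain) || outside_gain < 0.5 || outside_gain > 1)
    stop("`outside_gain` must lie in [0.5, 1]")
  if (missing(rng_seed)) stop("`rng_seed` is required for reproducibility")
  k <- 0:(grid$n_bins - 1L)
  in_band <- k > 0L & k * grid$bin_hz <= cutoff_hz + 1e-12
  gains <- rep(outside_gain, grid$n_bins)
  gains[1L] <- 1
  gains[in_band] <- with_preserved_seed(rng_seed, {
    stats::runif(sum(in_band), min = 0.5, max = 1)
  })
  new_gain_profile(grid, gains, "random")
}

#' All-pass (unit) profile
#'
#' Gain 1 at every bin; applying it is the identity up to round-off.
#'
#' @inheritParams make_mask_profile
#' @return A `gain_profile` of kind `"unit"`.
#' @export
make_unit_profile <- function(grid) {
  stopifnot(inherits(grid, "spectrum_grid"))
  new_gain_profile(grid, rep(1, grid$n_bins), "unit")
}

# Run `expr` under a local RNG seed without disturbing the caller's stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write / read a gain profile as two-column text
#'
#' Serializes a profile as plain text with columns `bin_hz` and `gain`
#' (one row per one-sided bin) for inspection and plotting; `read_profile()`
#' reconstructs the profile given the grid it was built on.
#'
#' @param profile A `gain_profile`.
#' @param path File path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a `gain_profile` of kind `"unit"`-agnostic `"custom"` with the
#'   stored gains.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "gain_profile"))
  df <- data.frame(
    bin_hz = bin_frequency(profile$grid, 0:(profile$grid$n_bins - 1L)),
    gain   = profile$gains
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param grid The [spectrum_grid()] the profile was built on.
#' @export
read_profile <- function(path, grid) {
  stopifnot(inherits(grid, "spectrum_grid"))
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (nrow(df) != grid$n_bins)
    stop("profile file does not match the grid's number of bins")
  new_gain_profile(grid, df$gain, "custom")
}

#' @export
print.gain_profile <- function(x, ...) {
  cat(sprintf(
    "<gain_profile> kind = %s%s over %d bins (gains in [%.3g, %.3g])\n",
    x$kind,
    if (!is.na(x$center_bin))
      sprintf(", center bin %d (%.3g Hz)", x$center_bin,
              x$center_bin * x$grid$bin_hz)
    else "",
    x$grid$n_bins, min(x$gains), max(x$gains)
  ))
  invisible(x)
}
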