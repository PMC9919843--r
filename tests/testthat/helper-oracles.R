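# Independent oracles and small fixtures shared across test files.

# Brute-force O(n^2) DFT: complex coefficient at one-sided bin k.
# Independent of stats::fft on purpose.
brute_dft_bin <- function(x, k) {
  n <- length(x)
  t <- 0:(n - 1)
  sum(x * exp(-2i * pi * k * t / n))
}

# One-sided amplitude of bin k as carried by a real signal.
brute_amplitude <- function(x, k) {
  n <- length(x)
  scale <- if (k == 0 || (n %% 2 == 0 && k == n / 2)) n else n / 2
  Mod(brute_dft_bin(x, k)) / scale
}

# A pure real tone sitting exactly on bin k of a length-w window.
# Uses cos so bin 0 (DC) and the Nyquist bin are non-degenerate.
tone_window <- function(w, k, amp = 1, phase = 0) {
  amp * cos(2 * pi * k * (0:(w - 1)) / w + phase)
}

# Triaxial window set holding the same series on all three axes.
tone_set <- function(series, fs, label = "a", subject = "s1") {
  window_set(rbind(series, series, series), label, subject, fs)
}

# Brute-force sliding-window count: number of 0-based starts i with
# i*stride + w <= T.
brute_window_count <- function(T_, w, stride) {
  n <- 0L
  i <- 0L
  while (i + w <= T_) {
    n <- n + 1L
    i <- i + stride
  }
  n
}

# Brute-force majority vote used as the voting oracle: count labels;
# among maximal counts take highest mean winning score; then lowest index.
brute_majority <- function(labels, winning, class_set) {
  counts <- sapply(class_set, function(c) sum(labels == c))
  best <- which(counts == max(counts))
  if (length(best) > 1L) {
    mw <- sapply(best, function(b)
      mean(winning[labels == class_set[b]]))
    best <- best[mw == max(mw)]
  }
  class_set[best[1L]]
}

# Brute-force per-layer length simulator for the VGG plan.
brute_length_plan <- function(len, padding) {
  for (b in c(2L, 2L, 3L, 3L, 3L)) {
    for (l in seq_len(b)) {
      len <- if (padding == "none") len - 2L else len
      if (len <= 0L) return(NA_integer_)
    }
    len <- len %/% 2L
    if (len <= 0L) return(NA_integer_)
  }
  len
}

# A micro classifier for plumbing tests: 2-channel conv stack, cheap to
# build and train.
micro_model_config <- function(n_classes, window_len, ...) {
  model_config(n_classes, window_len, padding = "same",
               conv_channels = rep(2L, 13L), ...)
}

# Small synthetic recording for segmentation tests.
toy_recording <- function(T_, fs = 32, label = "walk", subject = "S01") {
  accel_recording(matrix(seq_len(T_ * 3L) / 10, T_, 3L), fs, label, subject)
}
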