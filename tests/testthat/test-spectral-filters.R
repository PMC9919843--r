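test_that("mask profiles zero the band, protect DC and reject bad bands", {
  g <- spectrum_grid(8, 8)
  expect_equal(make_mask_profile(g, 1)$gains, c(1, 0, 1, 1, 1))

  g256 <- spectrum_grid(256, 100)
  p <- make_mask_profile(g256, 2)
  expect_equal(p$gains[3], 0)
  expect_true(all(p$gains[-3] == 1))
  expect_equal(bin_frequency(g256, 2), 0.78125)  # the "0.78 Hz" bin

  expect_error(make_mask_profile(g256, 0), "DC")
  expect_error(make_mask_profile(g256, c(0, 3)), "DC")
  expect_error(make_mask_profile(g256, 129), "spectrum")
  # range mask
  pr <- make_mask_profile(g256, c(5, 8))
  expect_equal(which(pr$gains == 0) - 1L, 5:8)
})

test_that("masking a bin annihilates a tone planted at that bin", {
  g <- spectrum_grid(8, 8)
  x <- tone_window(8, 1)
  expect_gt(brute_amplitude(x, 1), 0.99)   # tone really sits at bin 1
  out <- apply_profile(tone_set(x, 8), make_mask_profile(g, 1))
  expect_lt(sum(out$values[1, , 1]^2), 1e-12 * sum(x^2))
})

test_that("peak profile is 1 at center (and DC), floor elsewhere", {
  g <- spectrum_grid(256, 100)
  p <- make_peak_profile(g, 8)             # ~3.13 Hz, the jog bin
  expect_equal(bin_frequency(g, 8), 3.125)
  expect_equal(p$gains[9], 1)
  expect_equal(p$gains[6], 0.5)
  expect_equal(p$gains[1], 1)              # DC never attenuated
  expect_true(all(p$gains[-c(1, 9)] == 0.5))

  expect_equal(make_peak_profile(g, 8, floor = 1)$gains,
               make_unit_profile(g)$gains)
  expect_error(make_peak_profile(g, 8, floor = 0), "floor")
  expect_error(make_peak_profile(g, 8, floor = 1.2), "floor")
  expect_error(make_peak_profile(g, 300), "center_bin")
})

test_that("gaussian profile follows the closed form between 1 and the floor", {
  g <- spectrum_grid(256, 100)
  p <- make_gaussian_profile(g, 40)
  expect_equal(p$gains[41], 1)
  expect_equal(p$gains[51], 0.5 + 0.5 * exp(-1 / 2))  # one sigma out
  expect_equal(p$gains[31], 0.5 + 0.5 * exp(-1 / 2))
  expect_lt(max(abs(p$gains[110:129] - 0.5)), 1e-8)   # far tail at floor
  k <- 0:128
  expect_equal(p$gains[-1],
               (0.5 + 0.5 * exp(-(k - 40)^2 / 200))[-1])
  expect_error(make_gaussian_profile(g, 40, sigma_bins = 0), "sigma")
  expect_error(make_gaussian_profile(g, 40, sigma_bins = -3), "sigma")
})

test_that("triangular profile is linear to the half width then clamped", {
  g <- spectrum_grid(256, 100)
  p <- make_triangular_profile(g, 20, half_width_bins = 4)
  expect_equal(p$gains[21], 1)                      # vertex
  expect_equal(p$gains[23], 0.75)                   # |k-c| = 2 of 4
  expect_equal(p$gains[20], 0.875)                  # |k-c| = 1 of 4
  expect_equal(p$gains[19], 0.75)                   # symmetric side
  expect_true(all(p$gains[26:129] == 0.5))          # clamped at floor
  expect_true(all(abs(p$gains) <= 1))
  # default half width spans to the farther spectrum edge
  pd <- make_triangular_profile(g, 20)
  expect_equal(pd$gains[129], 0.5)
  expect_gt(pd$gains[60], 0.5)
  expect_error(make_triangular_profile(g, 20, half_width_bins = 0),
               "half_width")
})

test_that("random profile randomizes exactly the (0, cutoff] band, reproducibly", {
  g <- spectrum_grid(256, 100)
  p1 <- make_random_profile(g, rng_seed = 42)
  p2 <- make_random_profile(g, rng_seed = 42)
  p3 <- make_random_profile(g, rng_seed = 43)
  expect_identical(p1$gains, p2$gains)
  expect_false(identical(p1$gains, p3$gains))

  in_band <- 2:20                 # bins 1..19: 19 = floor(7.8 * 256 / 100)
  expect_true(all(p1$gains[in_band] >= 0.5 & p1$gains[in_band] <= 1))
  expect_true(all(p1$gains[-in_band] == 1))         # DC and above cutoff
  expect_gt(sd(p1$gains[in_band]), 0)               # actually random

  pf <- make_random_profile(g, rng_seed = 1, outside_gain = 0.5)
  expect_true(all(pf$gains[21:129] == 0.5))
  expect_error(make_random_profile(g, cutoff_hz = 0, rng_seed = 1),
               "cutoff")
  expect_error(make_random_profile(g, cutoff_hz = 51, rng_seed = 1),
               "cutoff")
})

test_that("unit profile application is the identity", {
  set.seed(11)
  vals <- array(rnorm(3 * 64 * 5), dim = c(3, 64, 5))
  ws <- window_set(vals, rep("a", 5), rep("s", 5), 50)
  out <- apply_profile(ws, make_unit_profile(spectrum_grid(64, 50)))
  expect_lt(max(abs(out$values - vals)), 1e-9)
  expect_identical(out$labels, ws$labels)
  expect_identical(out$subjects, ws$subjects)
})

test_that("a tone at bin k emerges with amplitude gains[k], any profile, all bins", {
  w <- 32
  g <- spectrum_grid(w, 32)
  profiles <- list(
    make_peak_profile(g, 5),
    make_gaussian_profile(g, 9, sigma_bins = 3),
    make_triangular_profile(g, 12, half_width_bins = 4),
    make_random_profile(g, cutoff_hz = 16, rng_seed = 7),
    make_mask_profile(g, 6),
    make_mask_profile(g, c(3, 10))
  )
  for (p in profiles) {
    for (k in 0:(g$n_bins - 1)) {
      x <- tone_window(w, k, amp = 1, phase = if (k %in% c(0, 16)) 0 else 0.4)
      out <- apply_profile(tone_set(x, 32), p)$values[1, , ]
      expect_lt(max(abs(out - p$gains[k + 1] * x)), 1e-9)
    }
  }
})

test_that("filtering is linear and contracts energy when gains <= 1", {
  g <- spectrum_grid(64, 64)
  p <- make_gaussian_profile(g, 10, sigma_bins = 4)
  set.seed(21)
  for (rep in 1:5) {
    x <- matrix(rnorm(3 * 64), 3, 64)
    y <- matrix(rnorm(3 * 64), 3, 64)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    fx <- apply_profile(x, p); fy <- apply_profile(y, p)
    fxy <- apply_profile(a * x + b * y, p)
    expect_lt(max(abs(fxy - (a * fx + b * fy))), 1e-9)
    expect_lte(sum(fx^2), sum(x^2) + 1e-9)          # Parseval contraction
  }
})

test_that("masking is idempotent", {
  g <- spectrum_grid(64, 64)
  m <- make_mask_profile(g, c(4, 9))
  set.seed(31)
  x <- matrix(rnorm(3 * 64), 3, 64)
  once <- apply_profile(x, m)
  twice <- apply_profile(once, m)
  expect_lt(max(abs(twice - once)), 1e-9)
})

test_that("apply_profile validates shapes and finiteness", {
  g <- spectrum_grid(64, 64)
  p <- make_unit_profile(g)
  set.seed(5)
  ws <- window_set(array(rnorm(3 * 32 * 2), dim = c(3, 32, 2)),
                   c("a", "a"), c("s", "s"), 64)
  expect_error(apply_profile(ws, p), "does not match")
  bad <- matrix(rnorm(3 * 64), 3, 64); bad[2, 5] <- NA
  expect_error(apply_profile(bad, p), "finite")
})

test_that("profiles serialize to two-column text and read back", {
  g <- spectrum_grid(64, 50)
  p <- make_gaussian_profile(g, 7, sigma_bins = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(p, path)
  txt <- read.table(path, header = TRUE)
  expect_named(txt, c("bin_hz", "gain"))
  expect_equal(nrow(txt), g$n_bins)
  p2 <- read_profile(path, g)
  expect_equal(p2$gains, p$gains, tolerance = 1e-6)
})

test_that("gain profiles reject out-of-range gains at construction", {
  g <- spectrum_grid(16, 16)
  expect_error(freqhar:::new_gain_profile(g, rep(2, g$n_bins), "unit"),
               "\\[0, 1\\]")
  expect_error(freqhar:::new_gain_profile(g, rep(NA_real_, g$n_bins),
                                          "unit"))
})
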