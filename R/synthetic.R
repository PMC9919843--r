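#' Class specification for synthetic accelerometer signals
#'
#' Describes the signal model of one synthetic activity class: a dominant
#' oscillation frequency (optionally with harmonics), per-axis DC offsets
#' and amplitudes, and additive Gaussian noise. A `static` class has no
#' oscillatory terms at all -- it is pure DC plus noise, the analogue of
#' standing still, and exercises the 0 Hz selection path of the importance
#' sweep.
#'
#' @param label Class label.
#' @param dominant_hz Fundamental frequency in Hz (0 for static classes).
#' @param harmonics List of `c(multiple, relative_amplitude)` pairs added on
#'   top of the fundamental (default none).
#' @param dc_offset Per-axis DC offsets (length 3; default `c(0, 0, 1)`,
#'   gravity on the third axis).
#' @param amplitude Per-axis oscillation amplitudes (length 3).
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise per sample
#'   per axis.
#' @param static If TRUE the class is DC-only; `dominant_hz` and all
#'   amplitudes must be 0.
#' @return An object of class `"class_spec"`.
#' @export
class_spec <- function(label, dominant_hz, harmonics = list(),
                       dc_offset = c(0, 0, 1),
                       amplitude = c(1, 0.8, 0.6),
                       noise_sd = 0.3, static = FALSE) {
  stopifnot(length(dc_offset) == 3L, length(amplitude) == 3L,
            all(is.finite(dc_offset)), all(is.finite(amplitude)),
            all(amplitude >= 0), is.finite(noise_sd), noise_sd >= 0,
            is.finite(dominant_hz), dominant_hz >= 0)
  if (isTRUE(static) && (dominant_hz > 0 || any(amplitude > 0)))
    stop("a static class has no oscillatory terms: dominant_hz and amplitudes must be 0")
  if (!isTRUE(static) && dominant_hz <= 0)
    stop("non-static classes need a positive dominant frequency")
  if (length(harmonics) > 0L &&
      !all(vapply(harmonics, function(h)
        length(h) == 2L && h[1L] > 1 && h[2L] >= 0, logical(1L))))
    stop("harmonics must be c(multiple > 1, relative_amplitude >= 0) pairs")
  structure(
    list(label = as.character(label), dominant_hz = dominant_hz,
         harmonics = harmonics, dc_offset = dc_offset,
         amplitude = amplitude, noise_sd = noise_sd,
         static = isTRUE(static)),
    class = "class_spec"
  )
}

#' Subject specification: per-subject signal perturbations
#'
#' Per-subject multiplicative jitter of the dominant frequency and the
#' amplitudes, plus per-axis phase offsets. Jitter makes recordings of the
#' same activity differ systematically between subjects, so subject-wise
#' train/validation/test splits are meaningful (a model cannot memorize a
#' subject's exact phase or rate).
#'
#' @param id Subject identifier.
#' @param freq_factor Multiplier applied to every class's dominant
#'   frequency (e.g. 0.98 -- 1.02).
#' @param amp_factor Multiplier applied to oscillation amplitudes.
#' @param phase Per-axis phase offsets in radians (length 3).
#' @return An object of class `"subject_spec"`.
#' @export
subject_spec <- function(id, freq_factor = 1, amp_factor = 1,
                         phase = c(0, 0, 0)) {
  stopifnot(is.finite(freq_factor), freq_factor > 0,
            is.finite(amp_factor), amp_factor > 0, length(phase) == 3L)
  structure(
    list(id = as.character(id), freq_factor = freq_factor,
         amp_factor = amp_factor, phase = phase),
    class = "subject_spec"
  )
}

#' Draw a cohort of subject specifications
#'
#' @param n Number of subjects (IDs `S01, S02, ...`).
#' @param seed Integer seed.
#' @param freq_jitter Half-width of the uniform multiplicative frequency
#'   jitter (default 0.02, i.e. +/- 2%; keeps planted frequencies within
#'   half a bin of their grid bin for the default benchmark).
#' @param amp_jitter Half-width of the uniform amplitude jitter.
#' @return List of [subject_spec()] objects.
#' @export
make_subject_specs <- function(n, seed, freq_jitter = 0.02,
                               amp_jitter = 0.1) {
  stopifnot(n >= 1L, freq_jitter >= 0, freq_jitter < 1,
            amp_jitter >= 0, amp_jitter < 1)
  with_preserved_seed(seed, {
    lapply(seq_len(n), function(i) {
      subject_spec(
        id = sprintf("S%02d", i),
        freq_factor = stats::runif(1, 1 - freq_jitter, 1 + freq_jitter),
        amp_factor = stats::runif(1, 1 - amp_jitter, 1 + amp_jitter),
        phase = stats::runif(3, 0, 2 * pi)
      )
    })
  })
}

#' Generate one synthetic recording
#'
#' Per axis `a`: `dc[a] + amp[a] * sin(2 pi f t + phi[a])` plus harmonics
#' and i.i.d. Gaussian noise, with the subject's frequency/amplitude jitter
#' and phase applied. Reproducible under `seed`.
#'
#' @param cls A [class_spec()].
#' @param subj A [subject_spec()].
#' @param duration_s Recording duration in seconds.
#' @param fs Sampling frequency in Hz.
#' @param seed Integer seed for the noise.
#' @return An [accel_recording()] of `duration_s * fs` samples.
#' @export
generate_recording <- function(cls, subj, duration_s, fs, seed) {
  stopifnot(inherits(cls, "class_spec"), inherits(subj, "subject_spec"),
            is.finite(duration_s), duration_s > 0, is.finite(fs), fs > 0)
  T_ <- as.integer(round(duration_s * fs))
  if (T_ < 1L) stop("duration too short for one sample")
  f <- cls$dominant_hz * subj$freq_factor
  if (f >= fs / 2)
    stop("jittered dominant frequency reaches the Nyquist frequency")
  t <- (seq_len(T_) - 1L) / fs
  noise <- with_preserved_seed(seed,
    matrix(stats::rnorm(T_ * 3L, sd = cls$noise_sd), T_, 3L))
  samples <- matrix(0, T_, 3L)
  for (a in 1:3) {
    sig <- rep(cls$dc_offset[a], T_)
    if (!cls$static && cls$amplitude[a] > 0) {
      amp <- cls$amplitude[a] * subj$amp_factor
      sig <- sig + amp * sin(2 * pi * f * t + subj$phase[a])
      for (h in cls$harmonics)
        sig <- sig + amp * h[2L] * sin(2 * pi * h[1L] * f * t +
                                         subj$phase[a])
    }
    samples[, a] <- sig + noise[, a]
  }
  accel_recording(samples, fs, cls$label, subj$id, source = "synthetic")
}

#' Generate the synthetic activity-recognition benchmark
#'
#' Builds a labeled multi-class dataset with planted class-specific spectral
#' structure: each non-static class oscillates at a distinct grid bin of the
#' target window's spectrum, one static (DC-only) class plays the
#' standing-still role, every subject carries frequency/amplitude jitter and
#' random phases, and recordings are segmented and split subject-wise. The
#' planted bins are returned as a ground-truth [frequency_bank()] so
#' recovery by the importance sweep can be scored.
#'
#' Defaults plant bins `{0, 3, 6, 10}` of a 128-sample window at 64 Hz
#' (0, 1.5, 3, 5 Hz) across classes `stay, walk, jog, run`, with 16 subjects
#' split 8/4/4 and one 10 s recording per subject and class.
#'
#' @param planted_bins Integer bins of the `(w, fs)` grid, one per class;
#'   include 0 for the static class. Distinct, below Nyquist.
#' @param class_labels Labels, same length as `planted_bins`.
#' @param n_subjects Cohort size.
#' @param per_split_subjects `c(train, valid, test)` subject counts.
#' @param duration_s Duration of each recording in seconds.
#' @param fs Sampling frequency in Hz.
#' @param w Window size in samples.
#' @param stride Segmentation stride (default `w %/% 2`, half-overlapping).
#' @param noise_sd Gaussian noise standard deviation.
#' @param freq_jitter,amp_jitter Passed to [make_subject_specs()].
#' @param seed Master seed; everything (subjects, noise, split) derives
#'   from it.
#' @return A list of class `"har_benchmark"`: `split` (a
#'   `"dataset_split"`), `bank` (planted ground truth), `recordings`,
#'   `class_specs`, `subject_specs`, `grid`, `seed`.
#' @export
generate_benchmark <- function(planted_bins = c(0L, 3L, 6L, 10L),
                               class_labels = NULL,
                               n_subjects = 16L,
                               per_split_subjects = c(8L, 4L, 4L),
                               duration_s = 10, fs = 64, w = 128L,
                               stride = w %/% 2L,
                               noise_sd = 0.3,
                               freq_jitter = 0.02, amp_jitter = 0.1,
                               seed = 1L) {
  grid <- spectrum_grid(w, fs)
  planted_bins <- as.integer(planted_bins)
  if (anyDuplicated(planted_bins))
    stop("planted bins must be distinct so ground truth is unambiguous")
  if (any(planted_bins < 0L) || any(planted_bins >= grid$n_bins - 1L))
    stop("planted bins must lie strictly below the Nyquist bin")
  n_cls <- length(planted_bins)
  if (is.null(class_labels)) {
    base_names <- c("stay", "walk", "jog", "run", "skip", "jump")
    class_labels <- if (n_cls <= length(base_names))
      base_names[seq_len(n_cls)] else sprintf("class%02d", seq_len(n_cls))
    # keep "stay" on the static (bin 0) class if present
    if (any(planted_bins == 0L)) {
      class_labels <- setdiff(class_labels, "stay")
      class_labels <- append(class_labels, "stay",
                             after = which(planted_bins == 0L) - 1L)
      class_labels <- class_labels[seq_len(n_cls)]
    }
  }
  stopifnot(length(class_labels) == n_cls,
            length(per_split_subjects) == 3L,
            sum(per_split_subjects) <= n_subjects)
  # jitter must not move a planted tone across a bin boundary
  if (any(planted_bins * (1 + freq_jitter) - planted_bins > 0.5))
    stop("frequency jitter can move a planted bin by more than half a bin")

  specs <- lapply(seq_len(n_cls), function(i) {
    if (planted_bins[i] == 0L)
      class_spec(class_labels[i], 0, dc_offset = c(0, 0, 1),
                 amplitude = c(0, 0, 0), noise_sd = noise_sd,
                 static = TRUE)
    else
      class_spec(class_labels[i], planted_bins[i] * grid$bin_hz,
                 dc_offset = c(0, 0, 1), amplitude = c(1, 0.8, 0.6),
                 noise_sd = noise_sd)
  })
  subjects <- make_subject_specs(n_subjects, seed = seed * 7L + 1L,
                                 freq_jitter = freq_jitter,
                                 amp_jitter = amp_jitter)
  recordings <- list()
  for (si in seq_along(subjects)) {
    for (ci in seq_len(n_cls)) {
      recordings[[length(recordings) + 1L]] <- generate_recording(
        specs[[ci]], subjects[[si]], duration_s, fs,
        seed = seed * 100003L + si * 211L + ci)
    }
  }
  split <- split_by_subject(recordings,
                            per_split_subjects[1L], per_split_subjects[2L],
                            per_split_subjects[3L],
                            seed = seed * 13L + 5L, w = w, stride = stride)
  structure(
    list(split = split,
         bank = frequency_bank(sort(class_labels), planted_bins[
           match(sort(class_labels), class_labels)], grid),
         recordings = recordings, class_specs = specs,
         subject_specs = subjects, grid = grid, seed = as.integer(seed)),
    class = "har_benchmark"
  )
}

#' @export
print.har_benchmark <- function(x, ...) {
  cat(sprintf("<har_benchmark> %d classes planted at bins {%s} (w = %d @ %g Hz)\n",
              nrow(x$bank), paste(x$bank$bin, collapse = ", "),
              x$grid$n_samples, x$grid$fs))
  print(x$split)
  invisible(x)
}

#' Score frequency recovery against planted ground truth
#'
#' @param bank A discovered `"frequency_bank"`.
#' @param planted The planted ground-truth bank.
#' @param tol_bins Allowed absolute bin error (default 1).
#' @return Fraction of classes whose discovered bin is within `tol_bins`
#'   of the planted bin.
#' @export
recovery_score <- function(bank, planted, tol_bins = 1L) {
  stopifnot(inherits(bank, "frequency_bank"),
            inherits(planted, "frequency_bank"))
  m <- merge(as.data.frame(bank), as.data.frame(planted),
             by = "class", suffixes = c("", "_planted"))
  if (nrow(m) != nrow(planted)) stop("banks cover different classes")
  mean(abs(m$bin - m$bin_planted) <= tol_bins)
}

#' Write a benchmark to disk as HASC-style CSVs plus manifest
#'
#' One `time,x,y,z` CSV per recording plus a `manifest.csv`
#' (`path,label,subject`), so the real-data code path
#' ([read_manifest()] and [read_accel_csv()]) can be exercised end to end on
#' synthetic data.
#'
#' @param benchmark A `"har_benchmark"` (or plain list of recordings).
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_benchmark_csv <- function(benchmark, dir) {
  recs <- if (inherits(benchmark, "har_benchmark"))
    benchmark$recordings else benchmark
  stopifnot(length(recs) > 0L,
            all(vapply(recs, inherits, logical(1L), "accel_recording")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    fn <- sprintf("rec_%03d_%s_%s.csv", i, r$subject, r$label)
    write_accel_csv(r, file.path(dir, fn))
    data.frame(path = fn, label = r$label, subject = r$subject)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE,
                   quote = FALSE)
  invisible(manifest)
}
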