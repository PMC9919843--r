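#' Sliding-window segmentation
#'
#' Cuts a recording into fixed-length windows at a fixed stride. Window `i`
#' (0-based) covers samples `[i*stride, i*stride + w)` (0-based, half-open),
#' so a recording of `T` samples yields `floor((T - w)/stride) + 1` windows;
#' the trailing remainder is dropped. Every window inherits the recording's
#' label and subject. No normalization or denoising is applied: raw values
#' pass through.
#'
#' @param rec An [accel_recording()].
#' @param w Window size in samples.
#' @param stride Step between window starts, in samples (default `w`,
#'   i.e. non-overlapping).
#' @return A [window_set()] (possibly with zero windows, with a warning,
#'   when the recording is shorter than `w`).
#' @export
sliding_windows <- function(rec, w, stride = w) {
  stopifnot(inherits(rec, "accel_recording"))
  w <- as.integer(w); stride <- as.integer(stride)
  if (is.na(w) || w < 1L) stop("`w` must be a positive window size")
  if (is.na(stride) || stride < 1L) stop("`stride` must be >= 1")
  T_ <- nrow(rec$samples)
  if (w > T_) {
    warning(sprintf(
      "recording (%d samples) shorter than window (%d): no windows produced",
      T_, w))
    return(window_set(array(numeric(0), dim = c(3L, w, 0L)),
                      character(0), character(0), rec$fs))
  }
  n <- (T_ - w) %/% stride + 1L
  starts <- (seq_len(n) - 1L) * stride          # 0-based starts
  vals <- array(0, dim = c(3L, w, n))
  for (i in seq_len(n))
    vals[, , i] <- t(rec$samples[(starts[i] + 1L):(starts[i] + w), ,
                                 drop = FALSE])
  window_set(vals, rec$label, rec$subject, rec$fs)
}

#' Subject-wise train/validation/test split
#'
#' Shuffles the distinct subjects under `seed`, assigns the first `n_train`
#' to training, the next `n_valid` to validation and the next `n_test` to
#' testing, then segments every recording with [sliding_windows()]. All
#' windows of a subject land in that subject's partition, so the three
#' partitions are subject-disjoint and accuracy estimates are not inflated
#' by within-subject leakage.
#'
#' @param recordings List of [accel_recording()] objects (several recordings
#'   per subject are fine).
#' @param n_train,n_valid,n_test Subject counts per partition.
#' @param seed Integer seed for the subject shuffle.
#' @param w Window size in samples.
#' @param stride Stride in samples (default `w`).
#' @return An object of class `"dataset_split"`: list with `train`, `valid`,
#'   `test` ([window_set()]s), `class_set` (ordered labels), `subjects` (per
#'   partition), `fs`, `w`, `stride`, `seed`.
#' @export
split_by_subject <- function(recordings, n_train, n_valid, n_test, seed,
                             w, stride = w) {
  stopifnot(is.list(recordings), length(recordings) > 0L,
            all(vapply(recordings, inherits, logical(1L), "accel_recording")))
  subjects <- unique(vapply(recordings, function(r) r$subject, character(1L)))
  need <- n_train + n_valid + n_test
  if (length(subjects) < need)
    stop(sprintf("need %d distinct subjects, have %d", need,
                 length(subjects)))
  shuffled <- with_preserved_seed(seed, sample(subjects))
  assign_of <- list(
    train = shuffled[seq_len(n_train)],
    valid = shuffled[n_train + seq_len(n_valid)],
    test  = shuffled[n_train + n_valid + seq_len(n_test)]
  )
  fs <- unique(vapply(recordings, function(r) r$fs, numeric(1L)))
  if (length(fs) != 1L)
    stop("recordings have mixed sampling frequencies")

  segment_part <- function(subs) {
    keep <- Filter(function(r) r$subject %in% subs, recordings)
    sets <- suppressWarnings(lapply(keep, sliding_windows, w = w,
                                    stride = stride))
    sets <- Filter(function(s) n_windows(s) > 0L, sets)
    if (length(sets) == 0L)
      return(window_set(array(numeric(0), dim = c(3L, w, 0L)),
                        character(0), character(0), fs))
    bind_windows(sets)
  }
  parts <- lapply(assign_of, segment_part)
  class_set <- sort(unique(vapply(recordings, function(r) r$label,
                                  character(1L))))
  structure(
    list(train = parts$train, valid = parts$valid, test = parts$test,
         class_set = class_set, subjects = assign_of,
         fs = fs, w = as.integer(w), stride = as.integer(stride),
         seed = as.integer(seed)),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf(
    paste0("<dataset_split> w = %d, stride = %d @ %g Hz | classes: %s\n",
           "  train: %d windows / %d subjects; valid: %d / %d; test: %d / %d\n"),
    x$w, x$stride, x$fs, paste(x$class_set, collapse = ", "),
    n_windows(x$train), length(x$subjects$train),
    n_windows(x$valid), length(x$subjects$valid),
    n_windows(x$test),  length(x$subjects$test)
  ))
  invisible(x)
}

#' Dataset manifests and split descriptions
#'
#' A manifest is a plain CSV with one row per recording file
#' (`path, label, subject`), relative paths resolved against the manifest's
#' directory. `read_manifest()` loads every listed recording;
#' `write_split_description()` persists which subject went to which
#' partition (plus `w`, `stride`, `fs`, `seed`) as a small CSV so a split
#' can be audited and reproduced.
#'
#' @param manifest_path Path to a manifest CSV with header
#'   `path,label,subject`.
#' @param fs Sampling frequency of the listed recordings (Hz).
#' @return `read_manifest()`: a list of [accel_recording()] objects.
#' @export
read_manifest <- function(manifest_path, fs) {
  df <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("path", "label", "subject")
  if (!all(need %in% names(df)))
    stop("manifest must have columns path, label, subject")
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(df)), function(i) {
    p <- df$path[i]
    if (!file.exists(p)) p <- file.path(base, df$path[i])
    read_accel_csv(p, fs = fs, label = df$label[i], subject = df$subject[i])
  })
}

#' @rdname read_manifest
#' @param split A `"dataset_split"`.
#' @param path Output CSV path.
#' @export
write_split_description <- function(split, path) {
  stopifnot(inherits(split, "dataset_split"))
  rows <- do.call(rbind, lapply(names(split$subjects), function(part) {
    if (length(split$subjects[[part]]) == 0L) return(NULL)
    data.frame(partition = part, subject = split$subjects[[part]])
  }))
  rows$w <- split$w; rows$stride <- split$stride
  rows$fs <- split$fs; rows$seed <- split$seed
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
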