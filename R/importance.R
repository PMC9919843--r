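#' Mask sweep: per-class accuracy under single-bin occlusion
#'
#' Phase 1 of the method. A model trained on unfiltered data is evaluated on
#' validation windows (from subjects disjoint from training) while each
#' one-sided frequency bin in `1 .. n_bins - 1` is masked in turn with
#' [make_mask_profile()]; bin 0 is the DC component and is never masked.
#' For every masked bin the per-class accuracy -- the recall among windows
#' truly labeled with that class -- is recorded, along with the baseline
#' accuracy on unmasked data. A class whose validation accuracy collapses
#' when some bin is masked depends on that frequency for recognition.
#'
#' @param model A trained `"har_cnn"`.
#' @param valid_windows Validation [window_set()].
#' @param band_width Number of adjacent bins occluded per sweep step
#'   (default 1, single-bin masks).
#' @return An object of class `"importance_curves"`: a list of per-class
#'   curves, each with `class`, `baseline_acc`, `acc_by_bin` (named by bin
#'   index `1 .. n_bins - 1`), `defined`, and the shared `grid`.
#' @export
mask_sweep <- function(model, valid_windows, band_width = 1L) {
  stopifnot(inherits(model, "har_cnn"), inherits(valid_windows, "window_set"))
  band_width <- as.integer(band_width)
  if (is.na(band_width) || band_width < 1L) stop("`band_width` must be >= 1")
  grid <- window_grid(valid_windows)
  nb <- grid$n_bins
  classes <- model$class_set
  truth <- valid_windows$labels
  counts <- vapply(classes, function(c) sum(truth == c), integer(1L))

  recall_of <- function(pred) {
    vapply(classes, function(c) {
      if (counts[[c]] == 0L) return(NA_real_)
      mean(pred[truth == c] == c)
    }, numeric(1L))
  }
  baseline <- recall_of(predict(model, valid_windows, type = "class"))

  bins <- seq_len(nb - 1L)
  acc <- matrix(NA_real_, nrow = length(bins), ncol = length(classes),
                dimnames = list(bins, classes))
  for (k in bins) {
    prof <- make_mask_profile(grid, c(k, min(k + band_width - 1L, nb - 1L)))
    pred <- predict(model, apply_profile(valid_windows, prof),
                    type = "class")
    acc[k, ] <- recall_of(pred)
  }
  curves <- lapply(classes, function(c) {
    structure(
      list(class = c, baseline_acc = baseline[[c]],
           acc_by_bin = stats::setNames(acc[, c], bins),
           defined = counts[[c]] > 0L, grid = grid),
      class = "importance_curve"
    )
  })
  structure(stats::setNames(curves, classes), class = "importance_curves")
}

#' @export
print.importance_curves <- function(x, ...) {
  cat(sprintf("<importance_curves> %d classes, %d swept bins\n",
              length(x), length(x[[1L]]$acc_by_bin)))
  for (cv in x) {
    cat(if (!cv$defined)
      sprintf("  %-10s undefined (no validation windows)\n", cv$class)
      else sprintf("  %-10s baseline %.3f, min %.3f at bin %s\n",
                   cv$class, cv$baseline_acc, min(cv$acc_by_bin),
                   names(which.min(cv$acc_by_bin))))
  }
  invisible(x)
}

#' Select a class's important frequency from its masking curve
#'
#' The important frequency is the masked bin at which the class's accuracy
#' drops the most (the argmin of the curve), ties broken toward the lowest
#' bin. If no mask hurts -- the curve minimum stays within `tolerance` of
#' the baseline accuracy -- the class is DC-dominated and 0 Hz (bin 0) is
#' returned.
#'
#' @param curve An `"importance_curve"` from [mask_sweep()].
#' @param tolerance Accuracy drop below baseline that still counts as "no
#'   decrease" (default 0.005).
#' @return List with `bin` (integer) and `hz` (numeric).
#' @export
select_important_frequency <- function(curve, tolerance = 0.005) {
  stopifnot(inherits(curve, "importance_curve"))
  if (!isTRUE(curve$defined))
    stop(sprintf("importance curve for class '%s' is undefined", curve$class))
  if (!is.finite(tolerance) || tolerance < 0)
    stop("`tolerance` must be a non-negative accuracy drop")
  if (min(curve$acc_by_bin) >= curve$baseline_acc - tolerance)
    return(list(bin = 0L, hz = 0))
  k <- as.integer(names(curve$acc_by_bin)[which.min(curve$acc_by_bin)])
  list(bin = k, hz = k * curve$grid$bin_hz)
}

#' Build the frequency bank: one important frequency per class
#'
#' Applies [select_important_frequency()] to every class's curve, yielding
#' the set of frequencies to be emphasized in the later phases (one entry
#' per class, as bin index and Hz).
#'
#' @param curves An `"importance_curves"` object from [mask_sweep()].
#' @param tolerance Passed to [select_important_frequency()].
#' @param provenance Optional named list (e.g. seed, model id) recorded on
#'   the bank.
#' @return An object of class `"frequency_bank"`: a data frame with columns
#'   `class`, `bin`, `hz`, carrying the grid and provenance as attributes.
#' @export
build_frequency_bank <- function(curves, tolerance = 0.005,
                                 provenance = list()) {
  stopifnot(inherits(curves, "importance_curves"), length(curves) > 0L)
  picks <- lapply(curves, select_important_frequency, tolerance = tolerance)
  bank <- data.frame(
    class = vapply(curves, function(cv) cv$class, character(1L)),
    bin = vapply(picks, function(p) p$bin, integer(1L)),
    hz = vapply(picks, function(p) p$hz, numeric(1L)),
    row.names = NULL
  )
  structure(bank, class = c("frequency_bank", "data.frame"),
            grid = curves[[1L]]$grid,
            provenance = c(provenance, list(tolerance = tolerance)))
}

#' Construct a frequency bank directly from known bins
#'
#' Used for planted ground truth in synthetic benchmarks and for loading a
#' persisted bank.
#'
#' @param classes Character vector of class labels.
#' @param bins Integer vector of important bins, one per class.
#' @param grid The [spectrum_grid()] the bins refer to.
#' @return A `"frequency_bank"`.
#' @export
frequency_bank <- function(classes, bins, grid) {
  stopifnot(inherits(grid, "spectrum_grid"),
            length(classes) == length(bins), !anyDuplicated(classes))
  bins <- as.integer(bins)
  if (any(bins < 0L) || any(bins > grid$n_bins - 1L))
    stop("bins must lie in 0 .. n_bins - 1")
  structure(
    data.frame(class = as.character(classes), bin = bins,
               hz = bins * grid$bin_hz, row.names = NULL),
    class = c("frequency_bank", "data.frame"),
    grid = grid, provenance = list()
  )
}

#' Persist / load importance results
#'
#' `write_importance_curves()` writes all curves as a long CSV
#' (`class, bin, hz, accuracy`, with bin 0 rows holding each class's
#' baseline). `write_frequency_bank()` / `read_frequency_bank()` persist the
#' bank as a `class, bin, hz` CSV.
#'
#' @param curves An `"importance_curves"`.
#' @param path Output CSV path.
#' @export
write_importance_curves <- function(curves, path) {
  stopifnot(inherits(curves, "importance_curves"))
  grid <- curves[[1L]]$grid
  rows <- do.call(rbind, lapply(curves, function(cv) {
    bins <- c(0L, as.integer(names(cv$acc_by_bin)))
    data.frame(class = cv$class, bin = bins, hz = bins * grid$bin_hz,
               accuracy = c(cv$baseline_acc, unname(cv$acc_by_bin)))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_importance_curves
#' @param bank A `"frequency_bank"`.
#' @export
write_frequency_bank <- function(bank, path) {
  stopifnot(inherits(bank, "frequency_bank"))
  utils::write.csv(as.data.frame(bank), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_importance_curves
#' @param grid The [spectrum_grid()] the stored bins refer to.
#' @export
read_frequency_bank <- function(path, grid) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  frequency_bank(df$class, df$bin, grid)
}
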