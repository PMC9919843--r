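#' Build the emphasis filter for one class from the frequency bank
#'
#' @param grid A [spectrum_grid()].
#' @param bin Important bin of the class.
#' @param filter_kind One of `"peak"`, `"gaussian"`, `"triangular"`,
#'   `"random"`.
#' @param filter_opts Optional list: `sigma_bins` (Gaussian, default 10),
#'   `half_width_bins` (triangular, default spans to the farther spectrum
#'   edge), `floor` (default 0.5), `cutoff_hz` and `rng_seed` (random).
#' @return A [gain_profile].
#' @export
class_filter <- function(grid, bin,
                         filter_kind = c("peak", "gaussian", "triangular",
                                         "random"),
                         filter_opts = list()) {
  filter_kind <- match.arg(filter_kind)
  fo <- filter_opts
  floor <- fo$floor %||% 0.5
  switch(filter_kind,
    peak = make_peak_profile(grid, bin, floor = floor),
    gaussian = make_gaussian_profile(grid, bin,
                                     sigma_bins = fo$sigma_bins %||% 10,
                                     floor = floor),
    triangular = make_triangular_profile(grid, bin,
                                         half_width_bins =
                                           fo$half_width_bins,
                                         floor = floor),
    random = make_random_profile(grid,
                                 cutoff_hz = fo$cutoff_hz %||%
                                   min(7.8, grid$fs / 2),
                                 rng_seed = fo$rng_seed %||%
                                   stop("random filter needs filter_opts$rng_seed"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the per-class model ensemble (Phase 2)
#'
#' Trains one classifier per activity class. With `use_DA = TRUE` each
#' branch's training windows are first passed through that class's emphasis
#' filter (built from the frequency bank), so branch `c` specializes in the
#' band important for class `c`. With `use_DA = FALSE` every branch trains
#' on the original windows and ensemble diversity comes from seed-varied
#' initialization only. Random filters are drawn once per branch (seed
#' recorded in the profile) and reused at test time by that branch.
#'
#' @param split A `"dataset_split"` from [split_by_subject()] (training
#'   windows are used; validation windows feed the metrics log).
#' @param bank A `"frequency_bank"` covering every class in the split.
#' @param filter_kind Emphasis filter family; see [class_filter()].
#' @param train_cfg A [train_config()]; branch `i` trains under seed
#'   `branch_seeds[i]`.
#' @param model_cfg A [model_config()] shared by all branches.
#' @param use_DA Apply the per-class filter to training data (default TRUE).
#' @param filter_opts Passed to [class_filter()].
#' @param branch_seeds Integer vector of per-branch training seeds (default
#'   `train_cfg$seed + 0:(|C|-1)`).
#' @return An object of class `"ensemble_set"`: `members` (list of
#'   `class`, `profile`, `model`, `seed`), `filter_kind`, `bank`,
#'   `class_set`.
#' @export
train_ensemble <- function(split, bank, filter_kind = "gaussian",
                           train_cfg = train_config(), model_cfg,
                           use_DA = TRUE, filter_opts = list(),
                           branch_seeds = NULL) {
  stopifnot(inherits(split, "dataset_split"),
            inherits(bank, "frequency_bank"),
            inherits(model_cfg, "model_config"))
  classes <- split$class_set
  missing_cls <- setdiff(classes, bank$class)
  if (length(missing_cls) > 0L)
    stop(sprintf("frequency bank lacks class(es): %s",
                 paste(missing_cls, collapse = ", ")))
  if (is.null(branch_seeds))
    branch_seeds <- train_cfg$seed + seq_along(classes) - 1L
  stopifnot(length(branch_seeds) == length(classes))
  grid <- window_grid(split$train)

  members <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    fo <- filter_opts
    if (filter_kind == "random" && is.null(fo$rng_seed))
      fo$rng_seed <- branch_seeds[i] * 131L + i
    prof <- class_filter(grid, bank$bin[bank$class == cl], filter_kind, fo)
    tr <- if (use_DA) apply_profile(split$train, prof) else split$train
    cfg_i <- train_cfg
    cfg_i$seed <- as.integer(branch_seeds[i])
    model <- build_model(model_cfg, class_set = classes,
                         init_seed = branch_seeds[i])
    model <- train_model(model, tr, cfg_i)
    members[[i]] <- list(class = cl, profile = prof, model = model,
                        seed = branch_seeds[i])
  }
  structure(
    list(members = members, filter_kind = filter_kind, bank = bank,
         class_set = classes, use_DA = isTRUE(use_DA)),
    class = "ensemble_set"
  )
}

#' @export
print.ensemble_set <- function(x, ...) {
  cat(sprintf(
    "<ensemble_set> %d members (%s filters%s); classes: %s\n",
    length(x$members), x$filter_kind,
    if (x$use_DA) ", trained on filtered data" else ", trained on raw data",
    paste(x$class_set, collapse = ", ")))
  invisible(x)
}

#' Majority voting over member predictions
#'
#' Returns the most frequent label among the votes. Ties are broken toward
#' the tied label whose voters have the highest mean winning score (the
#' probability each voter assigned to its own argmax); a residual tie goes
#' to the lowest class index. Deterministic and auditable.
#'
#' @param votes A list with one element per voter: `list(label =, scores =)`
#'   where `scores` is the voter's named probability vector over classes.
#' @param class_set Optional ordered class labels fixing the tie-break
#'   index order (default: the score names of the first vote).
#' @return The winning label (character scalar).
#' @examples
#' v <- function(l, p) list(label = l, scores = p)
#' s <- c(a = 0.6, b = 0.4)
#' majority_vote(list(v("a", s), v("a", s), v("b", rev(s))))  # "a"
#' @export
majority_vote <- function(votes, class_set = NULL) {
  stopifnot(is.list(votes), length(votes) >= 1L)
  if (is.null(class_set)) class_set <- names(votes[[1L]]$scores)
  labels <- vapply(votes, function(v) as.character(v$label), character(1L))
  winning <- vapply(votes, function(v) max(v$scores), numeric(1L))
  majority_vote_core(labels, winning, class_set)
}

# labels, winning: length-m vectors for one window.
majority_vote_core <- function(labels, winning, class_set) {
  counts <- vapply(class_set, function(c) sum(labels == c), integer(1L))
  top <- class_set[counts == max(counts)]
  if (length(top) == 1L) return(top)
  mean_win <- vapply(top, function(c) mean(winning[labels == c]),
                     numeric(1L))
  top <- top[mean_win == max(mean_win)]
  top[1L]                                     # lowest class index
}

#' Ensemble prediction with test-time filtered augmentation (Phase 3)
#'
#' Each ensemble member votes with its argmax label; with `use_TTA = TRUE`
#' a member sees the test windows passed through its own class's emphasis
#' filter first, otherwise the original windows. The final label per window
#' is the majority vote ([majority_vote()] tie-break). The full vote record
#' (per-member labels and probability vectors) is returned so any reported
#' accuracy can be recomputed from it.
#'
#' @param ens An `"ensemble_set"`.
#' @param windows Test [window_set()].
#' @param use_TTA Apply each member's filter to the test input (default
#'   TRUE).
#' @return An object of class `"ensemble_prediction"`: `class` (majority
#'   labels, length n), `member_labels` (n x m), `member_winning` (n x m),
#'   `member_prob` (n x K x m array), `class_set`.
#' @export
predict_ensemble <- function(ens, windows, use_TTA = TRUE) {
  stopifnot(inherits(ens, "ensemble_set"), inherits(windows, "window_set"))
  if (length(ens$members) == 0L) stop("empty ensemble")
  vote_over_inputs(
    models = lapply(ens$members, `[[`, "model"),
    inputs = lapply(ens$members, function(m)
      if (use_TTA) apply_profile(windows, m$profile) else windows),
    class_set = ens$class_set
  )
}

#' Single-model test-time augmentation
#'
#' One trained model makes `|C|` predictions, each on the test windows
#' passed through a different class's emphasis filter, and the predictions
#' are combined by the same majority vote as [predict_ensemble()]. This is
#' the TTA-without-ensembling configuration.
#'
#' @param model A trained `"har_cnn"`.
#' @param windows Test [window_set()].
#' @param bank A `"frequency_bank"` (one filter per class).
#' @param filter_kind,filter_opts See [class_filter()].
#' @return An `"ensemble_prediction"` (one vote per class filter).
#' @export
predict_single_tta <- function(model, windows, bank,
                               filter_kind = "gaussian",
                               filter_opts = list()) {
  stopifnot(inherits(model, "har_cnn"), inherits(bank, "frequency_bank"))
  grid <- window_grid(windows)
  profs <- lapply(seq_len(nrow(bank)), function(i) {
    fo <- filter_opts
    if (filter_kind == "random" && is.null(fo$rng_seed))
      fo$rng_seed <- 977L + i
    class_filter(grid, bank$bin[i], filter_kind, fo)
  })
  vote_over_inputs(
    models = rep(list(model), nrow(bank)),
    inputs = lapply(profs, function(p) apply_profile(windows, p)),
    class_set = model$class_set
  )
}

vote_over_inputs <- function(models, inputs, class_set) {
  m <- length(models)
  n <- n_windows(inputs[[1L]])
  K <- length(class_set)
  member_prob <- array(NA_real_, dim = c(n, K, m),
                       dimnames = list(NULL, class_set, NULL))
  member_labels <- matrix(NA_character_, n, m)
  for (i in seq_len(m)) {
    p <- predict(models[[i]], inputs[[i]], type = "prob")
    member_prob[, , i] <- p
    member_labels[, i] <- class_set[max.col(p, ties.method = "first")]
  }
  member_winning <- apply(member_prob, c(1L, 3L), max)
  if (n == 1L) {
    member_winning <- matrix(member_winning, 1L, m)
  }
  final <- vapply(seq_len(n), function(r)
    majority_vote_core(member_labels[r, ], member_winning[r, ], class_set),
    character(1L))
  structure(
    list(class = final, member_labels = member_labels,
         member_winning = member_winning, member_prob = member_prob,
         class_set = class_set),
    class = "ensemble_prediction"
  )
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat(sprintf("<ensemble_prediction> %d windows, %d voters, %d classes\n",
              length(x$class), ncol(x$member_labels), length(x$class_set)))
  invisible(x)
}

#' The eight ablation configurations
#'
#' The three components of the method -- DA (per-class emphasis filters on
#' training data), TTA (emphasis filters on test data) and EL (one model per
#' class combined by majority vote) -- give eight on/off combinations,
#' labeled (a) through (h): (a) all three, (h) a plain single model.
#'
#' @return Data frame with columns `label`, `DA`, `TTA`, `EL`.
#' @export
ablation_configs <- function() {
  data.frame(
    label = letters[1:8],
    DA  = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    TTA = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    EL  = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  )
}

#' Run the DA/TTA/EL ablation study
#'
#' Evaluates any subset of the eight configurations of [ablation_configs()]
#' on a split's test windows, repeated over seeds. Within a seed, models are
#' shared between configurations that train identically (e.g. (a)/(c) share
#' the DA ensemble, (f)/(h) the plain single model); single-model DA
#' configurations ((b)/(d)) train one model on the union of all per-class
#' filtered copies of the training set. The metric is overall accuracy, the
#' fraction of test windows whose final label is correct.
#'
#' @param split A `"dataset_split"`.
#' @param bank A `"frequency_bank"`.
#' @param filter_kind,filter_opts See [class_filter()].
#' @param configs Character vector of configuration labels (subset of
#'   `letters[1:8]`, default all).
#' @param seeds Integer vector of seeds; each seed retrains everything.
#' @param train_cfg A [train_config()] (its `seed` field is replaced by
#'   each element of `seeds`).
#' @param model_cfg A [model_config()].
#' @return Data frame (`config`, `DA`, `TTA`, `EL`, `seed`, `accuracy`)
#'   with a `summary` attribute of per-config means and standard
#'   deviations; class `"ablation_result"`.
#' @export
run_ablation <- function(split, bank, filter_kind = "gaussian",
                         configs = letters[1:8], seeds = 1:3,
                         train_cfg = train_config(), model_cfg,
                         filter_opts = list()) {
  tab <- ablation_configs()
  unknown <- setdiff(configs, tab$label)
  if (length(unknown) > 0L)
    stop(sprintf("unknown ablation config label(s): %s",
                 paste(unknown, collapse = ", ")))
  tab <- tab[tab$label %in% configs, , drop = FALSE]
  truth <- split$test$labels
  grid <- window_grid(split$train)

  rows <- list()
  for (seed in seeds) {
    cfg_s <- train_cfg
    cfg_s$seed <- as.integer(seed)
    cache <- new.env(parent = emptyenv())

    get_ensemble <- function(use_DA) {
      key <- paste0("ens_", use_DA)
      if (!exists(key, envir = cache, inherits = FALSE))
        cache[[key]] <- train_ensemble(split, bank, filter_kind, cfg_s,
                                       model_cfg, use_DA = use_DA,
                                       filter_opts = filter_opts)
      cache[[key]]
    }
    get_single <- function(use_DA) {
      key <- paste0("single_", use_DA)
      if (!exists(key, envir = cache, inherits = FALSE)) {
        tr <- split$train
        if (use_DA) {
          copies <- lapply(seq_len(nrow(bank)), function(i) {
            fo <- filter_opts
            if (filter_kind == "random" && is.null(fo$rng_seed))
              fo$rng_seed <- seed * 131L + i
            apply_profile(split$train,
                          class_filter(grid, bank$bin[i], filter_kind, fo))
          })
          tr <- bind_windows(copies)
        }
        model <- build_model(model_cfg, class_set = split$class_set,
                             init_seed = seed)
        cache[[key]] <- train_model(model, tr, cfg_s)
      }
      cache[[key]]
    }

    for (r in seq_len(nrow(tab))) {
      DA <- tab$DA[r]; TTA <- tab$TTA[r]; EL <- tab$EL[r]
      pred <- if (EL) {
        predict_ensemble(get_ensemble(DA), split$test, use_TTA = TTA)$class
      } else if (TTA) {
        predict_single_tta(get_single(DA), split$test, bank, filter_kind,
                           filter_opts)$class
      } else {
        predict(get_single(DA), split$test, type = "class")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        config = tab$label[r], DA = DA, TTA = TTA, EL = EL,
        seed = seed, accuracy = mean(pred == truth))
    }
  }
  res <- do.call(rbind, rows)
  agg <- stats::aggregate(accuracy ~ config, data = res,
                          FUN = function(a) c(mean = mean(a),
                                              sd = stats::sd(a)))
  summ <- data.frame(config = agg$config,
                     mean = agg$accuracy[, "mean"],
                     sd = agg$accuracy[, "sd"])
  structure(res, summary = summ, class = c("ablation_result", "data.frame"))
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("Ablation study (overall test accuracy)\n")
  print.data.frame(attr(x, "summary"), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Compare the four emphasis-filter families
#'
#' Runs the full method (configuration (a): DA + TTA + EL) once per filter
#' family over the given seeds and reports mean overall test accuracy per
#' family. Random-filter runs draw fresh profiles per branch under recorded
#' seeds.
#'
#' @inheritParams run_ablation
#' @param filters Filter families to compare (default all four).
#' @return Data frame (`filter`, `seed`, `accuracy`) with a `summary`
#'   attribute; class `"filter_comparison"`.
#' @export
run_filter_comparison <- function(split, bank, train_cfg = train_config(),
                                  model_cfg, seeds = 1:3,
                                  filters = c("peak", "gaussian",
                                              "triangular", "random"),
                                  filter_opts = list()) {
  filters <- match.arg(filters, several.ok = TRUE)
  rows <- list()
  for (flt in filters) {
    for (seed in seeds) {
      cfg_s <- train_cfg
      cfg_s$seed <- as.integer(seed)
      ens <- train_ensemble(split, bank, flt, cfg_s, model_cfg,
                            use_DA = TRUE, filter_opts = filter_opts)
      pred <- predict_ensemble(ens, split$test, use_TTA = TRUE)$class
      rows[[length(rows) + 1L]] <- data.frame(
        filter = flt, seed = seed,
        accuracy = mean(pred == split$test$labels))
    }
  }
  res <- do.call(rbind, rows)
  agg <- stats::aggregate(accuracy ~ filter, data = res,
                          FUN = function(a) c(mean = mean(a),
                                              sd = stats::sd(a)))
  summ <- data.frame(filter = agg$filter,
                     mean = agg$accuracy[, "mean"],
                     sd = agg$accuracy[, "sd"])
  structure(res, summary = summ,
            class = c("filter_comparison", "data.frame"))
}

#' @export
print.filter_comparison <- function(x, ...) {
  cat("Filter comparison (full method, overall test accuracy)\n")
  print.data.frame(attr(x, "summary"), row.names = FALSE, digits = 3)
  invisible(x)
}
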