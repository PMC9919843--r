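# Small trained fixtures shared by the ensemble tests: a 2-class split with
# strongly separable planted spectra and micro models, trained once.
ens_fixture_env <- new.env(parent = emptyenv())
ens_fixture <- function() {
  if (!exists("fx", envir = ens_fixture_env, inherits = FALSE)) {
    bm <- generate_benchmark(planted_bins = c(3L, 7L),
                             n_subjects = 6L,
                             per_split_subjects = c(3L, 1L, 2L),
                             duration_s = 4, fs = 32, w = 64L,
                             noise_sd = 0.2, seed = 5)
    cfg <- micro_model_config(2, 64L)
    tc <- train_config(batch_size = 8, epochs = 6, seed = 2)
    ens_fixture_env$fx <- list(bm = bm, cfg = cfg, tc = tc)
  }
  ens_fixture_env$fx
}

test_that("the eight ablation configurations reproduce the flag table", {
  tab <- ablation_configs()
  expect_equal(tab$label, letters[1:8])
  expect_equal(tab$DA,  c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(tab$TTA, c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(tab$EL,  c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  # (a) is the full method, (h) the plain single model
  expect_true(all(unlist(tab[tab$label == "a", c("DA", "TTA", "EL")])))
  expect_false(any(unlist(tab[tab$label == "h", c("DA", "TTA", "EL")])))
})

test_that("majority_vote agrees with brute-force counting, exhaustively", {
  # all label patterns for up to 4 voters over up to 4 classes, with
  # deterministic winning scores exercising ties and tie-breaks
  for (K in 2:4) {
    class_set <- letters[1:K]
    for (m in 1:4) {
      patterns <- expand.grid(rep(list(seq_len(K)), m))
      for (r in seq_len(nrow(patterns))) {
        labels <- class_set[as.integer(patterns[r, ])]
        winning <- 0.5 + 0.4 * ((seq_len(m) * 7 + r) %% 5) / 5
        votes <- lapply(seq_len(m), function(i) {
          scores <- rep((1 - winning[i]) / (K - 1), K)
          names(scores) <- class_set
          scores[labels[i]] <- winning[i]
          list(label = labels[i], scores = scores)
        })
        expect_identical(majority_vote(votes, class_set),
                         brute_majority(labels, winning, class_set))
      }
    }
  }
})

test_that("tie-breaks use mean winning score, then lowest class index", {
  cs <- c("A", "B", "C")
  mk <- function(lab, win) {
    s <- rep((1 - win) / 2, 3); names(s) <- cs; s[lab] <- win
    list(label = lab, scores = s)
  }
  # 3-3 tie: B's voters are more confident on average
  expect_equal(majority_vote(list(mk("A", 0.6), mk("A", 0.6), mk("A", 0.6),
                                  mk("B", 0.9), mk("B", 0.9), mk("B", 0.4)),
                             cs), "B")
  # exact residual tie -> lowest class index
  expect_equal(majority_vote(list(mk("B", 0.7), mk("A", 0.7)), cs), "A")
  expect_equal(majority_vote(list(mk("C", 0.8)), cs), "C")
  expect_equal(majority_vote(list(mk("A", 0.5), mk("A", 0.5), mk("B", 0.99)),
                             cs), "A")
})

test_that("train_ensemble yields one filtered member per class", {
  fx <- ens_fixture()
  ens <- train_ensemble(fx$bm$split, fx$bm$bank, "gaussian", fx$tc, fx$cfg)
  expect_s3_class(ens, "ensemble_set")
  expect_length(ens$members, 2L)
  expect_equal(vapply(ens$members, `[[`, character(1), "class"),
               fx$bm$split$class_set)
  for (i in 1:2) {
    mem <- ens$members[[i]]
    expect_equal(mem$profile$kind, "gaussian")
    expect_equal(mem$profile$center_bin,
                 fx$bm$bank$bin[fx$bm$bank$class == mem$class])
    expect_true(mem$model$trained)
  }
  bad_bank <- frequency_bank("other", 3L, fx$bm$grid)
  expect_error(train_ensemble(fx$bm$split, bad_bank, "gaussian", fx$tc,
                              fx$cfg), "lacks class")
})

test_that("without DA and with equal seeds the ensemble collapses to one model", {
  fx <- ens_fixture()
  ens <- train_ensemble(fx$bm$split, fx$bm$bank, "gaussian", fx$tc, fx$cfg,
                        use_DA = FALSE, branch_seeds = c(2L, 2L))
  expect_identical(ens$members[[1]]$model$layers,
                   ens$members[[2]]$model$layers)
  pr <- predict_ensemble(ens, fx$bm$split$test, use_TTA = FALSE)
  single <- predict(ens$members[[1]]$model, fx$bm$split$test, type = "class")
  expect_identical(pr$class, single)

  # distinct seeds -> members differ (diversity from initialization only)
  ens2 <- train_ensemble(fx$bm$split, fx$bm$bank, "gaussian", fx$tc, fx$cfg,
                         use_DA = FALSE)
  expect_false(identical(ens2$members[[1]]$model$layers,
                         ens2$members[[2]]$model$layers))
})

test_that("vote records are complete and reported labels recomputable from them", {
  fx <- ens_fixture()
  ens <- train_ensemble(fx$bm$split, fx$bm$bank, "gaussian", fx$tc, fx$cfg)
  pr <- predict_ensemble(ens, fx$bm$split$test, use_TTA = TRUE)
  n <- n_windows(fx$bm$split$test)
  expect_length(pr$class, n)
  expect_equal(dim(pr$member_labels), c(n, 2L))
  expect_equal(dim(pr$member_prob), c(n, 2L, 2L))
  # audit trail: recompute every final label from the persisted votes
  recomputed <- vapply(seq_len(n), function(r)
    brute_majority(pr$member_labels[r, ], pr$member_winning[r, ],
                   pr$class_set), character(1))
  expect_identical(pr$class, recomputed)
  # per-member probabilities are simplices
  expect_equal(unname(apply(pr$member_prob, c(1, 3), sum)),
               matrix(1, n, 2), tolerance = 1e-6)
})

test_that("single-model TTA votes match an ensemble of model copies", {
  fx <- ens_fixture()
  m <- build_model(fx$cfg, fx$bm$split$class_set, init_seed = 3)
  m <- train_model(m, fx$bm$split$train, fx$tc)
  tta <- predict_single_tta(m, fx$bm$split$test, fx$bm$bank, "gaussian")
  expect_equal(ncol(tta$member_labels), nrow(fx$bm$bank))

  grid <- fx$bm$grid
  copies <- structure(list(
    members = lapply(seq_len(nrow(fx$bm$bank)), function(i) list(
      class = fx$bm$bank$class[i],
      profile = make_gaussian_profile(grid, fx$bm$bank$bin[i]),
      model = m, seed = 3L)),
    filter_kind = "gaussian", bank = fx$bm$bank,
    class_set = fx$bm$split$class_set, use_DA = FALSE),
    class = "ensemble_set")
  ens_pr <- predict_ensemble(copies, fx$bm$split$test, use_TTA = TRUE)
  expect_identical(tta$member_labels, ens_pr$member_labels)
  expect_identical(tta$class, ens_pr$class)

  one <- frequency_bank("stay", 0L, grid)
  m1 <- build_model(micro_model_config(1 + 1, 64L),
                    c("stay", "walk"), init_seed = 1)
  single <- predict_single_tta(m1, fx$bm$split$test[1:2], one, "peak")
  expect_equal(ncol(single$member_labels), 1L)
})

test_that("the ablation harness evaluates requested configs over seeds", {
  fx <- ens_fixture()
  res <- run_ablation(fx$bm$split, fx$bm$bank, "peak",
                      configs = c("a", "f", "h"), seeds = c(1, 2),
                      train_cfg = fx$tc, model_cfg = fx$cfg)
  expect_s3_class(res, "ablation_result")
  expect_equal(nrow(res), 6L)
  expect_setequal(unique(res$config), c("a", "f", "h"))
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  summ <- attr(res, "summary")
  expect_equal(nrow(summ), 3L)
  # flag semantics encoded in the result rows
  expect_true(all(res$EL[res$config == "a"]))
  expect_false(any(res$DA[res$config == "f"]))
  expect_error(run_ablation(fx$bm$split, fx$bm$bank, configs = "z",
                            train_cfg = fx$tc, model_cfg = fx$cfg),
               "unknown ablation config")
})

test_that("the filter comparison reports one row per family and seed", {
  fx <- ens_fixture()
  res <- run_filter_comparison(fx$bm$split, fx$bm$bank, fx$tc, fx$cfg,
                               seeds = 1, filters = c("peak", "random"))
  expect_s3_class(res, "filter_comparison")
  expect_equal(nrow(res), 2L)
  expect_setequal(res$filter, c("peak", "random"))
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  expect_equal(nrow(attr(res, "summary")), 2L)
})
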