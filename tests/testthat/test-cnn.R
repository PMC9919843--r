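test_that("temporal length arithmetic matches the per-block plan", {
  plan <- temporal_length_plan(256, "none")
  expect_equal(tail(plan$length_out, 1), 2L)        # pre-GAP length
  # the per-block checkpoints: conv pairs/triples then pool halving
  pools <- plan$length_out[plan$type == "pool"]
  expect_equal(pools, c(126L, 61L, 27L, 10L, 2L))

  plan_same <- temporal_length_plan(256, "same")
  expect_equal(tail(plan_same$length_out, 1), 8L)   # 256 / 2^5
  expect_true(all(plan_same$length_in[plan_same$type == "conv"] ==
                  plan_same$length_out[plan_same$type == "conv"]))

  expect_error(temporal_length_plan(151, "none"), "block 5")
  expect_error(model_config(4, 151, padding = "none"), "block 5")
  expect_silent(model_config(4, 151, padding = "same"))
})

test_that("length arithmetic agrees with a brute-force simulator, lengths 32..512", {
  for (pad in c("none", "same")) {
    for (len in 32:512) {
      expected <- brute_length_plan(len, pad)
      got <- tryCatch(
        tail(temporal_length_plan(len, pad)$length_out, 1),
        error = function(e) NA_integer_)
      expect_identical(got, expected,
                       info = sprintf("len=%d pad=%s", len, pad))
    }
  }
})

test_that("model construction is seeded and shaped by the config", {
  cfg <- micro_model_config(3, 64)
  m1 <- build_model(cfg, c("a", "b", "c"), init_seed = 5)
  m2 <- build_model(cfg, c("a", "b", "c"), init_seed = 5)
  m3 <- build_model(cfg, c("a", "b", "c"), init_seed = 6)
  expect_identical(m1$layers, m2$layers)
  expect_false(identical(m1$layers, m3$layers))
  convs <- Filter(function(l) l$type == "conv", m1$layers)
  expect_length(convs, 13L)
  expect_equal(sum(vapply(m1$layers, function(l) l$type == "pool",
                          logical(1))), 5L)
  expect_error(build_model(cfg, c("a", "b")), "class_set")
})

test_that("predictions are a probability simplex; zeroed head is uniform", {
  cfg <- micro_model_config(4, 32)
  m <- build_model(cfg, letters[1:4], init_seed = 2)
  set.seed(3)
  ws <- window_set(array(rnorm(3 * 32 * 6), dim = c(3, 32, 6)),
                   rep("a", 6), rep("s", 6), 32)
  p <- predict(m, ws, type = "prob")
  expect_equal(dim(p), c(6L, 4L))
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
  expect_true(all(p > 0))

  # zero the fully-connected head -> logits 0 -> uniform scores
  mz <- m
  fc <- length(mz$layers)
  mz$layers[[fc]]$W[] <- 0
  mz$layers[[fc]]$b[] <- 0
  pz <- predict(mz, ws, type = "prob")
  expect_equal(unname(pz), matrix(0.25, 6, 4), tolerance = 1e-12)

  # argmax labels invariant to a constant shift of all logits
  msh <- m
  msh$layers[[fc]]$b <- msh$layers[[fc]]$b + 3.7
  expect_identical(predict(m, ws, type = "class"),
                   predict(msh, ws, type = "class"))

  short <- window_set(array(rnorm(3 * 16), dim = c(3, 16, 1)),
                      "a", "s", 32)
  expect_error(predict(m, short), "window length")
})

test_that("training is deterministic under a fixed seed and a no-op at 0 epochs", {
  cfg <- micro_model_config(2, 32)
  set.seed(14)
  vals <- array(rnorm(3 * 32 * 20), dim = c(3, 32, 20))
  vals[3, , 1:10] <- vals[3, , 1:10] + 2        # class offset
  ws <- window_set(vals, rep(c("a", "b"), each = 10), rep("s", 20), 32)

  m0 <- build_model(cfg, c("a", "b"), init_seed = 1)
  tc <- train_config(batch_size = 8, epochs = 3, seed = 9)
  f1 <- train_model(m0, ws, tc)
  f2 <- train_model(m0, ws, tc)
  expect_identical(f1$metrics, f2$metrics)
  expect_identical(f1$layers, f2$layers)
  expect_equal(nrow(f1$metrics), 3L)

  f0 <- train_model(m0, ws, train_config(epochs = 0, seed = 9))
  expect_identical(f0$layers, m0$layers)
  expect_equal(nrow(f0$metrics), 0L)

  bad <- window_set(vals, rep(c("a", "zz"), each = 10), rep("s", 20), 32)
  expect_error(train_model(m0, bad, tc), "absent from the model's class set")
})

test_that("the tiny model separates two linearly separable classes quickly", {
  # class "hi" oscillates at bin 4 around a raised mean, class "lo" is
  # flat noise: separable by spectrum and by mean
  w <- 64
  set.seed(100)
  n_per <- 24
  vals <- array(rnorm(3 * w * 2 * n_per, sd = 0.2),
                dim = c(3, w, 2 * n_per))
  for (i in seq_len(n_per))
    vals[, , i] <- vals[, , i] + 1 +
      rbind(tone_window(w, 4, phase = runif(1, 0, 2 * pi)),
            tone_window(w, 4, phase = runif(1, 0, 2 * pi)),
            tone_window(w, 4, phase = runif(1, 0, 2 * pi)))
  ws <- window_set(vals, rep(c("hi", "lo"), each = n_per), rep("s", 2 * n_per), w)

  cfg <- model_config(2, w, scale = "tiny", padding = "same")
  m <- build_model(cfg, c("hi", "lo"), init_seed = 1)
  fit <- train_model(m, ws, train_config(batch_size = 8, epochs = 5,
                                         seed = 1))
  expect_gt(tail(fit$metrics$train_acc, 1), 0.95)
  expect_true(fit$trained)
})

test_that("per-epoch metrics are logged and written as CSV", {
  cfg <- micro_model_config(2, 32)
  set.seed(15)
  ws <- window_set(array(rnorm(3 * 32 * 8), dim = c(3, 32, 8)),
                   rep(c("a", "b"), 4), rep("s", 8), 32)
  path <- withr::local_tempfile(fileext = ".csv")
  fit <- train_model(build_model(cfg, c("a", "b")), ws,
                     train_config(batch_size = 4, epochs = 2, seed = 1),
                     valid_windows = ws, metrics_path = path)
  log <- read.csv(path)
  expect_named(log, c("epoch", "loss", "train_acc", "valid_acc"))
  expect_equal(log$epoch, 1:2)
  expect_false(any(is.na(log$valid_acc)))
})
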