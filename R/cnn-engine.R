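# Self-contained 1D CNN engine on base matrix algebra.
#
# Activations live as a matrix of shape (channels, length * batch) with the
# columns of each sample contiguous, so a kernel-3 stride-1 convolution is
# three shifted GEMMs -- the whole engine reduces to BLAS calls plus
# elementwise ops, which keeps desk-scale training in seconds without
# compiled code.

#' Build a 1D VGG-style classifier
#'
#' Instantiates the network described by a [model_config()]: 13 kernel-3
#' convolutions with ReLU (optionally batch-normalized) in five max-pooled
#' blocks, global average pooling, and one fully-connected layer producing
#' class logits. Weights use He initialization under `init_seed`, so two
#' models built with the same configuration and seed are identical.
#'
#' @param cfg A [model_config()].
#' @param class_set Ordered character vector of class labels the model
#'   predicts (length `cfg$n_classes`); defaults to `"1" .. "K"`.
#' @param init_seed Integer seed for weight initialization.
#' @return An object of class `"har_cnn"`.
#' @export
build_model <- function(cfg, class_set = NULL, init_seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  if (is.null(class_set)) class_set <- as.character(seq_len(cfg$n_classes))
  class_set <- as.character(class_set)
  if (length(class_set) != cfg$n_classes || anyDuplicated(class_set))
    stop("`class_set` must hold n_classes distinct labels")
  plan <- temporal_length_plan(cfg$window_len, cfg$padding)

  layers <- with_preserved_seed(init_seed, {
    out <- list()
    cin <- cfg$in_axes
    li <- 0L
    for (r in seq_len(nrow(plan))) {
      if (plan$type[r] == "conv") {
        li <- li + 1L
        cout <- cfg$conv_channels[li]
        sd <- sqrt(2 / (cin * cfg$kernel))
        lay <- list(
          type = "conv", cin = cin, cout = cout,
          block = plan$block[r], layer = plan$layer[r],
          W = lapply(1:3, function(j)
            matrix(stats::rnorm(cout * cin, sd = sd), cout, cin)),
          b = numeric(cout)
        )
        if (cfg$batch_norm) {
          lay$gamma <- rep(1, cout); lay$beta <- numeric(cout)
          lay$run_mean <- numeric(cout); lay$run_var <- rep(1, cout)
        }
        out[[length(out) + 1L]] <- lay
        cin <- cout
      } else {
        out[[length(out) + 1L]] <- list(type = "pool")
      }
    }
    feat <- cin
    out[[length(out) + 1L]] <- list(type = "gap")
    out[[length(out) + 1L]] <- list(
      type = "fc",
      W = matrix(stats::rnorm(cfg$n_classes * feat, sd = sqrt(2 / feat)),
                 cfg$n_classes, feat),
      b = numeric(cfg$n_classes)
    )
    out
  })

  structure(
    list(cfg = cfg, class_set = class_set, layers = layers,
         pre_gap_length = utils::tail(plan$length_out, 1L),
         init_seed = as.integer(init_seed), trained = FALSE,
         metrics = NULL),
    class = "har_cnn"
  )
}

#' @export
print.har_cnn <- function(x, ...) {
  cat(sprintf(
    "<har_cnn> 1D VGG (%s scale, padding %s%s): input 3 x %d -> %d classes [%s]%s\n",
    x$cfg$scale, x$cfg$padding,
    if (x$cfg$batch_norm) ", batch-norm" else "",
    x$cfg$window_len, x$cfg$n_classes,
    paste(x$class_set, collapse = ", "),
    if (x$trained) " (trained)" else " (untrained)"
  ))
  invisible(x)
}

# ---- layer primitives -------------------------------------------------------

conv_fwd <- function(X, L, N, lay, pad_same) {
  cin <- lay$cin
  if (pad_same) {
    Lp <- L + 2L
    Xp <- matrix(0, cin, Lp * N)
    inpos <- rep.int((0:(N - 1L)) * Lp, rep.int(L, N)) + seq_len(L) + 1L
    Xp[, inpos] <- X
    Lo <- L
  } else {
    Xp <- X; Lp <- L; Lo <- L - 2L; inpos <- NULL
  }
  base <- rep.int((0:(N - 1L)) * Lp, rep.int(Lo, N)) + seq_len(Lo)
  out <- lay$W[[1L]] %*% Xp[, base, drop = FALSE] +
         lay$W[[2L]] %*% Xp[, base + 1L, drop = FALSE] +
         lay$W[[3L]] %*% Xp[, base + 2L, drop = FALSE] + lay$b
  list(out = out, Lo = Lo, Xp = Xp, base = base, inpos = inpos)
}

conv_bwd <- function(dOut, lay, cache) {
  dW <- lapply(1:3, function(j)
    tcrossprod(dOut, cache$Xp[, cache$base + (j - 1L), drop = FALSE]))
  db <- rowSums(dOut)
  dXp <- matrix(0, lay$cin, ncol(cache$Xp))
  for (j in 1:3) {
    idx <- cache$base + (j - 1L)
    dXp[, idx] <- dXp[, idx] + crossprod(lay$W[[j]], dOut)
  }
  dX <- if (is.null(cache$inpos)) dXp else dXp[, cache$inpos, drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

bn_fwd <- function(X, lay, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- rowMeans(X)
    xc <- X - mu
    v <- rowMeans(xc * xc)
    run_mean <- (1 - momentum) * lay$run_mean + momentum * mu
    run_var  <- (1 - momentum) * lay$run_var  + momentum * v
  } else {
    mu <- lay$run_mean; v <- lay$run_var
    xc <- X - mu
    run_mean <- lay$run_mean; run_var <- lay$run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = xhat * lay$gamma + lay$beta, xhat = xhat, inv = inv,
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(dOut, lay, cache) {
  m <- ncol(dOut)
  dgamma <- rowSums(dOut * cache$xhat)
  dbeta <- rowSums(dOut)
  dxhat <- dOut * lay$gamma
  dX <- (cache$inv / m) *
    (m * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

pool_fwd <- function(X, L, N) {
  Lo <- L %/% 2L
  ia <- rep.int((0:(N - 1L)) * L, rep.int(Lo, N)) + (2L * seq_len(Lo) - 1L)
  ib <- ia + 1L
  A <- X[, ia, drop = FALSE]; B <- X[, ib, drop = FALSE]
  left <- A >= B
  list(out = ifelse(left, A, B), Lo = Lo, ia = ia, ib = ib, left = left,
       L = L, N = N, cin = nrow(X))
}

pool_bwd <- function(dOut, cache) {
  dX <- matrix(0, cache$cin, cache$L * cache$N)
  dX[, cache$ia] <- dOut * cache$left
  dX[, cache$ib] <- dX[, cache$ib] + dOut * (!cache$left)
  dX
}

gap_fwd <- function(X, L, N) {
  A <- array(X, dim = c(nrow(X), L, N))
  G <- colMeans(aperm(A, c(2L, 1L, 3L)), dims = 1L)   # (channels, N)
  if (is.null(dim(G))) G <- matrix(G, ncol = N)
  list(out = G, L = L, N = N)
}

gap_bwd <- function(dG, cache) {
  dG[, rep(seq_len(cache$N), each = cache$L), drop = FALSE] / cache$L
}

softmax_cols <- function(Z) {
  Z <- Z - matrix(apply(Z, 2L, max), nrow(Z), ncol(Z), byrow = TRUE)
  E <- exp(Z)
  E / matrix(colSums(E), nrow(Z), ncol(Z), byrow = TRUE)
}

# ---- full network forward / backward ---------------------------------------

cnn_forward <- function(model, X, N, training = FALSE) {
  pad_same <- model$cfg$padding == "same"
  L <- model$cfg$window_len
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    lay <- model$layers[[i]]
    if (lay$type == "conv") {
      cf <- conv_fwd(X, L, N, lay, pad_same)
      L <- cf$Lo
      X <- cf$out
      bnc <- NULL
      if (!is.null(lay$gamma)) {
        bnc <- bn_fwd(X, lay, training)
        X <- bnc$out
      }
      mask <- X > 0
      X <- X * mask
      caches[[i]] <- list(conv = cf[c("Xp", "base", "inpos")], bn = bnc,
                          relu = mask)
    } else if (lay$type == "pool") {
      pf <- pool_fwd(X, L, N)
      L <- pf$Lo
      X <- pf$out
      caches[[i]] <- pf
    } else if (lay$type == "gap") {
      gf <- gap_fwd(X, L, N)
      X <- gf$out
      caches[[i]] <- gf
    } else {                                   # fc
      caches[[i]] <- list(input = X)
      X <- lay$W %*% X + lay$b
    }
  }
  list(logits = X, caches = caches)
}

# Backward pass; returns gradients aligned with model$layers.
cnn_backward <- function(model, caches, dlogits) {
  grads <- vector("list", length(model$layers))
  d <- dlogits
  for (i in rev(seq_along(model$layers))) {
    lay <- model$layers[[i]]
    if (lay$type == "fc") {
      grads[[i]] <- list(dW = tcrossprod(d, caches[[i]]$input),
                         db = rowSums(d))
      d <- crossprod(lay$W, d)
    } else if (lay$type == "gap") {
      d <- gap_bwd(d, caches[[i]])
    } else if (lay$type == "pool") {
      d <- pool_bwd(d, caches[[i]])
    } else {                                   # conv (+bn) + relu
      d <- d * caches[[i]]$relu
      g <- list()
      if (!is.null(lay$gamma)) {
        bb <- bn_bwd(d, lay, caches[[i]]$bn)
        d <- bb$dX
        g$dgamma <- bb$dgamma; g$dbeta <- bb$dbeta
      }
      cb <- conv_bwd(d, lay, caches[[i]]$conv)
      d <- cb$dX
      g$dW <- cb$dW; g$db <- cb$db
      grads[[i]] <- g
    }
  }
  grads
}

# ---- Adam -------------------------------------------------------------------

adam_init_like <- function(x) {
  if (is.list(x)) lapply(x, adam_init_like) else x * 0
}

adam_step <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(p)) {
    out <- Map(adam_step, p, g, m, v,
               MoreArgs = list(lr = lr, t = t, b1 = b1, b2 = b2, eps = eps))
    return(list(p = lapply(out, `[[`, "p"),
                m = lapply(out, `[[`, "m"),
                v = lapply(out, `[[`, "v")))
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

# ---- training and prediction ------------------------------------------------

windows_to_input <- function(windows) {
  v <- windows$values
  dim(v) <- c(3L, dim(windows$values)[2L] * dim(windows$values)[3L])
  v
}

#' Train the classifier
#'
#' Minibatch training with Adam on the cross-entropy loss. Windows are
#' shuffled every epoch under the training seed, so a fixed seed, fixed data
#' and fixed hardware give bit-identical results. Training aborts with
#' diagnostics if the loss becomes non-finite. With `epochs = 0` the model
#' is returned unchanged.
#'
#' @param model A [build_model()] classifier.
#' @param windows Training [window_set()]; every label must be in the
#'   model's `class_set`.
#' @param cfg A [train_config()].
#' @param valid_windows Optional validation [window_set()] for the per-epoch
#'   metrics log (and for `select = "best_valid"`).
#' @param select Return the final-epoch model (default) or the epoch with
#'   the best validation accuracy.
#' @param metrics_path Optional CSV path for the per-epoch metrics log
#'   (`epoch, loss, train_acc, valid_acc`).
#' @param verbose Print one line per epoch.
#' @return The trained `"har_cnn"`, with the metrics log in `$metrics`.
#' @export
train_model <- function(model, windows, cfg, valid_windows = NULL,
                        select = c("final", "best_valid"),
                        metrics_path = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "har_cnn"), inherits(windows, "window_set"),
            inherits(cfg, "train_config"))
  select <- match.arg(select)
  if (window_length(windows) != model$cfg$window_len)
    stop("window length does not match the model's input length")
  unknown <- setdiff(unique(windows$labels), model$class_set)
  if (length(unknown) > 0L)
    stop(sprintf("label(s) absent from the model's class set: %s",
                 paste(unknown, collapse = ", ")))
  n <- n_windows(windows)
  if (n == 0L) stop("no training windows")
  if (cfg$epochs == 0L) {
    model$metrics <- data.frame(epoch = integer(0), loss = numeric(0),
                                train_acc = numeric(0),
                                valid_acc = numeric(0))
    return(model)
  }
  y <- match(windows$labels, model$class_set)
  L <- model$cfg$window_len
  K <- model$cfg$n_classes
  lr <- cfg$learning_rate

  adam_m <- lapply(model$layers, function(l)
    lapply(l[intersect(names(l), c("W", "b", "gamma", "beta"))],
           adam_init_like))
  adam_v <- adam_m
  t_step <- 0L
  metrics <- vector("list", cfg$epochs)
  best <- list(acc = -Inf, model = NULL)

  with_preserved_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0; tot_correct <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        N <- length(idx)
        Xb <- windows_to_input(windows[idx])
        fw <- cnn_forward(model, Xb, N, training = TRUE)
        P <- softmax_cols(fw$logits)
        picked <- P[cbind(y[idx], seq_len(N))]
        loss <- -mean(log(pmax(picked, 1e-12)))
        if (!is.finite(loss))
          stop(sprintf(
            "non-finite loss at epoch %d, batch starting %d (lr %g): training diverged",
            epoch, start, lr))
        tot_loss <- tot_loss + loss * N
        tot_correct <- tot_correct +
          sum(max.col(t(fw$logits), ties.method = "first") == y[idx])

        Y <- matrix(0, K, N)
        Y[cbind(y[idx], seq_len(N))] <- 1
        grads <- cnn_backward(model, fw$caches, (P - Y) / N)

        t_step <- t_step + 1L
        for (i in seq_along(model$layers)) {
          lay <- model$layers[[i]]
          if (lay$type %in% c("pool", "gap")) next
          if (lay$type == "conv" && !is.null(lay$gamma)) {
            # adopt the batch-norm running statistics from this batch
            model$layers[[i]]$run_mean <- fw$caches[[i]]$bn$run_mean
            model$layers[[i]]$run_var  <- fw$caches[[i]]$bn$run_var
          }
          for (fld in intersect(names(adam_m[[i]]),
                                c("W", "b", "gamma", "beta"))) {
            gfld <- paste0("d", fld)
            st <- adam_step(model$layers[[i]][[fld]], grads[[i]][[gfld]],
                            adam_m[[i]][[fld]], adam_v[[i]][[fld]],
                            lr = lr, t = t_step)
            model$layers[[i]][[fld]] <- st$p
            adam_m[[i]][[fld]] <- st$m
            adam_v[[i]][[fld]] <- st$v
          }
        }
      }
      valid_acc <- NA_real_
      if (!is.null(valid_windows) && n_windows(valid_windows) > 0L) {
        pv <- predict(model, valid_windows, type = "class")
        valid_acc <- mean(pv == valid_windows$labels)
        if (select == "best_valid" && valid_acc > best$acc)
          best <- list(acc = valid_acc, model = model)
      }
      metrics[[epoch]] <- data.frame(
        epoch = epoch, loss = tot_loss / n,
        train_acc = tot_correct / n, valid_acc = valid_acc)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  train_acc %.3f  valid_acc %s",
                        epoch, tot_loss / n, tot_correct / n,
                        ifelse(is.na(valid_acc), "-",
                               sprintf("%.3f", valid_acc))))
    }
  })
  metrics <- do.call(rbind, metrics)
  if (select == "best_valid" && !is.null(best$model)) model <- best$model
  model$trained <- TRUE
  model$metrics <- metrics
  model$train_seed <- cfg$seed
  if (!is.null(metrics_path))
    utils::write.csv(metrics, metrics_path, row.names = FALSE)
  model
}

#' Predict activity classes for windows
#'
#' Runs the network in evaluation mode and returns softmax probabilities
#' (each row a probability simplex) and/or argmax labels.
#'
#' @param object A `"har_cnn"`.
#' @param windows A [window_set()] with the model's window length.
#' @param type `"prob"` (n x K matrix), `"class"` (label vector) or
#'   `"both"` (list with `prob` and `class`).
#' @param batch_size Evaluation batch size.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.har_cnn <- function(object, windows, type = c("prob", "class", "both"),
                            batch_size = 256L, ...) {
  type <- match.arg(type)
  stopifnot(inherits(windows, "window_set"))
  if (window_length(windows) != object$cfg$window_len)
    stop("window length does not match the model's input length")
  n <- n_windows(windows)
  K <- object$cfg$n_classes
  prob <- matrix(NA_real_, n, K, dimnames = list(NULL, object$class_set))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    Xb <- windows_to_input(windows[idx])
    fw <- cnn_forward(object, Xb, length(idx), training = FALSE)
    prob[idx, ] <- t(softmax_cols(fw$logits))
  }
  if (type == "prob") return(prob)
  cls <- object$class_set[max.col(prob, ties.method = "first")]
  if (type == "class") cls else list(prob = prob, class = cls)
}
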