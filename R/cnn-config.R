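#' Model configuration for the 1D VGG-style classifier
#'
#' The classifier is a one-dimensional adaptation of VGG16: 13 convolution
#' layers (kernel 3, stride 1) in five blocks of widths
#' `64,64 | 128,128 | 256,256,256 | 512,512,512 | 512,512,512`, each block
#' followed by max pooling of size 2, then a shallow head of global average
#' pooling and a single fully-connected layer. `scale = "tiny"` divides all
#' channel widths by 8, giving a desk-scale model with the same shape used
#' throughout the package's synthetic benchmarks.
#'
#' With `padding = "none"` (the default) each convolution shortens the
#' temporal axis by 2 and each pool halves it (floor), so short windows can
#' exhaust the length budget before the fifth block; `padding = "same"`
#' keeps convolutions length-preserving so only pooling shrinks, which is
#' required for windows much shorter than 256 samples.
#'
#' @param n_classes Number of activity classes (>= 2).
#' @param window_len Temporal length of the input windows, in samples.
#' @param scale `"full"` or `"tiny"` (channel widths / 8).
#' @param padding `"none"` (valid convolutions) or `"same"`.
#' @param batch_norm Add batch normalization after every convolution
#'   (default `FALSE`, faithful to the original VGG16; turn on for training
#'   stability of deep stacks).
#' @param conv_channels Optional explicit 13-vector of channel widths,
#'   overriding `scale`.
#' @return An object of class `"model_config"`.
#' @export
model_config <- function(n_classes, window_len,
                         scale = c("tiny", "full"),
                         padding = c("none", "same"),
                         batch_norm = FALSE,
                         conv_channels = NULL) {
  scale <- match.arg(scale)
  padding <- match.arg(padding)
  stopifnot(n_classes >= 2L, window_len >= 2L)
  base_plan <- c(64L, 64L, 128L, 128L, 256L, 256L, 256L,
                 512L, 512L, 512L, 512L, 512L, 512L)
  if (is.null(conv_channels)) {
    conv_channels <- if (scale == "tiny") base_plan %/% 8L else base_plan
  } else {
    conv_channels <- as.integer(conv_channels)
    if (length(conv_channels) != 13L || any(conv_channels < 1L))
      stop("`conv_channels` must be 13 positive channel widths")
  }
  cfg <- structure(
    list(n_classes = as.integer(n_classes),
         window_len = as.integer(window_len),
         in_axes = 3L, kernel = 3L, stride = 1L, pool = 2L,
         scale = scale, padding = padding, batch_norm = isTRUE(batch_norm),
         conv_channels = conv_channels,
         blocks = c(2L, 2L, 3L, 3L, 3L)),
    class = "model_config"
  )
  # fail fast: the length arithmetic must survive the whole stack
  temporal_length_plan(cfg$window_len, cfg$padding)
  cfg
}

#' Temporal length arithmetic of the convolution stack
#'
#' Traces the temporal length of the signal through the 13 convolutions and
#' 5 pools: with no padding each kernel-3 convolution removes 2 samples and
#' each pool halves (floor); with `"same"` padding only pooling shrinks.
#' Errors as soon as a layer would produce a non-positive length, naming the
#' failing block and layer -- the same check [model_config()] runs at
#' construction.
#'
#' @param window_len Input length in samples.
#' @param padding `"none"` or `"same"`.
#' @return A data frame with one row per layer (`block`, `layer`, `type`,
#'   `length_in`, `length_out`); the last row's `length_out` is the pre-GAP
#'   temporal length.
#' @examples
#' plan <- temporal_length_plan(256, "none")
#' tail(plan$length_out, 1)  # 2
#' @export
temporal_length_plan <- function(window_len, padding = c("none", "same")) {
  padding <- match.arg(padding)
  blocks <- c(2L, 2L, 3L, 3L, 3L)
  len <- as.integer(window_len)
  rows <- list()
  for (b in seq_along(blocks)) {
    for (l in seq_len(blocks[b])) {
      out <- if (padding == "none") len - 2L else len
      rows[[length(rows) + 1L]] <- data.frame(
        block = b, layer = l, type = "conv",
        length_in = len, length_out = out)
      if (out <= 0L)
        stop(sprintf(
          "temporal length exhausted: conv %d of block %d maps length %d to %d (<= 0); use padding = \"same\" for short windows",
          l, b, len, out))
      len <- out
    }
    out <- len %/% 2L
    rows[[length(rows) + 1L]] <- data.frame(
      block = b, layer = NA_integer_, type = "pool",
      length_in = len, length_out = out)
    if (out <= 0L)
      stop(sprintf(
        "temporal length exhausted: pool of block %d maps length %d to %d (<= 0); use padding = \"same\" for short windows",
        b, len, out))
    len <- out
  }
  do.call(rbind, rows)
}

#' Training configuration
#'
#' @param batch_size Minibatch size (default 256).
#' @param learning_rate Adam step size (default 0.001).
#' @param epochs Number of passes over the training windows (default 200;
#'   0 returns the model unchanged).
#' @param optimizer Only `"adam"` is implemented.
#' @param loss Only `"cross_entropy"` is implemented.
#' @param seed Integer seed controlling initialization-independent training
#'   randomness (epoch shuffling); recorded in the metrics log.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(batch_size = 256L, learning_rate = 0.001,
                         epochs = 200L, optimizer = "adam",
                         loss = "cross_entropy", seed = 1L) {
  stopifnot(batch_size >= 1L, learning_rate > 0, epochs >= 0L)
  optimizer <- match.arg(optimizer, "adam")
  loss <- match.arg(loss, "cross_entropy")
  structure(
    list(batch_size = as.integer(batch_size),
         learning_rate = as.numeric(learning_rate),
         epochs = as.integer(epochs),
         optimizer = optimizer, loss = loss, seed = as.integer(seed)),
    class = "train_config"
  )
}
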