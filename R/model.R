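# The six-layer hybrid architecture: trainable nucleotide embedding ->
# 1D convolution (ReLU) -> max pooling -> bidirectional LSTM -> dense
# (ReLU) -> dense (sigmoid), with dropout after the convolution, the
# pooling, the BiLSTM, and between the two dense layers.

#' Describe the hybrid network architecture
#'
#' Returns the complete architecture description. Defaults follow the
#' published configuration: a 5-letter vocabulary embedded in 5 dimensions,
#' 320 convolution kernels of size 12 with ReLU, max pooling, a
#' bidirectional LSTM with 32 hidden units per direction (ReLU output
#' activation, with a tanh fallback flag), a 16-unit ReLU hidden dense
#' layer and a 1-unit sigmoid output. Pool size/stride (2/2), the hidden
#' dense width, the optimizer (Adam) and the loss (binary cross-entropy)
#' are package choices where the published description is silent; all are
#' exposed here.
#'
#' Layer-removal flags (`has_conv`, `has_pool`, `has_rnn`,
#' `has_dense_hidden`, `dropout_active`) support the ablation variants; see
#' [variant_spec()].
#'
#' @param input_len Encoded pair length: 79 under the (26, 53) schema, 66
#'   under the (26, 40) schema.
#' @param vocab_size,embed_dim Embedding vocabulary (5: A,U,G,C,N) and
#'   output dimension (5).
#' @param n_kernels,kernel_size Convolution: number of kernels (320) and
#'   kernel width (12); "valid" boundary mode (no implicit zero padding).
#' @param pool_size,pool_stride Max-pooling window and stride.
#' @param rnn_units BiLSTM hidden units per direction (32); the two
#'   directions are concatenated and the final time-step state feeds the
#'   dense head.
#' @param rnn_activation `"relu"` (as published) or `"tanh"` for the cell
#'   output nonlinearity.
#' @param dense_hidden_units Width of the hidden dense layer.
#' @param dropout_rate Dropout probability applied at the four sites.
#' @param has_conv,has_pool,has_rnn,has_dense_hidden,dropout_active
#'   Structural flags used by the ablation harness.
#' @return A `model_spec` object.
#' @examples
#' spec <- model_spec(input_len = 79)
#' count_params(build_model(spec, seed = 1))
#' @export
model_spec <- function(input_len,
                       vocab_size = 5L, embed_dim = 5L,
                       n_kernels = 320L, kernel_size = 12L,
                       pool_size = 2L, pool_stride = 2L,
                       rnn_units = 32L, rnn_activation = c("relu", "tanh"),
                       dense_hidden_units = 16L,
                       dropout_rate = 0.2,
                       has_conv = TRUE, has_pool = TRUE, has_rnn = TRUE,
                       has_dense_hidden = TRUE, dropout_active = TRUE) {
  rnn_activation <- match.arg(rnn_activation)
  stopifnot(input_len >= 1L, vocab_size >= 2L, embed_dim >= 1L,
            n_kernels >= 1L, kernel_size >= 1L, pool_size >= 1L,
            pool_stride >= 1L, rnn_units >= 1L, dense_hidden_units >= 1L,
            dropout_rate > 0, dropout_rate < 1)
  if (has_pool && !has_conv) {
    stop("pooling without a convolution layer is not a supported variant",
         call. = FALSE)
  }
  spec <- structure(list(
    input_len = as.integer(input_len), vocab_size = as.integer(vocab_size),
    embed_dim = as.integer(embed_dim), n_kernels = as.integer(n_kernels),
    kernel_size = as.integer(kernel_size), pool_size = as.integer(pool_size),
    pool_stride = as.integer(pool_stride), rnn_units = as.integer(rnn_units),
    rnn_activation = rnn_activation,
    dense_hidden_units = as.integer(dense_hidden_units),
    dropout_rate = dropout_rate,
    has_conv = has_conv, has_pool = has_pool, has_rnn = has_rnn,
    has_dense_hidden = has_dense_hidden, dropout_active = dropout_active),
    class = "model_spec")
  sh <- model_shapes(spec)  # validates pool_size vs conv output length
  if (sh$conv_out_len < 1L || (has_pool && sh$pooled_len < 1L)) {
    stop("invalid spec: layer output would be empty for this input length",
         call. = FALSE)
  }
  spec
}

#' Derived layer shapes for a spec
#'
#' Convolution output length under "valid" mode is
#' `input_len - kernel_size + 1`; pooled length is
#' `floor((conv_len - pool_size)/pool_stride) + 1`.
#'
#' @param spec A `model_spec`.
#' @return List: conv_out_len, pooled_len, rnn_steps, rnn_in_dim, feat_dim.
#' @export
model_shapes <- function(spec) {
  conv_out_len <- if (spec$has_conv) spec$input_len - spec$kernel_size + 1L
                  else spec$input_len
  pooled_len <- if (spec$has_pool)
    (conv_out_len - spec$pool_size) %/% spec$pool_stride + 1L
  else conv_out_len
  rnn_in_dim <- if (spec$has_conv) spec$n_kernels else spec$embed_dim
  feat_dim <- if (spec$has_rnn) 2L * spec$rnn_units
              else pooled_len * rnn_in_dim
  list(conv_out_len = conv_out_len, pooled_len = pooled_len,
       rnn_steps = pooled_len, rnn_in_dim = rnn_in_dim, feat_dim = feat_dim)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Instantiate a trainable model from a spec
#'
#' Initializes all weights (uniform(-0.05, 0.05) embedding, Glorot-uniform
#' matrices, zero biases with the LSTM forget-gate bias at 1) and returns a
#' model handle whose forward pass maps encoded pairs to probabilities.
#'
#' @param spec A [model_spec()].
#' @param schema Optional [pair_schema()] recorded on the model so scanning
#'   and prediction know the slot layout; its total length must equal
#'   `spec$input_len`.
#' @param seed Optional integer; when given, initialization is a pure
#'   function of it.
#' @return An object of class `mirtar_model` (spec + weights + schema).
#' @export
build_model <- function(spec, schema = NULL, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(schema)) {
    stopifnot(inherits(schema, "pair_schema"))
    if (schema$total_len != spec$input_len) {
      stop(sprintf("schema total length %d != spec input_len %d",
                   schema$total_len, spec$input_len), call. = FALSE)
    }
  }
  init <- function() {
    # Near-one-hot embedding start when the dimensions permit: with
    # embed_dim == vocab_size the embedding can begin as the identity (one
    # letter -> one channel) plus noise, which gives the convolution
    # usable signal from the first epoch; a tiny uniform start leaves the
    # six-layer stack on a seed-dependent plateau (see vignette).
    E0 <- if (spec$embed_dim == spec$vocab_size) {
      diag(spec$vocab_size) +
        matrix(stats::rnorm(spec$vocab_size * spec$embed_dim, 0, 0.05),
               spec$vocab_size, spec$embed_dim)
    } else {
      matrix(stats::runif(spec$vocab_size * spec$embed_dim, -0.05, 0.05),
             spec$vocab_size, spec$embed_dim)
    }
    w <- list(E = E0)
    sh <- model_shapes(spec)
    if (spec$has_conv) {
      w$Wc <- glorot(spec$kernel_size * spec$embed_dim, spec$n_kernels)
      w$bc <- numeric(spec$n_kernels)
    }
    if (spec$has_rnn) {
      H <- spec$rnn_units
      fb <- rep(c(0, 1, 0, 0), each = H)  # forget-gate bias 1
      w$Wf <- glorot(sh$rnn_in_dim, 4L * H); w$Vf <- glorot(H, 4L * H)
      w$bf <- fb
      w$Wb <- glorot(sh$rnn_in_dim, 4L * H); w$Vb <- glorot(H, 4L * H)
      w$bb <- fb
    }
    if (spec$has_dense_hidden) {
      w$W1 <- glorot(sh$feat_dim, spec$dense_hidden_units)
      w$b1 <- numeric(spec$dense_hidden_units)
      w$W2 <- glorot(spec$dense_hidden_units, 1L)
    } else {
      w$W2 <- glorot(sh$feat_dim, 1L)
    }
    w$b2 <- 0
    w
  }
  weights <- if (is.null(seed)) init() else with_seed(seed, init())
  model <- structure(list(spec = spec, weights = weights, schema = schema),
                     class = "mirtar_model")
  if (spec$has_conv) {
    model$colidx <- conv_col_index(spec$input_len, spec$kernel_size,
                                   spec$embed_dim)
  }
  model
}

#' @export
print.mirtar_model <- function(x, ...) {
  s <- x$spec; sh <- model_shapes(s)
  layers <- c("embedding(5x5)",
              if (s$has_conv) sprintf("conv1d(%d kernels x %d, relu)",
                                      s$n_kernels, s$kernel_size),
              if (s$has_pool) sprintf("maxpool(%d/%d)", s$pool_size,
                                      s$pool_stride),
              if (s$has_rnn) sprintf("bilstm(%d x 2, %s)", s$rnn_units,
                                     s$rnn_activation),
              if (s$has_dense_hidden) sprintf("dense(%d, relu)",
                                              s$dense_hidden_units),
              "dense(1, sigmoid)")
  cat(sprintf("<mirtar_model> input %d nt -> %s\n  %s params; dropout %s\n",
              s$input_len, paste(layers, collapse = " -> "),
              format(count_params(x), big.mark = ","),
              if (s$dropout_active) format(s$dropout_rate) else "off"))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model A `mirtar_model` (or a `model_spec`, which is instantiated
#'   without randomness just to count).
#' @return Integer total, with a per-tensor breakdown in
#'   `attr(, "by_tensor")`.
#' @export
count_params <- function(model) {
  if (inherits(model, "model_spec")) model <- build_model(model, seed = 0L)
  by_tensor <- vapply(model$weights, length, integer(1))
  structure(sum(by_tensor), by_tensor = by_tensor)
}

#' Run the forward pass on a batch of encoded pairs
#'
#' Inference mode (dropout off): a pure function of the weights and the
#' input, so repeated calls on the same batch are bitwise identical.
#'
#' @param model A `mirtar_model`.
#' @param x Integer code matrix (rows = pairs, `input_len` columns, values
#'   0..4), as produced by [encode_dataset()].
#' @param batch_size Internal evaluation batch size (memory control only).
#' @return Numeric vector of probabilities, one per row.
#' @export
forward <- function(model, x, batch_size = 512L) {
  stopifnot(inherits(model, "mirtar_model"), is.matrix(x))
  n <- nrow(x)
  out <- numeric(n)
  for (from in seq(1L, n, by = batch_size)) {
    to <- min(from + batch_size - 1L, n)
    out[from:to] <- nn_forward(model, x[from:to, , drop = FALSE],
                               training = FALSE)$prob
  }
  out
}

#' Predict target probabilities for a pair table
#'
#' @param object A `mirtar_model` carrying a `pair_schema`.
#' @param pairs Data frame with `mirna_seq` and `site_seq` columns (label
#'   optional).
#' @param ... Unused.
#' @return Numeric probability vector.
#' @export
predict.mirtar_model <- function(object, pairs, ...) {
  if (is.null(object$schema)) {
    stop("model has no pair schema attached; rebuild with build_model(schema=)",
         call. = FALSE)
  }
  if (!"label" %in% names(pairs)) pairs$label <- 0L
  enc <- encode_dataset(pairs, object$schema)
  forward(object, enc$x)
}

#' Save / load a model artifact
#'
#' One versioned file holding the weights, the architecture spec and the
#' codec schema.
#'
#' @param model A `mirtar_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mirtar_model"))
  obj <- list(format = "mirtarnet-model", version = 1L,
              spec = model$spec, schema = model$schema,
              weights = model$weights)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "mirtarnet-model")) {
    stop(sprintf("%s is not a mirtarnet model artifact", path), call. = FALSE)
  }
  model <- structure(list(spec = obj$spec, weights = obj$weights,
                          schema = obj$schema), class = "mirtar_model")
  if (obj$spec$has_conv) {
    model$colidx <- conv_col_index(obj$spec$input_len, obj$spec$kernel_size,
                                   obj$spec$embed_dim)
  }
  model
}
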