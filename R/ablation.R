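# Layer-removal ablation: build architecture variants with one component
# removed while keeping everything else the same, and compare repeated-run
# accuracies against the full model on seed-matched splits.

ABLATION_COMPONENTS <- c("max_pool", "cnn_and_pool", "rnn", "dense_hidden",
                         "dropouts")

#' Derive a layer-removal variant of an architecture
#'
#' Removal semantics, shapes reconciled per the base spec with everything
#' else unchanged:
#' \describe{
#'   \item{max_pool}{convolution output feeds the BiLSTM directly}
#'   \item{cnn_and_pool}{the embedding output feeds the BiLSTM directly}
#'   \item{rnn}{the (pooled) feature map is flattened into the dense head}
#'   \item{dense_hidden}{the feature vector feeds the sigmoid unit
#'     directly}
#'   \item{dropouts}{all four dropout sites disabled}
#' }
#'
#' @param base A [model_spec()] (the full model).
#' @param removed Non-empty character vector over the component names
#'   above.
#' @return A `model_spec` for the variant.
#' @export
variant_spec <- function(base, removed) {
  stopifnot(inherits(base, "model_spec"), length(removed) >= 1L)
  bad <- setdiff(removed, ABLATION_COMPONENTS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown component(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  s <- base
  if ("max_pool" %in% removed) s$has_pool <- FALSE
  if ("cnn_and_pool" %in% removed) { s$has_conv <- FALSE; s$has_pool <- FALSE }
  if ("rnn" %in% removed) s$has_rnn <- FALSE
  if ("dense_hidden" %in% removed) s$has_dense_hidden <- FALSE
  if ("dropouts" %in% removed) s$dropout_active <- FALSE
  if (!s$has_conv && !s$has_rnn && !s$has_dense_hidden) {
    stop("invalid variant: no trainable layer left between embedding and output",
         call. = FALSE)
  }
  # revalidate through the constructor so shape checks run
  do.call(model_spec, unclass(s))
}

#' Build the model for a variant
#'
#' @param base Full-model [model_spec()].
#' @param removed Components to remove; see [variant_spec()].
#' @param schema,seed Passed to [build_model()].
#' @return A `mirtar_model`.
#' @export
build_variant <- function(base, removed, schema = NULL, seed = NULL) {
  build_model(variant_spec(base, removed), schema = schema, seed = seed)
}

#' Compare the full model against layer-removal variants
#'
#' Trains the full model and each variant over the same `n_repeats`
#' seed-matched random re-splits (identical splits and seeds across
#' variants, so accuracy deltas reflect architecture only) and tabulates
#' mean test accuracy, its percentile interval and the delta versus the
#' full model.
#'
#' @param pairs Pair table.
#' @param schema [pair_schema()].
#' @param base Full-model [model_spec()].
#' @param variants Named list of removal sets, e.g.
#'   `list(noMP = "max_pool", noCNN = "cnn_and_pool")`.
#' @param n_repeats Re-splits per variant.
#' @param lr,dropout,batch_size Training hyperparameters (shared across
#'   variants, mirroring the keep-everything-else-the-same protocol).
#' @param rule [early_stop_rule()].
#' @param max_epochs Epoch cap.
#' @param master_seed Seed deriving the shared per-repeat seeds.
#' @return List: `table` (one row per variant: mean_accuracy, ci, delta
#'   vs full), `accuracies` (per-variant per-repeat matrix).
#' @export
compare_variants <- function(pairs, schema, base = NULL,
                             variants = list(noMP = "max_pool",
                                             noCNNMP = "cnn_and_pool"),
                             n_repeats = 5L, lr = 0.005, dropout = 0.2,
                             batch_size = 30L, rule = early_stop_rule(),
                             max_epochs = 1000L, master_seed = 1L) {
  if (is.null(base)) base <- model_spec(input_len = schema$total_len)
  stopifnot(n_repeats >= 1L, length(variants) >= 1L)
  specs <- c(list(full = base),
             lapply(variants, function(rm) variant_spec(base, rm)))
  seeds <- with_seed(master_seed,
                     matrix(sample.int(.Machine$integer.max - 1L,
                                       2L * n_repeats), ncol = 2L))
  acc <- matrix(NA_real_, nrow = n_repeats, ncol = length(specs),
                dimnames = list(NULL, names(specs)))
  for (r in seq_len(n_repeats)) {
    sp <- split_spec(seed = seeds[r, 1L])
    splits <- split_dataset(pairs, sp)
    for (v in names(specs)) {
      rec <- train_once(splits, schema, spec = specs[[v]], lr = lr,
                        dropout = dropout, batch_size = batch_size,
                        rule = rule, max_epochs = max_epochs,
                        seed = seeds[r, 2L])
      acc[r, v] <- rec$test_metrics[["accuracy"]]
    }
  }
  means <- colMeans(acc)
  cis <- if (n_repeats >= 2L) apply(acc, 2L, percentile_ci) else
    rbind(ci_low = means, ci_high = means)
  tab <- data.frame(variant = names(specs),
                    removed = c("", vapply(variants, paste, character(1),
                                           collapse = "+")),
                    params = vapply(specs, function(s)
                      as.integer(count_params(s)), integer(1)),
                    mean_accuracy = means,
                    ci_low = cis["ci_low", ], ci_high = cis["ci_high", ],
                    delta_vs_full = means - means[["full"]],
                    row.names = NULL)
  list(table = tab, accuracies = acc,
       seeds = data.frame(repeat_ = seq_len(n_repeats),
                          split_seed = seeds[, 1L], train_seed = seeds[, 2L]))
}
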