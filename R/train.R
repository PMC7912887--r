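# Training harness: stratified splitting, minibatch Adam with early
# stopping on validation accuracy, hyperparameter grid search, repeated
# random re-splits, and the two-source unified-dataset composition.

#' Dataset split specification
#'
#' Default fractions 64% train / 16% validation / 20% test.
#'
#' @param train_frac,val_frac,test_frac Fractions summing to 1.
#' @param seed Integer seed making the partition deterministic.
#' @return A `split_spec` object.
#' @export
split_spec <- function(train_frac = 0.64, val_frac = 0.16, test_frac = 0.20,
                       seed = 1L) {
  stopifnot(abs(train_frac + val_frac + test_frac - 1) < 1e-9,
            train_frac > 0, val_frac > 0, test_frac > 0)
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac, seed = as.integer(seed)),
            class = "split_spec")
}

#' Split-size arithmetic
#'
#' test = round(test_frac * n), val = round(val_frac * n),
#' train = remainder. Applied per label stratum by [split_dataset()].
#'
#' @param n Number of pairs.
#' @param spec A [split_spec()].
#' @return Named integer vector (train, val, test).
#' @export
split_sizes <- function(n, spec = split_spec()) {
  n_test <- round(spec$test_frac * n)
  n_val <- round(spec$val_frac * n)
  n_train <- n - n_test - n_val
  if (n_test < 1L || n_val < 1L || n_train < 1L) {
    stop(sprintf("dataset of %d pairs cannot fill all three splits", n),
         call. = FALSE)
  }
  c(train = n_train, val = n_val, test = n_test)
}

#' Stratified train/validation/test split
#'
#' Splits a pair table into disjoint train/val/test sets, stratified by
#' label so the near-balanced class design is preserved in every split.
#' Sizes follow [split_sizes()] within each stratum; the partition is a
#' pure function of `spec$seed`.
#'
#' @param pairs Pair table (data frame with a `label` column).
#' @param spec A [split_spec()].
#' @return List of data frames: `train`, `val`, `test`.
#' @export
split_dataset <- function(pairs, spec = split_spec()) {
  stopifnot(is.data.frame(pairs), nrow(pairs) > 0L, "label" %in% names(pairs))
  with_seed(spec$seed, {
    idx <- list(train = integer(0), val = integer(0), test = integer(0))
    for (lab in sort(unique(pairs$label))) {
      rows <- which(pairs$label == lab)
      sz <- split_sizes(length(rows), spec)
      rows <- sample(rows)
      idx$test <- c(idx$test, rows[seq_len(sz[["test"]])])
      idx$val <- c(idx$val, rows[sz[["test"]] + seq_len(sz[["val"]])])
      idx$train <- c(idx$train,
                     rows[sz[["test"]] + sz[["val"]] + seq_len(sz[["train"]])])
    }
    lapply(idx, function(i) pairs[sort(i), , drop = FALSE])
  })
}

#' Early-stopping rule
#'
#' Training halts when the monitored validation accuracy has not improved
#' by at least `min_delta` (absolute; default 0.001 = 0.1%) within
#' `patience` epochs. The weights achieving the best validation accuracy
#' are restored on stop.
#'
#' @param min_delta Minimum absolute improvement that resets the counter.
#' @param patience Number of epochs without such improvement before
#'   stopping.
#' @return An `early_stop_rule` object.
#' @export
early_stop_rule <- function(min_delta = 0.001, patience = 100L) {
  stopifnot(min_delta >= 0, patience >= 1L)
  structure(list(min_delta = min_delta, patience = as.integer(patience)),
            class = "early_stop_rule")
}

#' The hyperparameter grid
#'
#' The full published search grid: learning rates
#' \{0.2, 0.1, 0.05, 0.01, 0.005, 0.001\}, dropout rates
#' \{0.1, ..., 0.5\}, batch sizes \{10, 30, 50, 100, 200\}, 1000 epochs
#' maximum. Restrict any axis for cheaper searches.
#'
#' @param learning_rates,dropout_rates,batch_sizes Grid axes.
#' @param max_epochs Epoch cap per cell.
#' @return A `hyper_grid` object; the cells are the full Cartesian product.
#' @export
hyper_grid <- function(learning_rates = c(0.2, 0.1, 0.05, 0.01, 0.005, 0.001),
                       dropout_rates = c(0.1, 0.2, 0.3, 0.4, 0.5),
                       batch_sizes = c(10L, 30L, 50L, 100L, 200L),
                       max_epochs = 1000L) {
  stopifnot(length(learning_rates) > 0, length(dropout_rates) > 0,
            length(batch_sizes) > 0, max_epochs >= 1L)
  cells <- expand.grid(lr = learning_rates, dropout = dropout_rates,
                       batch_size = batch_sizes, KEEP.OUT.ATTRS = FALSE)
  structure(list(cells = cells, max_epochs = as.integer(max_epochs)),
            class = "hyper_grid")
}

encode_splits <- function(splits, schema) {
  lapply(splits, function(s) {
    if (is.null(s) || (is.data.frame(s) && nrow(s) == 0L)) return(NULL)
    if (is.data.frame(s)) encode_dataset(s, schema) else s
  })
}

#' Train one model on a fixed split
#'
#' Minibatch Adam on binary cross-entropy with dropout and early stopping
#' on validation accuracy. Deterministic given `seed` (initialization,
#' batch order and dropout all draw from the seeded stream). A non-finite
#' training loss (e.g. divergence at an aggressive learning rate) aborts
#' with an error carrying the epoch/batch diagnostics.
#'
#' @param splits List with `train`, `val` and optionally `test` pair tables
#'   (or pre-encoded `list(x, y)` objects).
#' @param schema [pair_schema()] used to encode the tables.
#' @param spec [model_spec()]; defaults to the standard architecture for
#'   the schema's total length.
#' @param lr Learning rate.
#' @param dropout Dropout rate (overrides `spec$dropout_rate`).
#' @param batch_size Minibatch size.
#' @param rule [early_stop_rule()].
#' @param max_epochs Epoch cap (published cap: 1000).
#' @param seed Integer seed for the run.
#' @param verbose Print one line per epoch.
#' @return A `run_record`: trained model (best-validation weights
#'   restored), per-epoch history, epochs run, hyperparameters, best
#'   validation accuracy, and a test-set [metrics_report()] when a test
#'   split was supplied.
#' @export
train_once <- function(splits, schema, spec = NULL, lr = 0.005,
                       dropout = 0.2, batch_size = 30L,
                       rule = early_stop_rule(), max_epochs = 1000L,
                       seed = 1L, verbose = FALSE) {
  if (is.null(spec)) spec <- model_spec(input_len = schema$total_len)
  spec$dropout_rate <- dropout
  enc <- encode_splits(splits, schema)
  stopifnot(!is.null(enc$train), !is.null(enc$val))
  n <- nrow(enc$train$x)

  run <- with_seed(seed, {
    model <- build_model(spec, schema = schema)
    state <- adam_init(model$weights)
    best_acc <- -Inf; best_w <- model$weights; best_epoch <- 0L
    wait <- 0L; stop_ref <- -Inf
    hist <- list()
    epochs_run <- 0L
    for (epoch in seq_len(max_epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0
      for (from in seq(1L, n, by = batch_size)) {
        rows <- idx[from:min(from + batch_size - 1L, n)]
        fwd <- nn_forward(model, enc$train$x[rows, , drop = FALSE],
                          training = TRUE)
        loss <- bce_loss(enc$train$y[rows], fwd$prob)
        if (!is.finite(loss)) {
          stop(sprintf(
            "non-finite training loss at epoch %d (lr=%g, batch at row %d)",
            epoch, lr, from), call. = FALSE)
        }
        ep_loss <- ep_loss + loss * length(rows)
        grads <- nn_backward(model, fwd$cache, enc$train$y[rows])
        upd <- adam_step(model$weights, grads, state, lr)
        model$weights <- upd$weights
        state <- upd$state
      }
      val_prob <- forward(model, enc$val$x)
      val_acc <- mean((val_prob >= 0.5) == (enc$val$y == 1))
      hist[[epoch]] <- c(epoch = epoch, train_loss = ep_loss / n,
                         val_accuracy = val_acc)
      epochs_run <- epoch
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val_acc %.4f",
                        epoch, ep_loss / n, val_acc))
      }
      if (val_acc > best_acc) {
        best_acc <- val_acc; best_w <- model$weights; best_epoch <- epoch
      }
      if (val_acc >= stop_ref + rule$min_delta) {
        stop_ref <- val_acc; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= rule$patience) break
      }
    }
    model$weights <- best_w
    list(model = model, best_acc = best_acc, best_epoch = best_epoch,
         hist = do.call(rbind, hist), epochs_run = epochs_run)
  })

  rec <- list(model = run$model,
              history = as.data.frame(run$hist),
              epochs_run = run$epochs_run,
              best_epoch = run$best_epoch,
              lr = lr, dropout = dropout, batch_size = as.integer(batch_size),
              seed = as.integer(seed),
              val_accuracy = run$best_acc)
  if (!is.null(enc$test)) {
    prob <- forward(run$model, enc$test$x)
    rec$test_metrics <- metrics_report(enc$test$y, prob)
  }
  structure(rec, class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf(
    "<run_record> lr=%g dropout=%g batch=%d seed=%d | %d epochs, val_acc=%.4f\n",
    x$lr, x$dropout, x$batch_size, x$seed, x$epochs_run, x$val_accuracy))
  if (!is.null(x$test_metrics)) {
    cat("  test:", paste(sprintf("%s=%.4f", names(x$test_metrics),
                                 x$test_metrics), collapse = " "), "\n")
  }
  invisible(x)
}

#' Grid search over learning rate, dropout and batch size
#'
#' Trains one model per grid cell on a single fixed split and ranks cells
#' by validation accuracy. Ties break deterministically toward the lowest
#' learning rate, then the lowest dropout, then the smallest batch. A cell
#' that fails (e.g. divergence) is recorded in the leaderboard with its
#' error, not fatal.
#'
#' @param pairs Pair table.
#' @param schema [pair_schema()].
#' @param grid [hyper_grid()].
#' @param split [split_spec()].
#' @param spec Optional [model_spec()].
#' @param rule [early_stop_rule()].
#' @param seed Seed for weight init / batch order (same for every cell so
#'   cells differ only in hyperparameters).
#' @return List: `best` (row of the winning cell), `leaderboard` (one row
#'   per attempted cell), `records` (the `run_record`s).
#' @export
grid_search <- function(pairs, schema, grid = hyper_grid(),
                        split = split_spec(), spec = NULL,
                        rule = early_stop_rule(), seed = 1L) {
  splits <- split_dataset(pairs, split)
  cells <- grid$cells
  records <- vector("list", nrow(cells))
  lb <- cells
  lb$val_accuracy <- NA_real_; lb$epochs <- NA_integer_
  lb$status <- "ok"
  for (k in seq_len(nrow(cells))) {
    rec <- tryCatch(
      train_once(splits, schema, spec = spec, lr = cells$lr[k],
                 dropout = cells$dropout[k], batch_size = cells$batch_size[k],
                 rule = rule, max_epochs = grid$max_epochs, seed = seed),
      error = function(e) e)
    if (inherits(rec, "error")) {
      lb$status[k] <- conditionMessage(rec)
    } else {
      records[[k]] <- rec
      lb$val_accuracy[k] <- rec$val_accuracy
      lb$epochs[k] <- rec$epochs_run
    }
  }
  ok <- which(!is.na(lb$val_accuracy))
  if (length(ok) == 0L) stop("every grid cell failed", call. = FALSE)
  ord <- ok[order(-lb$val_accuracy[ok], lb$lr[ok], lb$dropout[ok],
                  lb$batch_size[ok])]
  list(best = lb[ord[1L], , drop = FALSE],
       best_record = records[[ord[1L]]],
       leaderboard = lb, records = records)
}

#' Repeated training over random re-splits
#'
#' Re-splits the dataset `n_repeats` times with distinct derived seeds,
#' trains at fixed hyperparameters, and returns the per-repeat test-set
#' metric reports plus their mean / 2.5-97.5 percentile summary — the
#' repeated-resplit evaluation protocol (30 repeats at publication scale).
#'
#' @inheritParams train_once
#' @param pairs Pair table.
#' @param n_repeats Number of re-splits (>= 2).
#' @param split Base [split_spec()] (its fractions are kept; its seed is
#'   replaced per repeat).
#' @param master_seed Seed from which per-repeat split and training seeds
#'   are derived (and recorded).
#' @return List: `reports` (per-repeat metric vectors), `seeds` (data
#'   frame of derived seeds), `summary` ([aggregate_reports()] output).
#' @export
repeated_runs <- function(pairs, schema, spec = NULL, lr = 0.005,
                          dropout = 0.2, batch_size = 30L, n_repeats = 30L,
                          split = split_spec(), rule = early_stop_rule(),
                          max_epochs = 1000L, master_seed = 1L) {
  stopifnot(n_repeats >= 2L)
  seeds <- with_seed(master_seed, matrix(sample.int(.Machine$integer.max - 1L,
                                                    2L * n_repeats),
                                         ncol = 2L))
  reports <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    sp <- split
    sp$seed <- seeds[r, 1L]
    splits <- split_dataset(pairs, sp)
    rec <- train_once(splits, schema, spec = spec, lr = lr, dropout = dropout,
                      batch_size = batch_size, rule = rule,
                      max_epochs = max_epochs, seed = seeds[r, 2L])
    if (is.null(rec$test_metrics)) {
      stop(sprintf("repeat %d produced no test metrics", r), call. = FALSE)
    }
    reports[[r]] <- rec$test_metrics
  }
  list(reports = reports,
       seeds = data.frame(repeat_ = seq_len(n_repeats),
                          split_seed = seeds[, 1L], train_seed = seeds[, 2L]),
       summary = aggregate_reports(reports))
}

#' Compose a unified dataset from two balanced sources
#'
#' Per class, draws `floor(frac_dmt * min(class counts))` pairs from the
#' first (smaller) source and caps the second source's contribution at
#' `cap_ratio` times that, so the larger source cannot dominate. Leftover
#' pairs from both sources are returned as held-out test sets. With the
#' published inputs (3,908/3,850 and 31,660/30,993 pairs per class) this
#' draws 3,465 + 10,395 pairs per class: a 27,720-pair combined set, 443
#' positive / 385 negative first-source leftovers, and 21,265 positive /
#' 20,598 negative second-source leftovers.
#'
#' @param dmt_pairs,miraw_pairs Pair tables of the two sources (near-
#'   balanced labels).
#' @param frac_dmt Fraction of the first source's smaller class drawn.
#' @param cap_ratio Maximum ratio of second-source to first-source draws.
#' @param seed Sampling seed.
#' @return List: `unified`, `dmt_left`, `miraw_left` (pair tables) and
#'   `counts` (per-class draw/leftover bookkeeping).
#' @export
compose_unified_dataset <- function(dmt_pairs, miraw_pairs, frac_dmt = 0.90,
                                    cap_ratio = 3, seed = 1L) {
  stopifnot(is.data.frame(dmt_pairs), is.data.frame(miraw_pairs))
  n_dmt_class <- floor(frac_dmt * min(table(dmt_pairs$label)))
  if (n_dmt_class < 1L) stop("cap produced an empty combined set", call. = FALSE)
  with_seed(seed, {
    take <- function(df, lab, k) {
      rows <- which(df$label == lab)
      stopifnot(length(rows) >= k)
      picked <- sort(sample(rows, k))
      list(in_ = df[picked, , drop = FALSE],
           out = df[setdiff(rows, picked), , drop = FALSE])
    }
    counts <- NULL
    uni <- dmt_left <- miraw_left <- list()
    for (lab in c(1L, 0L)) {
      d <- take(dmt_pairs, lab, n_dmt_class)
      avail <- sum(miraw_pairs$label == lab)
      n_raw <- min(cap_ratio * n_dmt_class, avail)
      m <- take(miraw_pairs, lab, n_raw)
      uni[[length(uni) + 1L]] <- rbind(d$in_, m$in_)
      dmt_left[[length(dmt_left) + 1L]] <- d$out
      miraw_left[[length(miraw_left) + 1L]] <- m$out
      counts <- rbind(counts, data.frame(
        label = lab, dmt_drawn = n_dmt_class, miraw_drawn = n_raw,
        dmt_left = nrow(d$out), miraw_left = nrow(m$out)))
    }
    list(unified = do.call(rbind, uni),
         dmt_left = do.call(rbind, dmt_left),
         miraw_left = do.call(rbind, miraw_left),
         counts = counts)
  })
}
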