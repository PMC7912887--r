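test_that("split sizes reproduce the published test-set arithmetic", {
  # printed dataset sizes: 7,758 -> 1,552 test; 27,720 -> 5,544 test
  expect_equal(unname(split_sizes(7758L)[["test"]]), 1552)
  expect_equal(unname(split_sizes(27720L)[["test"]]), 5544)
  sz <- split_sizes(1000L)
  expect_equal(sum(sz), 1000L)
  expect_equal(unname(sz[["val"]]), 160)
  expect_error(split_sizes(2L), "cannot fill")
  # per-stratum arithmetic at the published class counts
  expect_equal(unname(split_sizes(3908L)[["test"]] + split_sizes(3850L)[["test"]]),
               1552)
})

test_that("split_dataset is a disjoint, stratified, seed-reproducible cover", {
  ds <- micro_dataset(n = 50L)
  ds$row_id <- seq_len(nrow(ds))
  sp <- split_spec(seed = 7L)
  s1 <- split_dataset(ds, sp)
  ids <- c(s1$train$row_id, s1$val$row_id, s1$test$row_id)
  expect_equal(sort(ids), ds$row_id)               # cover, no duplicates
  expect_equal(nrow(s1$test), 20L)
  # stratified: both labels appear proportionally in each split
  expect_equal(as.vector(table(s1$test$label)), c(10L, 10L))
  expect_equal(as.vector(table(s1$val$label)), c(8L, 8L))
  expect_identical(split_dataset(ds, sp), s1)      # determinism
  s2 <- split_dataset(ds, split_spec(seed = 8L))
  expect_false(identical(s2$test$row_id, s1$test$row_id))
})

test_that("train_once with zero learning rate leaves weights unchanged", {
  ds <- micro_dataset(n = 25L)
  splits <- split_dataset(ds, split_spec(seed = 1L))
  r1 <- train_once(splits, micro_schema(), spec = micro_spec(), lr = 0,
                   batch_size = 16L, rule = early_stop_rule(0.001, 2L),
                   max_epochs = 1L, seed = 9L)
  r3 <- train_once(splits, micro_schema(), spec = micro_spec(), lr = 0,
                   batch_size = 16L, rule = early_stop_rule(0.001, 2L),
                   max_epochs = 3L, seed = 9L)
  expect_identical(r1$model$weights, r3$model$weights)
})

test_that("early stopping fires after patience epochs of flat accuracy", {
  ds <- micro_dataset(n = 25L)
  splits <- split_dataset(ds, split_spec(seed = 1L))
  # lr = 0 makes validation accuracy exactly flat after epoch 1
  rec <- train_once(splits, micro_schema(), spec = micro_spec(), lr = 0,
                    batch_size = 16L, rule = early_stop_rule(0.001, 3L),
                    max_epochs = 50L, seed = 9L)
  expect_equal(rec$epochs_run, 1L + 3L)
  expect_lt(rec$epochs_run, 50L)
})

test_that("train_once is deterministic given its seed and records history", {
  ds <- micro_dataset(n = 25L)
  splits <- split_dataset(ds, split_spec(seed = 2L))
  args <- list(splits, micro_schema(), spec = micro_spec(), lr = 0.01,
               batch_size = 16L, rule = early_stop_rule(0.001, 2L),
               max_epochs = 3L, seed = 123L)
  a <- do.call(train_once, args)
  b <- do.call(train_once, args)
  expect_identical(a$model$weights, b$model$weights)
  expect_identical(a$history, b$history)
  expect_equal(nrow(a$history), a$epochs_run)
  expect_named(a$test_metrics,
               c("accuracy", "sensitivity", "specificity", "f_score",
                 "ppv", "npv", "brier"))
  expect_equal(a$val_accuracy, max(a$history$val_accuracy))
})

test_that("grid search ranks cells and records failures non-fatally", {
  ds <- micro_dataset(n = 30L, seed = 5L, negative_mode = "resample_site")
  grid <- hyper_grid(learning_rates = c(0, 0.01), dropout_rates = 0.1,
                     batch_sizes = 16L, max_epochs = 4L)
  gs <- grid_search(ds, micro_schema(), grid = grid, spec = micro_spec(),
                    split = split_spec(seed = 3L),
                    rule = early_stop_rule(0.001, 2L), seed = 4L)
  expect_equal(nrow(gs$leaderboard), 2L)           # one row per cell
  # the degenerate lr = 0 cell cannot beat the trained cell
  expect_gte(gs$leaderboard$val_accuracy[gs$leaderboard$lr == 0.01],
             gs$leaderboard$val_accuracy[gs$leaderboard$lr == 0])
  one <- grid_search(ds, micro_schema(),
                     grid = hyper_grid(0.01, 0.1, 16L, max_epochs = 2L),
                     spec = micro_spec(), split = split_spec(seed = 3L),
                     rule = early_stop_rule(0.001, 2L), seed = 4L)
  expect_equal(nrow(one$leaderboard), 1L)
  expect_equal(one$best$lr, 0.01)
})

test_that("repeated_runs yields one report per derived-seed repeat", {
  ds <- micro_dataset(n = 25L)
  rr <- repeated_runs(ds, micro_schema(), spec = micro_spec(), lr = 0.01,
                      batch_size = 16L, n_repeats = 2L,
                      rule = early_stop_rule(0.001, 2L), max_epochs = 2L,
                      master_seed = 6L)
  expect_length(rr$reports, 2L)
  expect_equal(nrow(rr$seeds), 2L)
  expect_false(rr$seeds$split_seed[1] == rr$seeds$split_seed[2])
  expect_equal(rr$summary$metric[1], "accuracy")
  # same master seed -> identical runs
  rr2 <- repeated_runs(ds, micro_schema(), spec = micro_spec(), lr = 0.01,
                       batch_size = 16L, n_repeats = 2L,
                       rule = early_stop_rule(0.001, 2L), max_epochs = 2L,
                       master_seed = 6L)
  expect_identical(rr2$reports, rr$reports)
})

test_that("unified-dataset composition reproduces the published counts", {
  # pair tables with the published class sizes; payload content irrelevant
  fake <- function(n_pos, n_neg) {
    data.frame(mirna_id = "m", mirna_seq = "A", site_seq = "A",
               label = rep(c(1L, 0L), c(n_pos, n_neg)))
  }
  dmt <- fake(3908L, 3850L)
  raw <- fake(31660L, 30993L)
  cmp <- compose_unified_dataset(dmt, raw, frac_dmt = 0.90, cap_ratio = 3,
                                 seed = 1L)
  expect_equal(nrow(cmp$unified), 27720L)
  expect_equal(sum(cmp$unified$label == 1L), 13860L)
  expect_equal(cmp$counts$dmt_drawn, c(3465L, 3465L))
  expect_equal(cmp$counts$miraw_drawn, c(10395L, 10395L))
  expect_equal(sum(cmp$dmt_left$label == 1L), 443L)
  expect_equal(sum(cmp$dmt_left$label == 0L), 385L)
  expect_equal(sum(cmp$miraw_left$label == 1L), 21265L)
  expect_equal(sum(cmp$miraw_left$label == 0L), 20598L)
  # frac = 1 with a huge cap exhausts the first source's smaller class
  cmp2 <- compose_unified_dataset(fake(50L, 50L), fake(100L, 100L),
                                  frac_dmt = 1, cap_ratio = 100, seed = 1L)
  expect_equal(nrow(cmp2$dmt_left), 0L)
  expect_equal(nrow(cmp2$miraw_left), 0L)
})
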