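# Brute-force window enumeration oracle: every offset k*step that fits,
# plus a final end-anchored window when needed.
offsets_oracle <- function(glen, wlen, step) {
  if (glen <= wlen) return(0L)
  off <- integer(0); k <- 0L
  while (k * step + wlen <= glen) { off <- c(off, k * step); k <- k + 1L }
  if (off[length(off)] + wlen < glen) off <- c(off, glen - wlen)
  off
}

test_that("split_gene matches the enumeration oracle and covers the gene", {
  set.seed(41)
  expect_equal(split_gene(random_rna(100L), 40L, 20L)$offset,
               c(0L, 20L, 40L, 60L))
  for (i in 1:25) {
    glen <- sample(41:400, 1L)
    wlen <- sample(20:40, 1L)
    step <- sample(seq_len(wlen - 1L), 1L)
    w <- split_gene(random_rna(glen), wlen, step)
    expect_equal(w$offset, offsets_oracle(glen, wlen, step))
    expect_true(all(nchar(w$window) == wlen))
    # coverage: the union of [offset, offset + wlen) is [0, glen)
    covered <- rep(FALSE, glen)
    for (o in w$offset) covered[(o + 1L):(o + wlen)] <- TRUE
    expect_true(all(covered))
  }
})

test_that("split_gene handles exact-fit and short genes", {
  g <- random_rna(40L)
  w <- split_gene(g, 40L)
  expect_equal(nrow(w), 1L)
  expect_equal(w$offset, 0L)
  expect_equal(w$window, g)
  short <- split_gene(random_rna(30L), 40L)
  expect_equal(nrow(short), 1L)
  expect_equal(substr(short$window, 31L, 40L), strrep("N", 10L))
  expect_error(split_gene("AUGC", 40L, step = 40L), "step")
})

test_that("predict_sites thresholds and is deterministic over duplicates", {
  m <- build_model(micro_spec(), schema = micro_schema(), seed = 5L)
  set.seed(42)
  gene <- random_rna(60L)
  w <- split_gene(gene, 20L, 10L)
  res <- predict_sites(m, random_rna(12L), w)
  expect_equal(nrow(res), nrow(w))
  expect_true(all(res$probability > 0 & res$probability < 1))
  expect_equal(res$call, res$probability >= 0.5)
  # threshold 1.0: probabilities are strictly < 1, so zero calls
  res1 <- predict_sites(m, random_rna(12L), w,
                        scan_config(site_prob_threshold = 1))
  expect_equal(sum(res1$call), 0L)
  # duplicate windows score identically
  w2 <- rbind(w, w[1L, ])
  res2 <- predict_sites(m, random_rna(12L), w2)
  expect_identical(res2$probability[nrow(w2)], res2$probability[1L])
  expect_error(predict_sites(m, random_rna(12L), split_gene(gene, 15L, 7L)),
               "does not match model site slot")
})

test_that("call_genes equals a brute-force recount and scan_genes aggregates", {
  set.seed(43)
  fake <- data.frame(gene_id = sample(letters[1:4], 60L, TRUE),
                     call = sample(c(TRUE, FALSE), 60L, TRUE))
  got <- call_genes(fake, min_sites_per_gene = 2L)
  for (g in got$gene_id) {
    expect_equal(got$n_positive_sites[got$gene_id == g],
                 sum(fake$call[fake$gene_id == g]))
  }
  expect_equal(got$is_target, got$n_positive_sites >= 2L)
  expect_equal(call_genes(data.frame(gene_id = "g", call = FALSE))$is_target,
               FALSE)

  m <- build_model(micro_spec(), schema = micro_schema(), seed = 5L)
  genes <- c(g1 = random_rna(50L), g2 = random_rna(35L))
  sc <- scan_genes(m, random_rna(12L), genes)
  expect_s3_class(sc, "scan_result")
  expect_setequal(unique(sc$windows$gene_id), c("g1", "g2"))
  expect_equal(nrow(sc$genes), 2L)
  # gene order invariance of per-gene results
  sc2 <- scan_genes(m, random_rna(12L), rev(genes))
  expect_equal(sc2$genes[order(sc2$genes$gene_id), ],
               sc$genes[order(sc$genes$gene_id), ], ignore_attr = TRUE)
})

test_that("write_site_fasta round-trips positive windows", {
  m <- build_model(micro_spec(), schema = micro_schema(), seed = 5L)
  set.seed(44)
  genes <- c(gA = random_rna(60L))
  sc <- scan_genes(m, random_rna(12L), genes,
                   scan_config(site_prob_threshold = 1e-6))  # all positive
  tf <- tempfile(fileext = ".fa")
  write_site_fasta(sc, tf)
  back <- Biostrings::readBStringSet(tf)
  expect_equal(length(back), nrow(sc$windows))
  expect_equal(unname(as.character(back)), sc$windows$window)
  offs <- as.integer(sub(".*offset=(\\d+).*", "\\1", names(back)))
  expect_equal(offs, sc$windows$offset)
  # zero positives -> valid empty FASTA
  sc0 <- scan_genes(m, random_rna(12L), genes,
                    scan_config(site_prob_threshold = 1))
  tf0 <- tempfile(fileext = ".fa")
  write_site_fasta(sc0, tf0)
  expect_true(file.exists(tf0))
  expect_equal(length(Biostrings::readBStringSet(tf0)), 0L)
})
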