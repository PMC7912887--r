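test_that("random_mirna respects length range and base composition", {
  set.seed(31)
  lens <- replicate(500, length(random_mirna()))
  expect_true(all(lens >= 19 & lens <= 26))
  # base frequencies ~ 0.25 each within 3 sigma of the binomial bound
  bases <- unlist(strsplit(replicate(500, random_mirna()$residues), ""))
  n <- length(bases)
  for (b in c("A", "U", "G", "C")) {
    expect_lt(abs(mean(bases == b) - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  }
  expect_error(random_mirna(c(5L, 6L)), ">= 8")
})

test_that("canonical planting is verified by an independent complementarity check", {
  set.seed(32)
  wc <- c(A = "U", U = "A", G = "C", C = "G")
  for (i in 1:40) {
    m <- random_mirna()
    mode <- sample(c("canonical_2_7", "canonical_3_8"), 1L)
    pl <- plant_site(m, 40L, mode)
    from <- if (mode == "canonical_2_7") 2L else 3L
    seed <- substr(m$residues, from, from + 5L)
    # independent oracle: reversed WC complement, character by character
    expected <- paste(rev(vapply(strsplit(seed, "")[[1L]],
                                 function(ch) wc[[ch]], "")), collapse = "")
    expect_equal(substr(pl$site$residues, pl$offset + 1L, pl$offset + 6L),
                 expected)
    expect_true(verify_planted_site(m, pl$site, pl$offset, mode))
    expect_true(pl$offset >= 0L && pl$offset <= 40L - nchar(pl$motif))
    expect_equal(nchar(pl$site$residues), 40L)
  }
})

test_that("noncanonical planting has at most one non-pairing position", {
  set.seed(33)
  for (i in 1:40) {
    m <- random_mirna()
    pl <- plant_site(m, 40L, "noncanonical")
    expect_true(verify_planted_site(m, pl$site, pl$offset, "noncanonical"))
    expect_true(nchar(pl$motif) %in% c(6L, 7L))
    if (grepl("mismatch", pl$edit)) {
      # exactly one position fails both WC and wobble pairing, in the
      # register plant_site recorded
      from <- if (pl$register == "3_8") 3L else 2L
      seedc <- rev(strsplit(substr(m$residues, from, from + 5L), "")[[1L]])
      sub <- strsplit(substr(pl$site$residues, pl$offset + 1L,
                             pl$offset + 6L), "")[[1L]]
      bad <- sum(!mapply(pairs_wobble, seedc, sub))
      expect_lte(bad, 1L)
    }
  }
  expect_error(plant_site(random_mirna(), 5L, "canonical_2_7"), "too short")
})

test_that("shuffled negatives conserve the base multiset and break the seed", {
  set.seed(34)
  breaks <- 0L; n <- 300L
  for (i in seq_len(n)) {
    m <- random_mirna()
    pl <- plant_site(m, 40L, "canonical_2_7")
    sh <- shuffle_mirna(m$residues)
    expect_equal(sort(strsplit(sh$mirna_seq, "")[[1L]]),
                 sort(strsplit(m$residues, "")[[1L]]))
    expect_false(sh$mirna_seq == m$residues)
    expect_equal(strsplit(m$residues, "")[[1L]][sh$perm],
                 strsplit(sh$mirna_seq, "")[[1L]])
    if (!verify_planted_site(rna_seq(sh$mirna_seq), pl$site, pl$offset,
                             "canonical_2_7")) breaks <- breaks + 1L
  }
  expect_gte(breaks / n, 0.95)
  expect_error(shuffle_mirna("AAAAAAAA"), "homopolymer")
})

test_that("generate_dataset is balanced, bounded and seed-reproducible", {
  cfg <- synth_config(n_pos = 100L, n_neg = 100L, site_len = 40L, rng_seed = 35L)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds), 200L)
  expect_equal(as.vector(table(ds$label)), c(100L, 100L))
  expect_true(all(nchar(ds$mirna_seq) <= 26L))
  expect_true(all(nchar(ds$site_seq) == 40L))
  expect_identical(generate_dataset(cfg), ds)
  ds2 <- generate_dataset(synth_config(100L, 100L, site_len = 40L,
                                       rng_seed = 36L))
  expect_false(identical(ds2$site_seq, ds$site_seq))
  # every positive passes its mode's planted-structure verifier
  pos <- ds[ds$label == 1L, ]
  ok <- mapply(function(m, s, o, md)
    verify_planted_site(rna_seq(m), rna_seq(s), o, md),
    pos$mirna_seq, pos$site_seq, pos$site_offset, pos$seed_mode)
  expect_true(all(ok))
})

test_that("resample_site negatives carry no exact seed match", {
  ds <- micro_dataset(n = 40L, seed = 37L, negative_mode = "resample_site")
  neg <- ds[ds$label == 0L, ]
  wc <- c(A = "U", U = "A", G = "C", C = "G")
  rc <- function(s) paste(rev(wc[strsplit(s, "")[[1L]]]), collapse = "")
  hits <- mapply(function(m, s) {
    grepl(rc(substr(m, 2L, 7L)), s, fixed = TRUE) ||
      grepl(rc(substr(m, 3L, 8L)), s, fixed = TRUE)
  }, neg$mirna_seq, neg$site_seq)
  expect_false(any(hits))
  # and the miRNA is the pool miRNA, not a shuffle
  expect_true(all(neg$mirna_id %in% ds$mirna_id[ds$label == 1L]))
})

test_that("synthetic_target_gene plants the only exact seed matches", {
  set.seed(38)
  for (i in 1:10) {
    m <- random_mirna(c(21L, 21L))
    g <- synthetic_target_gene(m, gene_len = 300L, n_sites = 2L)
    expect_equal(nchar(g$gene$residues), 300L)
    found <- gregexpr(g$motif, g$gene$residues, fixed = TRUE)[[1L]] - 1L
    expect_equal(sort(found), sort(g$offsets))
  }
})
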