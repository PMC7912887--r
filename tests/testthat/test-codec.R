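test_that("normalize_sequence uppercases, maps T->U and rejects bad symbols", {
  expect_equal(normalize_sequence("augcu")$residues, "AUGCU")
  expect_equal(normalize_sequence("ATGCT")$residues, "AUGCU")
  expect_equal(normalize_sequence("AUGCN")$orientation, "five_to_three")
  expect_error(normalize_sequence("AXGCU"), "invalid symbol 'X' at position 2")
  expect_error(normalize_sequence(""), "empty")
})

test_that("orient_mirna reverses once and guards double reversal", {
  expect_equal(orient_mirna(rna_seq("AUGC"))$residues, "CGUA")
  expect_equal(orient_mirna(rna_seq("AUUA"))$residues, "AUUA")
  rev1 <- orient_mirna(rna_seq("AUGC"))
  expect_equal(rev1$orientation, "three_to_five")
  expect_error(orient_mirna(rev1), "refusing to reverse twice")
  # derived oracle: independent char-by-char reversal on random 22-mers
  set.seed(5)
  for (i in 1:20) {
    s <- random_rna(22L)
    expect_equal(orient_mirna(rna_seq(s))$residues, reverse_oracle(s))
  }
})

test_that("pad_sequence right-pads with N, preserves prefix, rejects overflow", {
  expect_equal(pad_sequence(rna_seq("AUG"), 5L)$residues, "AUGNN")
  s26 <- rna_seq(random_rna(26L))
  expect_equal(pad_sequence(s26, 26L)$residues, s26$residues)
  expect_error(pad_sequence(rna_seq(random_rna(27L)), 26L), "exceeds slot")
  set.seed(9)
  for (i in 1:10) {
    len <- sample(3:20, 1L)
    s <- random_rna(len)
    p <- pad_sequence(rna_seq(s), 25L)$residues
    expect_equal(substr(p, 1L, len), s)            # prefix untouched
    expect_equal(substr(p, len + 1L, 25L), strrep("N", 25L - len))
  }
})

test_that("the two published schemas give concatenated lengths 79 and 66", {
  dmt <- pair_schema("deepmirtar")
  raw <- pair_schema("miraw")
  expect_equal(dmt$total_len, 79L)
  expect_equal(raw$total_len, 66L)
  p1 <- labeled_pair(random_rna(26L), random_rna(53L), 1L)
  expect_equal(length(concatenate_pair(p1, dmt)), 79L)
  p2 <- labeled_pair(random_rna(22L), random_rna(40L), 1L)
  expect_equal(length(concatenate_pair(p2, raw)), 66L)
  # no padding needed at exact slot lengths -> zero N characters
  expect_false(grepl("N", concatenate_pair(p1, dmt)$residues, fixed = TRUE))
})

test_that("concatenation is pad(reverse(miRNA)) ++ pad(site)", {
  schema <- pair_schema(5L, 6L)
  pair <- labeled_pair("AUGC", "GGCC", 1L)
  cc <- concatenate_pair(pair, schema)
  expect_equal(cc$residues, paste0("CGUA", "N", "GGCC", "NN"))
})

test_that("encoding is a bijection and a round trip", {
  expect_equal(sort(encode_sequence("AUGCN")), 0:4)
  set.seed(3)
  for (i in 1:25) {
    s <- paste(sample(c("A", "U", "G", "C", "N"), sample(5:60, 1L),
                      replace = TRUE), collapse = "")
    expect_equal(decode_sequence(encode_sequence(s)), s)
  }
  expect_error(encode_sequence("AUXGC"), "not normalized")
})

test_that("encode_dataset produces fixed-width code matrices per schema", {
  ds <- micro_dataset(n = 10L)
  enc <- encode_dataset(ds, micro_schema())
  expect_equal(dim(enc$x), c(20L, 32L))
  expect_true(all(enc$x %in% 0:4))
  expect_equal(sort(unique(enc$y)), c(0L, 1L))
  # miRNA slot holds the reversed miRNA, site slot the site
  i <- 1L
  mir <- normalize_sequence(ds$mirna_seq[i])$residues
  expect_equal(decode_sequence(enc$x[i, 1:nchar(mir)]), reverse_oracle(mir))
  site <- ds$site_seq[i]
  expect_equal(decode_sequence(enc$x[i, 12L + seq_len(nchar(site))]), site)
  # under the full schemas the widths are 79 / 66
  big <- data.frame(mirna_id = "m", mirna_seq = random_rna(22L),
                    site_seq = random_rna(40L), label = 1L)
  expect_equal(ncol(encode_dataset(big, pair_schema("miraw"))$x), 66L)
  big$site_seq <- random_rna(53L)
  expect_equal(ncol(encode_dataset(big, pair_schema("deepmirtar"))$x), 79L)
  # slot overflow is an error
  big$site_seq <- random_rna(54L)
  expect_error(encode_dataset(big, pair_schema("deepmirtar")), "exceeds schema")
})

test_that("pair-table and FASTA round trips preserve content", {
  ds <- micro_dataset(n = 6L)
  tf <- tempfile(fileext = ".tsv")
  write_pair_table(ds, tf)
  back <- read_pair_table(tf)
  expect_equal(back$mirna_seq, ds$mirna_seq)
  expect_equal(back$label, ds$label)
  expect_error(read_pair_table({
    tf2 <- tempfile(); writeLines("a\tb\n1\t2", tf2); tf2
  }), "lacks column")

  fa <- tempfile(fileext = ".fa")
  writeLines(c(">g1 first", "ACGTacgt", ">g2", "UUGGN"), fa)
  seqs <- read_fasta_sequences(fa)
  expect_equal(unname(seqs), c("ACGUACGU", "UUGGN"))
  expect_equal(names(seqs), c("g1 first", "g2"))
})
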