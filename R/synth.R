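# Synthetic miRNA:site dataset generator. Positives carry a planted
# seed-complementary motif (canonical Watson-Crick pairing of miRNA
# positions 2-7 or 3-8, or a non-canonical variant allowing G-U wobbles and
# at most one bulge/mismatch); negatives are made by shuffling the mature
# miRNA while keeping the site, mirroring the shuffled-negative design of
# the curated training sets this generator emulates.

WC_PARTNER <- c(A = "U", U = "A", G = "C", C = "G")

#' Watson-Crick / wobble pairing predicates
#'
#' `pairs_wc()` tests exact Watson-Crick pairing (A-U, G-C);
#' `pairs_wobble()` additionally accepts the G-U wobble.
#'
#' @param a,b Single residue characters.
#' @return Logical.
#' @export
pairs_wc <- function(a, b) !is.na(WC_PARTNER[a]) && WC_PARTNER[a] == b

#' @rdname pairs_wc
#' @export
pairs_wobble <- function(a, b) {
  pairs_wc(a, b) || (a == "G" && b == "U") || (a == "U" && b == "G")
}

revcomp_rna <- function(s) {
  paste(rev(WC_PARTNER[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
}

random_rna_string <- function(len) {
  paste(sample(c("A", "U", "G", "C"), len, replace = TRUE), collapse = "")
}

#' Draw a random mature miRNA sequence
#'
#' Uniform base composition, length uniform on `len_range` (default 19-26
#' nt, the span of curated mature miRNAs).
#'
#' @param len_range Integer length 2: min and max length.
#' @return An `rna_seq`, 5'->3'.
#' @export
random_mirna <- function(len_range = c(19L, 26L)) {
  stopifnot(len_range[1L] >= 8L, len_range[2L] >= len_range[1L])
  lens <- seq.int(len_range[1L], len_range[2L])
  len <- lens[sample.int(length(lens), 1L)]  # robust to length-1 ranges
  rna_seq(random_rna_string(len))
}

seed_region <- function(mirna_str, mode) {
  from <- switch(mode, canonical_2_7 = 2L, canonical_3_8 = 3L,
                 noncanonical = 2L + sample(0:1, 1L))
  if (nchar(mirna_str) < from + 5L) {
    stop(sprintf("miRNA of %d nt is too short for the %d-%d seed register",
                 nchar(mirna_str), from, from + 5L), call. = FALSE)
  }
  substr(mirna_str, from, from + 5L)
}

#' Plant a seed-complementary binding site for a miRNA
#'
#' Builds a random site of length `site_len` containing, at a random
#' offset, the binding motif: the reverse complement of the miRNA seed
#' (positions 2-7 or 3-8). `mode = "noncanonical"` perturbs the motif with
#' G-U wobbles (if `gu_allowed`) and exactly one bulge or mismatch.
#' Flanks are uniform i.i.d. and are redrawn if they create a second exact
#' seed match, so the planted offset is the unique canonical match.
#'
#' @param mirna An `rna_seq` (5'->3').
#' @param site_len Site length in nt (40 or 53 under the built-in schemas).
#' @param mode One of `"canonical_2_7"`, `"canonical_3_8"`,
#'   `"noncanonical"`.
#' @param gu_allowed Allow G-U wobbles in non-canonical motifs.
#' @return List: `site` (`rna_seq`), `offset` (0-based position of the
#'   motif in the site), `motif`, `mode`, `register` (`"2_7"` or `"3_8"`,
#'   the seed register actually used), `edit` (what the non-canonical
#'   perturbation was).
#' @export
plant_site <- function(mirna, site_len, mode = "canonical_2_7",
                       gu_allowed = TRUE) {
  stopifnot(inherits(mirna, "rna_seq"))
  mode <- match.arg(mode, c("canonical_2_7", "canonical_3_8", "noncanonical"))
  from <- switch(mode, canonical_2_7 = 2L, canonical_3_8 = 3L,
                 noncanonical = 2L + sample(0:1, 1L))
  if (nchar(mirna$residues) < from + 5L) {
    stop(sprintf("miRNA of %d nt is too short for the %d-%d seed register",
                 nchar(mirna$residues), from, from + 5L), call. = FALSE)
  }
  seed <- substr(mirna$residues, from, from + 5L)
  motif <- revcomp_rna(seed)
  edit <- "none"
  if (mode == "noncanonical") {
    chars <- strsplit(motif, "", fixed = TRUE)[[1L]]
    seedc <- rev(strsplit(seed, "", fixed = TRUE)[[1L]])  # aligned with motif
    if (gu_allowed) {
      # optionally wobble one eligible position (site pairs miRNA G as U,
      # or miRNA U as G)
      elig <- which(seedc %in% c("G", "U"))
      if (length(elig) > 0L && stats::runif(1) < 0.5) {
        k <- elig[sample.int(length(elig), 1L)]
        chars[k] <- if (seedc[k] == "G") "U" else "G"
        edit <- sprintf("wobble@%d", k)
      }
    }
    if (stats::runif(1) < 0.5) {  # one mismatch
      k <- sample.int(length(chars), 1L)
      bad <- setdiff(c("A", "U", "G", "C"),
                     c(WC_PARTNER[seedc[k]],
                       if (gu_allowed && seedc[k] == "G") "U",
                       if (gu_allowed && seedc[k] == "U") "G"))
      chars[k] <- sample(bad, 1L)
      edit <- paste0(edit, "+mismatch@", k)
    } else {                       # one bulged nucleotide in the site
      k <- sample.int(length(chars) + 1L, 1L)
      chars <- append(chars, sample(c("A", "U", "G", "C"), 1L), after = k - 1L)
      edit <- paste0(edit, "+bulge@", k)
    }
    motif <- paste(chars, collapse = "")
  }
  mlen <- nchar(motif)
  if (site_len < mlen) stop("site too short for requested planting", call. = FALSE)
  canon <- revcomp_rna(seed)
  repeat {
    offset <- sample.int(site_len - mlen + 1L, 1L) - 1L
    left <- random_rna_string(offset)
    right <- random_rna_string(site_len - mlen - offset)
    site <- paste0(left, motif, right)
    # no exact seed match may fall outside the planted region (a bulged
    # non-canonical motif can still legitimately contain the exact hexamer)
    hits <- gregexpr(canon, site, fixed = TRUE)[[1L]]
    hits <- hits[hits > 0L]
    if (all(hits >= offset + 1L & hits + 5L <= offset + mlen)) break
  }
  list(site = rna_seq(site), offset = offset, motif = motif,
       mode = mode, register = if (from == 2L) "2_7" else "3_8", edit = edit)
}

#' Verify a planted site against its provenance
#'
#' Independent structural check used throughout the test-suite: for
#' canonical modes the site must contain the exact reverse complement of
#' the seed at the recorded offset; for non-canonical modes the recorded
#' motif region must pair with the seed with at most one non-pairing or
#' bulged position (G-U counted as pairing when allowed).
#'
#' @param mirna An `rna_seq`.
#' @param site An `rna_seq`.
#' @param offset 0-based motif offset as recorded by [plant_site()].
#' @param mode Seed mode string.
#' @param gu_allowed Whether wobbles count as pairing.
#' @return Logical.
#' @export
verify_planted_site <- function(mirna, site, offset, mode,
                                gu_allowed = TRUE) {
  seed27 <- substr(mirna$residues, 2L, 7L)
  seed38 <- substr(mirna$residues, 3L, 8L)
  ok_exact <- function(seed) {
    substr(site$residues, offset + 1L, offset + 6L) == revcomp_rna(seed)
  }
  if (mode == "canonical_2_7") return(ok_exact(seed27))
  if (mode == "canonical_3_8") return(ok_exact(seed38))
  # noncanonical: accept either seed register, gapless or one bulge/gap,
  # with at most one non-pairing position
  ok_fuzzy <- function(seed) {
    sc <- rev(strsplit(seed, "", fixed = TRUE)[[1L]])
    pairfun <- if (gu_allowed) pairs_wobble else pairs_wc
    for (span in c(6L, 7L)) {
      sub <- substr(site$residues, offset + 1L, offset + span)
      if (nchar(sub) < span) next
      subc <- strsplit(sub, "", fixed = TRUE)[[1L]]
      if (span == 6L) {  # gapless
        mism <- sum(!mapply(pairfun, sc, subc))
        if (mism <= 1L) return(TRUE)
      } else {           # one bulged site nucleotide: drop each in turn
        for (drop in seq_len(7L)) {
          mism <- sum(!mapply(pairfun, sc, subc[-drop]))
          if (mism <= 1L) return(TRUE)
        }
      }
    }
    FALSE
  }
  ok_fuzzy(seed27) || ok_fuzzy(seed38)
}

#' Shuffle the miRNA of a positive pair to make a negative
#'
#' The site is kept; the mature miRNA's residues are permuted (identity
#' permutations are redrawn, homopolymers rejected), so the nucleotide
#' multiset is conserved but the seed pairing relation is destroyed.
#'
#' @param mirna_seq miRNA sequence string (5'->3').
#' @return List: `mirna_seq` (shuffled string), `perm` (the permutation).
#' @export
shuffle_mirna <- function(mirna_seq) {
  chars <- strsplit(mirna_seq, "", fixed = TRUE)[[1L]]
  if (length(unique(chars)) == 1L) {
    stop("homopolymer miRNA cannot be shuffled into a distinct sequence",
         call. = FALSE)
  }
  repeat {
    perm <- sample.int(length(chars))
    shuf <- paste(chars[perm], collapse = "")
    if (shuf != mirna_seq) return(list(mirna_seq = shuf, perm = perm))
  }
}

#' Configuration for the synthetic dataset generator
#'
#' @param n_pos,n_neg Number of positive / negative pairs.
#' @param site_len Site length (40 for the 66-nt schema, 53 for the 79-nt
#'   schema).
#' @param mirna_len_range Mature miRNA length range.
#' @param n_mirnas Size of the miRNA pool the pairs are drawn from; real
#'   interaction catalogs reuse a finite set of mature miRNAs across many
#'   pairs, and a finite pool is what makes the classification task
#'   learnable at small n.
#' @param p_canonical Probability that a positive uses a canonical seed
#'   (split evenly between the 2-7 and 3-8 registers); the remainder are
#'   non-canonical.
#' @param gu_allowed Allow G-U wobbles in non-canonical sites.
#' @param negative_mode `"shuffle_mirna"` (default; shuffles the miRNA and
#'   keeps the site, as in the curated sets) or `"resample_site"` (keeps
#'   the miRNA and draws a motif-free random site; used when a model must
#'   learn site content, e.g. for gene scanning).
#' @param rng_seed Integer seed; the generator is a pure function of the
#'   config.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_pos = 1000L, n_neg = n_pos, site_len = 40L,
                         mirna_len_range = c(19L, 26L), n_mirnas = 64L,
                         p_canonical = 0.7, gu_allowed = TRUE,
                         negative_mode = c("shuffle_mirna", "resample_site"),
                         rng_seed = 1L) {
  negative_mode <- match.arg(negative_mode)
  stopifnot(n_pos > 0L, n_neg > 0L, site_len >= 8L,
            p_canonical >= 0, p_canonical <= 1, n_mirnas >= 1L,
            mirna_len_range[1L] >= 8L)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 site_len = as.integer(site_len),
                 mirna_len_range = as.integer(mirna_len_range),
                 n_mirnas = as.integer(n_mirnas),
                 p_canonical = p_canonical, gu_allowed = gu_allowed,
                 negative_mode = negative_mode,
                 rng_seed = as.integer(rng_seed)),
            class = "synth_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

draw_mode <- function(cfg) {
  if (stats::runif(1) < cfg$p_canonical) {
    sample(c("canonical_2_7", "canonical_3_8"), 1L)
  } else "noncanonical"
}

#' Generate a synthetic labeled miRNA:site dataset
#'
#' Draws a pool of random mature miRNAs, plants a seed-complementary motif
#' in each positive site, and builds negatives per
#' `cfg$negative_mode`. Output is a pair table (see [read_pair_table()])
#' with provenance columns (`seed_mode`, `site_offset`, `motif`) so every
#' planted structure can be re-verified deterministically.
#'
#' @param cfg A [synth_config()].
#' @return Data frame with columns pair_id, mirna_id, mirna_seq, site_seq,
#'   label, seed_mode, site_offset, motif; row order shuffled;
#'   reproducible from `cfg$rng_seed`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$rng_seed, {
    pool <- replicate(cfg$n_mirnas,
                      random_mirna(cfg$mirna_len_range)$residues)
    make_pos <- function(i) {
      mid <- sample.int(cfg$n_mirnas, 1L)
      mode <- draw_mode(cfg)
      pl <- plant_site(rna_seq(pool[mid]), cfg$site_len, mode, cfg$gu_allowed)
      data.frame(pair_id = sprintf("pos_%05d", i),
                 mirna_id = sprintf("mir_%03d", mid),
                 mirna_seq = pool[mid], site_seq = pl$site$residues,
                 label = 1L, seed_mode = mode, site_offset = pl$offset,
                 motif = pl$motif, stringsAsFactors = FALSE)
    }
    pos <- do.call(rbind, lapply(seq_len(cfg$n_pos), make_pos))
    make_neg <- function(i) {
      mid <- sample.int(cfg$n_mirnas, 1L)
      mode <- draw_mode(cfg)
      pl <- plant_site(rna_seq(pool[mid]), cfg$site_len, mode, cfg$gu_allowed)
      if (cfg$negative_mode == "shuffle_mirna") {
        sh <- shuffle_mirna(pool[mid])
        mir <- sh$mirna_seq
        site <- pl$site$residues
      } else {
        mir <- pool[mid]
        seedc <- revcomp_rna(seed_region(mir, "canonical_2_7"))
        seedc2 <- revcomp_rna(seed_region(mir, "canonical_3_8"))
        repeat {  # motif-free random site
          site <- random_rna_string(cfg$site_len)
          if (!grepl(seedc, site, fixed = TRUE) &&
              !grepl(seedc2, site, fixed = TRUE)) break
        }
      }
      data.frame(pair_id = sprintf("neg_%05d", i),
                 mirna_id = sprintf("mir_%03d", mid),
                 mirna_seq = mir, site_seq = site,
                 label = 0L, seed_mode = NA_character_,
                 site_offset = NA_integer_, motif = NA_character_,
                 stringsAsFactors = FALSE)
    }
    neg <- do.call(rbind, lapply(seq_len(cfg$n_neg), make_neg))
    out <- rbind(pos, neg)
    out[sample.int(nrow(out)), , drop = FALSE]
  })
}

#' Build a synthetic gene carrying planted target sites for one miRNA
#'
#' Returns a random transcript-like sequence of length `gene_len`
#' containing `n_sites` exact seed-complementary motifs (2-7 register) for
#' `mirna` at known, non-overlapping offsets; elsewhere the sequence is
#' kept free of chance exact seed matches so the planted windows are the
#' only true sites.
#'
#' @param mirna An `rna_seq` (5'->3').
#' @param gene_len Gene length in nt.
#' @param n_sites Number of planted sites.
#' @return List: `gene` (`rna_seq`), `offsets` (0-based motif starts).
#' @export
synthetic_target_gene <- function(mirna, gene_len = 500L, n_sites = 1L) {
  stopifnot(inherits(mirna, "rna_seq"), gene_len >= 20L, n_sites >= 1L)
  motif <- revcomp_rna(substr(mirna$residues, 2L, 7L))
  repeat {
    gene <- random_rna_string(gene_len)
    if (!grepl(motif, gene, fixed = TRUE)) break
  }
  # non-overlapping offsets, kept away from each other by one motif length
  offsets <- integer(0)
  tries <- 0L
  while (length(offsets) < n_sites && tries < 1000L) {
    cand <- sample.int(gene_len - nchar(motif) + 1L, 1L) - 1L
    if (all(abs(cand - offsets) >= 2L * nchar(motif)) || length(offsets) == 0L) {
      offsets <- c(offsets, cand)
    }
    tries <- tries + 1L
  }
  offsets <- sort(offsets)
  for (o in offsets) {
    substr(gene, o + 1L, o + nchar(motif)) <- motif
  }
  list(gene = rna_seq(gene), offsets = offsets, motif = motif)
}
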