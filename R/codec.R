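# Sequence normalization, orientation, padding, concatenation and integer
# encoding. All user-facing sequence input is 5'->3'; the miRNA is reversed
# to 3'->5' immediately before concatenation so that the network always sees
# miRNA(3'->5') ++ site(5'->3').

RNA_ALPHABET <- c("A", "U", "G", "C", "N")

#' Construct an RNA sequence with an explicit orientation
#'
#' A thin validated container: a single string over the five-letter alphabet
#' \{A, U, G, C, N\} plus an orientation flag. Orientation is always recorded,
#' never inferred from sequence content.
#'
#' @param residues Single character string over \{A,U,G,C,N\}.
#' @param orientation `"five_to_three"` (default) or `"three_to_five"`.
#' @return An object of class `rna_seq`.
#' @examples
#' rna_seq("AUGCN")
#' @export
rna_seq <- function(residues, orientation = c("five_to_three", "three_to_five")) {
  orientation <- match.arg(orientation)
  stopifnot(is.character(residues), length(residues) == 1L)
  if (nchar(residues) == 0L) stop("empty sequence", call. = FALSE)
  bad <- regmatches(residues, regexpr("[^AUGCN]", residues))
  if (length(bad) > 0L) {
    pos <- regexpr("[^AUGCN]", residues)
    stop(sprintf("invalid symbol '%s' at position %d", bad, pos), call. = FALSE)
  }
  structure(list(residues = residues, orientation = orientation),
            class = "rna_seq")
}

#' @export
print.rna_seq <- function(x, ...) {
  cat(sprintf("<rna_seq %s, %d nt> %s\n",
              sub("_", "'->", sub("_to_", "'", x$orientation)),
              nchar(x$residues), x$residues))
  invisible(x)
}

#' @export
length.rna_seq <- function(x) nchar(x$residues)

#' Normalize a raw sequence string into the model alphabet
#'
#' Uppercases, maps T to U (DNA-alphabet FASTA files are common), and rejects
#' any character outside \{A,U,G,C,N,T\} (either case) with an error naming
#' the offending character and its 1-based position.
#'
#' @param raw Non-empty character string.
#' @param orientation Orientation to record on the result; inputs are
#'   conventionally 5'->3'.
#' @return An `rna_seq` over \{A,U,G,C,N\}.
#' @examples
#' normalize_sequence("atgct")  # "AUGCU"
#' @export
normalize_sequence <- function(raw, orientation = "five_to_three") {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (is.na(raw) || nchar(raw) == 0L) stop("empty sequence", call. = FALSE)
  up <- toupper(raw)
  m <- regexpr("[^AUGCNT]", up)
  if (m > 0L) {
    stop(sprintf("invalid symbol '%s' at position %d",
                 substr(raw, m, m), as.integer(m)), call. = FALSE)
  }
  rna_seq(chartr("T", "U", up), orientation)
}

#' Re-orient a miRNA from 5'->3' to 3'->5'
#'
#' Reverses the residue string and flips the orientation flag. The network
#' input convention places the miRNA 3' end first, so mature miRNAs (always
#' written 5'->3') are reversed once, here, before concatenation. Calling
#' this on an already-reversed sequence is an error (double-reversal guard).
#'
#' @param mirna An `rna_seq` with orientation `five_to_three`.
#' @return The reversed `rna_seq`, orientation `three_to_five`.
#' @export
orient_mirna <- function(mirna) {
  stopifnot(inherits(mirna, "rna_seq"))
  if (mirna$orientation != "five_to_three") {
    stop("sequence is already 3'->5'; refusing to reverse twice", call. = FALSE)
  }
  rna_seq(reverse_string(mirna$residues), "three_to_five")
}

reverse_string <- function(s) {
  paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Right-pad a sequence with N to a fixed slot length
#'
#' @param seq An `rna_seq`.
#' @param slot_len Target length; must be >= the sequence length.
#' @return An `rna_seq` of length `slot_len` whose prefix is the input.
#' @export
pad_sequence <- function(seq, slot_len) {
  stopifnot(inherits(seq, "rna_seq"), slot_len >= 1L)
  n <- nchar(seq$residues)
  if (n > slot_len) {
    stop(sprintf("sequence length %d exceeds slot length %d", n, slot_len),
         call. = FALSE)
  }
  rna_seq(paste0(seq$residues, strrep("N", slot_len - n)), seq$orientation)
}

#' Define a pair-encoding schema (slot lengths)
#'
#' A schema fixes the miRNA slot and site slot lengths; every encoded pair
#' under a schema has length `mirna_slot_len + site_slot_len`.
#' Two named schemas cover the published input conventions:
#' `pair_schema("deepmirtar")` = (26, 53), total 79, and
#' `pair_schema("miraw")` = (26, 40), total 66.
#'
#' @param schema Either a schema name (`"deepmirtar"` or `"miraw"`) or a
#'   positive miRNA slot length.
#' @param site_slot_len Positive site slot length (ignored when `schema` is
#'   a name).
#' @return A `pair_schema` object with fields `mirna_slot_len`,
#'   `site_slot_len`, `total_len`.
#' @examples
#' pair_schema("deepmirtar")$total_len  # 79
#' pair_schema("miraw")$total_len       # 66
#' @export
pair_schema <- function(schema = "deepmirtar", site_slot_len = NULL) {
  if (is.character(schema)) {
    schema <- match.arg(schema, c("deepmirtar", "miraw"))
    dims <- switch(schema, deepmirtar = c(26L, 53L), miraw = c(26L, 40L))
    mirna_slot_len <- dims[1L]
    site_slot_len <- dims[2L]
    name <- schema
  } else {
    mirna_slot_len <- as.integer(schema)
    site_slot_len <- as.integer(site_slot_len)
    stopifnot(mirna_slot_len >= 1L, site_slot_len >= 1L)
    name <- "custom"
  }
  structure(list(name = name,
                 mirna_slot_len = mirna_slot_len,
                 site_slot_len = site_slot_len,
                 total_len = mirna_slot_len + site_slot_len),
            class = "pair_schema")
}

#' @export
print.pair_schema <- function(x, ...) {
  cat(sprintf("<pair_schema '%s'> miRNA slot %d + site slot %d = %d nt\n",
              x$name, x$mirna_slot_len, x$site_slot_len, x$total_len))
  invisible(x)
}

#' Construct one labeled miRNA:site pair
#'
#' @param mirna,site `rna_seq` objects (both stored 5'->3') or raw strings,
#'   which are passed through [normalize_sequence()].
#' @param label 0 (negative) or 1 (positive).
#' @param pair_id Identifier string.
#' @return A `labeled_pair`.
#' @export
labeled_pair <- function(mirna, site, label, pair_id = "") {
  if (!inherits(mirna, "rna_seq")) mirna <- normalize_sequence(mirna)
  if (!inherits(site, "rna_seq")) site <- normalize_sequence(site)
  stopifnot(label %in% c(0, 1))
  structure(list(mirna = mirna, site = site, label = as.integer(label),
                 pair_id = as.character(pair_id)),
            class = "labeled_pair")
}

#' Concatenate a pair into one fixed-length model input sequence
#'
#' The miRNA is reversed to 3'->5', each sequence is right-padded with N to
#' its slot length, and the two are joined: miRNA(3'->5') ++ site(5'->3').
#'
#' @param pair A `labeled_pair`.
#' @param schema A `pair_schema`.
#' @return An `rna_seq` of length `schema$total_len`.
#' @export
concatenate_pair <- function(pair, schema) {
  stopifnot(inherits(pair, "labeled_pair"), inherits(schema, "pair_schema"))
  m <- pad_sequence(orient_mirna(pair$mirna), schema$mirna_slot_len)
  s <- pad_sequence(pair$site, schema$site_slot_len)
  rna_seq(paste0(m$residues, s$residues), "five_to_three")
}

# Fixed letter -> code map; determinism across runs and serialized models.
CODE_OF <- c(A = 0L, U = 1L, G = 2L, C = 3L, N = 4L)

#' Integer-encode a normalized sequence
#'
#' Bijective letter map A=0, U=1, G=2, C=3, N=4. N is a first-class fifth
#' vocabulary letter (it receives its own trainable embedding row, not
#' zeros).
#'
#' @param seq An `rna_seq` or normalized string.
#' @return Integer vector in \{0..4\}, one code per residue.
#' @export
encode_sequence <- function(seq) {
  s <- if (inherits(seq, "rna_seq")) seq$residues else seq
  codes <- CODE_OF[strsplit(s, "", fixed = TRUE)[[1L]]]
  if (anyNA(codes)) stop("sequence is not normalized", call. = FALSE)
  unname(codes)
}

#' Decode an integer vector back into residues
#'
#' Inverse of [encode_sequence()].
#'
#' @param codes Integer vector in \{0..4\}.
#' @return Character string over \{A,U,G,C,N\}.
#' @export
decode_sequence <- function(codes) {
  stopifnot(all(codes %in% 0:4))
  paste(names(CODE_OF)[codes + 1L], collapse = "")
}

#' Encode a table of pairs into a model input matrix
#'
#' The bulk entry point used by training and scanning. Takes a pair table
#' (data frame with columns `mirna_seq`, `site_seq`, `label`, optionally
#' `mirna_id`/`pair_id`) and returns the integer code matrix plus labels.
#'
#' @param pairs Data frame; see [read_pair_table()] for the column contract.
#' @param schema A `pair_schema`.
#' @return List with `x` (integer matrix, one row per pair, `total_len`
#'   columns, values 0..4) and `y` (integer label vector).
#' @export
encode_dataset <- function(pairs, schema) {
  stopifnot(is.data.frame(pairs), nrow(pairs) > 0L,
            all(c("mirna_seq", "site_seq", "label") %in% names(pairs)))
  n <- nrow(pairs)
  x <- matrix(4L, nrow = n, ncol = schema$total_len)  # N everywhere, then fill
  for (i in seq_len(n)) {
    mir <- normalize_sequence(pairs$mirna_seq[i])
    site <- normalize_sequence(pairs$site_seq[i])
    if (length(mir) > schema$mirna_slot_len ||
        length(site) > schema$site_slot_len) {
      stop(sprintf("pair %d exceeds schema slots (%d/%d nt vs %d/%d)",
                   i, length(mir), length(site),
                   schema$mirna_slot_len, schema$site_slot_len), call. = FALSE)
    }
    mc <- rev(encode_sequence(mir))  # reversal == 3'->5' orientation
    sc <- encode_sequence(site)
    x[i, seq_along(mc)] <- mc
    x[i, schema$mirna_slot_len + seq_along(sc)] <- sc
  }
  labs <- as.integer(pairs$label)
  stopifnot(all(labs %in% c(0L, 1L)))
  list(x = x, y = labs)
}

#' Read a delimited miRNA:site pair table
#'
#' Expected columns: `mirna_id`, `mirna_seq`, `site_seq`, `label`
#' (tab-separated, header line). Extra columns are kept. Sequences are not
#' normalized here; normalization happens at encoding time so the file can
#' carry DNA-alphabet or lowercase sequences.
#'
#' @param path File path.
#' @return Data frame, one row per pair.
#' @export
read_pair_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "mirna_seq", "site_seq", "label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("pair table %s lacks column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Write a pair table in the delimited format read by [read_pair_table()]
#'
#' @param pairs Data frame with the pair-table columns.
#' @param path Output path.
#' @export
write_pair_table <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Wraps `Biostrings::readBStringSet` and normalizes every record into the
#' \{A,U,G,C,N\} alphabet (T is mapped to U). The description line is kept
#' as the sequence id.
#'
#' @param path FASTA file path.
#' @return Named character vector of normalized sequences (5'->3').
#' @export
read_fasta_sequences <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  out <- vapply(seqs, function(s) normalize_sequence(s)$residues, character(1))
  names(out) <- names(set)
  out
}
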