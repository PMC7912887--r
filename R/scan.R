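# Sliding-window scanning of long gene/transcript sequences: split into
# overlapped windows matching the model's site slot, score every window
# against a query miRNA, threshold per-site probabilities, and call target
# genes by positive-site count.

#' Scanner configuration
#'
#' @param site_prob_threshold Probability at or above which a window is
#'   called a binding site.
#' @param min_sites_per_gene Number of positive windows required to call
#'   the gene a target.
#' @param step Window step in nt; must be smaller than the window so
#'   consecutive windows overlap. Default `NULL` means half the window
#'   length (50% overlap), which guarantees any site of length
#'   <= window/2 + 1 lies wholly inside some window.
#' @return A `scan_config` object.
#' @export
scan_config <- function(site_prob_threshold = 0.5, min_sites_per_gene = 1L,
                        step = NULL) {
  stopifnot(site_prob_threshold > 0, site_prob_threshold <= 1,
            min_sites_per_gene >= 1L)
  structure(list(site_prob_threshold = site_prob_threshold,
                 min_sites_per_gene = as.integer(min_sites_per_gene),
                 step = if (is.null(step)) NULL else as.integer(step)),
            class = "scan_config")
}

#' Split a gene into overlapped fixed-length windows
#'
#' Windows start at offsets 0, step, 2*step, ...; when the last stride
#' overshoots, one extra window anchored at `gene_len - window_len` is
#' appended so every base is covered. A gene shorter than the window
#' yields a single N-padded window at offset 0.
#'
#' @param gene An `rna_seq` (or normalized string), 5'->3'.
#' @param window_len Window length in nt (the model's site slot length).
#' @param step Step between window starts; must be < `window_len`.
#' @return Data frame: `offset` (0-based), `window` (sequence string).
#' @export
split_gene <- function(gene, window_len, step = window_len %/% 2L) {
  if (!inherits(gene, "rna_seq")) gene <- normalize_sequence(gene)
  glen <- length(gene)
  if (glen == 0L) stop("empty gene", call. = FALSE)
  stopifnot(step >= 1L, step < window_len)
  if (glen <= window_len) {
    win <- pad_sequence(gene, window_len)$residues
    return(data.frame(offset = 0L, window = win, stringsAsFactors = FALSE))
  }
  offsets <- seq.int(0L, glen - window_len, by = step)
  if (offsets[length(offsets)] < glen - window_len) {
    offsets <- c(offsets, glen - window_len)
  }
  data.frame(offset = as.integer(offsets),
             window = substring(gene$residues, offsets + 1L,
                                offsets + window_len),
             stringsAsFactors = FALSE)
}

#' Score gene windows against one miRNA
#'
#' Encodes each (miRNA, window) pair under the model's schema — the miRNA
#' is re-oriented to 3'->5' by the codec, so pass it 5'->3' as written —
#' and runs the forward pass. A window is called a site when its
#' probability is >= the threshold.
#'
#' @param model A trained `mirtar_model` with an attached schema whose site
#'   slot equals the window length.
#' @param mirna `rna_seq` or string, 5'->3'.
#' @param windows Data frame from [split_gene()] (columns `offset`,
#'   `window`), or a vector of window sequences.
#' @param config A [scan_config()].
#' @return Data frame: offset, window, probability, call.
#' @export
predict_sites <- function(model, mirna, windows, config = scan_config()) {
  stopifnot(inherits(model, "mirtar_model"))
  if (is.null(model$schema)) stop("model has no pair schema", call. = FALSE)
  if (!inherits(mirna, "rna_seq")) mirna <- normalize_sequence(mirna)
  if (!is.data.frame(windows)) {
    windows <- data.frame(offset = NA_integer_, window = windows,
                          stringsAsFactors = FALSE)
  }
  wlen <- unique(nchar(windows$window))
  if (length(wlen) != 1L || wlen != model$schema$site_slot_len) {
    stop(sprintf("window length %s does not match model site slot %d",
                 paste(wlen, collapse = "/"), model$schema$site_slot_len),
         call. = FALSE)
  }
  pairs <- data.frame(mirna_seq = mirna$residues, site_seq = windows$window,
                      label = 0L, stringsAsFactors = FALSE)
  prob <- predict(model, pairs)
  data.frame(offset = windows$offset, window = windows$window,
             probability = prob,
             call = prob >= config$site_prob_threshold,
             stringsAsFactors = FALSE)
}

#' Call target genes from window-level results
#'
#' A gene is a target iff its number of positive windows is at least
#' `min_sites_per_gene`.
#'
#' @param window_results Data frame with columns `gene_id` and `call`.
#' @param min_sites_per_gene Threshold on positive-window count.
#' @return Data frame: gene_id, n_positive_sites, is_target.
#' @export
call_genes <- function(window_results, min_sites_per_gene = 1L) {
  stopifnot(all(c("gene_id", "call") %in% names(window_results)))
  agg <- stats::aggregate(call ~ gene_id, data = window_results, FUN = sum)
  names(agg)[2L] <- "n_positive_sites"
  agg$is_target <- agg$n_positive_sites >= min_sites_per_gene
  agg
}

#' Scan one or more genes for targets of one miRNA
#'
#' End-to-end scanner: splits each gene into overlapped windows, scores
#' them, and calls genes. Offsets are 0-based, half-open, on the given
#' strand (no reverse-complement scanning: inputs are transcript/3'UTR
#' sequences already in sense orientation).
#'
#' @param model Trained `mirtar_model` with schema.
#' @param mirna miRNA sequence, 5'->3'.
#' @param genes Named character vector (or named list of `rna_seq`) of gene
#'   sequences, 5'->3'.
#' @param config A [scan_config()].
#' @return A `scan_result`: list with `windows` (per-window data frame
#'   including gene_id) and `genes` (per-gene calls).
#' @export
scan_genes <- function(model, mirna, genes, config = scan_config()) {
  stopifnot(length(genes) > 0L)
  if (is.null(names(genes)) || any(names(genes) == "")) {
    names(genes) <- paste0("gene_", seq_along(genes))
  }
  wlen <- model$schema$site_slot_len
  step <- if (is.null(config$step)) wlen %/% 2L else config$step
  res <- lapply(names(genes), function(gid) {
    w <- split_gene(genes[[gid]], wlen, step)
    out <- predict_sites(model, mirna, w, config)
    out$gene_id <- gid
    out
  })
  windows <- do.call(rbind, res)[, c("gene_id", "offset", "window",
                                     "probability", "call")]
  structure(list(windows = windows,
                 genes = call_genes(windows, config$min_sites_per_gene),
                 config = config),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %d windows over %d gene(s); %d positive site(s), %d target gene(s)\n",
              nrow(x$windows), nrow(x$genes), sum(x$windows$call),
              sum(x$genes$is_target)))
  invisible(x)
}

#' Write positive windows as a FASTA file of target sites
#'
#' One record per positive window; the header carries the gene id, the
#' 0-based offset and the probability
#' (`>gene|offset=..|prob=..`). Zero positive windows produce a valid
#' empty FASTA file.
#'
#' @param result A `scan_result` (or its `windows` data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_fasta <- function(result, path) {
  windows <- if (inherits(result, "scan_result")) result$windows else result
  pos <- windows[windows$call, , drop = FALSE]
  seqs <- Biostrings::BStringSet(pos$window)
  names(seqs) <- sprintf("%s|offset=%d|prob=%.6f",
                         pos$gene_id, pos$offset, pos$probability)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
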