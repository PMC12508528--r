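#' Read a probe panel from FASTA
#'
#' Description lines may carry `gene=SYMBOL` and `stable=1` key-value pairs;
#' a probe with no `stable` key is treated as non-stable, a probe with no
#' `gene` key is assigned its own id as gene symbol.
#'
#' @param path FASTA file.
#' @return Probe panel `data.frame` (probe_id, sequence, gene, is_stable).
#' @export
read_panel_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("empty probe panel", call. = FALSE)
  hdr <- names(x)
  probe_id <- sub("\\s.*$", "", hdr)
  grab <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    out <- rep(NA_character_, length(hdr))
    out[grepl(paste0(key, "="), hdr)] <- sub(paste0(key, "="), "",
                                             m[m != ""], fixed = TRUE)
    out
  }
  gene <- grab("gene")
  stable <- grab("stable")
  panel <- data.frame(
    probe_id = probe_id,
    sequence = unname(as.character(x)),
    gene = ifelse(is.na(gene), probe_id, gene),
    is_stable = !is.na(stable) & stable == "1",
    stringsAsFactors = FALSE, row.names = NULL
  )
  validate_panel(panel)
  panel
}

#' Write a probe panel to FASTA
#'
#' @param panel probe panel data.frame.
#' @param path output file.
#' @export
write_panel_fasta <- function(panel, path) {
  validate_panel(panel)
  x <- Biostrings::DNAStringSet(panel$sequence)
  names(x) <- sprintf("%s gene=%s stable=%d", panel$probe_id, panel$gene,
                      as.integer(panel$is_stable))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("probe_id", "sequence", "gene", "is_stable") %in% names(panel)))
  if (anyDuplicated(panel$probe_id)) stop("probe_ids must be unique", call. = FALSE)
  if (length(unique(nchar(panel$sequence))) != 1L) {
    stop("panel sequences must all have the same length", call. = FALSE)
  }
  if (any(grepl("[^ACGTN]", panel$sequence))) {
    stop("panel sequences must be uppercase ACGT(N)", call. = FALSE)
  }
  invisible(panel)
}

# Split equal-length sequences into a character matrix (one row per sequence).
seq_char_matrix <- function(seqs, len) {
  matrix(unlist(strsplit(seqs, "", fixed = TRUE)), ncol = len, byrow = TRUE)
}

#' Assign reads to probes by minimal Hamming distance
#'
#' Each read goes to the unique probe at minimal Hamming distance, provided
#' that distance is at most `max_mismatches`. Reads beyond the threshold, or
#' tied between two or more probes at the minimum, are discarded and tallied
#' in a per-well `unassigned` counter. `N` bases (in read or probe) always
#' count as mismatches. Only reads of exactly the probe length are accepted.
#'
#' @param reads named list (one element per well) of character vectors of read
#'   sequences, as produced by [gen_reads()] or [read_well_fastq()].
#' @param panel probe panel data.frame.
#' @param max_mismatches maximum Hamming distance for assignment (default 3).
#' @return List with `counts` (well x probe matrix) and `unassigned`
#'   (named per-well counter, including ambiguous ties).
#' @export
count_reads <- function(reads, panel, max_mismatches = 3L) {
  validate_panel(panel)
  if (nrow(panel) == 0L) stop("empty probe panel", call. = FALSE)
  if (max_mismatches < 0) stop("max_mismatches must be >= 0", call. = FALSE)
  len <- nchar(panel$sequence[1])
  pmat <- seq_char_matrix(panel$sequence, len)
  probe_n <- pmat == "N"

  wells <- names(reads)
  counts <- matrix(0L, nrow = length(wells), ncol = nrow(panel),
                   dimnames = list(wells, panel$probe_id))
  unassigned <- stats::setNames(integer(length(wells)), wells)

  for (w in wells) {
    r <- reads[[w]]
    if (length(r) == 0) next
    if (any(nchar(r) != len)) {
      stop(sprintf("well %s: reads must match probe length %d (no trim policy)",
                   w, len), call. = FALSE)
    }
    rmat <- seq_char_matrix(r, len)
    read_n <- rmat == "N"
    # distance matrix reads x probes
    d <- matrix(0L, nrow = length(r), ncol = nrow(panel))
    for (p in seq_len(nrow(panel))) {
      mism <- rmat != matrix(pmat[p, ], nrow = length(r), ncol = len,
                             byrow = TRUE)
      mism <- mism | read_n | matrix(probe_n[p, ], nrow = length(r),
                                     ncol = len, byrow = TRUE)
      d[, p] <- rowSums(mism)
    }
    dmin <- apply(d, 1, min)
    n_at_min <- rowSums(d == dmin)
    ok <- dmin <= max_mismatches & n_at_min == 1L
    if (any(ok)) {
      assigned <- max.col(-d[ok, , drop = FALSE])
      tab <- table(factor(assigned, levels = seq_len(nrow(panel))))
      counts[w, ] <- counts[w, ] + as.integer(tab)
    }
    unassigned[w] <- sum(!ok)
  }
  list(counts = counts, unassigned = unassigned)
}

#' Read one well's reads from FASTQ
#'
#' @param path FASTQ file (plain or gzip).
#' @return Named character vector of read sequences.
#' @export
read_well_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' Normalize a screen count table to its stable probes
#'
#' Per-well size factor = (sum of stable-probe counts in the well) divided by
#' the across-well median of those sums, so stable-gene totals are equalized
#' across wells while values stay on the count scale. Every well must have
#' nonzero stable counts.
#'
#' @param counts well x probe count matrix.
#' @param panel probe panel data.frame; `is_stable` marks the anchors.
#' @return List with `values` (counts / size factor) and `size_factors`
#'   (per-well, named).
#' @export
normalize_stable <- function(counts, panel) {
  validate_panel(panel)
  stable <- panel$probe_id[panel$is_stable]
  if (length(stable) == 0L) stop("panel has no stable probes", call. = FALSE)
  stable <- intersect(stable, colnames(counts))
  if (length(stable) == 0L) stop("no stable probes in count table", call. = FALSE)
  ssum <- rowSums(counts[, stable, drop = FALSE])
  zero <- ssum == 0
  if (any(zero)) {
    stop("wells with zero stable counts: ",
         paste(rownames(counts)[zero], collapse = ", "), call. = FALSE)
  }
  sf <- ssum / stats::median(ssum)
  values <- counts / sf
  list(values = values, size_factors = stats::setNames(sf, rownames(counts)))
}
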