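.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Position weight matrix of log2 odds
#'
#' Converts a position frequency matrix into log2-odds scores against a
#' background base composition, with additive pseudocounts distributed by
#' the background:
#' `p[b, c] = (count[b, c] + pseudocount * bg[b]) / (colsum[c] + pseudocount)`
#' and `cell = log2(p / bg)`.
#'
#' @param pfm list with a 4 x width `counts` matrix (see [read_jaspar_pfm()]),
#'   or such a matrix directly.
#' @param pseudocount total pseudocount per column (default 0.8).
#' @param background base probabilities in A, C, G, T order (default uniform).
#' @return 4 x width numeric matrix of log2 odds (rownames A/C/G/T).
#' @export
pwm_log_odds <- function(pfm, pseudocount = 0.8, background = rep(0.25, 4)) {
  counts <- if (is.list(pfm)) pfm$counts else pfm
  stopifnot(nrow(counts) == 4)
  if (is.null(rownames(counts))) rownames(counts) <- .BASES
  counts <- counts[.BASES, , drop = FALSE]
  if (any(counts < 0)) stop("negative PFM entries")
  if (abs(sum(background) - 1) > 1e-9 || any(background <= 0))
    stop("background must be 4 positive probabilities summing to 1")
  tot <- colSums(counts)
  if (any(tot == 0)) stop("PFM column with zero total")
  p <- sweep(counts, 2, tot + pseudocount, "/") +
    outer(background * pseudocount, 1 / (tot + pseudocount))
  # columns of p sum to 1 by construction
  log2(p / background)
}

.revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# score matrix lookup with N scoring as background (0 contribution)
.seq_index <- function(seq) {
  idx <- match(strsplit(seq, "")[[1]], .BASES)  # N -> NA
  idx
}

.scan_one_strand <- function(idx, lom) {
  w <- ncol(lom)
  n <- length(idx)
  if (n < w) return(numeric(0))
  npos <- n - w + 1L
  scores <- numeric(npos)
  for (j in seq_len(w)) {
    col <- lom[, j]
    b <- idx[j:(j + npos - 1L)]
    contrib <- ifelse(is.na(b), 0, col[b])
    scores <- scores + contrib
  }
  scores
}

#' Scan a sequence with a log-odds matrix
#'
#' Scores every window on both strands and reports windows whose relative
#' score, `(score - min_possible) / (max_possible - min_possible)`, reaches
#' `min_rel_score`. Reverse-strand hits are reported in forward coordinates
#' (0-based, half-open within the sequence). Windows containing N score those
#' positions as background (zero contribution).
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param lom log-odds matrix from [pwm_log_odds()].
#' @param min_rel_score relative-score threshold in [0, 1] (default 0.8).
#' @param seq_id id recorded in the output (default "seq").
#' @return data.frame `seq_id`, `start`, `end`, `strand`, `score`, `rel_score`.
#' @export
scan_sequence <- function(seq, lom, min_rel_score = 0.8, seq_id = "seq") {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("sequence contains characters outside ACGTN")
  w <- ncol(lom)
  smax <- sum(apply(lom, 2, max))
  smin <- sum(apply(lom, 2, min))
  if (smax - smin <= 0) stop("degenerate log-odds matrix (max == min score)")
  empty <- data.frame(seq_id = character(), start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      rel_score = numeric(), stringsAsFactors = FALSE)
  if (nchar(seq) < w) return(empty)

  idx <- .seq_index(seq)
  # reverse strand: score the forward sequence with the reverse-complemented
  # matrix so hit coordinates are already in forward space
  lom_rc <- lom[c("T", "G", "C", "A"), rev(seq_len(w)), drop = FALSE]
  rownames(lom_rc) <- .BASES
  hits <- list()
  for (strand in c("+", "-")) {
    scores <- .scan_one_strand(idx, if (strand == "+") lom else lom_rc)
    rel <- (scores - smin) / (smax - smin)
    keep <- which(rel >= min_rel_score)
    if (length(keep)) {
      hits[[strand]] <- data.frame(seq_id = seq_id, start = keep - 1L,
                                   end = keep - 1L + w, strand = strand,
                                   score = scores[keep], rel_score = rel[keep],
                                   stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty)
  res <- do.call(rbind, hits)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Keep motif hits inside accessible regions
#'
#' Translates hit coordinates to genomic space by `seq_origin` and retains
#' hits overlapping at least one open peak by >= 1 bp.
#'
#' @param hits data.frame from [scan_sequence()].
#' @param open_peaks peak data.frame of accessible regions.
#' @param seq_origin genomic start (0-based) of the scanned sequence.
#' @param chrom chromosome of the scanned sequence.
#' @return the retained hits with genomic `gstart`, `gend`, `chrom` columns.
#' @export
hits_in_open_regions <- function(hits, open_peaks, seq_origin, chrom) {
  hits$gstart <- hits$start + as.integer(seq_origin)
  hits$gend <- hits$end + as.integer(seq_origin)
  hits$chrom <- chrom
  pk <- open_peaks[open_peaks$chrom == chrom, , drop = FALSE]
  if (!nrow(pk) || !nrow(hits)) return(hits[integer(0), , drop = FALSE])
  ov <- IRanges::overlapsAny(IRanges::IRanges(hits$gstart + 1L, hits$gend),
                             IRanges::IRanges(pk$start + 1L, pk$end))
  out <- hits[ov, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write motif hits as BED6
#'
#' Genomic coordinates, motif id as name, `round(1000 * rel_score)` as score.
#'
#' @param hits output of [hits_in_open_regions()] (needs genomic columns).
#' @param path output file.
#' @param motif_id name column value (default "motif").
#' @export
write_hits_bed <- function(hits, path, motif_id = "motif") {
  bed <- data.frame(hits$chrom, hits$gstart, hits$gend, motif_id,
                    round(1000 * hits$rel_score), hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
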