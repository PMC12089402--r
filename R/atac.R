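#' Filter peaks by maximum count
#'
#' Keeps peaks with strictly more than `threshold` counts in at least one
#' sample.
#'
#' @param counts raw peak count matrix.
#' @param threshold strict lower bound on the per-peak maximum (default 50).
#' @return the filtered count matrix.
#' @export
filter_peaks_min_count <- function(counts, threshold = 50) {
  keep <- apply(counts, 1, max) > threshold
  counts[keep, , drop = FALSE]
}

#' Sort and merge genomic intervals
#'
#' Per chromosome, unions intervals that overlap or are bookended (a gap of
#' zero merges, matching bedtools-merge defaults). Output is sorted by
#' (chrom, start) with ids synthesised from the merged coordinates.
#'
#' @param peaks peak data.frame (`chrom`, `start`, `end`, 0-based half-open).
#' @return merged, sorted peak data.frame.
#' @export
merge_intervals <- function(peaks) {
  peaks <- validate_peaks(peaks)
  pieces <- lapply(sort(unique(peaks$chrom)), function(ch) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = p$start + 1L, end = p$end))
    data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$peak_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  rownames(out) <- NULL
  out
}

#' Two-stage consensus peak set
#'
#' Merges peaks within each condition first, then merges the union of the
#' per-condition consensus sets into one global, non-overlapping peak set.
#'
#' @param per_condition named list of peak data.frames, one per condition
#'   (e.g. WT / het / KO within a cell-line context).
#' @return list with `peaks` (merged data.frame) and `provenance`
#'   (condition names).
#' @export
consensus_peaks <- function(per_condition) {
  if (!length(per_condition)) stop("consensus_peaks needs >= 1 condition")
  stage1 <- lapply(per_condition, merge_intervals)
  all <- do.call(rbind, lapply(stage1, function(p) p[, c("chrom", "start", "end", "peak_id")]))
  rownames(all) <- NULL
  all$peak_id <- sprintf("s1_%d", seq_len(nrow(all)))  # stage-1 ids may collide across conditions
  list(peaks = merge_intervals(all), provenance = names(per_condition))
}

#' Build strand-aware promoter windows
#'
#' The window spans `[tss - upstream, tss + downstream)` on the + strand and
#' is mirrored on the - strand; coordinates are clipped at zero.
#'
#' @param promoters data.frame `gene`, `chrom`, `tss`, `strand`.
#' @param upstream,downstream window extents in bp (defaults 3000/3000).
#' @return data.frame with `window_start`, `window_end` columns added.
#' @export
promoter_windows <- function(promoters, upstream = 3000, downstream = 3000) {
  stopifnot(upstream >= 0, downstream >= 0, upstream + downstream > 0)
  plus <- promoters$strand == "+"
  ws <- ifelse(plus, promoters$tss - upstream, promoters$tss - downstream)
  we <- ifelse(plus, promoters$tss + downstream, promoters$tss + upstream)
  promoters$window_start <- pmax(0L, as.integer(ws))
  promoters$window_end <- as.integer(we)
  promoters
}

#' Assign peaks to promoter windows
#'
#' One assignment per (peak, gene) pair whose intervals overlap by >= 1 bp; a
#' peak overlapping two promoters serves both genes. The reported distance is
#' the signed offset of the peak midpoint from the TSS in the direction of
#' transcription.
#'
#' @param peaks peak data.frame.
#' @param windows output of [promoter_windows()].
#' @return data.frame `peak_id`, `gene`, `distance_to_tss`.
#' @export
annotate_promoter <- function(peaks, windows) {
  peaks <- validate_peaks(peaks)
  out <- list()
  for (ch in intersect(unique(peaks$chrom), unique(windows$chrom))) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    w <- windows[windows$chrom == ch, , drop = FALSE]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(p$start + 1L, p$end),
      IRanges::IRanges(w$window_start + 1L, w$window_end))
    if (!length(hits)) next
    pi <- S4Vectors::queryHits(hits); wi <- S4Vectors::subjectHits(hits)
    mid <- (p$start[pi] + p$end[pi]) %/% 2L
    dist <- ifelse(w$strand[wi] == "+", mid - w$tss[wi], w$tss[wi] - mid)
    out[[ch]] <- data.frame(peak_id = p$peak_id[pi], gene = w$gene[wi],
                            distance_to_tss = as.integer(dist),
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(peak_id = character(), gene = character(),
                      distance_to_tss = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene, res$peak_id), , drop = FALSE]
}

#' Differential openness of ATAC peaks
#'
#' Delegates to [nb_wald_test()] on the peak count matrix: controls vs pooled
#' het + KO mutants, significance at |log2FC| > `lfc_threshold` and
#' BH-adjusted p < `alpha`.
#'
#' @inheritParams nb_wald_test
#' @return DESeq2-style results data.frame (see [nb_wald_test()]).
#' @export
differential_openness <- function(counts, samples, lfc_threshold = 1, alpha = 0.1,
                                  size_factors = NULL) {
  nb_wald_test(counts, samples, lfc_threshold = lfc_threshold, alpha = alpha,
               size_factors = size_factors)
}

#' Per-gene promoter openness report
#'
#' Collects the differential-openness statistics of every peak assigned to a
#' gene's promoter and summarises them into one flag: `closed` if at least one
#' significantly less-open peak and no significantly more-open one (a
#' "partially closed" promoter), `opened` mirrored, `mixed` if both, and
#' `unchanged` otherwise.
#'
#' @param gene gene id.
#' @param do_results data.frame from [differential_openness()].
#' @param assignments data.frame from [annotate_promoter()].
#' @return list with `gene`, `flag`, and the per-peak `peaks` data.frame.
#' @export
promoter_openness_report <- function(gene, do_results, assignments) {
  pk <- assignments$peak_id[assignments$gene == gene]
  tab <- do_results[do_results$feature %in% pk, , drop = FALSE]
  rownames(tab) <- NULL
  down <- any(tab$significant & tab$log2FoldChange < 0)
  up <- any(tab$significant & tab$log2FoldChange > 0)
  flag <- if (down && up) "mixed" else if (down) "closed" else if (up) "opened" else "unchanged"
  list(gene = gene, flag = flag, peaks = tab)
}
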