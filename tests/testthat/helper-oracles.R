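# Independent brute-force oracles and tiny fixture builders. Every oracle
# here is written from the definition, not from the implementation it checks.

# Benjamini-Hochberg by the step-up definition:
# padj_(i) = min_{j >= i} (m * p_(j) / j), clipped at 1, in input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# interval union per chromosome via a boolean mask over base pairs
interval_union_oracle <- function(peaks) {
  res <- list()
  for (ch in sort(unique(peaks$chrom))) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    n <- max(p$end)
    mask <- logical(n)
    for (i in seq_len(nrow(p))) mask[(p$start[i] + 1):p$end[i]] <- TRUE
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    res[[ch]] <- data.frame(chrom = ch, start = starts[keep], end = ends[keep],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# all-pairs peak-to-window overlap test from the definition
promoter_overlap_oracle <- function(peaks, windows) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(windows))) {
      if (peaks$chrom[i] == windows$chrom[j] &&
          peaks$start[i] < windows$window_end[j] &&
          peaks$end[i] > windows$window_start[j]) {
        mid <- (peaks$start[i] + peaks$end[i]) %/% 2L
        d <- if (windows$strand[j] == "+") mid - windows$tss[j] else windows$tss[j] - mid
        rows[[length(rows) + 1L]] <- data.frame(
          peak_id = peaks$peak_id[i], gene = windows$gene[j],
          distance_to_tss = as.integer(d), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(peak_id = character(), gene = character(),
                      distance_to_tss = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$gene, out$peak_id), , drop = FALSE]
}

# exhaustive motif scan: score every window on both strands by direct lookup
revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

scan_oracle <- function(seq, lom, min_rel) {
  w <- ncol(lom)
  smax <- sum(apply(lom, 2, max)); smin <- sum(apply(lom, 2, min))
  score_window <- function(win) {
    b <- strsplit(win, "")[[1]]
    sum(vapply(seq_len(w), function(j) {
      if (b[j] == "N") 0 else lom[b[j], j]
    }, 0))
  }
  rows <- list()
  for (s0 in seq_len(nchar(seq) - w + 1L)) {
    win <- substr(seq, s0, s0 + w - 1L)
    for (strand in c("+", "-")) {
      sc <- score_window(if (strand == "+") win else revcomp_chr(win))
      rel <- (sc - smin) / (smax - smin)
      if (rel >= min_rel) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = s0 - 1L, end = s0 - 1L + w, strand = strand,
          score = sc, rel_score = rel, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      score = numeric(), rel_score = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

# --- tiny fixture builders ---------------------------------------------------

make_samples <- function(n_control, n_mutant, context = "A", reps = 1L) {
  geno <- c(rep("WT", n_control), rep(c("HET", "KO"), length.out = n_mutant))
  rows <- list()
  for (i in seq_along(geno)) {
    clone <- sprintf("%s_c%d", context, i)
    for (r in seq_len(reps)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_r%d", clone, r), context = context,
        genotype = geno[i], clone_id = clone, tech_rep = r,
        stringsAsFactors = FALSE)
    }
  }
  cotfinder::validate_sample_sheet(do.call(rbind, rows))
}

make_counts <- function(samples, n_features = 50, mu = 100, alpha = 0.1,
                        lfc = NULL, seed = 1) {
  set.seed(seed)
  mut <- samples$genotype_group == "MUTANT"
  if (is.null(lfc)) lfc <- numeric(n_features)
  m <- outer(rep(mu, n_features), rep(1, nrow(samples))) * 2^outer(lfc, as.numeric(mut))
  counts <- matrix(rnbinom(length(m), mu = as.vector(m), size = 1 / alpha),
                   nrow = n_features,
                   dimnames = list(sprintf("F%03d", seq_len(n_features)),
                                   samples$sample_id))
  counts
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000, seed = 1) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(300, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + width, peak_id = sprintf("p%03d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# minimal per-context results structure for inference tests
make_context <- function(de_table, openness = character(0), expressed = NULL) {
  deg <- data.frame(feature = names(de_table),
                    baseMean = 100,
                    log2FoldChange = unname(de_table),
                    lfcSE = 0.1, stat = 0,
                    pvalue = ifelse(de_table != 0, 1e-6, 0.9),
                    padj = ifelse(de_table != 0, 1e-4, 0.95),
                    significant = de_table != 0,
                    stringsAsFactors = FALSE)
  if (is.null(expressed)) expressed <- names(de_table)
  list(deg = deg, openness = openness, expressed = expressed)
}
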