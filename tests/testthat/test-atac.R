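test_that("peak count filter keeps only maxima strictly above threshold", {
  m <- rbind(flat50 = c(50L, 50L, 50L),
             one51 = c(0L, 0L, 51L),
             high = c(200L, 10L, 5L))
  colnames(m) <- sprintf("s%d", 1:3)
  kept <- filter_peaks_min_count(m)
  expect_identical(rownames(kept), c("one51", "high"))

  set.seed(6)
  r <- matrix(rpois(300, 45), 100, dimnames = list(sprintf("p%03d", 1:100), sprintf("s%d", 1:3)))
  expect_identical(rownames(filter_peaks_min_count(r)),
                   rownames(r)[apply(r, 1, max) > 50])
})

test_that("interval merging unions overlapping and bookended intervals", {
  p <- data.frame(chrom = "chr1", start = c(100L, 150L), end = c(200L, 250L),
                  peak_id = c("a", "b"))
  m <- merge_intervals(p)
  expect_identical(m[, c("start", "end")], data.frame(start = 100L, end = 250L))

  pb <- data.frame(chrom = "chr1", start = c(100L, 200L), end = c(200L, 300L),
                   peak_id = c("a", "b"))
  mb <- merge_intervals(pb)
  expect_identical(nrow(mb), 1L)
  expect_identical(c(mb$start, mb$end), c(100L, 300L))

  r <- random_peaks(200, seed = 10)
  got <- merge_intervals(r)
  oracle <- interval_union_oracle(r)
  expect_equal(got[, c("chrom", "start", "end")], oracle)

  # idempotence
  expect_equal(merge_intervals(got), got)
})

test_that("consensus peaks are a two-stage merge, order-invariant", {
  a <- random_peaks(30, seed = 1)
  b <- random_peaks(30, seed = 2)
  cc <- random_peaks(30, seed = 3)

  one <- consensus_peaks(list(x = a))
  expect_equal(one$peaks, merge_intervals(a))

  d1 <- data.frame(chrom = "chr1", start = 0L, end = 10L, peak_id = "u")
  d2 <- data.frame(chrom = "chr1", start = 100L, end = 120L, peak_id = "v")
  expect_identical(nrow(consensus_peaks(list(A = d1, B = d2))$peaks), 2L)

  cons <- consensus_peaks(list(A = a, B = b, C = cc))
  oneshot <- merge_intervals(rbind(
    a[, c("chrom", "start", "end")] |> transform(peak_id = sprintf("q%d", 1:30)),
    b[, c("chrom", "start", "end")] |> transform(peak_id = sprintf("r%d", 1:30)),
    cc[, c("chrom", "start", "end")] |> transform(peak_id = sprintf("s%d", 1:30))))
  expect_equal(cons$peaks, oneshot)   # two-stage merge is idempotent

  shuffled <- consensus_peaks(list(C = cc[sample(30), ], A = a[sample(30), ], B = b))
  expect_equal(shuffled$peaks, cons$peaks)
  expect_error(consensus_peaks(list()), "condition")
})

test_that("promoter assignment matches the all-pairs overlap definition", {
  prom <- data.frame(gene = c("gX", "gY"), chrom = "chr1",
                     tss = c(1000L, 4000L), strand = c("+", "-"),
                     stringsAsFactors = FALSE)
  win <- promoter_windows(prom, 3000, 3000)

  centered <- data.frame(chrom = "chr1", start = 980L, end = 1020L, peak_id = "c")
  asn <- annotate_promoter(centered, win)
  expect_true(any(asn$gene == "gX" & asn$distance_to_tss == 0L))

  far <- data.frame(chrom = "chr1", start = 9000L, end = 9100L, peak_id = "f")
  expect_identical(nrow(annotate_promoter(far, win)), 0L)

  set.seed(12)
  prom_r <- data.frame(gene = sprintf("g%02d", 1:10), chrom = sample(c("chr1", "chr2"), 10, TRUE),
                       tss = sample.int(6000, 10), strand = sample(c("+", "-"), 10, TRUE),
                       stringsAsFactors = FALSE)
  win_r <- promoter_windows(prom_r, 500, 500)
  peaks_r <- random_peaks(60, max_pos = 7000, seed = 13)
  got <- annotate_promoter(peaks_r, win_r)
  oracle <- promoter_overlap_oracle(peaks_r, win_r)
  rownames(got) <- rownames(oracle) <- NULL
  expect_equal(got, oracle)
  # never duplicated per (peak, gene)
  expect_false(anyDuplicated(paste(got$peak_id, got$gene)) > 0)
})

test_that("differential openness finds a planted closing peak and is calibrated", {
  ss <- make_samples(3, 5)
  m <- make_counts(ss, n_features = 200, mu = 300, alpha = 0.05,
                   lfc = c(-1.5, rep(0, 199)), seed = 1)
  rownames(m) <- sprintf("peak%03d", 1:200)
  res <- differential_openness(m, ss)
  expect_true(res$significant[1])
  expect_lt(res$log2FoldChange[1], 0)
  expect_lte(mean(res$padj[-1] < 0.1, na.rm = TRUE), 0.05)

  swapped <- ss
  swapped$genotype_group <- ifelse(ss$genotype_group == "CONTROL", "MUTANT", "CONTROL")
  res_s <- differential_openness(m, swapped)
  expect_equal(res_s$log2FoldChange, -res$log2FoldChange)
})

test_that("promoter openness flags summarise significant peak directions", {
  do_res <- data.frame(feature = c("p1", "p2", "p3", "p4"),
                       baseMean = 100,
                       log2FoldChange = c(-1.6, 0.2, 1.2, -1.2),
                       lfcSE = 0.2, stat = 0, pvalue = 0.01,
                       padj = c(0.01, 0.8, 0.02, 0.04),
                       significant = c(TRUE, FALSE, TRUE, TRUE),
                       stringsAsFactors = FALSE)
  asn <- data.frame(peak_id = c("p1", "p2", "p3", "p4"),
                    gene = c("closing", "closing", "both", "both"),
                    distance_to_tss = 0L, stringsAsFactors = FALSE)
  expect_identical(promoter_openness_report("closing", do_res, asn)$flag, "closed")
  expect_identical(promoter_openness_report("both", do_res, asn)$flag, "mixed")
  asn_null <- data.frame(peak_id = "p2", gene = "quiet", distance_to_tss = 0L)
  expect_identical(promoter_openness_report("quiet", do_res, asn_null)$flag, "unchanged")
})
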