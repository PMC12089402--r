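#' Pipeline configuration
#'
#' Collects every threshold of the analysis in one place, so a bare run uses
#' the standard regime throughout: DE/DO calls at
#' |log2FC| > 1 and BH-adjusted p < 0.1, gene filter mean > 5, peak filter
#' max > 50, promoter windows of TSS +/- 3000 bp, motif relative score 0.8,
#' physical PPI edges at any score, cohort VAF cutoff 5%.
#'
#' @param target target gene id (default "TGT", the simulator's).
#' @param lfc_threshold,alpha differential-call thresholds.
#' @param gene_min_mean RNA expression filter.
#' @param peak_min_count ATAC peak filter.
#' @param promoter_upstream,promoter_downstream promoter window in bp.
#' @param motif_min_rel_score motif-scan relative-score threshold.
#' @param ppi_min_score minimum physical-interaction score.
#' @param vaf_min cohort allelic-fraction cutoff.
#' @param exclude_target_regulators see [hypothesis2()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(target = "TGT", lfc_threshold = 1, alpha = 0.1,
                            gene_min_mean = 5, peak_min_count = 50,
                            promoter_upstream = 3000, promoter_downstream = 3000,
                            motif_min_rel_score = 0.8, ppi_min_score = 0,
                            vaf_min = 0.05, exclude_target_regulators = TRUE) {
  stopifnot(nzchar(target), lfc_threshold > 0, alpha > 0, peak_min_count > 0)
  cfg <- list(target = target, lfc_threshold = lfc_threshold, alpha = alpha,
              gene_min_mean = gene_min_mean, peak_min_count = peak_min_count,
              promoter_upstream = promoter_upstream,
              promoter_downstream = promoter_downstream,
              motif_min_rel_score = motif_min_rel_score,
              ppi_min_score = ppi_min_score, vaf_min = vaf_min,
              exclude_target_regulators = exclude_target_regulators)
  class(cfg) <- "pipeline_config"
  cfg
}

# per-context stage: collapse, filter, DE; peak filter, DO; promoter flags
.run_context <- function(ctx_name, ctx, promoters, config) {
  rna <- collapse_technical_replicates(ctx$rna$counts, ctx$rna$samples)
  rna_f <- filter_low_expression(rna$counts, config$gene_min_mean)
  deg <- nb_wald_test(rna_f, rna$samples, lfc_threshold = config$lfc_threshold,
                      alpha = config$alpha)
  expressed <- rownames(rna_f)

  atac <- collapse_technical_replicates(ctx$atac$counts, ctx$atac$samples)
  atac_f <- filter_peaks_min_count(atac$counts, config$peak_min_count)
  do_res <- differential_openness(atac_f, atac$samples,
                                  lfc_threshold = config$lfc_threshold,
                                  alpha = config$alpha)
  windows <- promoter_windows(promoters, config$promoter_upstream,
                              config$promoter_downstream)
  kept_peaks <- ctx$atac$peaks[ctx$atac$peaks$peak_id %in% rownames(atac_f), , drop = FALSE]
  assignments <- annotate_promoter(kept_peaks, windows)
  genes_with_peaks <- unique(assignments$gene)
  openness <- vapply(genes_with_peaks, function(g) {
    promoter_openness_report(g, do_res, assignments)$flag
  }, "")
  list(context = ctx_name, deg = deg, do = do_res, assignments = assignments,
       openness = openness, expressed = expressed, open_peaks = kept_peaks)
}

#' Run the full inference pipeline
#'
#' Chains, per context, replicate collapsing, expression filtering and the
#' controls-vs-mutants NB Wald test; peak filtering, differential openness and
#' promoter-openness flags; then tests hypothesis I (a direct target regulator
#' is mutually differentially expressed), and on its failure hypothesis II
#' (a mutually differential co-TF physically linked to a shared target
#' regulator), corroborated by a motif scan of the target promoter restricted
#' to accessible peaks. Deterministic for fixed inputs.
#'
#' @param bundle an input bundle (see [simulate_bundle()]); the same structure
#'   can be assembled from files with the `read_*` functions.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, result tables and a JSON
#'   summary are written there.
#' @return list with `contexts` (per-context DE/DO/openness results),
#'   `regulators`, `hypothesis1`, `candidates`, `motif_hits`, and `summary`.
#' @export
run_pipeline <- function(bundle, config = pipeline_config()) {
  target <- config$target
  ctx_results <- lapply(names(bundle$contexts), function(nm) {
    tryCatch(.run_context(nm, bundle$contexts[[nm]], bundle$promoters, config),
             error = function(e) stop("context stage [", nm, "]: ",
                                      conditionMessage(e), call. = FALSE))
  })
  names(ctx_results) <- names(bundle$contexts)
  cr <- lapply(ctx_results, function(x) {
    list(deg = x$deg, openness = x$openness, expressed = x$expressed)
  })

  regs <- target_regulating_tfs(target, bundle$regulon, cr)
  h1 <- hypothesis1(target, bundle$regulon, cr)

  # motif evidence: the partner TF's motif in the accessible target promoter
  lom <- pwm_log_odds(bundle$pfm)
  hits <- scan_sequence(bundle$promoter_seq[[1]], lom,
                        min_rel_score = config$motif_min_rel_score,
                        seq_id = names(bundle$promoter_seq)[1])
  target_open <- do.call(rbind, lapply(ctx_results, function(x) {
    pk <- x$assignments$peak_id[x$assignments$gene == target]
    x$open_peaks[x$open_peaks$peak_id %in% pk, , drop = FALSE]
  }))
  open_hits <- hits_in_open_regions(hits, target_open, bundle$seq_origin,
                                    bundle$seq_chrom)
  motif_partners <- if (nrow(open_hits) > 0) bundle$pfm$name else character(0)

  candidates <- NULL
  if (h1$status == "failed") {
    candidates <- hypothesis2(target, bundle$regulon, bundle$ppi, cr,
                              min_score = config$ppi_min_score,
                              exclude_target_regulators = config$exclude_target_regulators,
                              motif_supported_partners = motif_partners)
  }

  summary <- if (h1$status == "explained") {
    list(verdict = "hypothesis1", target = target,
         explained_by = h1$explained_by$tf)
  } else if (!is.null(candidates) && nrow(candidates) > 0) {
    list(verdict = "hypothesis2", target = target,
         top_candidate = candidates$cotf[1],
         top_partner = candidates$best_partner[1],
         direction = candidates$direction[1],
         rank_score = candidates$rank_score[1],
         n_candidates = nrow(candidates),
         motif_hits_in_open_promoter = nrow(open_hits))
  } else {
    list(verdict = "no candidate", target = target,
         motif_hits_in_open_promoter = nrow(open_hits))
  }

  list(contexts = ctx_results, regulators = regs, hypothesis1 = h1,
       candidates = candidates, motif_hits = open_hits, summary = summary,
       config = config)
}

#' Write pipeline outputs
#'
#' Per-context DE and DO tables, promoter assignments, the candidate table,
#' motif hits (BED6) and the JSON summary.
#'
#' @param result output of [run_pipeline()].
#' @param out_dir output directory.
#' @return invisibly, the written file paths.
#' @export
write_pipeline_results <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, path)
  }
  for (nm in names(result$contexts)) {
    x <- result$contexts[[nm]]
    wr(x$deg, sprintf("deg_%s.tsv", nm))
    wr(x$do, sprintf("do_%s.tsv", nm))
    wr(x$assignments, sprintf("promoter_assignments_%s.tsv", nm))
    wr(data.frame(gene = names(x$openness), flag = unname(x$openness)),
       sprintf("promoter_openness_%s.tsv", nm))
  }
  if (!is.null(result$candidates)) wr(result$candidates, "cotf_candidates.tsv")
  if (nrow(result$motif_hits) > 0) {
    path <- file.path(out_dir, "motif_hits.bed")
    write_hits_bed(result$motif_hits, path)
    paths <- c(paths, path)
  }
  spath <- file.path(out_dir, "summary.json")
  jsonlite::write_json(c(result$summary, list(config = unclass(result$config))),
                       spath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, spath))
}
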