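# The two-hypothesis engine. A "context" is one cell-line background carrying
# its own differential-expression table, promoter-openness flags, and
# expressed-gene set; all set logic intersects evidence across contexts.
#
# context_results: named list, one element per context, each a list with
#   deg       - data.frame from nb_wald_test (rows keyed by `feature`)
#   openness  - named character vector gene -> {closed, opened, unchanged, mixed}
#   expressed - character vector of genes passing the expression filter

.de_row <- function(deg, gene) deg[match(gene, deg$feature), , drop = FALSE]

# Signed DE call: -1 / +1 when the compound call (|lfc| > threshold and
# padj < alpha, i.e. the `significant` flag) holds, 0 otherwise.
.de_sign <- function(deg, gene) {
  r <- .de_row(deg, gene)
  if (is.na(r$feature) || !isTRUE(r$significant)) return(0L)
  as.integer(sign(r$log2FoldChange))
}

#' Target-regulating TFs per context
#'
#' The regulon edges pointing at the target, restricted per context to TFs in
#' that context's expressed-gene set; self-edges are ignored.
#'
#' @param target target gene id.
#' @param regulon regulon data.frame (`tf`, `target`, ...).
#' @param context_results per-context results list (see package docs).
#' @return list with `per_context` (named list of TF character vectors) and
#'   `shared` (their intersection).
#' @export
target_regulating_tfs <- function(target, regulon, context_results) {
  tfs <- unique(regulon$tf[regulon$target == target & regulon$tf != target])
  if (!length(tfs)) stop("target '", target, "' absent from regulon")
  per_context <- lapply(context_results, function(cr) sort(intersect(tfs, cr$expressed)))
  shared <- sort(Reduce(intersect, per_context))
  list(per_context = per_context, shared = shared)
}

#' Hypothesis I: a direct regulator explains the target
#'
#' Succeeds when at least one target-regulating TF is significantly
#' differentially expressed with the same sign in every context — i.e. the
#' overlap of regulator DEGs across contexts is non-empty and concordant.
#'
#' @inheritParams target_regulating_tfs
#' @return list with `status` ("explained" or "failed") and `explained_by`
#'   (data.frame of TFs and their shared direction; empty on failure).
#' @export
hypothesis1 <- function(target, regulon, context_results) {
  regs <- target_regulating_tfs(target, regulon, context_results)
  hits <- list()
  for (tf in regs$shared) {
    signs <- vapply(context_results, function(cr) .de_sign(cr$deg, tf), 0L)
    if (all(signs == 1L) || all(signs == -1L)) {
      hits[[tf]] <- data.frame(tf = tf,
                               direction = if (signs[1] < 0) "down" else "up",
                               stringsAsFactors = FALSE)
    }
  }
  if (length(hits)) {
    list(status = "explained", explained_by = do.call(rbind, c(hits, list(make.row.names = FALSE))))
  } else {
    list(status = "failed",
         explained_by = data.frame(tf = character(), direction = character(),
                                   stringsAsFactors = FALSE))
  }
}

#' Mutually differential TFs across contexts
#'
#' @param all_tfs candidate TF universe (expressed in all contexts).
#' @param context_results per-context results list.
#' @return list with `down` and `up` character vectors: TFs significantly
#'   down (resp. up) in every context.
#' @export
mutual_differential_tfs <- function(all_tfs, context_results) {
  signs <- vapply(all_tfs, function(tf) {
    s <- vapply(context_results, function(cr) .de_sign(cr$deg, tf), 0L)
    if (all(s == -1L)) -1L else if (all(s == 1L)) 1L else 0L
  }, 0L)
  list(down = sort(all_tfs[signs == -1L]), up = sort(all_tfs[signs == 1L]))
}

#' Physical PPI partners among the target regulators
#'
#' For each candidate co-TF, the target-regulating TFs that share a physical
#' interaction edge with it at score >= `min_score`. Candidates without any
#' partner are dropped.
#'
#' @param candidate_tfs character vector of candidate co-TFs.
#' @param target_regulators character vector of target-regulating TFs.
#' @param ppi PPI data.frame (`protein_a`, `protein_b`, `physical`, `score`).
#' @param min_score minimum interaction score (default 0; the physical flag
#'   is always required).
#' @return named list: candidate -> data.frame(`partner`, `score`).
#' @export
ppi_link <- function(candidate_tfs, target_regulators, ppi, min_score = 0) {
  phys <- ppi[ppi$physical & ppi$score >= min_score, , drop = FALSE]
  out <- list()
  for (cand in candidate_tfs) {
    sel <- (phys$protein_a == cand & phys$protein_b %in% target_regulators) |
           (phys$protein_b == cand & phys$protein_a %in% target_regulators)
    if (!any(sel)) next
    partner <- ifelse(phys$protein_a[sel] == cand, phys$protein_b[sel], phys$protein_a[sel])
    df <- data.frame(partner = partner, score = phys$score[sel], stringsAsFactors = FALSE)
    df <- stats::aggregate(score ~ partner, df, max)          # collapse duplicate edges
    out[[cand]] <- df[order(-df$score, df$partner), , drop = FALSE]
  }
  out
}

.openness_flag <- function(cr, gene) {
  f <- unname(cr$openness[gene])
  if (is.null(f) || is.na(f)) "unchanged" else f
}

#' Hypothesis II: a co-TF coupled to a direct regulator
#'
#' Candidates are the TFs (outside the target-regulator set by default) that
#' are mutually differentially expressed with a concordant sign in every
#' context and physically linked to at least one target-regulating TF shared
#' by all contexts. Each candidate carries an evidence ledger; corroborating
#' evidence (promoter closing, partner stability, motif support) affects the
#' rank, never eligibility.
#'
#' Evidence flags are evaluated against the candidate's best partner (highest
#' PPI score, lexicographic tie-break). For down-regulated candidates the
#' promoter flag requires a "closed" promoter call in every context; for
#' up-regulated candidates the mirrored "opened" condition is used.
#'
#' @inheritParams target_regulating_tfs
#' @param ppi PPI data.frame.
#' @param min_score minimum physical-interaction score (default 0).
#' @param exclude_target_regulators drop TFs that directly regulate the target
#'   from the co-TF pool (default TRUE; they are hypothesis-I material).
#' @param motif_supported_partners partners whose binding motif was found in
#'   the target's accessible promoter region (fills the `motif_support` flag).
#' @return data.frame of ranked candidates: `cotf`, `direction`, `partners`
#'   ("tf:score;..."), `best_partner`, `best_ppi_score`, the six evidence
#'   flags, and `rank_score`.
#' @export
hypothesis2 <- function(target, regulon, ppi, context_results, min_score = 0,
                        exclude_target_regulators = TRUE,
                        motif_supported_partners = character(0)) {
  regs <- target_regulating_tfs(target, regulon, context_results)
  pool <- unique(regulon$tf)
  pool <- setdiff(pool, target)
  if (exclude_target_regulators) pool <- setdiff(pool, regs$shared)
  expressed_all <- Reduce(intersect, lapply(context_results, `[[`, "expressed"))
  pool <- sort(intersect(pool, expressed_all))

  mutual <- mutual_differential_tfs(pool, context_results)
  cand <- c(mutual$down, mutual$up)
  links <- ppi_link(cand, regs$shared, ppi, min_score = min_score)

  rows <- lapply(names(links), function(cotf) {
    partners <- links[[cotf]]
    best <- partners[1, ]
    direction <- if (cotf %in% mutual$down) "down" else "up"
    prom_ok <- if (direction == "down") {
      all(vapply(context_results, function(cr) .openness_flag(cr, cotf) == "closed", TRUE))
    } else {
      all(vapply(context_results, function(cr) .openness_flag(cr, cotf) == "opened", TRUE))
    }
    partner_expr_ok <- all(vapply(context_results,
                                  function(cr) .de_sign(cr$deg, best$partner) == 0L, TRUE))
    partner_prom_ok <- all(vapply(context_results,
                                  function(cr) .openness_flag(cr, best$partner) == "unchanged", TRUE))
    flags <- c(de_all_contexts = TRUE,           # candidates are mutual by construction
               concordant_direction = TRUE,
               promoter_closed_all_contexts = prom_ok,
               partner_expression_unchanged = partner_expr_ok,
               partner_promoter_unchanged = partner_prom_ok,
               motif_support = best$partner %in% motif_supported_partners)
    data.frame(cotf = cotf, direction = direction,
               partners = paste(sprintf("%s:%g", partners$partner, partners$score),
                                collapse = ";"),
               best_partner = best$partner, best_ppi_score = best$score,
               t(flags), rank_score = sum(flags), stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(cotf = character(), direction = character(),
                      partners = character(), best_partner = character(),
                      best_ppi_score = numeric(), de_all_contexts = logical(),
                      concordant_direction = logical(),
                      promoter_closed_all_contexts = logical(),
                      partner_expression_unchanged = logical(),
                      partner_promoter_unchanged = logical(),
                      motif_support = logical(), rank_score = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res <- res[order(-res$rank_score, -res$best_ppi_score, res$cotf), , drop = FALSE]
  rownames(res) <- NULL
  res
}
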