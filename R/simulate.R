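#' Simulation configuration
#'
#' Defines the synthetic study: two cell-line contexts with the clone design
#' of the emulated experiment (context A: 3 WT, 2 het, 3 KO; context B: 3 WT,
#' 3 het, 1 KO; two technical replicates per clone), negative-binomial counts,
#' and a planted regulatory structure — a down-regulated target gene, a
#' down-regulated co-TF with one partially closed promoter peak, an unchanged
#' direct-regulator partner physically linked to the co-TF, and decoys that
#' exercise every filter (a near-miss co-TF down in one context only, a mutual
#' down TF without a physical edge, a mutual up TF without a physical edge).
#'
#' @param seed integer seed; the bundle is fully determined by seed + config.
#' @param n_genes total genes (default 2000).
#' @param n_tfs number of TF genes (default 60).
#' @param tech_reps technical replicates per clone (default 2).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline expression of
#'   non-TF genes (defaults 4, 1.5).
#' @param tf_baseline_meanlog,tf_baseline_sdlog baseline of TF genes and the
#'   target (defaults 5, 0.5) — regulators must be reliably expressed.
#' @param dispersion_range per-feature NB dispersion, uniform (default
#'   0.05-0.5); use equal bounds for a fixed dispersion.
#' @param planted_dispersion dispersion of the planted features (target,
#'   co-TF, partner, decoys, planted promoter peak; default 0.2) — the planted
#'   effect is defined at a known dispersion so recovery is a property of the
#'   method, not of one random draw.
#' @param sf_range per-library depth factors, log-uniform (default 0.5-2).
#' @param lfc_target,lfc_cotf,lfc_cotf_peak,lfc_partner planted log2 fold
#'   changes in mutants (defaults -1.5, -2, -1.5, 0).
#' @param lfc_nearmiss near-miss co-TF LFC, applied in context A only
#'   (default -2).
#' @param lfc_decoy_down,lfc_decoy_up mutual decoys without a physical PPI
#'   edge (defaults -2, +2).
#' @param peaks_per_promoter integer range of promoter peaks per gene
#'   (default 1-5).
#' @param n_peak_genes_extra non-TF genes that also receive promoter peaks
#'   (default 150).
#' @param atac_baseline_meanlog,atac_baseline_sdlog log-normal peak baseline
#'   (defaults 5, 1).
#' @param planted_peak_floor minimum baseline of the planted truth peaks so
#'   the planted promoter structure is actually detectable (default 200).
#' @param pwm_width motif width (default 8).
#' @param n_motif_instances motif copies planted in the target's designated
#'   open promoter peak (default 2).
#' @param n_random_ppi random PPI edges beside the planted one (default 100).
#' @param n_decoy_regulators decoy TFs regulating the target (default 20,
#'   giving 21 target regulators with the planted partner).
#' @param targets_per_tf random regulon out-degree per TF (default 30).
#' @param promoter_upstream,promoter_downstream promoter window (default
#'   3000/3000).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_genes = 2000L, n_tfs = 60L,
                              tech_reps = 2L,
                              baseline_meanlog = 4, baseline_sdlog = 1.5,
                              tf_baseline_meanlog = 5, tf_baseline_sdlog = 0.5,
                              dispersion_range = c(0.05, 0.5),
                              planted_dispersion = 0.2,
                              sf_range = c(0.5, 2),
                              lfc_target = -1.5, lfc_cotf = -2,
                              lfc_cotf_peak = -1.5, lfc_partner = 0,
                              lfc_nearmiss = -2, lfc_decoy_down = -2,
                              lfc_decoy_up = 2,
                              peaks_per_promoter = c(1L, 5L),
                              n_peak_genes_extra = 150L,
                              atac_baseline_meanlog = 5, atac_baseline_sdlog = 1,
                              planted_peak_floor = 200,
                              pwm_width = 8L, n_motif_instances = 2L,
                              n_random_ppi = 100L, n_decoy_regulators = 20L,
                              targets_per_tf = 30L,
                              promoter_upstream = 3000L, promoter_downstream = 3000L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_tfs = as.integer(n_tfs), tech_reps = as.integer(tech_reps),
              contexts = list(A = c(WT = 3L, HET = 2L, KO = 3L),
                              B = c(WT = 3L, HET = 3L, KO = 1L)),
              baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
              tf_baseline_meanlog = tf_baseline_meanlog,
              tf_baseline_sdlog = tf_baseline_sdlog,
              dispersion_range = dispersion_range,
              planted_dispersion = planted_dispersion, sf_range = sf_range,
              lfc_target = lfc_target, lfc_cotf = lfc_cotf,
              lfc_cotf_peak = lfc_cotf_peak, lfc_partner = lfc_partner,
              lfc_nearmiss = lfc_nearmiss, lfc_decoy_down = lfc_decoy_down,
              lfc_decoy_up = lfc_decoy_up,
              peaks_per_promoter = as.integer(peaks_per_promoter),
              n_peak_genes_extra = as.integer(n_peak_genes_extra),
              atac_baseline_meanlog = atac_baseline_meanlog,
              atac_baseline_sdlog = atac_baseline_sdlog,
              planted_peak_floor = planted_peak_floor,
              pwm_width = as.integer(pwm_width),
              n_motif_instances = as.integer(n_motif_instances),
              n_random_ppi = as.integer(n_random_ppi),
              n_decoy_regulators = as.integer(n_decoy_regulators),
              targets_per_tf = as.integer(targets_per_tf),
              promoter_upstream = as.integer(promoter_upstream),
              promoter_downstream = as.integer(promoter_downstream))
  stopifnot(cfg$n_genes > cfg$n_tfs + 1L, cfg$n_tfs >= 30L,
            all(cfg$dispersion_range > 0), all(cfg$sf_range > 0),
            cfg$peaks_per_promoter[1] >= 1L)
  class(cfg) <- "simulation_config"
  cfg
}

#' All-null variant of a simulation config
#'
#' Sets every planted log2 fold change (genes and peaks) to zero, yielding a
#' pure null bundle for calibration checks.
#'
#' @param config a [simulation_config()].
#' @return the config with all planted effects zeroed.
#' @export
null_config <- function(config) {
  for (f in c("lfc_target", "lfc_cotf", "lfc_cotf_peak", "lfc_partner",
              "lfc_nearmiss", "lfc_decoy_down", "lfc_decoy_up")) {
    config[[f]] <- 0
  }
  config
}

.runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

# NB draws, vectorised over a mean matrix with per-row dispersion
.rnb_matrix <- function(mu, alpha) {
  n <- length(mu)
  size <- 1 / rep(alpha, times = ncol(mu))
  m <- matrix(stats::rnbinom(n, mu = as.vector(mu), size = size),
              nrow = nrow(mu), dimnames = dimnames(mu))
  storage.mode(m) <- "integer"
  m
}

.make_samples <- function(context, design, tech_reps, assay) {
  rows <- list()
  for (g in names(design)) {
    for (k in seq_len(design[[g]])) {
      clone <- sprintf("%s_%s%d", context, g, k)
      for (r in seq_len(tech_reps)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s_r%d", clone, assay, r),
          context = context, genotype = g, clone_id = clone,
          tech_rep = r, stringsAsFactors = FALSE)
      }
    }
  }
  validate_sample_sheet(do.call(rbind, rows))
}

.consensus_sequence <- function(pfm) {
  paste(rownames(pfm$counts)[apply(pfm$counts, 2, which.max)], collapse = "")
}

#' Simulate a complete multi-omic input bundle
#'
#' Generates, from a seeded configuration, everything the pipeline consumes:
#' per-context RNA and ATAC count matrices with sample sheets, per-condition
#' and consensus peak sets, a TF regulon, a physical PPI network, promoter/TSS
#' annotation, the target's promoter sequence with planted motif instances, a
#' position frequency matrix for the partner TF, and a truth record.
#'
#' Counts are negative-binomial with per-feature dispersion; technical
#' replicates are independent draws at half the clone depth, so summing them
#' restores clone-level depth. Identical seeds give identical bundles.
#'
#' @param config a [simulation_config()].
#' @return a bundle list (`config`, `truth`, `contexts`, `regulon`, `ppi`,
#'   `promoters`, `promoter_seq`, `seq_chrom`, `seq_origin`, `pfm`).
#' @export
simulate_bundle <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cfg <- config

  ## --- gene universe and roles -------------------------------------------
  target <- "TGT"
  tfs <- sprintf("TF%03d", seq_len(cfg$n_tfs))
  fillers <- sprintf("G%04d", seq_len(cfg$n_genes - cfg$n_tfs - 1L))
  genes <- c(target, tfs, fillers)
  partner <- tfs[1]; cotf <- tfs[2]; nearmiss <- tfs[3]
  decoy_up <- tfs[4]; decoy_down <- tfs[5]
  regulators <- c(partner, tfs[6:(5 + cfg$n_decoy_regulators)])

  ## --- promoters ----------------------------------------------------------
  strands <- rep(c("+", "-"), length.out = length(genes))
  strands[1] <- "+"                                  # target kept on + strand
  promoters <- data.frame(gene = genes, chrom = "chr1",
                          tss = 10000L * seq_along(genes),
                          strand = strands, stringsAsFactors = FALSE)

  ## --- baselines, dispersions, per-context gene LFCs ----------------------
  baseline <- stats::setNames(
    stats::rlnorm(length(genes), cfg$baseline_meanlog, cfg$baseline_sdlog), genes)
  is_tfish <- genes %in% c(target, tfs)
  baseline[is_tfish] <- stats::rlnorm(sum(is_tfish), cfg$tf_baseline_meanlog,
                                      cfg$tf_baseline_sdlog)
  dispersion <- stats::setNames(
    stats::runif(length(genes), cfg$dispersion_range[1], cfg$dispersion_range[2]), genes)
  dispersion[c(target, partner, cotf, nearmiss, decoy_up, decoy_down)] <-
    cfg$planted_dispersion

  gene_lfc <- list()
  for (ctx in names(cfg$contexts)) {
    lfc <- stats::setNames(numeric(length(genes)), genes)
    lfc[target] <- cfg$lfc_target
    lfc[cotf] <- cfg$lfc_cotf
    lfc[partner] <- cfg$lfc_partner
    lfc[decoy_up] <- cfg$lfc_decoy_up
    lfc[decoy_down] <- cfg$lfc_decoy_down
    if (ctx == names(cfg$contexts)[1]) lfc[nearmiss] <- cfg$lfc_nearmiss
    gene_lfc[[ctx]] <- lfc
  }

  ## --- regulon -------------------------------------------------------------
  reg_rows <- list(data.frame(tf = regulators, target = target,
                              confidence = sample(c("A", "B", "C"), length(regulators), TRUE),
                              sign = 1L, stringsAsFactors = FALSE))
  for (tf in tfs) {
    tg <- sample(fillers, cfg$targets_per_tf)
    reg_rows[[length(reg_rows) + 1L]] <- data.frame(
      tf = tf, target = tg,
      confidence = sample(c("A", "B", "C", "D", "E"), length(tg), TRUE),
      sign = sample(c(-1L, 0L, 1L), length(tg), TRUE), stringsAsFactors = FALSE)
  }
  regulon <- do.call(rbind, reg_rows)
  # the planted co-TF must not be a direct regulator of the target
  regulon <- regulon[!(regulon$tf == cotf & regulon$target == target), , drop = FALSE]
  rownames(regulon) <- NULL

  ## --- PPI ------------------------------------------------------------------
  ppi <- data.frame(protein_a = cotf, protein_b = partner,
                    physical = TRUE, score = 900, stringsAsFactors = FALSE)
  protected <- c(cotf, nearmiss, decoy_up, decoy_down)
  n_drawn <- 0L
  while (n_drawn < cfg$n_random_ppi) {
    a <- sample(genes, 1L); b <- sample(genes, 1L)
    if (a == b) next
    # keep planted truth identifiable: no accidental physical link between a
    # mutual/decoy TF and a target regulator
    if ((a %in% protected && b %in% regulators) ||
        (b %in% protected && a %in% regulators)) next
    ppi <- rbind(ppi, data.frame(protein_a = a, protein_b = b,
                                 physical = stats::runif(1) < 0.5,
                                 score = round(stats::runif(1, 100, 999)),
                                 stringsAsFactors = FALSE))
    n_drawn <- n_drawn + 1L
  }

  ## --- PFM for the partner TF ----------------------------------------------
  consensus_idx <- sample(4L, cfg$pwm_width, replace = TRUE)
  counts <- matrix(5, nrow = 4, ncol = cfg$pwm_width,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(consensus_idx, seq_len(cfg$pwm_width))] <- 85
  pfm <- list(id = sprintf("M%05d", cfg$seed %% 100000L),
              name = partner, counts = counts)
  consensus <- .consensus_sequence(pfm)

  ## --- promoter peaks -------------------------------------------------------
  peak_genes <- c(target, tfs, fillers[seq_len(min(cfg$n_peak_genes_extra,
                                                   length(fillers)))])
  win <- promoter_windows(promoters[match(peak_genes, promoters$gene), ],
                          cfg$promoter_upstream, cfg$promoter_downstream)
  base_peaks <- list()
  for (i in seq_len(nrow(win))) {
    kk <- seq(cfg$peaks_per_promoter[1], cfg$peaks_per_promoter[2])
    k <- if (length(kk) == 1L) kk else sample(kk, 1L)
    slot <- (win$window_end[i] - win$window_start[i]) %/% k
    width <- pmin(sample(200:600, k, replace = TRUE), slot - 60L)
    off <- vapply(seq_len(k), function(j) {
      sample.int(slot - width[j] - 40L, 1L) + 20L
    }, 0L)
    base_peaks[[i]] <- data.frame(
      gene = win$gene[i], chrom = win$chrom[i],
      start = win$window_start[i] + (seq_len(k) - 1L) * slot + off,
      end = win$window_start[i] + (seq_len(k) - 1L) * slot + off + width,
      stringsAsFactors = FALSE)
  }
  base_peaks <- do.call(rbind, base_peaks)
  cotf_base_peak <- base_peaks[base_peaks$gene == cotf, ][1, ]
  motif_base_peak <- base_peaks[base_peaks$gene == target, ][1, ]

  ## --- per-context data -----------------------------------------------------
  contexts <- list()
  truth_ctx <- list()
  for (ctx in names(cfg$contexts)) {
    design <- as.list(cfg$contexts[[ctx]])

    # RNA
    rna_samples <- .make_samples(ctx, design, cfg$tech_reps, "rna")
    mut <- rna_samples$genotype_group == "MUTANT"
    sf <- .runif_log(nrow(rna_samples), cfg$sf_range)
    names(sf) <- rna_samples$sample_id
    mu <- outer(baseline, sf * 0.5) *
      2^outer(gene_lfc[[ctx]], as.numeric(mut))
    colnames(mu) <- rna_samples$sample_id
    rna_counts <- .rnb_matrix(mu, dispersion)

    # per-condition peak sets: the base peaks jittered per genotype condition
    per_condition <- lapply(stats::setNames(nm = names(design)), function(g) {
      jit <- sample(-20:20, 2L * nrow(base_peaks), replace = TRUE)
      data.frame(chrom = base_peaks$chrom,
                 start = pmax(0L, base_peaks$start + jit[seq_len(nrow(base_peaks))]),
                 end = base_peaks$end + jit[nrow(base_peaks) + seq_len(nrow(base_peaks))],
                 stringsAsFactors = FALSE)
    })
    cons <- consensus_peaks(per_condition)
    peaks <- cons$peaks

    # map planted peaks onto consensus ids (they overlap by construction)
    find_peak <- function(bp) {
      hit <- which(peaks$chrom == bp$chrom & peaks$start < bp$end & peaks$end > bp$start)
      peaks$peak_id[hit[1]]
    }
    cotf_peak_id <- find_peak(cotf_base_peak)
    motif_peak_id <- find_peak(motif_base_peak)

    # ATAC counts over the consensus peaks
    atac_samples <- .make_samples(ctx, design, cfg$tech_reps, "atac")
    amut <- atac_samples$genotype_group == "MUTANT"
    asf <- .runif_log(nrow(atac_samples), cfg$sf_range)
    names(asf) <- atac_samples$sample_id
    abase <- stats::setNames(
      stats::rlnorm(nrow(peaks), cfg$atac_baseline_meanlog, cfg$atac_baseline_sdlog),
      peaks$peak_id)
    abase[c(cotf_peak_id, motif_peak_id)] <-
      pmax(abase[c(cotf_peak_id, motif_peak_id)], cfg$planted_peak_floor)
    adisp <- stats::setNames(
      stats::runif(nrow(peaks), cfg$dispersion_range[1], cfg$dispersion_range[2]),
      peaks$peak_id)
    adisp[cotf_peak_id] <- cfg$planted_dispersion
    peak_lfc <- stats::setNames(numeric(nrow(peaks)), peaks$peak_id)
    peak_lfc[cotf_peak_id] <- cfg$lfc_cotf_peak
    amu <- outer(abase, asf * 0.5) * 2^outer(peak_lfc, as.numeric(amut))
    colnames(amu) <- atac_samples$sample_id
    atac_counts <- .rnb_matrix(amu, adisp)

    contexts[[ctx]] <- list(
      rna = list(counts = rna_counts, samples = rna_samples),
      atac = list(counts = atac_counts, samples = atac_samples,
                  peaks = peaks, per_condition = per_condition))
    truth_ctx[[ctx]] <- list(gene_lfc = gene_lfc[[ctx]], peak_lfc = peak_lfc,
                             cotf_peak_id = cotf_peak_id,
                             motif_peak_id = motif_peak_id,
                             rna_size_factors = sf, atac_size_factors = asf)
  }

  ## --- target promoter sequence with planted motifs -------------------------
  up <- cfg$promoter_upstream; down <- cfg$promoter_downstream
  tss <- promoters$tss[promoters$gene == target]
  origin <- tss - up
  seq_len_total <- up + down
  seq_chars <- sample(c("A", "C", "G", "T"), seq_len_total, replace = TRUE)
  # plant inside the base peak shrunk by the jitter margin so every
  # per-condition variant of the peak still contains the instances
  w <- cfg$pwm_width
  pos0 <- motif_base_peak$start - origin + 30L
  motif_positions <- integer(0)
  for (m in seq_len(cfg$n_motif_instances)) {
    pos <- pos0 + (m - 1L) * (w + 12L)
    inst <- if (m %% 2L == 1L) consensus else .revcomp(consensus)
    seq_chars[(pos + 1L):(pos + w)] <- strsplit(inst, "")[[1]]
    motif_positions <- c(motif_positions, pos)
  }
  promoter_seq <- stats::setNames(paste(seq_chars, collapse = ""),
                                  sprintf("%s_promoter", target))

  truth <- list(target = target, cotf = cotf, partner = partner,
                nearmiss = nearmiss, decoy_up = decoy_up,
                decoy_down = decoy_down, regulators = regulators,
                baseline = baseline, dispersion = dispersion,
                contexts = truth_ctx,
                motif_positions = motif_positions,
                motif_consensus = consensus)

  list(config = cfg, truth = truth, contexts = contexts, regulon = regulon,
       ppi = ppi, promoters = promoters, promoter_seq = promoter_seq,
       seq_chrom = "chr1", seq_origin = origin, pfm = pfm)
}

#' Write a simulated bundle to disk
#'
#' Emits every component in the package's standard text formats plus a JSON
#' manifest listing the files, the seed, and a hash of the configuration.
#'
#' @param bundle output of [simulate_bundle()].
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, sprintf(...))
  files <- character(0)
  add <- function(path) files <<- c(files, basename(path))

  for (ctx in names(bundle$contexts)) {
    b <- bundle$contexts[[ctx]]
    add(write_counts(b$rna$counts, p("rna_counts_%s.tsv", ctx), "gene"))
    add(write_sample_sheet(b$rna$samples, p("rna_samples_%s.tsv", ctx)))
    add(write_counts(b$atac$counts, p("atac_counts_%s.tsv", ctx), "peak"))
    add(write_sample_sheet(b$atac$samples, p("atac_samples_%s.tsv", ctx)))
    add(write_bed(b$atac$peaks, p("atac_peaks_%s.bed", ctx)))
    for (cond in names(b$atac$per_condition)) {
      add(write_bed(validate_peaks(b$atac$per_condition[[cond]]),
                    p("atac_condition_%s_%s.bed", ctx, cond)))
    }
  }
  add(write_regulon(bundle$regulon, p("regulon.tsv")))
  add(write_ppi(bundle$ppi, p("ppi.tsv")))
  add(write_promoters(bundle$promoters, p("promoters.tsv")))
  add(write_fasta(bundle$promoter_seq, p("promoter.fasta")))
  add(write_jaspar_pfm(bundle$pfm, p("motif.pfm")))

  cfg_path <- p("config.json")
  jsonlite::write_json(unclass(bundle$config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  add(cfg_path)
  truth_path <- p("truth.json")
  jsonlite::write_json(bundle$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  add(truth_path)

  manifest <- list(seed = bundle$config$seed,
                   config_hash = unname(tools::md5sum(cfg_path)),
                   seq_chrom = bundle$seq_chrom,
                   seq_origin = bundle$seq_origin,
                   contexts = names(bundle$contexts),
                   files = files)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Synthetic patient cohort
#'
#' Builds a cohort mutation table with a stated composition: `n_mutant`
#' patients carrying qualifying mutations (allelic fraction at or above
#' `vaf_min`), of which `n_disruptive` are disruptive, plus `n_subthreshold`
#' mutated patients below the allelic-fraction cutoff who must not count.
#'
#' @param n_total cohort size (default 151).
#' @param n_mutant qualifying mutant patients (default 27).
#' @param n_disruptive disruptive among the qualifying (default 23).
#' @param n_subthreshold mutated but sub-threshold patients (default 3).
#' @param vaf_min allelic-fraction cutoff (default 0.05).
#' @param seed seed for the allelic fractions.
#' @return cohort data.frame (see [read_cohort()]).
#' @export
simulate_cohort <- function(n_total = 151L, n_mutant = 27L, n_disruptive = 23L,
                            n_subthreshold = 3L, vaf_min = 0.05, seed = 1L) {
  stopifnot(n_mutant + n_subthreshold <= n_total, n_disruptive <= n_mutant)
  set.seed(seed)
  n_wt <- n_total - n_mutant - n_subthreshold
  cat_mut <- c(rep("disruptive", n_disruptive),
               sample(c("missense", "other"), n_mutant - n_disruptive, TRUE))
  df <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n_total)),
    has_nonsyn_mutation = c(rep(TRUE, n_mutant + n_subthreshold), rep(FALSE, n_wt)),
    allelic_fraction = c(stats::runif(n_mutant, vaf_min, 0.9),
                         stats::runif(n_subthreshold, 0.001, vaf_min * 0.9),
                         rep(NA_real_, n_wt)),
    category = c(cat_mut, sample(c("missense", "other"), n_subthreshold, TRUE),
                 rep(NA_character_, n_wt)),
    stringsAsFactors = FALSE)
  validate_cohort(df)
}
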