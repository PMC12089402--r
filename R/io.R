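#' @import stats
#' @import utils
NULL

GENOTYPES <- c("WT", "HET", "KO")
MUT_CATEGORIES <- c("disruptive", "missense", "other")

#' Read a sample sheet
#'
#' The sample sheet describes the experimental design: one row per sequenced
#' library, with the cell-line context, the CRISPR genotype of the clone it
#' came from, and the technical replicate index. Wild-type clones form the
#' CONTROL group; heterozygous and knock-out clones are pooled into the
#' MUTANT group for all differential contrasts.
#'
#' @param path tab-separated file with columns `sample_id`, `context`,
#'   `genotype` (one of WT, HET, KO), `clone_id`, `tech_rep`.
#' @return data.frame with the input columns plus `genotype_group`
#'   (CONTROL for WT, MUTANT otherwise).
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_sheet(ss)
}

#' Validate and augment sample metadata
#'
#' @param ss data.frame with columns `sample_id`, `context`, `genotype`,
#'   `clone_id`, `tech_rep`.
#' @return the validated data.frame with a derived `genotype_group` column.
#' @export
validate_sample_sheet <- function(ss) {
  need <- c("sample_id", "context", "genotype", "clone_id", "tech_rep")
  miss <- setdiff(need, names(ss))
  if (length(miss)) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  ss$sample_id <- as.character(ss$sample_id)
  ss$context <- as.character(ss$context)
  ss$genotype <- as.character(ss$genotype)
  ss$clone_id <- as.character(ss$clone_id)
  if (anyDuplicated(ss$sample_id)) stop("duplicate sample_id in sample sheet")
  bad <- setdiff(unique(ss$genotype), GENOTYPES)
  if (length(bad)) stop("unknown genotype value(s): ", paste(bad, collapse = ", "))
  ss$tech_rep <- as.integer(ss$tech_rep)
  if (any(is.na(ss$tech_rep)) || any(ss$tech_rep < 1L)) stop("tech_rep must be an integer >= 1")
  key <- paste(ss$context, ss$clone_id, ss$tech_rep, sep = "\r")
  if (anyDuplicated(key)) stop("(clone_id, tech_rep) not unique within a context")
  ss$genotype_group <- ifelse(ss$genotype == "WT", "CONTROL", "MUTANT")
  ss
}

#' Read a feature-by-sample count matrix
#'
#' @param path tab-separated file; first column holds feature ids, remaining
#'   columns are samples.
#' @param sample_sheet_path path to the sample sheet the columns must resolve
#'   against, or an already-read sample sheet data.frame.
#' @return list with `counts` (integer matrix, features x samples) and
#'   `samples` (the sample sheet rows for the matrix columns, in column order).
#' @export
read_counts <- function(path, sample_sheet_path) {
  ss <- if (is.data.frame(sample_sheet_path)) validate_sample_sheet(sample_sheet_path)
        else read_sample_sheet(sample_sheet_path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("count file needs a feature column and >= 1 sample column")
  feats <- tab[[1]]
  if (anyDuplicated(feats)) {
    stop("duplicate feature id(s): ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  }
  sample_ids <- colnames(tab)[-1]
  unknown <- setdiff(sample_ids, ss$sample_id)
  if (length(unknown)) {
    stop("sample id(s) absent from sample sheet: ", paste(unknown, collapse = ", "))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(m), nrow = nrow(m)))
  if (anyNA(num)) stop("non-numeric count cell(s) in ", path)
  if (any(num < 0)) stop("negative count(s) in ", path)
  if (any(num != round(num))) stop("non-integer count(s) in ", path)
  counts <- matrix(as.integer(round(num)), nrow = nrow(m),
                   dimnames = list(feats, sample_ids))
  list(counts = counts, samples = ss[match(sample_ids, ss$sample_id), , drop = FALSE])
}

#' Write a count matrix as TSV
#'
#' @param counts integer matrix with feature rownames and sample colnames.
#' @param path output file.
#' @param feature_col name of the first (feature id) column.
#' @export
write_counts <- function(counts, path, feature_col = "feature") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sample sheet as TSV
#' @param ss sample sheet data.frame.
#' @param path output file.
#' @export
write_sample_sheet <- function(ss, path) {
  cols <- c("sample_id", "context", "genotype", "clone_id", "tech_rep")
  utils::write.table(ss[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED4 peak file
#'
#' Coordinates are kept in the BED convention (0-based, half-open) throughout
#' the package. A missing 4th column is synthesised as "chrom:start-end".
#'
#' @param path BED file, tab-separated, no header.
#' @return data.frame with columns `chrom`, `start`, `end`, `peak_id`.
#' @export
read_bed <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 3) stop("BED needs >= 3 columns")
  suppressWarnings({
    start <- as.numeric(tab[[2]]); end <- as.numeric(tab[[3]])
  })
  if (anyNA(start) || anyNA(end) || any(start != round(start)) || any(end != round(end)))
    stop("non-integer BED coordinates in ", path)
  peaks <- data.frame(chrom = tab[[1]], start = as.integer(start),
                      end = as.integer(end),
                      peak_id = if (ncol(tab) >= 4) tab[[4]] else NA_character_,
                      stringsAsFactors = FALSE)
  peaks$peak_id[is.na(peaks$peak_id) | peaks$peak_id == ""] <-
    with(peaks[is.na(peaks$peak_id) | peaks$peak_id == "", , drop = FALSE],
         sprintf("%s:%d-%d", chrom, start, end))
  validate_peaks(peaks)
}

#' Validate a peak table
#' @param peaks data.frame with `chrom`, `start`, `end` and optional `peak_id`.
#' @return validated data.frame (peak_id synthesised where missing).
#' @export
validate_peaks <- function(peaks) {
  if (is.null(peaks$peak_id))
    peaks$peak_id <- sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  if (any(peaks$start < 0)) stop("negative start coordinate")
  bad <- peaks$start >= peaks$end
  if (any(bad)) {
    stop("invalid interval (start >= end): ",
         paste(sprintf("%s:%d-%d", peaks$chrom[bad], peaks$start[bad],
                       peaks$end[bad]), collapse = ", "))
  }
  if (anyDuplicated(peaks$peak_id)) stop("duplicate peak_id")
  peaks[, c("chrom", "start", "end", "peak_id")]
}

#' Write peaks as BED4
#' @param peaks peak data.frame (`chrom`, `start`, `end`, `peak_id`).
#' @param path output file.
#' @export
write_bed <- function(peaks, path) {
  utils::write.table(peaks[, c("chrom", "start", "end", "peak_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a TF regulon table
#'
#' A DoRothEA-style table of curated TF-to-target edges. A missing
#' `confidence` column defaults to class "C"; a missing `sign` column
#' defaults to 0 (unknown).
#'
#' @param path TSV with header columns `tf`, `target`, optional `confidence`
#'   (A-E) and `sign` (-1/0/1).
#' @return data.frame `tf`, `target`, `confidence`, `sign`.
#' @export
read_regulon <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("tf", "target")
  if (!all(need %in% names(tab))) stop("regulon TSV needs columns tf, target")
  conf <- if ("confidence" %in% names(tab)) as.character(tab$confidence) else rep("C", nrow(tab))
  bad <- setdiff(unique(conf), c("A", "B", "C", "D", "E"))
  if (length(bad)) stop("unknown regulon confidence class: ", paste(bad, collapse = ", "))
  sgn <- if ("sign" %in% names(tab)) as.integer(tab$sign) else rep(0L, nrow(tab))
  if (any(!sgn %in% c(-1L, 0L, 1L))) stop("regulon sign must be -1, 0 or 1")
  data.frame(tf = as.character(tab$tf), target = as.character(tab$target),
             confidence = conf, sign = sgn, stringsAsFactors = FALSE)
}

#' Write a regulon table
#' @param regulon data.frame from [read_regulon()].
#' @param path output file.
#' @export
write_regulon <- function(regulon, path) {
  utils::write.table(regulon, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein-protein interaction table
#'
#' STRING-style undirected edges with a physical-interaction flag and a
#' combined score in [0, 1000]. Self-edges are dropped with a warning.
#'
#' @param path TSV with header columns `protein_a`, `protein_b`, `physical`
#'   (TRUE/FALSE or 1/0), `score`.
#' @return data.frame `protein_a`, `protein_b`, `physical`, `score`.
#' @export
read_ppi <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("protein_a", "protein_b", "physical", "score")
  if (!all(need %in% names(tab))) {
    stop("PPI TSV needs columns protein_a, protein_b, physical, score")
  }
  phys <- tab$physical
  if (!is.logical(phys)) phys <- as.logical(as.integer(phys))
  if (anyNA(phys)) stop("PPI physical flag must be logical or 0/1")
  score <- as.numeric(tab$score)
  if (anyNA(score) || any(score < 0 | score > 1000)) stop("PPI score must lie in [0, 1000]")
  ppi <- data.frame(protein_a = as.character(tab$protein_a),
                    protein_b = as.character(tab$protein_b),
                    physical = phys, score = score, stringsAsFactors = FALSE)
  self <- ppi$protein_a == ppi$protein_b
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped from PPI table")
    ppi <- ppi[!self, , drop = FALSE]
  }
  ppi
}

#' Write a PPI table
#' @param ppi data.frame from [read_ppi()].
#' @param path output file.
#' @export
write_ppi <- function(ppi, path) {
  utils::write.table(ppi, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a JASPAR text position frequency matrix
#'
#' Accepts the JASPAR 2016/2020 dialect: a ">ID NAME" header line followed by
#' four rows "A  [ 4 19 0 ... ]" (brackets optional) in A, C, G, T order.
#'
#' @param path PFM text file.
#' @return list with `id`, `name`, and `counts` (4 x width numeric matrix,
#'   rownames A/C/G/T).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!startsWith(lines[1], ">")) stop("JASPAR PFM must start with a '>' header")
  hdr <- strsplit(sub("^>\\s*", "", lines[1]), "\\s+")[[1]]
  if (length(lines) < 5) stop("JASPAR PFM needs 4 base rows")
  rows <- lapply(lines[2:5], function(l) {
    base <- sub("^\\s*([ACGT]).*", "\\1", l)
    nums <- gsub("[^0-9eE+. -]", " ", sub("^\\s*[ACGT]", "", l))
    vals <- as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    if (anyNA(vals)) stop("unparseable PFM row: ", l)
    list(base = base, vals = vals)
  })
  bases <- vapply(rows, `[[`, "", "base")
  if (!identical(sort(bases), c("A", "C", "G", "T"))) stop("PFM rows must cover A, C, G, T")
  widths <- vapply(rows, function(r) length(r$vals), 0L)
  if (length(unique(widths)) != 1L) stop("PFM rows of unequal width")
  if (widths[1] < 4L) stop("PFM width must be >= 4")
  counts <- do.call(rbind, lapply(rows, `[[`, "vals"))
  rownames(counts) <- bases
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(counts < 0)) stop("negative PFM entries")
  if (any(colSums(counts) == 0)) stop("PFM column with zero total")
  list(id = hdr[1], name = if (length(hdr) > 1) hdr[2] else hdr[1], counts = counts)
}

#' Write a JASPAR-style text PFM
#' @param pfm list from [read_jaspar_pfm()].
#' @param path output file.
#' @export
write_jaspar_pfm <- function(pfm, path) {
  lines <- c(sprintf(">%s %s", pfm$id, pfm$name),
             vapply(c("A", "C", "G", "T"), function(b) {
               sprintf("%s [ %s ]", b, paste(format(pfm$counts[b, ], trim = TRUE),
                                             collapse = " "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read promoter sequence FASTA
#'
#' @param path FASTA file; sequences must be over the A/C/G/T/N alphabet.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("FASTA sequence(s) with characters outside ACGTN: ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  seqs
}

#' Write sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read a promoter/TSS annotation table
#'
#' @param path TSV with header columns `gene`, `chrom`, `tss`, `strand`.
#' @return validated data.frame.
#' @export
read_promoters <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "chrom", "tss", "strand")
  if (!all(need %in% names(tab))) stop("promoter TSV needs columns gene, chrom, tss, strand")
  if (any(!tab$strand %in% c("+", "-"))) stop("promoter strand must be '+' or '-'")
  tab$tss <- as.integer(tab$tss)
  if (anyNA(tab$tss)) stop("non-integer TSS")
  tab[, need]
}

#' Write a promoter/TSS table
#' @param promoters data.frame from [read_promoters()].
#' @param path output file.
#' @export
write_promoters <- function(promoters, path) {
  utils::write.table(promoters[, c("gene", "chrom", "tss", "strand")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort mutation table
#'
#' One row per patient; `allelic_fraction` and `category` must be present
#' exactly for mutated patients.
#'
#' @param path TSV with header columns `patient_id`, `has_nonsyn_mutation`,
#'   `allelic_fraction`, `category`.
#' @return validated data.frame.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  validate_cohort(tab)
}

#' Validate a cohort mutation table
#' @param tab data.frame with cohort columns.
#' @return validated data.frame.
#' @export
validate_cohort <- function(tab) {
  need <- c("patient_id", "has_nonsyn_mutation", "allelic_fraction", "category")
  if (!all(need %in% names(tab))) {
    stop("cohort table needs columns ", paste(need, collapse = ", "))
  }
  mut <- tab$has_nonsyn_mutation
  if (!is.logical(mut)) mut <- as.logical(as.integer(mut))
  if (anyNA(mut)) stop("has_nonsyn_mutation must be logical or 0/1")
  tab$has_nonsyn_mutation <- mut
  vaf <- as.numeric(tab$allelic_fraction)
  if (any(mut & (is.na(vaf) | vaf < 0 | vaf > 1)))
    stop("mutated records need allelic_fraction in [0, 1]")
  if (any(!mut & !is.na(vaf))) stop("allelic_fraction set for non-mutated record")
  if (any(mut & is.na(tab$category))) stop("mutated records need a category")
  bad <- setdiff(unique(tab$category[mut]), MUT_CATEGORIES)
  if (length(bad)) stop("unknown mutation category: ", paste(bad, collapse = ", "))
  tab$allelic_fraction <- vaf
  tab[, need]
}
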