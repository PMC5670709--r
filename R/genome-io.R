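#' Read a multi-record FASTA file
#'
#' Parses nucleotide or protein FASTA. The record ID is the first
#' whitespace-delimited token of the header; the remainder of the header is
#' kept as the description. Sequence lines are joined and upper-cased.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `seq`, `desc`, one row per record,
#'   in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(ss))
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    stop("FASTA record with empty sequence: ", paste(ids[empty], collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA IDs within ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(id = ids, seq = unname(seqs), desc = unname(desc),
             stringsAsFactors = FALSE)
}

#' Write records to a FASTA file
#'
#' @param records Either a data.frame with columns `id`, `seq` (and optional
#'   `desc`), or a named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), seq = unname(records),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "seq") %in% names(records)))
  if (any(nchar(records$seq) == 0L)) stop("refusing to write empty sequence")
  desc <- if ("desc" %in% names(records)) records$desc else rep("", nrow(records))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
    writeLines(paste0(">", header), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a genome record
#'
#' A genome is an ordered set of named scaffolds (nucleotide sequences).
#'
#' @param genome_id Short unique label.
#' @param scaffolds Named character vector of upper-case nucleotide sequences.
#' @param source_path Provenance string (file of origin, or "simulated").
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(genome_id, scaffolds, source_path = "") {
  if (!is.character(genome_id) || length(genome_id) != 1L || !nzchar(genome_id)) {
    stop("genome_id must be a non-empty string")
  }
  if (length(scaffolds) < 1L) stop("genome must have at least one scaffold")
  if (is.null(names(scaffolds)) || any(!nzchar(names(scaffolds)))) {
    stop("scaffolds must be named")
  }
  if (anyDuplicated(names(scaffolds))) {
    stop("duplicate scaffold IDs in genome ", genome_id)
  }
  if (any(nchar(scaffolds) == 0L)) stop("empty scaffold in genome ", genome_id)
  structure(list(genome_id = genome_id,
                 scaffolds = toupper(scaffolds),
                 source_path = source_path),
            class = "genome_record")
}

#' Read a genome assembly from FASTA
#'
#' @param path FASTA of scaffolds/contigs.
#' @param genome_id Label for the genome; defaults to the file name without
#'   extension.
#' @return A `genome_record`.
#' @export
read_genome <- function(path, genome_id = NULL) {
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(fa|fna|fasta)(\\.gz)?$", "",
                     basename(path), ignore.case = TRUE)
  }
  recs <- read_fasta(path)
  genome_record(genome_id, stats::setNames(recs$seq, recs$id), source_path = path)
}

#' Per-genome assembly statistics
#'
#' Computes scaffold count, genome size and GC content. GC is
#' 100*(G+C)/(A+C+G+T): ambiguity codes (N etc.) are excluded from both the
#' numerator and the denominator.
#'
#' @param genome A `genome_record`.
#' @param coding_genes Optional predicted coding-gene count (pass-through from
#'   annotation).
#' @return One-row data.frame: genome_id, scaffold_count, size_bp, size_mb
#'   (2 decimals), gc_percent (2 decimals), coding_genes.
#' @export
genome_stats <- function(genome, coding_genes = NA_integer_) {
  stopifnot(inherits(genome, "genome_record"))
  freq <- Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(unname(genome$scaffolds)))
  tot <- colSums(freq)
  acgt <- tot[c("A", "C", "G", "T")]
  if (sum(acgt) == 0) {
    stop("GC undefined: genome ", genome$genome_id, " has no A/C/G/T letters")
  }
  size_bp <- sum(nchar(genome$scaffolds))
  data.frame(
    genome_id = genome$genome_id,
    scaffold_count = length(genome$scaffolds),
    size_bp = size_bp,
    size_mb = round(size_bp / 1e6, 2),
    gc_percent = round(100 * sum(acgt[c("C", "G")]) / sum(acgt), 2),
    coding_genes = as.integer(coding_genes),
    stringsAsFactors = FALSE
  )
}

#' Genus-level summary of genome statistics
#'
#' Arithmetic means and extremes (with the genomes attaining them) of genome
#' size and GC content across a set of genomes.
#'
#' @param stats A data.frame as produced by [genome_stats()] (one row per
#'   genome; columns genome_id, size_mb, gc_percent at minimum).
#' @return A list of class `genus_summary`.
#' @export
summarize_genus <- function(stats) {
  if (!is.data.frame(stats) || nrow(stats) < 1L) {
    stop("need at least one genome's statistics")
  }
  if (anyDuplicated(stats$genome_id)) stop("duplicate genome_ids")
  pick <- function(v, f) stats$genome_id[which(v == f(v))[1L]]
  out <- list(
    n_genomes = nrow(stats),
    mean_size_mb = round(mean(stats$size_mb), 2),
    min_size_mb = min(stats$size_mb),
    min_size_genome = pick(stats$size_mb, min),
    max_size_mb = max(stats$size_mb),
    max_size_genome = pick(stats$size_mb, max),
    mean_gc_percent = round(mean(stats$gc_percent), 2),
    min_gc_percent = min(stats$gc_percent),
    min_gc_genome = pick(stats$gc_percent, min),
    max_gc_percent = max(stats$gc_percent),
    max_gc_genome = pick(stats$gc_percent, max)
  )
  class(out) <- "genus_summary"
  out
}

#' @export
print.genus_summary <- function(x, ...) {
  cat(sprintf("Genus summary over %d genomes\n", x$n_genomes))
  cat(sprintf("  size: %.2f-%.2f Mb (mean %.2f; min %s, max %s)\n",
              x$min_size_mb, x$max_size_mb, x$mean_size_mb,
              x$min_size_genome, x$max_size_genome))
  cat(sprintf("  GC:   %.2f-%.2f%% (mean %.2f; min %s, max %s)\n",
              x$min_gc_percent, x$max_gc_percent, x$mean_gc_percent,
              x$min_gc_genome, x$max_gc_genome))
  invisible(x)
}

#' Write genome statistics as TSV
#'
#' Fixed column order: genome_id, scaffold_count, size_bp, size_mb,
#' gc_percent, coding_genes.
#'
#' @param stats data.frame of per-genome statistics.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_stats <- function(stats, path) {
  cols <- c("genome_id", "scaffold_count", "size_bp", "size_mb",
            "gc_percent", "coding_genes")
  for (m in setdiff(cols, names(stats))) stats[[m]] <- NA
  utils::write.table(stats[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bundled genomic-feature table for the ten Lactococcus type strains
#'
#' Scaffold counts, genome sizes (Mb), GC percentages, predicted coding-gene
#' counts and GenBank accessions for the ten type strains of the genus, as
#' reported in the genus-wide genomic survey these analyses reproduce.
#'
#' @return data.frame with columns strain, species, scaffold_count, size_mb,
#'   gc_percent, coding_genes, accession.
#' @export
lactococcus_genome_table <- function() {
  path <- system.file("extdata", "lactococcus_genome_features.tsv",
                      package = "lactopan", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
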