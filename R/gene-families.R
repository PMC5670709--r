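#' Clustering thresholds for the gene-family rule
#'
#' Two genes belong to the same family when pairwise amino-acid identity is
#' strictly greater than `min_identity` AND the alignment covers strictly more
#' than `min_coverage_longer` of the longer sequence. Both default to 0.50
#' (the ">50%" rule).
#'
#' @param min_identity Identity threshold in `[0, 1]`, strict.
#' @param min_coverage_longer Coverage-of-the-longer threshold in `[0, 1]`,
#'   strict.
#' @return A list of class `cluster_thresholds`.
#' @export
cluster_thresholds <- function(min_identity = 0.5, min_coverage_longer = 0.5) {
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_coverage_longer >= 0, min_coverage_longer <= 1)
  structure(list(min_identity = min_identity,
                 min_coverage_longer = min_coverage_longer),
            class = "cluster_thresholds")
}

#' Protein alignment scoring parameters
#'
#' @param matrix Substitution matrix name (passed to Biostrings).
#' @param gap_open,gap_extend Affine gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @return A list of class `align_scoring`.
#' @export
align_scoring <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 1) {
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

#' Smith-Waterman local alignment of two proteins
#'
#' Computes the maximal-scoring local alignment under affine gap penalties and
#' reports identity (identical residues / aligned columns, internal gap
#' columns included, terminal overhangs excluded) and coverage of the longer
#' sequence (aligned span on the longer sequence / its length). A pair with
#' no positive-scoring alignment is flagged `no_hit` with identity and
#' coverage 0.
#'
#' @param a,b Protein sequences (single strings).
#' @param scoring An [align_scoring()].
#' @return One-row data.frame: identity, coverage_of_longer, score, no_hit.
#' @export
align_pair <- function(a, b, scoring = align_scoring()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  hit_metrics(Biostrings::score(aln),
              Biostrings::pid(aln, type = "PID1") / 100,
              span_a = BiocGenerics::width(Biostrings::pattern(aln)@range),
              span_b = BiocGenerics::width(Biostrings::subject(aln)@range),
              len_a = nchar(a), len_b = nchar(b))
}

# shared metric assembly for single and vectorized alignment paths.
# span_* are aligned spans in original (ungapped) coordinates.
hit_metrics <- function(score, identity, span_a, span_b, len_a, len_b) {
  longer_span <- ifelse(len_a >= len_b, span_a, span_b)
  longer_len <- pmax(len_a, len_b)
  no_hit <- score <= 0 | (span_a == 0)
  data.frame(
    identity = ifelse(no_hit, 0, identity),
    coverage_of_longer = ifelse(no_hit, 0, longer_span / longer_len),
    score = ifelse(no_hit, 0, score),
    no_hit = no_hit
  )
}

#' Does a pairwise hit satisfy the gene-family rule?
#'
#' True iff identity and coverage-of-the-longer both strictly exceed their
#' thresholds.
#'
#' @param hit One-row data.frame from [align_pair()] (or any list with
#'   `identity` and `coverage_of_longer`).
#' @param thresholds A [cluster_thresholds()].
#' @return Logical.
#' @export
passes_family_rule <- function(hit, thresholds = cluster_thresholds()) {
  hit$identity > thresholds$min_identity &
    hit$coverage_of_longer > thresholds$min_coverage_longer
}

#' All-vs-all pairwise protein comparison
#'
#' Runs Smith-Waterman over every unordered pair of genes and returns the
#' hit table. Vectorized over Biostrings; O(n^2) alignments.
#'
#' @param genes data.frame with columns gene_id, genome_id, protein_seq.
#' @param scoring An [align_scoring()].
#' @return data.frame: gene_a, gene_b, identity, coverage_of_longer, score,
#'   no_hit (gene_a < gene_b lexicographically).
#' @export
pairwise_hits <- function(genes, scoring = align_scoring()) {
  validate_gene_table(genes)
  genes <- genes[order(genes$gene_id), ]
  n <- nrow(genes)
  if (n < 2L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      identity = numeric(0), coverage_of_longer = numeric(0),
                      score = numeric(0), no_hit = logical(0)))
  }
  seqs <- Biostrings::AAStringSet(stats::setNames(genes$protein_seq,
                                                  genes$gene_id))
  lens <- nchar(genes$protein_seq)
  out <- vector("list", n - 1L)
  for (j in 2:n) {
    idx <- seq_len(j - 1L)
    aln <- Biostrings::pairwiseAlignment(
      seqs[idx], seqs[[j]], type = "local",
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    m <- hit_metrics(Biostrings::score(aln),
                     Biostrings::pid(aln, type = "PID1") / 100,
                     span_a = BiocGenerics::width(Biostrings::pattern(aln)@range),
                     span_b = BiocGenerics::width(Biostrings::subject(aln)@range),
                     len_a = lens[idx], len_b = lens[j])
    out[[j - 1L]] <- cbind(data.frame(gene_a = genes$gene_id[idx],
                                      gene_b = genes$gene_id[j]), m)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

validate_gene_table <- function(genes) {
  if (!is.data.frame(genes) ||
      !all(c("gene_id", "genome_id", "protein_seq") %in% names(genes))) {
    stop("genes must be a data.frame with gene_id, genome_id, protein_seq")
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  if (any(!nzchar(genes$protein_seq))) stop("empty protein sequence")
  invisible(genes)
}

#' Cluster genes into families by single linkage
#'
#' Builds the graph whose edges are gene pairs passing the identity/coverage
#' rule (all-vs-all, within and across genomes) and returns its connected
#' components as gene families. The family ID is the lexicographically
#' smallest member gene ID, making the result order-invariant.
#'
#' @param genes data.frame with columns gene_id, genome_id, protein_seq.
#' @param thresholds A [cluster_thresholds()].
#' @param scoring An [align_scoring()].
#' @param hits Optional precomputed [pairwise_hits()] table (to cluster the
#'   same comparisons under several thresholds without re-aligning).
#' @return A `family_matrix`: list with `counts` (genomes x families integer
#'   matrix), `member_map` (family_id -> gene_ids), `genome_ids`,
#'   `family_ids`, `gene_genome` (gene_id -> genome_id).
#' @export
cluster_families <- function(genes, thresholds = cluster_thresholds(),
                             scoring = align_scoring(), hits = NULL) {
  validate_gene_table(genes)
  if (is.null(hits)) hits <- pairwise_hits(genes, scoring)
  edges <- hits[passes_family_rule(hits, thresholds), c("gene_a", "gene_b")]
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = sort(genes$gene_id)))
  comp <- igraph::components(g)$membership
  members <- split(names(comp), comp)
  fam_ids <- vapply(members, function(m) min(m), character(1))
  members <- stats::setNames(members, fam_ids)[order(fam_ids)]
  members <- lapply(members, sort)

  genome_ids <- sort(unique(genes$genome_id))
  gene_genome <- stats::setNames(genes$genome_id, genes$gene_id)
  counts <- matrix(0L, length(genome_ids), length(members),
                   dimnames = list(genome_ids, names(members)))
  for (f in names(members)) {
    tab <- table(gene_genome[members[[f]]])
    counts[names(tab), f] <- as.integer(tab)
  }
  structure(list(counts = counts, member_map = members,
                 genome_ids = genome_ids, family_ids = names(members),
                 gene_genome = gene_genome),
            class = "family_matrix")
}

#' @export
print.family_matrix <- function(x, ...) {
  cat(sprintf("family_matrix: %d genomes x %d families (%d genes)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Write a family matrix as TSV
#'
#' Two files: `<stem>_counts.tsv` (rows genomes, columns families) and
#' `<stem>_members.tsv` (family_id, gene_id).
#'
#' @param fm A `family_matrix`.
#' @param stem Output path stem.
#' @return The counts path, invisibly.
#' @export
write_family_matrix <- function(fm, stem) {
  cpath <- paste0(stem, "_counts.tsv")
  df <- data.frame(genome_id = rownames(fm$counts), fm$counts,
                   check.names = FALSE)
  utils::write.table(df, cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  mdf <- data.frame(
    family_id = rep(names(fm$member_map), lengths(fm$member_map)),
    gene_id = unlist(fm$member_map, use.names = FALSE))
  utils::write.table(mdf, paste0(stem, "_members.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(cpath)
}

# COG functional categories and superclasses (single-letter codes)
COG_SUPERCLASS <- c(
  A = "Information Storage and Processing", B = "Information Storage and Processing",
  J = "Information Storage and Processing", K = "Information Storage and Processing",
  L = "Information Storage and Processing",
  D = "Cellular Processes and Signaling", M = "Cellular Processes and Signaling",
  N = "Cellular Processes and Signaling", O = "Cellular Processes and Signaling",
  T = "Cellular Processes and Signaling", U = "Cellular Processes and Signaling",
  V = "Cellular Processes and Signaling", W = "Cellular Processes and Signaling",
  Y = "Cellular Processes and Signaling", Z = "Cellular Processes and Signaling",
  C = "Metabolism", E = "Metabolism", F = "Metabolism", H = "Metabolism",
  G = "Metabolism", I = "Metabolism", P = "Metabolism", Q = "Metabolism",
  R = "Poorly Characterized", S = "Poorly Characterized")

#' Summarize COG functional categories over a gene set
#'
#' Tallies single-letter COG categories over a gene set, with percentages over
#' assigned genes and superclass roll-ups. Genes without a mapping are counted
#' as unassigned and excluded from percentages.
#'
#' @param gene_to_category Named character vector gene_id -> COG letter.
#' @param gene_set Character vector of gene IDs to summarize.
#' @param grouping Named vector category -> superclass; defaults to the
#'   standard four-superclass grouping.
#' @return A list with `categories` (data.frame category, superclass, count,
#'   percent), `superclasses` (data.frame superclass, count, percent), and
#'   `n_unassigned`.
#' @export
cog_summary <- function(gene_to_category, gene_set,
                        grouping = COG_SUPERCLASS) {
  cats <- gene_to_category[gene_set]
  unassigned <- sum(is.na(cats))
  cats <- cats[!is.na(cats)]
  bad <- setdiff(unique(cats), names(grouping))
  if (length(bad)) stop("unknown COG category letter: ",
                        paste(bad, collapse = ", "))
  tab <- table(factor(cats, levels = names(grouping)))
  categories <- data.frame(
    category = names(tab),
    superclass = unname(grouping[names(tab)]),
    count = as.integer(tab),
    percent = if (sum(tab) > 0) round(100 * as.integer(tab) / sum(tab), 2)
              else rep(0, length(tab)))
  sc <- stats::aggregate(cbind(count, percent) ~ superclass, categories, sum)
  list(categories = categories,
       superclasses = sc[order(match(sc$superclass, unique(unname(grouping)))), ],
       n_unassigned = unassigned)
}
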