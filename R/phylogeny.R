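#' Single-copy core families
#'
#' Families with exactly one member in every genome — the families eligible
#' for concatenation into the core phylogeny supermatrix.
#'
#' @param fm A `family_matrix` or count matrix.
#' @return Character vector of family IDs, sorted.
#' @export
select_single_copy_core <- function(fm) {
  counts <- family_counts(fm)
  ids <- colnames(counts)[colSums(counts == 1L) == nrow(counts)]
  if (length(ids) == 0L) {
    warning("no single-copy core families found")
  }
  sort(ids)
}

#' Construct a multiple sequence alignment object
#'
#' @param seqs Named character vector of equal-length gapped sequences
#'   (gap symbol `-`).
#' @param origins Optional per-column origin labels (e.g. family of origin
#'   after concatenation).
#' @return A list of class `msa`: taxa, seqs, origins, length.
#' @export
msa <- function(seqs, origins = NULL) {
  if (length(seqs) < 2L) stop("alignment needs >= 2 taxa")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("aligned sequences must be named by taxon")
  }
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  if (any(colSums(mat != "-") == 0L)) stop("alignment has an all-gap column")
  if (is.null(origins)) origins <- rep(NA_character_, L)
  if (length(origins) != L) stop("origins must have one label per column")
  structure(list(taxa = names(seqs), seqs = seqs, origins = origins,
                 length = L), class = "msa")
}

msa_matrix <- function(aln) {
  do.call(rbind, strsplit(stats::setNames(unname(aln$seqs), aln$taxa), "",
                          fixed = TRUE))
}

#' Center-star multiple alignment of one protein per genome
#'
#' The center is the sequence maximizing the summed pairwise global alignment
#' score against all others (ties broken by taxon ID). Every other sequence
#' is merged via its global pairwise alignment to the center under the
#' "once a gap, always a gap" rule, which makes the procedure deterministic.
#'
#' @param seqs Named character vector (taxon -> ungapped protein).
#' @param scoring An [align_scoring()].
#' @param family_id Optional label stored as the per-column origin.
#' @return An `msa`.
#' @export
align_family <- function(seqs, scoring = align_scoring(), family_id = NULL) {
  if (length(seqs) < 2L) stop("need >= 2 sequences")
  if (any(!nzchar(seqs))) stop("empty sequence in family")
  seqs <- seqs[order(names(seqs))]
  n <- length(seqs)
  ss <- Biostrings::AAStringSet(seqs)
  # summed pairwise global score per candidate center
  tot <- numeric(n)
  for (i in seq_len(n)) {
    sc <- Biostrings::pairwiseAlignment(
      ss[-i], ss[[i]], type = "global",
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
      scoreOnly = TRUE)
    tot[i] <- sum(sc)
  }
  ci <- which.max(tot)  # ties: first in taxon order
  center_id <- names(seqs)[ci]

  # master alignment starts as the bare center; merge the others in turn
  master <- matrix(strsplit(seqs[[ci]], "")[[1L]], nrow = 1,
                   dimnames = list(center_id, NULL))
  for (tid in setdiff(names(seqs), center_id)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs[[ci]]), Biostrings::AAString(seqs[[tid]]),
      type = "global", substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    pc <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    sc <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    master <- merge_into_master(master, center_id, pc, sc, tid)
  }
  master <- master[order(rownames(master)), , drop = FALSE]
  origins <- rep(if (is.null(family_id)) NA_character_ else family_id,
                 ncol(master))
  msa(apply(master, 1, paste, collapse = ""), origins = origins)
}

# merge a center/new-seq pairwise alignment (gapped vectors pc/sc) into the
# master alignment, whose center row may already hold gaps from earlier merges
merge_into_master <- function(master, center_id, pc, sc, new_id) {
  crow <- master[center_id, ]
  ncol_out <- 0L
  # worst case: every column of both sources survives
  out <- matrix("-", nrow(master) + 1L, ncol(master) + length(pc),
                dimnames = list(c(rownames(master), new_id), NULL))
  i <- 1L; j <- 1L
  while (i <= ncol(master) || j <= length(pc)) {
    ncol_out <- ncol_out + 1L
    if (i <= ncol(master) && crow[i] == "-") {
      # gap already in master's center: emit master column, gap for new seq
      out[seq_len(nrow(master)), ncol_out] <- master[, i]
      i <- i + 1L
    } else if (j <= length(pc) && pc[j] == "-") {
      # insertion relative to the center: new column, gaps for master rows
      out[nrow(master) + 1L, ncol_out] <- sc[j]
      j <- j + 1L
    } else {
      # both sides carry the same center residue
      out[seq_len(nrow(master)), ncol_out] <- master[, i]
      out[nrow(master) + 1L, ncol_out] <- sc[j]
      i <- i + 1L; j <- j + 1L
    }
  }
  out[, seq_len(ncol_out), drop = FALSE]
}

#' Concatenate alignments over identical taxon sets
#'
#' @param alignments List of `msa` objects over the same taxa.
#' @return An `msa` whose columns are the input alignments' columns appended
#'   in list order, with per-column origins preserved.
#' @export
concatenate_alignments <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  taxa <- alignments[[1L]]$taxa
  for (a in alignments) {
    miss <- c(setdiff(taxa, a$taxa), setdiff(a$taxa, taxa))
    if (length(miss)) {
      stop("taxon set mismatch across alignments: ", paste(miss, collapse = ", "))
    }
  }
  seqs <- vapply(taxa, function(t) {
    paste(vapply(alignments, function(a) a$seqs[[t]], character(1)),
          collapse = "")
  }, character(1))
  origins <- unlist(lapply(alignments, function(a) a$origins))
  msa(seqs, origins = origins)
}

#' Pairwise distances from an alignment
#'
#' Uncorrected p-distance (mismatched column pairs / compared columns, gaps
#' deleted pairwise) or its Poisson correction `d = -ln(1 - p)`.
#'
#' @param aln An `msa`.
#' @param model `"p"` or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(aln, model = c("p", "poisson")) {
  model <- match.arg(model)
  mat <- msa_matrix(aln)
  n <- nrow(mat)
  if (n < 2L) stop("need >= 2 taxa")
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(ok)) {
        stop("zero compared columns between ", rownames(mat)[i], " and ",
             rownames(mat)[j])
      }
      p <- sum(mat[i, ok] != mat[j, ok]) / sum(ok)
      if (model == "poisson") {
        if (p >= 1) stop("Poisson distance undefined (p = 1) between ",
                         rownames(mat)[i], " and ", rownames(mat)[j])
        p <- -log(1 - p)
      }
      D[i, j] <- D[j, i] <- p
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining; negative branch lengths, which NJ can produce
#' on non-additive input, are clamped to zero with a message.
#'
#' @param d Symmetric zero-diagonal distance matrix (>= 3 taxa).
#' @return An unrooted `ape::phylo`.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need >= 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    message("nj_tree: clamped ", sum(tr$edge.length < 0),
            " negative branch length(s) to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage hierarchical clustering rendered as a phylogeny; used for
#' heatmap ordering and as an independent topology cross-check.
#'
#' @param d Symmetric distance matrix.
#' @return A rooted ultrametric `ape::phylo`.
#' @export
upgma_tree <- function(d) {
  ape::as.phylo(stats::hclust(stats::as.dist(as.matrix(d)), method = "average"))
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `replicates` times (RNG consumed once per replicate, so the
#' result is invariant to taxon input order), rebuilds the NJ tree for each
#' replicate, and maps bipartition frequencies (percent) onto the full tree's
#' internal nodes as node labels.
#'
#' @param aln An `msa` (>= 4 taxa for internal edges to exist).
#' @param model Distance model, as in [distance_matrix()].
#' @param replicates Bootstrap replicates (>= 1); conventional defaults are
#'   500 for concatenated core-gene trees and 1000 for single-gene trees.
#' @param seed Integer seed.
#' @return A `phylo` with `node.label` holding integer support percentages.
#' @export
bootstrap_support <- function(aln, model = "poisson", replicates = 500L,
                              seed = 1L) {
  if (replicates < 1L) stop("replicates must be >= 1")
  full <- nj_tree(distance_matrix(aln, model))
  mat <- msa_matrix(aln)
  rep_trees <- with_seed(seed, lapply(seq_len(replicates), function(b) {
    cols <- sample.int(ncol(mat), replace = TRUE)
    sub <- mat[, cols, drop = FALSE]
    keep <- colSums(sub != "-") > 0L
    sub <- sub[, keep, drop = FALSE]
    a <- msa(apply(sub, 1, paste, collapse = ""))
    suppressMessages(nj_tree(distance_matrix(a, model)))
  }))
  counts <- ape::prop.clades(full, rep_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  full$node.label <- as.character(round(100 * counts / replicates))
  full
}

#' Concatenated single-copy-core alignment for a gene set
#'
#' Selects single-copy core families from the family matrix, center-star
#' aligns each family's per-genome proteins, and concatenates the family
#' alignments in family-ID order.
#'
#' @param genes data.frame with gene_id, genome_id, protein_seq.
#' @param fm The `family_matrix` produced from those genes.
#' @param scoring An [align_scoring()].
#' @return An `msa` with taxa = genome IDs and per-column family origins.
#' @export
core_concat_alignment <- function(genes, fm, scoring = align_scoring()) {
  fams <- select_single_copy_core(fm)
  if (length(fams) == 0L) stop("no single-copy core families to concatenate")
  seq_of <- stats::setNames(genes$protein_seq, genes$gene_id)
  alns <- lapply(fams, function(f) {
    members <- fm$member_map[[f]]
    taxa <- unname(fm$gene_genome[members])
    align_family(stats::setNames(seq_of[members], taxa), scoring,
                 family_id = f)
  })
  concatenate_alignments(alns)
}

#' Write an alignment to FASTA
#'
#' @param aln An `msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  write_fasta(stats::setNames(unname(aln$seqs), aln$taxa), path)
}
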