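#' Parameters for fragment-based ANI
#'
#' Defaults follow the classical fragment-based (ANIb-style) procedure:
#' 1020-bp non-overlapping query fragments, a fragment retained when its best
#' local alignment to the reference reaches at least 30% identity over at
#' least 70% of the fragment length, blastn-like scoring (match +2,
#' mismatch -3, gap open 5, gap extend 2), and a 95% species threshold.
#'
#' @param fragment_length Fragment size in nucleotides (>= 100).
#' @param min_fragment_identity Minimum identity fraction for retention.
#' @param min_fragment_alignable Minimum alignable fraction of the fragment.
#' @param species_threshold Species demarcation threshold, percent.
#' @param match,mismatch,gap_open,gap_extend Nucleotide scoring.
#' @return A list of class `ani_params`.
#' @export
ani_params <- function(fragment_length = 1020L,
                       min_fragment_identity = 0.30,
                       min_fragment_alignable = 0.70,
                       species_threshold = 95,
                       match = 2, mismatch = -3,
                       gap_open = 5, gap_extend = 2) {
  if (fragment_length < 100L) stop("fragment_length must be >= 100")
  stopifnot(min_fragment_identity >= 0, min_fragment_identity <= 1,
            min_fragment_alignable >= 0, min_fragment_alignable <= 1)
  structure(list(fragment_length = as.integer(fragment_length),
                 min_fragment_identity = min_fragment_identity,
                 min_fragment_alignable = min_fragment_alignable,
                 species_threshold = species_threshold,
                 match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "ani_params")
}

#' Cut a genome into consecutive fragments
#'
#' Non-overlapping windows of `fragment_length` per scaffold (0-based,
#' half-open coordinates). Terminal partial windows are discarded, as are
#' fragments with more than 50% N.
#'
#' @param genome A `genome_record`.
#' @param fragment_length Window size in nt.
#' @return data.frame: scaffold_id, start, end, seq.
#' @export
fragment_genome <- function(genome, fragment_length = 1020L) {
  stopifnot(inherits(genome, "genome_record"))
  out <- lapply(names(genome$scaffolds), function(sid) {
    s <- genome$scaffolds[[sid]]
    n_frag <- nchar(s) %/% fragment_length
    if (n_frag == 0L) return(NULL)
    start <- (seq_len(n_frag) - 1L) * fragment_length
    data.frame(scaffold_id = sid, start = start, end = start + fragment_length,
               seq = substring(s, start + 1L, start + fragment_length),
               stringsAsFactors = FALSE)
  })
  frags <- do.call(rbind, out)
  if (is.null(frags)) {
    return(data.frame(scaffold_id = character(0), start = integer(0),
                      end = integer(0), seq = character(0)))
  }
  n_frac <- vapply(frags$seq, function(x) {
    sum(strsplit(x, "")[[1L]] == "N")
  }, numeric(1)) / fragment_length
  frags <- frags[n_frac <= 0.5, , drop = FALSE]
  rownames(frags) <- NULL
  frags
}

blastn_path <- function() {
  p <- Sys.which("blastn")
  if (!nzchar(p)) {
    stop("blastn not found on PATH; the ANI stage requires the BLAST+ suite")
  }
  p
}

# best local alignment of each fragment against a reference FASTA, via blastn
blast_fragments <- function(frag_fa, ref_fa, params, db_dir) {
  db <- file.path(db_dir, "refdb")
  if (!file.exists(paste0(db, ".nin"))) {
    out <- system2(Sys.which("makeblastdb"),
                   c("-in", shQuote(ref_fa), "-dbtype", "nucl",
                     "-out", shQuote(db)),
                   stdout = TRUE, stderr = TRUE)
    if (!file.exists(paste0(db, ".nin"))) {
      stop("makeblastdb failed: ", paste(out, collapse = "\n"))
    }
  }
  res <- system2(blastn_path(),
                 c("-task", "blastn", "-query", shQuote(frag_fa),
                   "-db", shQuote(db),
                   "-reward", params$match, "-penalty", params$mismatch,
                   "-gapopen", params$gap_open, "-gapextend", params$gap_extend,
                   "-dust", "no", "-evalue", "1e-5",
                   "-outfmt", shQuote("6 qseqid pident length bitscore")),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(res, "status")
  if (!is.null(status) && status != 0L) {
    stop("blastn failed (status ", status, "): ",
         paste(utils::tail(res, 3), collapse = " "))
  }
  if (length(res) == 0L) {
    return(data.frame(qseqid = character(0), pident = numeric(0),
                      length = integer(0), bitscore = numeric(0)))
  }
  hits <- utils::read.delim(text = res, header = FALSE,
                            col.names = c("qseqid", "pident", "length",
                                          "bitscore"))
  # best HSP per fragment
  hits <- hits[order(hits$qseqid, -hits$bitscore), ]
  hits[!duplicated(hits$qseqid), ]
}

#' One-way average nucleotide identity
#'
#' Fragments the query genome and locally aligns each fragment against the
#' reference (both strands; best alignment kept). Fragments reaching
#' `min_fragment_identity` over at least `min_fragment_alignable` of the
#' fragment length are retained; the one-way ANI is the mean percent identity
#' of retained fragments.
#'
#' @param query,reference `genome_record`s.
#' @param params An [ani_params()].
#' @return List: ani_percent (NA when no fragment is retained),
#'   fragments_used, fragments_retained, no_signal.
#' @export
one_way_ani <- function(query, reference, params = ani_params()) {
  frags <- fragment_genome(query, params$fragment_length)
  if (nrow(frags) == 0L) {
    return(list(ani_percent = NA_real_, fragments_used = 0L,
                fragments_retained = 0L, no_signal = TRUE))
  }
  wd <- tempfile("ani_")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE))
  frag_fa <- file.path(wd, "frags.fa")
  ref_fa <- file.path(wd, "ref.fa")
  write_fasta(stats::setNames(frags$seq,
                              sprintf("frag%06d", seq_len(nrow(frags)))),
              frag_fa)
  write_fasta(stats::setNames(reference$scaffolds, names(reference$scaffolds)),
              ref_fa)
  hits <- blast_fragments(frag_fa, ref_fa, params, wd)
  keep <- hits$pident / 100 >= params$min_fragment_identity &
    hits$length >= params$min_fragment_alignable * params$fragment_length
  retained <- hits[keep, , drop = FALSE]
  if (nrow(retained) == 0L) {
    return(list(ani_percent = NA_real_, fragments_used = nrow(frags),
                fragments_retained = 0L, no_signal = TRUE))
  }
  list(ani_percent = mean(retained$pident),
       fragments_used = nrow(frags),
       fragments_retained = nrow(retained),
       no_signal = FALSE)
}

#' Pairwise ANI matrix over a set of genomes
#'
#' Each off-diagonal cell is the arithmetic mean of the two one-way ANI
#' values; the diagonal is fixed at 100. A pair with no retained fragments in
#' either direction is set to NA and reported in `missing_pairs`.
#'
#' @param genomes Named list of `genome_record`s (>= 2).
#' @param params An [ani_params()].
#' @return A list of class `ani_matrix`: values (symmetric percent matrix),
#'   fragments (per-pair used/retained), params, missing_pairs.
#' @export
ani_matrix <- function(genomes, params = ani_params()) {
  if (length(genomes) < 2L) stop("need at least 2 genomes")
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  names(genomes) <- ids
  ids <- sort(ids)
  M <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(M) <- 100
  frag_log <- list()
  missing <- character(0)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      fwd <- one_way_ani(genomes[[ids[i]]], genomes[[ids[j]]], params)
      rev_ <- one_way_ani(genomes[[ids[j]]], genomes[[ids[i]]], params)
      vals <- c(fwd$ani_percent, rev_$ani_percent)
      if (all(is.na(vals))) {
        missing <- c(missing, paste(ids[i], ids[j], sep = "~"))
      } else {
        M[i, j] <- M[j, i] <- mean(vals, na.rm = TRUE)
      }
      frag_log[[paste(ids[i], ids[j], sep = "~")]] <-
        list(used = c(fwd$fragments_used, rev_$fragments_used),
             retained = c(fwd$fragments_retained, rev_$fragments_retained))
    }
  }
  structure(list(values = M, fragments = frag_log, params = params,
                 missing_pairs = missing),
            class = "ani_matrix")
}

#' Species demarcation and heatmap ordering from an ANI matrix
#'
#' Genomes are joined into one species cluster by single linkage whenever
#' their ANI strictly exceeds `species_threshold`. The heatmap row/column
#' order comes from UPGMA (average-linkage) clustering of 100 - ANI
#' distances; input rows are sorted by genome_id first so ties resolve
#' deterministically.
#'
#' @param am An `ani_matrix` (or plain symmetric percent matrix).
#' @param species_threshold Percent ANI above which two genomes are
#'   conspecific.
#' @return List: clusters (named integer vector genome -> cluster),
#'   n_clusters, heatmap_order (genome IDs), upgma (hclust object).
#' @export
demarcate_species <- function(am, species_threshold = 95) {
  M <- if (inherits(am, "ani_matrix")) am$values else as.matrix(am)
  if (any(is.na(M))) {
    bad <- which(is.na(M) & upper.tri(M), arr.ind = TRUE)
    stop("ANI matrix has missing cells: ",
         paste(rownames(M)[bad[, 1]], colnames(M)[bad[, 2]],
               sep = "~", collapse = ", "))
  }
  ord <- order(rownames(M))
  M <- M[ord, ord]
  d <- stats::as.dist(100 - M)
  single <- stats::hclust(d, method = "single")
  # strict ANI > threshold <=> distance < 100 - threshold
  clusters <- stats::cutree(single, h = (100 - species_threshold) - 1e-9)
  upgma <- stats::hclust(d, method = "average")
  list(clusters = clusters,
       n_clusters = max(clusters),
       heatmap_order = rownames(M)[upgma$order],
       upgma = upgma)
}

#' Write an ANI matrix as TSV
#'
#' @param am An `ani_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ani_matrix <- function(am, path) {
  M <- if (inherits(am, "ani_matrix")) am$values else as.matrix(am)
  df <- data.frame(genome_id = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
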