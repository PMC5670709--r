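#' Parameters for the synthetic pan-genome generator
#'
#' Describes a genus of `n_genomes` genomes drawn from a shared gene-family
#' pool: `core_families` present everywhere, `accessory_families` present in
#' each genome independently with probability `accessory_presence_prob`, and
#' `unique_per_genome` families private to each genome. Protein copies of a
#' family diverge from the family's ancestral sequence by point substitution
#' at rate `within_family_divergence`; nucleotide genomes are GC-calibrated
#' back-translations evolved along a tree with per-branch substitution
#' fractions.
#'
#' @param n_genomes Number of genomes (>= 2).
#' @param core_families Gene families present in every genome.
#' @param accessory_families Size of the accessory family pool.
#' @param accessory_presence_prob Per-genome presence probability of each
#'   accessory family.
#' @param unique_per_genome Families private to each genome.
#' @param protein_length_mean,protein_length_sd Ancestral protein length
#'   distribution (amino acids); lengths are truncated below at 60.
#' @param within_family_divergence Expected substituted fraction per gene copy
#'   relative to the family ancestor; must be < 0.5 so that within-family
#'   identity stays comfortably above the 50% clustering threshold.
#' @param genome_gc_target Target genomic GC fraction, achieved by GC-biased
#'   synonymous codon choice and matching intergenic composition.
#' @param intergenic_length_mean Mean intergenic spacer length (nt).
#' @param tree Optional rooted `ape::phylo` with branch lengths giving the
#'   per-branch nucleotide substitution fraction; tip labels must be
#'   `g1..gN`. If `NULL`, a random topology with branch lengths
#'   Uniform(0.005, 0.03) is drawn from the seed.
#' @param seed Integer seed; the same `sim_params` give byte-identical output.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_genomes = 5L,
                       core_families = 40L,
                       accessory_families = 30L,
                       accessory_presence_prob = 0.5,
                       unique_per_genome = 5L,
                       protein_length_mean = 120,
                       protein_length_sd = 25,
                       within_family_divergence = 0.2,
                       genome_gc_target = 0.37,
                       intergenic_length_mean = 100,
                       tree = NULL,
                       seed = 1L) {
  p <- list(n_genomes = as.integer(n_genomes),
            core_families = as.integer(core_families),
            accessory_families = as.integer(accessory_families),
            accessory_presence_prob = accessory_presence_prob,
            unique_per_genome = as.integer(unique_per_genome),
            protein_length_mean = protein_length_mean,
            protein_length_sd = protein_length_sd,
            within_family_divergence = within_family_divergence,
            genome_gc_target = genome_gc_target,
            intergenic_length_mean = intergenic_length_mean,
            tree = tree, seed = as.integer(seed))
  if (p$n_genomes < 2L) stop("n_genomes must be >= 2")
  if (p$core_families < 0L || p$accessory_families < 0L || p$unique_per_genome < 0L) {
    stop("family counts must be non-negative")
  }
  if (p$accessory_presence_prob < 0 || p$accessory_presence_prob > 1) {
    stop("accessory_presence_prob must be in [0, 1]")
  }
  if (p$within_family_divergence < 0 || p$within_family_divergence >= 0.5) {
    stop("within_family_divergence must be in [0, 0.5)")
  }
  if (p$genome_gc_target <= 0 || p$genome_gc_target >= 1) {
    stop("genome_gc_target must be in (0, 1)")
  }
  if (!is.null(tree)) {
    if (!inherits(tree, "phylo") || is.null(tree$edge.length)) {
      stop("tree must be an ape::phylo with branch lengths")
    }
    if (length(tree$tip.label) != p$n_genomes) {
      stop("tree must have one tip per genome")
    }
    if (any(tree$edge.length < 0) || any(tree$edge.length >= 0.75)) {
      stop("branch lengths must be substitution fractions in [0, 0.75)")
    }
  }
  class(p) <- "sim_params"
  p
}

AA_ALPHABET20 <- c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V")
DNA_ALPHABET4 <- c("A", "C", "G", "T")

# standard codon table, stop codons excluded
CODON_TABLE <- list(
  A = c("GCT","GCC","GCA","GCG"), R = c("CGT","CGC","CGA","CGG","AGA","AGG"),
  N = c("AAT","AAC"), D = c("GAT","GAC"), C = c("TGT","TGC"),
  Q = c("CAA","CAG"), E = c("GAA","GAG"), G = c("GGT","GGC","GGA","GGG"),
  H = c("CAT","CAC"), I = c("ATT","ATC","ATA"),
  L = c("TTA","TTG","CTT","CTC","CTA","CTG"), K = c("AAA","AAG"),
  M = "ATG", F = c("TTT","TTC"), P = c("CCT","CCC","CCA","CCG"),
  S = c("TCT","TCC","TCA","TCG","AGT","AGC"), T = c("ACT","ACC","ACA","ACG"),
  W = "TGG", Y = c("TAT","TAC"), V = c("GTT","GTC","GTA","GTG")
)

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

random_seq <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Mutate a sequence by independent point substitution
#'
#' Each position is substituted with probability `divergence` to a uniformly
#' chosen *different* letter of the alphabet; length is preserved.
#'
#' @param seq A single character string.
#' @param divergence Substitution probability per position, in `[0, 1]`.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param seed Optional integer seed applied locally (the caller's RNG state
#'   is restored afterwards).
#' @return The mutated string.
#' @export
mutate_sequence <- function(seq, divergence, alphabet = c("protein", "nucleotide"),
                            seed = NULL) {
  alphabet <- match.arg(alphabet)
  if (!is.numeric(divergence) || length(divergence) != 1L ||
      is.na(divergence) || divergence < 0 || divergence > 1) {
    stop("divergence must be a single number in [0, 1]")
  }
  letters_ <- if (alphabet == "protein") AA_ALPHABET20 else DNA_ALPHABET4
  run <- function() {
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    hit <- stats::runif(length(chars)) < divergence
    if (any(hit)) {
      k <- length(letters_)
      # uniform over the k-1 letters different from the current one
      idx <- match(chars[hit], letters_)
      draw <- sample.int(k - 1L, sum(hit), replace = TRUE)
      repl <- ifelse(draw >= idx, draw + 1L, draw)
      chars[hit] <- letters_[repl]
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# expected GC fraction of coding sequence under codon weights exp(theta*gc),
# given amino-acid counts `aa_counts` (named by residue)
coding_gc_expectation <- function(theta, aa_counts) {
  num <- 0; den <- 0
  for (aa in names(aa_counts)) {
    codons <- CODON_TABLE[[aa]]
    gc <- vapply(codons, function(cd) {
      sum(strsplit(cd, "")[[1L]] %in% c("G", "C"))
    }, numeric(1))
    w <- exp(theta * gc)
    num <- num + aa_counts[[aa]] * sum(w * gc) / sum(w)
    den <- den + aa_counts[[aa]] * 3
  }
  num / den
}

# back-translate a protein with codon weights exp(theta * gc(codon))
back_translate <- function(protein, theta) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1L]]
  codons <- vapply(chars, function(aa) {
    cds <- CODON_TABLE[[aa]]
    if (length(cds) == 1L) return(cds)
    gc <- vapply(cds, function(cd) sum(strsplit(cd, "")[[1L]] %in% c("G", "C")),
                 numeric(1))
    w <- exp(theta * gc)
    sample(cds, 1L, prob = w / sum(w))
  }, character(1), USE.NAMES = FALSE)
  paste(codons, collapse = "")
}

random_spacer <- function(n, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' Simulate a synthetic genus with ground truth
#'
#' Generates per-genome proteomes (one gene copy per family present, mutated
#' from the family's ancestral protein), nucleotide genomes (GC-calibrated
#' back-translations plus intergenic spacers, evolved along a tree), and a
#' machine-readable truth object: the true gene-family partition, pan/core/
#' unique counts, the tree, and expected pairwise nucleotide identities.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `pangenome_sim` with elements `genomes` (list of
#'   [genome_record()]), `genes` (data.frame gene_id, genome_id, protein_seq),
#'   `truth` (list), and `params`.
#' @export
simulate_pangenome <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, simulate_pangenome_impl(params))
}

simulate_pangenome_impl <- function(p) {
  gids <- paste0("g", seq_len(p$n_genomes))

  tree <- p$tree
  if (is.null(tree)) {
    tree <- ape::rtree(p$n_genomes,
                       br = function(n) stats::runif(n, 0.005, 0.03))
    tree$tip.label <- gids[as.integer(sub("^t", "", tree$tip.label))]
  }

  # family inventory and presence matrix (genomes x families)
  fam_core <- sprintf("fam_core_%03d", seq_len(p$core_families))
  fam_acc <- sprintf("fam_acc_%03d", seq_len(p$accessory_families))
  fam_uni <- unlist(lapply(gids, function(g) {
    sprintf("fam_uniq_%s_%03d", g, seq_len(p$unique_per_genome))
  }))
  fams <- c(fam_core, fam_acc, fam_uni)
  presence <- matrix(FALSE, p$n_genomes, length(fams),
                     dimnames = list(gids, fams))
  presence[, fam_core] <- TRUE
  if (p$accessory_families > 0L) {
    presence[, fam_acc] <- stats::runif(p$n_genomes * p$accessory_families) <
      p$accessory_presence_prob
  }
  for (g in gids) presence[g, grep(paste0("fam_uniq_", g, "_"), fams)] <- TRUE

  # ancestral proteins
  lens <- pmax(60L, round(stats::rnorm(length(fams), p$protein_length_mean,
                                       p$protein_length_sd)))
  anc_prot <- stats::setNames(
    vapply(lens, random_seq, character(1), alphabet = AA_ALPHABET20), fams)

  # per-genome protein copies: each family's ancestral protein evolves along
  # the tree, with branch substitution probabilities scaled so the mean
  # root-to-tip protein divergence equals within_family_divergence (keeps the
  # true partition exact while giving the core alignment real tree signal)
  rtree_ <- ape::reorder.phylo(tree, "cladewise")
  nnode <- max(rtree_$edge)
  root <- setdiff(rtree_$edge[, 1], rtree_$edge[, 2])[1L]
  tip_depth <- ape::node.depth.edgelength(rtree_)[seq_along(gids)]
  k_prot <- if (mean(tip_depth) > 0) {
    p$within_family_divergence / mean(tip_depth)
  } else 0
  evolve_family <- function(anc) {
    node_seq <- vector("list", nnode)
    node_seq[[root]] <- anc
    for (e in seq_len(nrow(rtree_$edge))) {
      par <- rtree_$edge[e, 1]; child <- rtree_$edge[e, 2]
      node_seq[[child]] <- mutate_sequence(
        node_seq[[par]], min(0.95, k_prot * rtree_$edge.length[e]),
        alphabet = "protein")
    }
    stats::setNames(unlist(node_seq[seq_along(gids)]), rtree_$tip.label)
  }
  tip_prot <- lapply(fams, function(f) evolve_family(anc_prot[[f]]))
  names(tip_prot) <- fams
  genes <- do.call(rbind, lapply(gids, function(g) {
    fset <- fams[presence[g, ]]
    data.frame(gene_id = paste0(g, ".", fset), genome_id = g, family_id = fset,
               stringsAsFactors = FALSE)
  }))
  genes$protein_seq <- vapply(seq_len(nrow(genes)), function(i) {
    tip_prot[[genes$family_id[i]]][[genes$genome_id[i]]]
  }, character(1))

  # ancestral pan-genome nucleotide sequence: spacer + gene per family, with
  # codon GC bias solved so expected genomic GC hits the target
  aa_counts <- table(strsplit(paste(anc_prot, collapse = ""), "")[[1L]])
  theta <- stats::uniroot(function(th) {
    coding_gc_expectation(th, as.list(aa_counts)) - p$genome_gc_target
  }, c(-25, 25))$root
  spacer_len <- pmax(10L, stats::rpois(length(fams), p$intergenic_length_mean))
  segments <- lapply(seq_along(fams), function(i) {
    paste0(random_spacer(spacer_len[i], p$genome_gc_target),
           back_translate(anc_prot[[i]], theta))
  })
  names(segments) <- fams
  seg_len <- vapply(segments, nchar, integer(1))
  pan_anc <- paste(unlist(segments), collapse = "")

  # evolve the full pan-sequence down the tree; leaves keep only the segments
  # of families they carry
  node_seq <- vector("list", nnode)
  node_seq[[root]] <- pan_anc
  for (e in seq_len(nrow(rtree_$edge))) {
    par <- rtree_$edge[e, 1]; child <- rtree_$edge[e, 2]
    node_seq[[child]] <- mutate_sequence(node_seq[[par]], rtree_$edge.length[e],
                                         alphabet = "nucleotide")
  }
  seg_end <- cumsum(seg_len)
  seg_start <- seg_end - seg_len + 1L
  genomes <- lapply(gids, function(g) {
    tip <- match(g, rtree_$tip.label)
    keep <- which(presence[g, ])
    seqs <- substring(node_seq[[tip]], seg_start[keep], seg_end[keep])
    genome_record(g, stats::setNames(paste(seqs, collapse = ""), "s1"),
                  source_path = "simulated")
  })
  names(genomes) <- gids

  # expected observed pairwise identity: both lineages mutate from the common
  # ancestor; per-branch eigenvalue 1 - 4b/3 composes multiplicatively along
  # the tip-to-tip path, giving P(same) = 1/4 + 3/4 * prod(1 - 4b/3)
  tr_log <- tree
  tr_log$edge.length <- -log(pmax(1e-12, 1 - 4 * tree$edge.length / 3))
  pd <- ape::cophenetic.phylo(tr_log)[gids, gids]
  true_ident <- 100 * (0.25 + 0.75 * exp(-pd))
  diag(true_ident) <- 100

  support <- colSums(presence)
  truth <- list(
    family_membership = stats::setNames(genes$family_id, genes$gene_id),
    genome_membership = stats::setNames(genes$genome_id, genes$gene_id),
    presence = presence,
    true_pan_count = sum(support >= 1L),
    true_core_count = sum(support == p$n_genomes),
    true_unique_counts = stats::setNames(vapply(gids, function(g) {
      sum(support == 1L & presence[g, ])
    }, integer(1)), gids),
    true_tree = tree,
    true_pairwise_nucleotide_identity = true_ident
  )

  structure(list(genomes = genomes,
                 genes = genes[, c("gene_id", "genome_id", "protein_seq")],
                 truth = truth, params = p),
            class = "pangenome_sim")
}

#' Write a simulated genus to disk
#'
#' Emits per-genome nucleotide FASTA (`<genome>.fna`), per-genome protein
#' FASTA (`<genome>.faa`, headers `geneID genomeID`), truth tables as TSV, the
#' true tree as Newick, and a JSON manifest of parameters and truth counts.
#'
#' @param sim A `pangenome_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pangenome_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "pangenome_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(sim$genomes)) {
    gr <- sim$genomes[[g]]
    write_fasta(stats::setNames(gr$scaffolds, names(gr$scaffolds)),
                file.path(dir, paste0(g, ".fna")))
    sub <- sim$genes[sim$genes$genome_id == g, ]
    write_fasta(data.frame(id = sub$gene_id, seq = sub$protein_seq,
                           desc = sub$genome_id),
                file.path(dir, paste0(g, ".faa")))
  }
  truth_df <- data.frame(gene_id = names(sim$truth$family_membership),
                         genome_id = unname(sim$truth$genome_membership),
                         family_id = unname(sim$truth$family_membership))
  utils::write.table(truth_df, file.path(dir, "truth_families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$truth$true_tree, file.path(dir, "truth_tree.nwk"))
  manifest <- list(
    seed = sim$params$seed,
    n_genomes = sim$params$n_genomes,
    true_pan_count = sim$truth$true_pan_count,
    true_core_count = sim$truth$true_core_count,
    true_unique_counts = as.list(sim$truth$true_unique_counts))
  jsonlite::write_json(manifest, file.path(dir, "truth_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
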