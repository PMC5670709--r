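#' Configuration for an end-to-end pipeline run
#'
#' Either `sim` (a [sim_params()] object: the genus is simulated) or both
#' `genomes_dir` (nucleotide FASTAs) and `proteins_dir` (protein FASTAs with
#' headers `geneID genomeID`) must be given.
#'
#' @param sim Optional [sim_params()].
#' @param genomes_dir,proteins_dir Optional input directories.
#' @param stages Character vector of stages to run, from
#'   `c("stats", "families", "pangenome", "phylogeny", "ani")`.
#' @param thresholds A [cluster_thresholds()].
#' @param ani An [ani_params()].
#' @param permutations Genome orderings for the accumulation curve.
#' @param bootstrap Bootstrap replicates for the core tree (0 disables).
#' @param model Distance model for the phylogeny stage.
#' @param seed Global seed; per-stage seeds are derived as `seed + fixed
#'   per-stage offset` so toggling stages never changes another stage's
#'   stream.
#' @param out_dir Optional output directory; when given, primary outputs are
#'   written there as headered TSV/Newick.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = NULL, genomes_dir = NULL, proteins_dir = NULL,
                       stages = c("stats", "families", "pangenome",
                                  "phylogeny", "ani"),
                       thresholds = cluster_thresholds(),
                       ani = ani_params(),
                       permutations = 100L,
                       bootstrap = 100L,
                       model = "poisson",
                       seed = 1L,
                       out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(sim)) {
    if (is.null(genomes_dir) || is.null(proteins_dir)) {
      stop("config needs either sim params or genomes_dir + proteins_dir")
    }
    if (!dir.exists(genomes_dir)) stop("genomes_dir not found: ", genomes_dir)
    if (!dir.exists(proteins_dir)) stop("proteins_dir not found: ", proteins_dir)
  }
  structure(list(sim = sim, genomes_dir = genomes_dir,
                 proteins_dir = proteins_dir, stages = stages,
                 thresholds = thresholds, ani = ani,
                 permutations = as.integer(permutations),
                 bootstrap = as.integer(bootstrap), model = model,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# fixed per-stage seed offsets (documented derivation: global seed + offset)
STAGE_SEED_OFFSET <- c(simulate = 0L, pangenome = 101L, phylogeny = 202L)

read_protein_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(faa|fa|fasta)$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no protein FASTA files in ", dir)
  do.call(rbind, lapply(files, function(f) {
    recs <- read_fasta(f)
    genome <- ifelse(nzchar(recs$desc), recs$desc,
                     sub("\\.(faa|fa|fasta)$", "", basename(f)))
    data.frame(gene_id = recs$id, genome_id = genome,
               protein_seq = recs$seq, stringsAsFactors = FALSE)
  }))
}

read_genome_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(fna|fa|fasta)$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no genome FASTA files in ", dir)
  gs <- lapply(files, read_genome)
  stats::setNames(gs, vapply(gs, function(g) g$genome_id, character(1)))
}

#' Run the comparative-genomics pipeline end to end
#'
#' Executes the enabled stages in dependency order (genome stats ->
#' gene-family clustering -> pan-genome dynamics and core phylogeny; ANI is
#' independent of clustering). A failed stage stops its dependents but not
#' independent stages; errors are recorded in the report.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report`: per-stage results, parameter echo,
#'   warnings/errors, and a `summary` list (pan/core sizes, Heaps gamma, ANI
#'   cluster count, concordance, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- list(stages = list(), errors = list(),
                 params = config[setdiff(names(config), "sim")],
                 seed = config$seed)

  sim <- NULL
  if (!is.null(config$sim)) {
    sim_p <- config$sim
    sim_p$seed <- config$seed + STAGE_SEED_OFFSET[["simulate"]]
    sim <- simulate_pangenome(sim_p)
    genomes <- sim$genomes
    genes <- sim$genes
    report$stages$simulate <- list(
      n_genomes = length(genomes),
      n_genes = nrow(genes),
      true_pan = sim$truth$true_pan_count,
      true_core = sim$truth$true_core_count)
  } else {
    genomes <- read_genome_dir(config$genomes_dir)
    genes <- read_protein_dir(config$proteins_dir)
  }

  try_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) report$stages[[name]] <<- res
    res
  }

  if ("stats" %in% config$stages) {
    try_stage("stats", function() {
      st <- do.call(rbind, lapply(genomes, genome_stats))
      list(stats = st, summary = summarize_genus(st))
    })
  }

  fm <- NULL
  if ("families" %in% config$stages) {
    fam_res <- try_stage("families", function() {
      fm <- cluster_families(genes, config$thresholds)
      list(fm = fm, n_families = length(fm$family_ids),
           core = core_families(fm), unique = unique_families(fm))
    })
    fm <- fam_res$fm
  }

  if ("pangenome" %in% config$stages && !is.null(fm)) {
    try_stage("pangenome", function() {
      curve <- accumulate(fm, config$permutations,
                          seed = config$seed + STAGE_SEED_OFFSET[["pangenome"]])
      list(curve = curve, heaps = fit_heaps(curve))
    })
  }

  if ("phylogeny" %in% config$stages && !is.null(fm)) {
    try_stage("phylogeny", function() {
      aln <- core_concat_alignment(genes, fm)
      tree <- if (config$bootstrap > 0L) {
        bootstrap_support(aln, config$model, config$bootstrap,
                          seed = config$seed + STAGE_SEED_OFFSET[["phylogeny"]])
      } else {
        nj_tree(distance_matrix(aln, config$model))
      }
      list(alignment_length = aln$length,
           n_families = length(unique(aln$origins)), tree = tree)
    })
  }

  if ("ani" %in% config$stages) {
    try_stage("ani", function() {
      am <- ani_matrix(genomes, config$ani)
      sp <- demarcate_species(am, config$ani$species_threshold)
      list(matrix = am, species = sp)
    })
  }

  report$summary <- list(
    n_genomes = length(genomes),
    pan_size = if (!is.null(fm)) length(fm$family_ids) else NA,
    core_size = if (!is.null(fm)) length(core_families(fm)) else NA,
    heaps_gamma = if (!is.null(report$stages$pangenome))
      report$stages$pangenome$heaps$gamma else NA,
    ani_clusters = if (!is.null(report$stages$ani))
      report$stages$ani$species$n_clusters else NA)

  if (!is.null(sim)) report$truth <- sim$truth
  class(report) <- "run_report"

  if (!is.null(config$out_dir)) write_run_outputs(report, config, genomes)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, "): stages ",
      paste(names(x$stages), collapse = ", "), "\n", sep = "")
  s <- x$summary
  cat(sprintf("  genomes %d | pan %s | core %s | gamma %s | ANI clusters %s\n",
              s$n_genomes, s$pan_size, s$core_size,
              if (is.na(s$heaps_gamma)) "-" else sprintf("%.3f", s$heaps_gamma),
              s$ani_clusters))
  if (length(x$errors)) {
    cat("  errors:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

output_header <- function(config) {
  cfg <- config[setdiff(names(config), c("sim", "out_dir"))]
  hash <- substr(tools::md5sum(
    files = {
      f <- tempfile()
      saveRDS(utils::capture.output(utils::str(cfg)), f)
      f
    }), 1, 8)
  sprintf("# lactopan %s | seed %d | config %s",
          as.character(utils::packageVersion("lactopan")),
          config$seed, unname(hash))
}

write_run_outputs <- function(report, config, genomes) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- output_header(config)
  put <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    tmp <- tempfile()
    writer(tmp)
    writeLines(c(hdr, readLines(tmp)), path)
    unlink(tmp)
  }
  st <- report$stages
  if (!is.null(st$stats)) {
    put("genome_stats.tsv", function(p) write_genome_stats(st$stats$stats, p))
  }
  if (!is.null(st$families)) {
    fmstem <- file.path(config$out_dir, "families")
    write_family_matrix(st$families$fm, fmstem)
  }
  if (!is.null(st$pangenome)) {
    put("accumulation.tsv", function(p) write_accumulation_curve(st$pangenome$curve, p))
    jsonlite::write_json(st$pangenome$heaps[c("kappa", "gamma", "r_squared",
                                              "open_call")],
                         file.path(config$out_dir, "heaps_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(st$phylogeny)) {
    ape::write.tree(st$phylogeny$tree,
                    file.path(config$out_dir, "core_tree.nwk"))
  }
  if (!is.null(st$ani)) {
    put("ani_matrix.tsv", function(p) write_ani_matrix(st$ani$matrix, p))
  }
  invisible(config$out_dir)
}
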