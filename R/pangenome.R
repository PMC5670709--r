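#' Pan- and core-genome accumulation curves
#'
#' For each genome-addition order, pan(n) is the number of distinct gene
#' families in the first n genomes and core(n) the number present in all of
#' them. Orders are sampled permutations (seeded); when `n_permutations`
#' covers all G! orders (G! <= 5040) the full set of distinct permutations is
#' enumerated instead, so means are exact.
#'
#' @param fm A `family_matrix` from [cluster_families()], or any genomes x
#'   families count matrix.
#' @param n_permutations Number of genome orderings (>= 1).
#' @param seed Integer seed for order sampling.
#' @return A list of class `accumulation_curve`: n_values, pan_mean,
#'   core_mean, pan_by_perm, core_by_perm (permutations x G matrices),
#'   new_per_genome_mean, permutation_count, seed.
#' @export
accumulate <- function(fm, n_permutations = 100L, seed = 1L) {
  counts <- family_counts(fm)
  G <- nrow(counts)
  if (G < 2L) stop("need at least 2 genomes")
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  pres <- counts > 0L

  exhaustive <- factorial(G) <= 5040 && n_permutations >= factorial(G)
  orders <- if (exhaustive) {
    all_permutations(G)
  } else {
    with_seed(seed, lapply(seq_len(n_permutations), function(i) sample.int(G)))
  }

  pan <- matrix(0L, length(orders), G)
  core <- matrix(0L, length(orders), G)
  for (k in seq_along(orders)) {
    ord <- orders[[k]]
    in_pan <- rep(FALSE, ncol(pres))
    in_core <- rep(TRUE, ncol(pres))
    for (n in seq_len(G)) {
      in_pan <- in_pan | pres[ord[n], ]
      in_core <- in_core & pres[ord[n], ]
      pan[k, n] <- sum(in_pan)
      core[k, n] <- sum(in_core)
    }
  }
  structure(list(
    n_values = seq_len(G),
    pan_mean = colMeans(pan),
    core_mean = colMeans(core),
    pan_by_perm = pan,
    core_by_perm = core,
    new_per_genome_mean = mean((pan[, G] - pan[, 1]) / (G - 1)),
    permutation_count = length(orders),
    exhaustive = exhaustive,
    seed = seed
  ), class = "accumulation_curve")
}

# all G! orderings of 1..G (G small; guarded by caller)
all_permutations <- function(G) {
  if (G == 1L) return(list(1L))
  sub <- all_permutations(G - 1L)
  out <- vector("list", G * length(sub))
  i <- 0L
  for (first in seq_len(G)) {
    rest <- setdiff(seq_len(G), first)
    for (s in sub) {
      i <- i + 1L
      out[[i]] <- c(first, rest[s])
    }
  }
  out
}

family_counts <- function(fm) {
  if (inherits(fm, "family_matrix")) fm$counts else as.matrix(fm)
}

#' Fit Heaps' power law to a pan-genome curve
#'
#' Fits pan(n) = kappa * n^gamma by ordinary least squares on
#' (ln n, ln pan_mean). The pan-genome is called open when gamma exceeds
#' `open_threshold`.
#'
#' @param curve An `accumulation_curve`, or a list with `n_values` and
#'   `pan_mean`.
#' @param open_threshold Gamma above which the pan-genome is called open.
#' @return A list of class `heaps_fit`: kappa, gamma, r_squared, open_call,
#'   open_threshold.
#' @export
fit_heaps <- function(curve, open_threshold = 0.05) {
  n <- curve$n_values
  pan <- curve$pan_mean
  if (length(n) < 3L) stop("need at least 3 points to fit")
  if (any(pan <= 0)) stop("pan values must be positive for a log-log fit")
  fit <- stats::lm(log(pan) ~ log(n))
  gamma <- unname(stats::coef(fit)[2L])
  # summary.lm warns on an exactly power-law input; that's a legitimate case
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (is.nan(r2)) r2 <- 1  # zero-variance response: constant pan fits exactly
  structure(list(kappa = exp(unname(stats::coef(fit)[1L])),
                 gamma = gamma,
                 r_squared = r2,
                 open_call = gamma > open_threshold,
                 open_threshold = open_threshold),
            class = "heaps_fit")
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat(sprintf("Heaps fit: pan(n) = %.2f * n^%.4f (r^2 = %.4f) -> %s pan-genome\n",
              x$kappa, x$gamma, x$r_squared,
              if (x$open_call) "open" else "closed"))
  invisible(x)
}

#' Core gene families
#'
#' Families with at least one member in every genome.
#'
#' @param fm A `family_matrix` or count matrix.
#' @return Character vector of family IDs.
#' @export
core_families <- function(fm) {
  counts <- family_counts(fm)
  colnames(counts)[colSums(counts > 0L) == nrow(counts)]
}

#' Unique gene families per genome
#'
#' Families found in exactly one genome, keyed by that genome.
#'
#' @param fm A `family_matrix` or count matrix.
#' @return Named list genome_id -> character vector of family IDs.
#' @export
unique_families <- function(fm) {
  counts <- family_counts(fm)
  support <- colSums(counts > 0L)
  out <- lapply(rownames(counts), function(g) {
    colnames(counts)[support == 1L & counts[g, ] > 0L]
  })
  stats::setNames(out, rownames(counts))
}

#' Core-genome fraction of each genome's predicted genes
#'
#' The share of a genome's predicted coding genes accounted for by the core
#' genome, as a percentage to one decimal.
#'
#' @param core_size Number of core gene families.
#' @param coding_genes Named integer vector of per-genome predicted gene
#'   counts.
#' @return Named numeric vector of percentages.
#' @export
core_fraction_percent <- function(core_size, coding_genes) {
  round(100 * core_size / coding_genes, 1)
}

#' Write an accumulation curve as TSV
#'
#' @param curve An `accumulation_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accumulation_curve <- function(curve, path) {
  utils::write.table(
    data.frame(n = curve$n_values, pan_mean = curve$pan_mean,
               core_mean = curve$core_mean),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
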