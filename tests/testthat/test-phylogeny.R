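test_that("select_single_copy_core keeps exactly-one-copy-everywhere families", {
  m <- matrix(1L, 3, 4, dimnames = list(paste0("g", 1:3), paste0("f", 1:4)))
  expect_equal(select_single_copy_core(m), paste0("f", 1:4))
  m[2, 3] <- 2L
  expect_equal(select_single_copy_core(m), c("f1", "f2", "f4"))
  m2 <- m; m2[, ] <- 0L
  expect_warning(out <- select_single_copy_core(m2), "no single-copy")
  expect_length(out, 0)
})

test_that("single-copy selection equals a brute-force column scan on random matrices", {
  set.seed(71)
  m <- matrix(rbinom(5 * 40, 3, 0.35), 5, 40,
              dimnames = list(paste0("g", 1:5), sprintf("f%02d", 1:40)))
  expected <- sort(colnames(m)[apply(m, 2, function(col) all(col == 1L))])
  if (length(expected)) {
    expect_equal(select_single_copy_core(m), expected)
  } else {
    expect_warning(expect_length(select_single_copy_core(m), 0))
  }
})

test_that("center-star alignment handles identical, pairwise and gapped cases", {
  a <- align_family(c(t1 = "MKTAYIAK", t2 = "MKTAYIAK", t3 = "MKTAYIAK"))
  expect_equal(a$length, 8L)
  expect_false(any(grepl("-", a$seqs)))

  # two sequences degenerate to the pairwise global alignment
  two <- align_family(c(x = "MKTAYIAK", y = "MKTAYWWIAK"))
  expect_equal(two$length, 10L)
  expect_equal(gsub("-", "", two$seqs[["x"]]), "MKTAYIAK")
  expect_equal(gsub("-", "", two$seqs[["y"]]), "MKTAYWWIAK")
})

test_that("center-star sum-of-pairs beats random valid alignments of the same sequences", {
  set.seed(72)
  seqs <- c(a = "MKTAYIWQRL", b = "MKTAYIQRL", c = "MKTWYIWQR", d = "MTAYIWQRL")
  aln <- align_family(seqs)
  B <- get_blosum62()
  sop <- function(rows) {
    tot <- 0
    n <- length(rows)
    mat <- do.call(rbind, strsplit(rows, ""))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      tot <- tot + sum(B[cbind(mat[i, ok], mat[j, ok])])
    }
    tot
  }
  ours <- sop(unname(aln$seqs))
  # random valid alignments: pad each sequence with gaps at random positions
  L <- aln$length + 2L
  for (k in 1:20) {
    rows <- vapply(unname(seqs), function(s) {
      ch <- strsplit(s, "")[[1L]]
      pos <- sort(sample(L, length(ch)))
      row <- rep("-", L); row[pos] <- ch
      paste(row, collapse = "")
    }, character(1))
    expect_gte(ours, sop(rows))
  }
})

test_that("concatenate appends columns and preserves origins", {
  a1 <- msa(c(x = "MKTAY", y = "MKTAY"), origins = rep("f1", 5))
  a2 <- msa(c(y = "IAKQRQISFV", x = "IAKQRQISFV"), origins = rep("f2", 10))
  cc <- concatenate_alignments(list(a1, a2))
  expect_equal(cc$length, 15L)
  expect_equal(cc$origins, c(rep("f1", 5), rep("f2", 10)))
  expect_identical(concatenate_alignments(list(a1))$seqs, a1$seqs)
  a3 <- msa(c(x = "MK", z = "ML"))
  expect_error(concatenate_alignments(list(a1, a3)), "mismatch")
})

test_that("p-distance of a concatenation is the compared-column-weighted mean", {
  set.seed(73)
  mk <- function(len, d) {
    s <- random_protein(len)
    msa(c(x = s, y = mutate_sequence(s, d)))
  }
  parts <- list(mk(40, 0.1), mk(80, 0.3), mk(25, 0.05))
  cc <- concatenate_alignments(parts)
  p_all <- distance_matrix(cc, "p")["x", "y"]
  ps <- vapply(parts, function(a) distance_matrix(a, "p")["x", "y"], numeric(1))
  lens <- vapply(parts, `[[`, integer(1), "length")
  expect_equal(p_all, sum(ps * lens) / sum(lens))
})

test_that("distance_matrix matches closed forms and a column-counting oracle", {
  s <- paste(rep("A", 100), collapse = "")
  t100 <- paste(c(rep("R", 10), rep("A", 90)), collapse = "")
  aln <- msa(c(a = s, b = t100))
  expect_equal(distance_matrix(aln, "p")["a", "b"], 0.1)
  expect_equal(distance_matrix(aln, "poisson")["a", "b"], -log(0.9))

  set.seed(74)
  rows <- c(x = random_protein(60), y = random_protein(60), z = random_protein(60))
  # sprinkle gaps
  gapify <- function(s) {
    ch <- strsplit(s, "")[[1L]]
    ch[sample(60, 8)] <- "-"
    paste(ch, collapse = "")
  }
  rows <- vapply(rows, gapify, character(1))
  aln2 <- msa(rows)
  D <- distance_matrix(aln2, "p")
  mat <- do.call(rbind, strsplit(rows, ""))
  for (i in 1:2) for (j in (i + 1):3) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    expect_equal(D[i, j], sum(mat[i, ok] != mat[j, ok]) / sum(ok))
  }
  expect_equal(diag(D), stats::setNames(rep(0, 3), names(rows)))
})

test_that("nj_tree solves the three-taxon closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 3)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), ">= 3 taxa")
})

test_that("nj_tree recovers additive four-taxon trees exactly", {
  # known tree: ((A:1,B:2):1.5,(C:3,D:1):0 ...) encoded via its path metric
  tt <- ape::read.tree(text = "((A:1,B:2):1.5,C:3,D:1);")
  d <- ape::cophenetic.phylo(tt)
  tr <- nj_tree(d)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
  expect_equal(phangorn::RF.dist(ape::unroot(tt), ape::unroot(tr)), 0)
})

test_that("NJ topology equals UPGMA topology on ultrametric input", {
  tt <- ape::read.tree(text = "((A:1,B:1):2,(C:2.5,D:2.5):0.5);")
  d <- ape::cophenetic.phylo(tt)
  nj_ <- nj_tree(d)
  up <- upgma_tree(d)
  expect_equal(phangorn::RF.dist(ape::unroot(nj_), ape::unroot(up)), 0)
})

test_that("bootstrap supports saturate on clean signal and are byte-reproducible", {
  set.seed(75)
  base <- random_protein(120)
  # two clean clades: large divergence between groups, none within
  grp <- mutate_sequence(base, 0.5, seed = 8)
  aln <- msa(c(a1 = base, a2 = base, b1 = grp, b2 = grp))
  tr <- bootstrap_support(aln, model = "p", replicates = 50, seed = 4)
  expect_true(any(tr$node.label == "100"))

  tr2 <- bootstrap_support(aln, model = "p", replicates = 50, seed = 4)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))

  one <- bootstrap_support(aln, model = "p", replicates = 1, seed = 4)
  expect_true(all(one$node.label %in% c("0", "100")))
})

test_that("bootstrap supports are invariant to taxon input order", {
  set.seed(76)
  base <- random_protein(150)
  seqs <- c(a = base,
            b = mutate_sequence(base, 0.05, seed = 1),
            c = mutate_sequence(base, 0.4, seed = 2),
            d = mutate_sequence(base, 0.45, seed = 3))
  tr1 <- bootstrap_support(msa(seqs), replicates = 30, seed = 9)
  tr2 <- bootstrap_support(msa(seqs[c(3, 1, 4, 2)]), replicates = 30, seed = 9)
  key <- function(tr) {
    # supports keyed by the tip set of each internal edge's clade
    parts <- ape::prop.part(tr)
    lab <- attr(parts, "labels")
    stats::setNames(tr$node.label,
                    vapply(parts, function(p) paste(sort(lab[p]), collapse = ","),
                           character(1)))
  }
  expect_identical(sort(names(key(tr1))), sort(names(key(tr2))))
  expect_identical(key(tr1)[sort(names(key(tr1)))],
                   key(tr2)[sort(names(key(tr1)))])
})

test_that("core concatenation tree recovers the simulated topology", {
  sim <- get_sim5()
  fm <- get_sim5_fm()
  aln <- core_concat_alignment(sim$genes, fm)
  expect_setequal(aln$taxa, names(sim$genomes))
  tr <- nj_tree(distance_matrix(aln, "poisson"))
  expect_equal(phangorn::RF.dist(ape::unroot(sim$truth$true_tree),
                                 ape::unroot(tr)), 0)
})

test_that("Newick output round-trips", {
  tt <- ape::read.tree(text = "((A:1,B:2):1.5,C:3,D:1);")
  tf <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tt, tf)
  back <- ape::read.tree(tf)
  tf2 <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(back, tf2)
  expect_identical(readLines(tf), readLines(tf2))
})
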