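# Independent oracles and shared fixtures for the test suite.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A","C","G","T"), n, replace = TRUE,
               prob = c((1-gc)/2, gc/2, gc/2, (1-gc)/2)), collapse = "")
}

# Exhaustive Smith-Waterman with affine gaps (Gotoh), score only.
# Gap cost convention matches the implementation: length-L gap costs
# open + L * ext.
sw_score_oracle <- function(a, b, open = 10, ext = 1) {
  S <- get_blosum62()
  x <- strsplit(a, "")[[1L]]; y <- strsplit(b, "")[[1L]]
  n <- length(x); m <- length(y)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in x (horizontal)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in y (vertical)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - (open + ext), E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - (open + ext), F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + S[x[i - 1], y[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# union-find partition oracle over an explicit edge list
components_oracle <- function(vertices, edges_a, edges_b) {
  parent <- stats::setNames(vertices, vertices)
  find <- function(v) {
    while (parent[[v]] != v) v <- parent[[v]]
    v
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k]); rb <- find(edges_b[k])
    if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
  }
  roots <- vapply(vertices, find, character(1))
  split(vertices, roots)
}

# canonical form of a partition (list of member vectors) for set comparison
partition_key <- function(members) {
  sort(unname(vapply(members, function(m) paste(sort(m), collapse = ","),
                     character(1))))
}

# all permutations of 1..n by recursive insertion (independent of the
# package's enumeration)
perms_by_insertion <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms_by_insertion(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# the default synthetic genus and its clustering, computed once per session
shared <- local({
  cache <- new.env()
  function(name, build) {
    if (is.null(cache[[name]])) cache[[name]] <- build()
    cache[[name]]
  }
})

get_sim5 <- function() {
  shared("sim5", function() simulate_pangenome(sim_params(seed = 101L)))
}

get_sim5_fm <- function() {
  shared("sim5_fm", function() cluster_families(get_sim5()$genes))
}
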