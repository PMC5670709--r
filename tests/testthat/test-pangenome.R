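test_that("accumulate handles identical and disjoint genomes", {
  # identical genomes: pan = core = F everywhere
  m <- matrix(1L, 4, 7, dimnames = list(paste0("g", 1:4), paste0("f", 1:7)))
  curve <- accumulate(m, n_permutations = 10, seed = 1)
  expect_equal(curve$pan_mean, rep(7, 4))
  expect_equal(curve$core_mean, rep(7, 4))

  # disjoint family sets: pan(n) = n*F, core(n >= 2) = 0
  d <- kronecker(diag(3), matrix(1L, 1, 5))
  dimnames(d) <- list(paste0("g", 1:3), paste0("f", 1:15))
  cv <- accumulate(d, n_permutations = 6, seed = 1)
  expect_equal(cv$pan_mean, c(5, 10, 15))
  expect_equal(cv$core_mean, c(5, 0, 0))
})

test_that("pan is monotone non-decreasing and core non-increasing per permutation", {
  fm <- get_sim5_fm()
  curve <- accumulate(fm, n_permutations = 50, seed = 3)
  expect_true(all(apply(curve$pan_by_perm, 1, function(p) all(diff(p) >= 0))))
  expect_true(all(apply(curve$core_by_perm, 1, function(p) all(diff(p) <= 0))))
  expect_equal(curve$pan_by_perm[, 1], curve$core_by_perm[, 1])
  # endpoints are permutation-independent
  expect_equal(length(unique(curve$pan_by_perm[, 5])), 1L)
  expect_equal(length(unique(curve$core_by_perm[, 5])), 1L)
})

test_that("sampled means at G=5 equal exhaustive 120-permutation enumeration", {
  fm <- get_sim5_fm()
  curve <- accumulate(fm, n_permutations = 120, seed = 1)
  expect_true(curve$exhaustive)
  pres <- fm$counts > 0
  perms <- perms_by_insertion(5L)
  expect_equal(length(perms), 120L)
  pan_tot <- numeric(5); core_tot <- numeric(5); newg <- numeric(0)
  for (ord in perms) {
    pan_set <- rep(FALSE, ncol(pres)); core_set <- rep(TRUE, ncol(pres))
    pans <- numeric(5)
    for (n in 1:5) {
      pan_set <- pan_set | pres[ord[n], ]
      core_set <- core_set & pres[ord[n], ]
      pans[n] <- sum(pan_set)
      core_tot[n] <- core_tot[n] + sum(core_set)
    }
    pan_tot <- pan_tot + pans
    newg <- c(newg, (pans[5] - pans[1]) / 4)
  }
  expect_equal(curve$pan_mean, pan_tot / 120)
  expect_equal(curve$core_mean, core_tot / 120)
  expect_equal(curve$new_per_genome_mean, mean(newg))
})

test_that("fit_heaps is exact on exact power-law data and flat data", {
  curve <- list(n_values = 1:10, pan_mean = 100 * (1:10)^0.5)
  fit <- fit_heaps(curve)
  expect_equal(fit$kappa, 100, tolerance = 1e-10)
  expect_equal(fit$gamma, 0.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_true(fit$open_call)

  flat <- fit_heaps(list(n_values = 1:6, pan_mean = rep(250, 6)))
  expect_equal(flat$gamma, 0, tolerance = 1e-12)
  expect_false(flat$open_call)

  expect_error(fit_heaps(list(n_values = 1:2, pan_mean = c(1, 2))), "3 points")
  expect_error(fit_heaps(list(n_values = 1:3, pan_mean = c(1, 0, 2))), "positive")
})

test_that("fitted gamma agrees with an independent log-log regression oracle", {
  fm <- get_sim5_fm()
  curve <- accumulate(fm, n_permutations = 120, seed = 1)
  fit <- fit_heaps(curve)
  # oracle: closed-form OLS slope on (ln n, ln pan)
  xx <- log(curve$n_values); yy <- log(curve$pan_mean)
  slope <- sum((xx - mean(xx)) * (yy - mean(yy))) / sum((xx - mean(xx))^2)
  expect_lt(abs(fit$gamma - slope), 0.1)
  expect_equal(fit$gamma, slope, tolerance = 1e-10)
})

test_that("core and unique families follow the set definitions", {
  m <- matrix(c(1L, 1L, 1L, 0L), 2, 2,
              dimnames = list(c("g1", "g2"), c("f1", "f2")))
  expect_equal(core_families(m), "f1")
  u <- unique_families(m)
  expect_equal(u$g1, "f2")
  expect_equal(u$g2, character(0))

  ones <- matrix(1L, 3, 4, dimnames = list(paste0("g", 1:3), paste0("f", 1:4)))
  expect_equal(core_families(ones), paste0("f", 1:4))
  expect_true(all(lengths(unique_families(ones)) == 0))
})

test_that("core/unique match a set-algebra oracle on random matrices", {
  set.seed(55)
  m <- matrix(rbinom(6 * 50, 2, 0.4), 6, 50,
              dimnames = list(paste0("g", 1:6), sprintf("f%02d", 1:50)))
  core <- core_families(m)
  uniq <- unique_families(m)
  sets <- apply(m > 0, 2, which, simplify = FALSE)
  expect_setequal(core, names(sets)[lengths(sets) == 6])
  for (g in 1:6) {
    expect_setequal(uniq[[paste0("g", g)]],
                    names(sets)[lengths(sets) == 1 &
                                  vapply(sets, function(s) identical(unname(s), g),
                                         logical(1))])
  }
  # core and unique are disjoint; unique counts sum to support-1 columns
  expect_length(intersect(core, unlist(uniq)), 0)
  expect_equal(sum(lengths(uniq)), sum(colSums(m > 0) == 1))
})

test_that("core_fraction_percent reports one-decimal percentages", {
  expect_equal(unname(core_fraction_percent(643, c(a = 1861))), 34.6)
  expect_equal(unname(core_fraction_percent(643, c(b = 2684))), 24.0)
})
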