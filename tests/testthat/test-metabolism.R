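test_that("EC validation accepts dotted forms and partial fields", {
  expect_true(all(is_valid_ec(c("3.2.1.26", "2.7.1.199", "1.1.1.-", "3.2"))))
  expect_false(any(is_valid_ec(c("abc", "3..1.2", "EC", ""))))
  expect_equal(normalize_ec("EC 3.2.1.26"), "3.2.1.26")
  expect_error(ec_profile("g", "not-an-ec"), "invalid EC")
})

test_that("builtin rule table encodes the pathway logic", {
  rules <- load_rule_table()
  by_carb <- stats::setNames(rules, vapply(rules, `[[`, "", "carbohydrate"))
  raff <- by_carb$raffinose$expr
  expect_equal(raff$type, "and")
  expect_setequal(unlist(lapply(raff$args, `[[`, "ec")),
                  c("3.2.1.26", "3.2.1.22"))
  lact <- by_carb$lactose$expr
  expect_equal(lact$type, "or")
  expect_length(lact$args, 2L)
  # every EC referenced by the rules parses
  all_ecs <- unlist(lapply(rules, function(r) {
    regmatches(r$expr_text, gregexpr("[0-9][0-9.]*", r$expr_text))[[1L]]
  }))
  expect_true(all(is_valid_ec(all_ecs)))
})

test_that("custom rule files parse, and malformed ones fail with a line number", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("carbohydrate\trule",
               "maltose\t3.2.1.20 OR (2.4.1.8 AND 5.4.2.6)"), tf)
  rules <- load_rule_table(tf)
  expect_equal(rules[[1]]$carbohydrate, "maltose")
  expect_equal(rules[[1]]$expr$type, "or")

  writeLines(c("carbohydrate\trule", "bad\t3..1 AND 2.7.1.4"), tf)
  expect_error(load_rule_table(tf), "line 2")

  writeLines("carbohydrate\trule", tf)
  expect_error(load_rule_table(tf), "at least one")
})

test_that("predictions follow the rule expressions over the EC set", {
  rules <- load_rule_table()
  p1 <- predict_phenotypes(ec_profile("gA", c("3.2.1.26", "3.2.1.22")), rules)
  got <- stats::setNames(p1$predicted, p1$carbohydrate)
  expect_equal(got[["raffinose"]], "positive")
  expect_equal(got[["melibiose"]], "positive")
  expect_equal(got[["sucrose"]], "positive")
  expect_equal(got[["glucose"]], "negative")

  p2 <- predict_phenotypes(ec_profile("gB", "3.2.1.26"), rules)
  got2 <- stats::setNames(p2$predicted, p2$carbohydrate)
  expect_equal(got2[["sucrose"]], "positive")
  expect_equal(got2[["raffinose"]], "negative")
  expect_equal(got2[["melibiose"]], "negative")

  p3 <- predict_phenotypes(ec_profile("gC", character(0)), rules)
  expect_true(all(p3$predicted == "negative"))

  # lactose is satisfied by either route
  via_bgal <- predict_phenotypes(ec_profile("g1", "3.2.1.23"), rules)
  via_pts <- predict_phenotypes(ec_profile("g2", c("2.7.1.207", "3.2.1.85")), rules)
  expect_equal(via_bgal$predicted[via_bgal$carbohydrate == "lactose"], "positive")
  expect_equal(via_pts$predicted[via_pts$carbohydrate == "lactose"], "positive")
})

test_that("partial profile ECs never satisfy rules; adding ECs never flips positive->negative", {
  rules <- load_rule_table()
  partial <- predict_phenotypes(ec_profile("g", "3.2.1.-"), rules)
  expect_true(all(partial$predicted == "negative"))

  set.seed(81)
  universe <- carb_ec_universe()
  base_ecs <- sample(universe, 4)
  base <- predict_phenotypes(ec_profile("g", base_ecs), rules)
  more <- predict_phenotypes(
    ec_profile("g", c(base_ecs, sample(universe, 6))), rules)
  flipped <- base$predicted == "positive" & more$predicted == "negative"
  expect_false(any(flipped))
})

test_that("the packaged enzyme catalog matches its printed dialect", {
  cat28 <- carb_enzyme_catalog()
  expect_equal(nrow(cat28), 28L)
  expect_equal(sum(cat28$ec_number == "2.7.1.40"), 2L)  # pyruvate kinase twice
  expect_true(all(is_valid_ec(cat28$ec_number)))
})

test_that("phenotype tables validate symbols and the control row", {
  obs <- lactococcus_phenotypes()
  expect_equal(length(obs$genomes), 10L)
  expect_true(all(obs$values[tolower(obs$carbohydrates) == "control", ] == "-"))

  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("carbohydrate\tg1\tg2", "control\t-\t+", "ribose\t+\t-"), tf)
  expect_error(read_phenotype_table(tf), "control")
  writeLines(c("carbohydrate\tg1\tg2", "control\t-\t-", "ribose\t?\t-"), tf)
  expect_error(read_phenotype_table(tf), "symbols")
})

test_that("concordance flags the reported lactose discordances on the bundled tables", {
  rules <- load_rule_table()
  profs <- ec_profiles_from_table(lactococcus_ec_table())
  preds <- do.call(rbind, lapply(profs, predict_phenotypes, rules = rules))
  rep_ <- concordance(preds, lactococcus_phenotypes())

  lact <- rep_$cells[rep_$cells$carbohydrate == "D-Lactose" &
                       rep_$cells$status == "scored", ]
  disc <- lact$genome_id[!lact$match]
  expect_setequal(disc, c("JCM 16395", "DSM 21502"))
  # discordant direction: predicted negative, observed +
  expect_true(all(lact$predicted[!lact$match] == "negative"))
  expect_true(all(lact$observed[!lact$match] == "+"))

  # raffinose and melibiose are fully concordant: the trio and only the trio
  raff <- rep_$cells[rep_$cells$carbohydrate == "D-Raffinose" &
                       rep_$cells$status == "scored", ]
  expect_true(all(raff$match))
  expect_setequal(raff$genome_id[raff$predicted == "positive"],
                  c("DSM 21502", "DSM 6634", "ATCC 43920"))
  # carbohydrates without a rule are unscored, not errors
  expect_true("L-Arabinose" %in% rep_$unscored)
})

test_that("identical prediction and observation tables give 100% concordance", {
  obs <- lactococcus_phenotypes()
  preds <- do.call(rbind, lapply(seq_along(obs$genomes), function(gi) {
    data.frame(genome_id = obs$genomes[gi],
               carbohydrate = obs$carbohydrates,
               predicted = ifelse(obs$values[, gi] %in% c("+", "w"),
                                  "positive", "negative"),
               rule = "")
  }))
  rep_ <- concordance(preds, obs)
  expect_equal(rep_$concordance_percent, 100)
  expect_equal(rep_$n_discordant, 0L)
})

test_that("flipping the w policy changes only cells observed as w", {
  rules <- load_rule_table()
  profs <- ec_profiles_from_table(lactococcus_ec_table())
  preds <- do.call(rbind, lapply(profs, predict_phenotypes, rules = rules))
  obs <- lactococcus_phenotypes()
  pos <- concordance(preds, obs, w_policy = "positive")$cells
  neg <- concordance(preds, obs, w_policy = "negative")$cells
  same <- mapply(identical, pos$match, neg$match)
  expect_true(all(pos$observed[!same] == "w"))
  expect_gt(sum(!same), 0)  # the table does contain w cells under a rule
})

test_that("core_carb_summary counts qualifying core families", {
  # constructed fixture: 643 core families, genes of the first 38 mapped to
  # catalog ECs
  core_ids <- sprintf("core_%04d", 1:643)
  universe <- carb_ec_universe()
  gene_to_ec <- data.frame(gene_id = sprintf("gene_%04d", 1:38),
                           ec_number = rep_len(universe, 38))
  gene_to_family <- stats::setNames(core_ids[1:38], gene_to_ec$gene_id)
  s <- core_carb_summary(core_ids, gene_to_ec, gene_to_family)
  expect_equal(s$n_carb_core_families, 38L)
  expect_equal(s$percent_of_core, 5.9)

  none <- core_carb_summary(core_ids,
                            data.frame(gene_id = "g", ec_number = "9.9.9.9"),
                            stats::setNames("core_0001", "g"))
  expect_equal(none$n_carb_core_families, 0L)
  expect_equal(none$percent_of_core, 0)
})
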