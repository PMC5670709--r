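#!/usr/bin/env Rscript
# Carbohydrate phenotype prediction for the ten Lactococcus type strains from
# their enzyme inventories, scored against the bundled API 50 CH table.

suppressMessages(library(lactopan))

rules <- load_rule_table()
profs <- ec_profiles_from_table(lactococcus_ec_table())
preds <- do.call(rbind, lapply(profs, predict_phenotypes, rules = rules))
utils::write.table(preds, "results/phenotype_predictions.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

obs <- lactococcus_phenotypes()
rep_ <- concordance(preds, obs)
utils::write.table(rep_$cells, "results/concordance_cells.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(rep_)

disc <- rep_$cells[rep_$cells$status == "scored" & !rep_$cells$match, ]
message("Discordant cells (prediction vs assay):")
for (i in seq_len(nrow(disc))) {
  message(sprintf("  %s / %s: predicted %s, observed %s",
                  disc$genome_id[i], disc$carbohydrate[i],
                  disc$predicted[i], disc$observed[i]))
}

cat28 <- carb_enzyme_catalog()
message("Core glycolysis/PPP catalog: ", nrow(cat28), " enzyme entries")
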