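#' Validate an EC number string
#'
#' Accepts the dotted Enzyme Commission form with 1-4 fields, each numeric or
#' `-` (partial ECs). An optional leading "EC " prefix is tolerated and
#' stripped by [normalize_ec()].
#'
#' @param ec Character vector of EC strings (without prefix).
#' @return Logical vector.
#' @export
is_valid_ec <- function(ec) {
  grepl("^[0-9]+(\\.([0-9]+|-)){0,3}$", ec)
}

#' @rdname is_valid_ec
#' @export
normalize_ec <- function(ec) {
  trimws(sub("^EC\\s+", "", trimws(ec), ignore.case = TRUE))
}

# a fully specified EC has four numeric fields
is_full_ec <- function(ec) {
  grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", ec)
}

#' Per-genome enzyme inventory
#'
#' @param genome_id Genome label.
#' @param ec_numbers Character vector of EC numbers (with or without "EC "
#'   prefix); partial ECs are allowed but never satisfy prediction rules.
#' @param source Provenance string.
#' @return A list of class `ec_profile`.
#' @export
ec_profile <- function(genome_id, ec_numbers, source = "") {
  ecs <- unique(normalize_ec(ec_numbers))
  bad <- ecs[!is_valid_ec(ecs)]
  if (length(bad)) stop("invalid EC number(s): ", paste(bad, collapse = ", "))
  structure(list(genome_id = genome_id, ec_numbers = ecs, source = source),
            class = "ec_profile")
}

#' Read a gene-to-EC annotation table
#'
#' TSV with columns gene_id, genome_id, ec_number; comment lines start
#' with `#`.
#'
#' @param path TSV path.
#' @return data.frame(gene_id, genome_id, ec_number) with normalized ECs.
#' @export
read_ec_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "genome_id", "ec_number") %in% names(df)))
  df$ec_number <- normalize_ec(df$ec_number)
  bad <- unique(df$ec_number[!is_valid_ec(df$ec_number)])
  if (length(bad)) stop("invalid EC number(s) in ", path, ": ",
                        paste(bad, collapse = ", "))
  df
}

#' Split an annotation table into per-genome EC profiles
#'
#' @param ec_table data.frame from [read_ec_table()].
#' @return Named list of [ec_profile()]s.
#' @export
ec_profiles_from_table <- function(ec_table) {
  out <- lapply(split(ec_table, ec_table$genome_id), function(d) {
    ec_profile(d$genome_id[1L], d$ec_number, source = "annotation table")
  })
  out[order(names(out))]
}

# ---- rule expressions -------------------------------------------------------

rule_leaf <- function(ec) list(type = "ec", ec = ec)
rule_node <- function(op, args) list(type = op, args = args)

eval_rule_expr <- function(expr, ecs) {
  switch(expr$type,
         ec = expr$ec %in% ecs,
         and = all(vapply(expr$args, eval_rule_expr, logical(1), ecs = ecs)),
         or = any(vapply(expr$args, eval_rule_expr, logical(1), ecs = ecs)),
         stop("bad rule expression node: ", expr$type))
}

rule_expr_ecs <- function(expr) {
  if (expr$type == "ec") return(expr$ec)
  unlist(lapply(expr$args, rule_expr_ecs))
}

deparse_rule_expr <- function(expr) {
  if (expr$type == "ec") return(expr$ec)
  inner <- vapply(expr$args, function(a) {
    s <- deparse_rule_expr(a)
    if (a$type %in% c("and", "or")) paste0("(", s, ")") else s
  }, character(1))
  paste(inner, collapse = paste0(" ", toupper(expr$type), " "))
}

# recursive-descent parser for "EC [AND|OR] EC" expressions with parentheses;
# OR binds looser than AND
parse_rule_expr <- function(text, line = NA) {
  toks <- regmatches(text, gregexpr("\\(|\\)|AND|OR|[0-9][0-9.\\-]*", text,
                                    ignore.case = TRUE))[[1L]]
  if (length(toks) == 0L) stop("empty rule expression", at_line(line))
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else ""
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_or <- function() {
    args <- list(parse_and())
    while (toupper(peek()) == "OR") { take(); args <- c(args, list(parse_and())) }
    if (length(args) == 1L) args[[1L]] else rule_node("or", args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (toupper(peek()) == "AND") { take(); args <- c(args, list(parse_atom())) }
    if (length(args) == 1L) args[[1L]] else rule_node("and", args)
  }
  parse_atom <- function() {
    t <- take()
    if (t == "(") {
      e <- parse_or()
      if (take() != ")") stop("unbalanced parentheses", at_line(line))
      return(e)
    }
    ec <- normalize_ec(t)
    if (!is_valid_ec(ec)) stop("malformed EC '", t, "'", at_line(line))
    rule_leaf(ec)
  }
  e <- parse_or()
  if (pos <= length(toks)) stop("trailing tokens in rule", at_line(line))
  e
}

at_line <- function(line) if (is.na(line)) "" else paste0(" at line ", line)

carb_rule <- function(carbohydrate, expr_text, note = "") {
  list(carbohydrate = carbohydrate,
       expr = parse_rule_expr(expr_text),
       expr_text = expr_text,
       note = note)
}

#' Load the carbohydrate fermentation rule table
#'
#' The builtin table encodes the genotype-to-phenotype logic of the central
#' Lactococcus carbohydrate pathways: hexose entry into glycolysis
#' (fructokinase EC 2.7.1.4, PTS enzyme I EC 2.7.1.199, glucose-6-phosphate
#' isomerase EC 5.3.1.9), sucrose/raffinose/melibiose hydrolysis
#' (beta-fructofuranosidase EC 3.2.1.26, alpha-galactosidase EC 3.2.1.22),
#' the two lactose routes (beta-galactosidase EC 3.2.1.23, or the
#' phosphotransferase route EC 2.7.1.207 + 6-phospho-beta-galactosidase
#' EC 3.2.1.85), and ribokinase (EC 2.7.1.15) for ribose.
#'
#' A custom table is a TSV with columns `carbohydrate`, `rule` (an AND/OR
#' expression over EC numbers, parentheses allowed) and optional `note`.
#'
#' @param source `"builtin"` or a TSV path.
#' @return List of rules, each with `carbohydrate`, `expr`, `expr_text`,
#'   `note`.
#' @export
load_rule_table <- function(source = "builtin") {
  if (identical(source, "builtin")) {
    return(list(
      carb_rule("glucose", "2.7.1.4 AND 2.7.1.199 AND 5.3.1.9",
                "hexose kinase + PTS enzyme I + phosphoglucose isomerase feed glycolysis"),
      carb_rule("fructose", "2.7.1.4 AND 2.7.1.199 AND 5.3.1.9",
                "fructokinase route into glycolysis"),
      carb_rule("mannose", "2.7.1.4 AND 2.7.1.199 AND 5.3.1.9",
                "mannose enters via the fructose/mannose PTS route"),
      carb_rule("sucrose", "3.2.1.26",
                "beta-fructofuranosidase hydrolyzes sucrose"),
      carb_rule("melibiose", "3.2.1.22",
                "alpha-galactosidase hydrolyzes melibiose to glucose"),
      carb_rule("raffinose", "3.2.1.26 AND 3.2.1.22",
                "raffinose -> melibiose (beta-fructofuranosidase) -> glucose (alpha-galactosidase)"),
      carb_rule("lactose", "3.2.1.23 OR (2.7.1.207 AND 3.2.1.85)",
                "beta-galactosidase route, or PTS phosphorylation + 6-phospho-beta-galactosidase"),
      carb_rule("ribose", "2.7.1.15",
                "ribokinase activates ribose for the pentose phosphate pathway")))
  }
  lines_raw <- readLines(source)
  df <- utils::read.delim(text = lines_raw, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L || !all(c("carbohydrate", "rule") %in% names(df))) {
    stop("rule table ", source,
         " must have columns 'carbohydrate' and 'rule' and at least one rule")
  }
  lapply(seq_len(nrow(df)), function(i) {
    list(carbohydrate = df$carbohydrate[i],
         expr = parse_rule_expr(df$rule[i], line = i + 1L),
         expr_text = df$rule[i],
         note = if ("note" %in% names(df)) df$note[i] else "")
  })
}

#' Predict fermentation phenotypes from an enzyme inventory
#'
#' A carbohydrate is predicted positive iff its rule expression evaluates
#' true over the genome's EC set. Only fully specified (four-field) profile
#' ECs can satisfy a rule; partial ECs are ignored (conservative).
#'
#' @param profile An [ec_profile()].
#' @param rules Rule list from [load_rule_table()].
#' @return data.frame: genome_id, carbohydrate, predicted
#'   (`"positive"`/`"negative"`), rule.
#' @export
predict_phenotypes <- function(profile, rules = load_rule_table()) {
  stopifnot(inherits(profile, "ec_profile"))
  ecs <- profile$ec_numbers[is_full_ec(profile$ec_numbers)]
  data.frame(
    genome_id = profile$genome_id,
    carbohydrate = vapply(rules, `[[`, character(1), "carbohydrate"),
    predicted = vapply(rules, function(r) {
      if (eval_rule_expr(r$expr, ecs)) "positive" else "negative"
    }, character(1)),
    rule = vapply(rules, `[[`, character(1), "expr_text"),
    stringsAsFactors = FALSE)
}

#' Read an observed phenotype table (API 50 CH dialect)
#'
#' TSV with a `carbohydrate` column and one column per strain; cells in
#' `{+, -, w}` (`w` = weakly positive). The table must contain a `control`
#' row, and the control must be `-` for every strain.
#'
#' @param path TSV path.
#' @return A list of class `phenotype_table`: values (carbohydrate x genome
#'   character matrix), genomes, carbohydrates.
#' @export
read_phenotype_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  stopifnot(names(df)[1L] == "carbohydrate")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df$carbohydrate
  bad <- setdiff(unique(as.vector(vals)), c("+", "-", "w"))
  if (length(bad)) stop("phenotype symbols must be one of +, -, w; found: ",
                        paste(bad, collapse = ", "))
  ctrl <- which(tolower(rownames(vals)) == "control")
  if (length(ctrl) != 1L) stop("phenotype table must have one 'control' row")
  if (any(vals[ctrl, ] != "-")) {
    stop("control row must be '-' for every strain; offending: ",
         paste(colnames(vals)[vals[ctrl, ] != "-"], collapse = ", "))
  }
  structure(list(values = vals, genomes = colnames(vals),
                 carbohydrates = rownames(vals)),
            class = "phenotype_table")
}

#' Bundled API 50 CH phenotype table for the ten type strains
#'
#' @return A `phenotype_table`.
#' @export
lactococcus_phenotypes <- function() {
  read_phenotype_table(system.file("extdata", "api50_phenotypes.tsv",
                                   package = "lactopan", mustWork = TRUE))
}

#' Bundled core glycolysis/pentose-phosphate enzyme catalog
#'
#' The 28-entry catalog of key enzymes of glycolysis/gluconeogenesis and the
#' pentose phosphate pathway encoded by the Lactococcus core genome (one EC,
#' pyruvate kinase, appears twice, as printed in the source table).
#'
#' @return data.frame: no, ec_number, enzyme.
#' @export
carb_enzyme_catalog <- function() {
  df <- utils::read.delim(system.file("extdata",
                                      "core_glycolysis_ppp_enzymes.tsv",
                                      package = "lactopan", mustWork = TRUE),
                          stringsAsFactors = FALSE)
  df$ec_number <- normalize_ec(df$ec_number)
  df
}

#' The packaged carbohydrate-metabolism EC universe
#'
#' Union of the core glycolysis/PPP catalog ECs and every EC referenced by
#' the builtin fermentation rules.
#'
#' @return Character vector of EC numbers.
#' @export
carb_ec_universe <- function() {
  sort(unique(c(carb_enzyme_catalog()$ec_number,
                unlist(lapply(load_rule_table(), function(r) {
                  rule_expr_ecs(r$expr)
                })))))
}

# case-insensitive, punctuation-normalized carbohydrate name key; the
# D-/L- configuration prefix is dropped ("D-Glucose" -> "glucose")
normalize_carb_name <- function(x) {
  x <- tolower(trimws(x))
  x <- sub("^[dl]-", "", x)
  gsub("[^a-z0-9]", "", x)
}

#' Score predictions against an observed phenotype table
#'
#' Compares per-genome predictions with observations cell by cell. Genome and
#' carbohydrate names are reconciled case-insensitively with punctuation and
#' sugar configuration prefixes normalized. Observed `w` (weak) is treated as
#' positive by default. Discordance is data, not an error; carbohydrates with
#' no rule are reported as `unscored`.
#'
#' @param predictions data.frame rbind-ed from [predict_phenotypes()] over
#'   the genomes of interest.
#' @param observed A `phenotype_table`.
#' @param w_policy `"positive"` or `"negative"`: how observed `w` is scored.
#' @return A list of class `concordance_report`: cells (data.frame genome_id,
#'   carbohydrate, predicted, observed, match, status), n_scored,
#'   n_concordant, n_discordant, concordance_percent, unscored
#'   (carbohydrates without a rule).
#' @export
concordance <- function(predictions, observed,
                        w_policy = c("positive", "negative")) {
  w_policy <- match.arg(w_policy)
  stopifnot(inherits(observed, "phenotype_table"))
  pred_key_g <- tolower(gsub("[^a-zA-Z0-9]", "", predictions$genome_id))
  obs_key_g <- tolower(gsub("[^a-zA-Z0-9]", "", observed$genomes))
  pred_key_c <- normalize_carb_name(predictions$carbohydrate)
  obs_key_c <- normalize_carb_name(observed$carbohydrates)

  cells <- do.call(rbind, lapply(seq_along(observed$genomes), function(gi) {
    do.call(rbind, lapply(seq_along(observed$carbohydrates), function(ci) {
      obs_sym <- observed$values[ci, gi]
      hit <- which(pred_key_g == obs_key_g[gi] & pred_key_c == obs_key_c[ci])
      pred <- if (length(hit)) predictions$predicted[hit[1L]] else NA_character_
      obs_call <- if (obs_sym == "w") {
        if (w_policy == "positive") "positive" else "negative"
      } else if (obs_sym == "+") "positive" else "negative"
      data.frame(genome_id = observed$genomes[gi],
                 carbohydrate = observed$carbohydrates[ci],
                 predicted = pred, observed = obs_sym,
                 match = if (is.na(pred)) NA else pred == obs_call,
                 status = if (is.na(pred)) "unscored" else "scored",
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(cells) <- NULL
  scored <- cells[cells$status == "scored", ]
  structure(list(
    cells = cells,
    n_scored = nrow(scored),
    n_concordant = sum(scored$match),
    n_discordant = sum(!scored$match),
    concordance_percent = round(100 * mean(scored$match), 1),
    unscored = unique(cells$carbohydrate[cells$status == "unscored"]),
    w_policy = w_policy
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance: %d/%d scored cells match (%.1f%%); %d discordant; %d carbohydrate(s) unscored\n",
              x$n_concordant, x$n_scored, x$concordance_percent,
              x$n_discordant, length(x$unscored)))
  invisible(x)
}

#' Carbohydrate-metabolism share of the core genome
#'
#' Counts core families having at least one member gene annotated with a
#' carbohydrate-metabolism EC (the packaged catalog plus rule-table ECs, or a
#' caller-supplied universe), with the percentage of the core to one decimal
#' and a per-EC breakdown.
#'
#' @param core_family_ids Character vector of core family IDs.
#' @param gene_to_ec data.frame(gene_id, ec_number) (one row per annotation).
#' @param gene_to_family Named character vector gene_id -> family_id.
#' @param ec_universe Carbohydrate EC set; defaults to [carb_ec_universe()].
#' @return List: n_carb_core_families, percent_of_core, breakdown
#'   (data.frame ec_number, n_families).
#' @export
core_carb_summary <- function(core_family_ids, gene_to_ec, gene_to_family,
                              ec_universe = carb_ec_universe()) {
  gene_to_ec$ec_number <- normalize_ec(gene_to_ec$ec_number)
  carb <- gene_to_ec[gene_to_ec$ec_number %in% ec_universe, ]
  carb$family <- gene_to_family[carb$gene_id]
  carb <- carb[!is.na(carb$family) & carb$family %in% core_family_ids, ]
  qualifying <- unique(carb$family)
  breakdown <- if (nrow(carb)) {
    stats::aggregate(family ~ ec_number, carb,
                     function(f) length(unique(f)))
  } else {
    data.frame(ec_number = character(0), family = integer(0))
  }
  names(breakdown)[2L] <- "n_families"
  list(n_carb_core_families = length(qualifying),
       percent_of_core = round(100 * length(qualifying) /
                                 length(core_family_ids), 1),
       breakdown = breakdown)
}

#' Bundled gene-to-EC annotation for the ten type strains
#'
#' A curated reconstruction (synthetic gene IDs) of which strains carry the
#' fermentation-rule enzymes; see the package vignette for provenance.
#'
#' @return data.frame(gene_id, genome_id, ec_number).
#' @export
lactococcus_ec_table <- function() {
  read_ec_table(system.file("extdata", "lactococcus_ec_profiles.tsv",
                            package = "lactopan", mustWork = TRUE))
}
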