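---
title: "Methods: pan-genome, ANI, phylogeny and phenotype prediction in lactopan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome, ANI, phylogeny and phenotype prediction in lactopan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

lactopan implements a genus-level comparative-genomics workflow for
bacteria, organized around the ten *Lactococcus* type strains. This vignette
is the package's own account of the models and the numerical choices behind
each stage, what the synthetic-data generator does and does not emulate, and
the known limitations.

## Gene families

Two genes belong to the same family when their amino-acid identity is
strictly greater than 50% **and** the local alignment covers strictly more
than 50% of the *longer* sequence. Both inequalities are strict; the
boundary behavior (identity exactly 0.50 fails) is unit-tested. Families are
the connected components of the graph whose edges are passing pairs,
computed over all genes of all genomes in one pass. A two-stage procedure
(cluster within genomes, then merge across) can only create a subset of the
edges the global pass sees, so the global single-linkage partition contains
every two-stage merge while being independent of genome order; we adopt it
as the canonical normalization.

Several conventions are deliberate choices where the rule itself is silent:

* **Aligner and scoring.** Smith–Waterman with affine gaps via
  Biostrings, BLOSUM62, gap open 10, extend 1 (a gap of length L costs
  open + L·ext). The test suite checks the scores against an independent
  brute-force Gotoh implementation on random small proteins.
* **Identity denominator** = aligned columns of the local alignment,
  internal gap columns included, terminal overhangs excluded (PID1).
* **Coverage** = aligned span on the longer sequence divided by its full
  length, which directly encodes "the longer gene covered by the shorter".
* **No prefilter.** All-vs-all alignment is O(n²) but exact; a k-mer
  prefilter would have to be provably lossless above the 50% identity
  threshold to be admissible, and is not implemented.
* **Family ID** = lexicographically smallest member gene ID, making output
  deterministic and order-invariant.

## Pan- and core-genome dynamics

For an ordering of the G genomes, pan(n) is the number of distinct families
among the first n genomes and core(n) the number present in all n. Since no
canonical ordering exists, curves are averaged over orderings: sampled
permutations (default 100, seeded) or, whenever G! ≤ 5040 and the requested
count covers it, the exhaustive set, making the means exact (at G = 5 the
suite compares against an independent 120-permutation enumeration).

The pan curve is fitted with Heaps' law pan(n) = κ·nᵞ by ordinary least
squares on (ln n, ln pan). OLS on the log scale is deterministic and
closed-form; a nonlinear fit would weight large-n points differently but
changes γ by far less than the permutation noise at these scales. The
pan-genome is called *open* when γ > 0.05; the threshold is a reporting
convention (γ of exactly 0 means a closed, saturating gene pool) and is
exposed as a parameter. The mean number of new families per added genome is
reported as (pan(G) − pan(1))/(G − 1) averaged over orderings — a protocol
choice, since "new genes per genome" depends on the ordering convention.

## Average nucleotide identity

ANI follows the classical fragment-based procedure: the query genome is cut
into consecutive non-overlapping 1020-bp fragments (0-based, half-open;
terminal partials discarded; fragments >50% N discarded), each fragment is
locally aligned to the reference on both strands, and fragments reaching
≥30% identity over ≥70% of their length contribute their percent identity
to the mean. The pairwise value is the arithmetic mean of the two
directions; the species rule joins genomes at ANI strictly above 95% by
single linkage, and heatmaps are ordered by UPGMA on 100 − ANI.

The fragment constants (1020 bp, 30%/70%, match +2, mismatch −3, gap open
5, extend 2) are the standard ANIb constants; all are exposed in
`ani_params()` and echoed in output. The per-fragment alignment is
delegated to `blastn -task blastn` with exactly that scoring — the
conventional executor of this procedure — with dust masking off so that
identity reflects the sequence itself. Self-ANI = 100, strand-flip
invariance, and recovery of simulated divergence (5% mutation → ANI ≈ 95.0)
are asserted in the tests.

## Core-gene phylogeny

Families with exactly one member in every genome are selected (strict
single-copy rule: paralog-containing families are excluded outright rather
than pruned, because within-family copy choice would be arbitrary), aligned
per family, and concatenated in family-ID order.

* **Alignment** is center-star: the center maximizes the summed global
  pairwise score; every other sequence is merged through its pairwise
  global alignment to the center under "once a gap, always a gap". This is
  deterministic (ties broken by taxon ID) and optimal within a factor of 2
  of the sum-of-pairs optimum — sufficient for the low-divergence core
  families the stage consumes; it is not a general-purpose MSA replacement.
* **Distances** are p-distances over pairwise-deleted columns (per-pair
  compared-column counts, not complete deletion) with optional Poisson
  correction d = −ln(1 − p). Poisson is the default for trees: additive
  under the simulator's uniform-substitution model at these divergences.
* **Trees** are canonical neighbor-joining; negative branch lengths, which
  NJ can produce on non-additive input, are clamped to 0 with a message.
  Exactness on additive matrices and the three-taxon closed form are tested.
* **Bootstrap** resamples alignment columns with replacement, one RNG draw
  per replicate (so supports are invariant to taxon input order), rebuilds
  the NJ tree, and maps bipartition frequencies onto the full-data tree.
  Conventional replicate counts are 500 for concatenated core trees and
  1000 for single-gene (e.g. 16S) trees; the workflow scripts use 100,
  which is ample for the 5-taxon synthetic genus.

Inference is unrooted; display rooting on an outgroup is a presentation
step. Maximum-likelihood inference is out of scope by design — the
distance/NJ route is self-contained and testable, and on the synthetic
genus it recovers the generating topology exactly (Robinson–Foulds 0).

## Carbohydrate phenotype prediction

Each genome's EC inventory is evaluated against AND/OR rule expressions:
hexoses require the fructokinase/PTS/isomerase trio (EC 2.7.1.4, 2.7.1.199,
5.3.1.9); sucrose requires β-fructofuranosidase (EC 3.2.1.26); melibiose
α-galactosidase (EC 3.2.1.22); raffinose both; lactose either
β-galactosidase (EC 3.2.1.23) or the phosphotransferase route (EC 2.7.1.207
AND EC 3.2.1.85); ribose requires ribokinase (EC 2.7.1.15). Only fully
specified four-field profile ECs can satisfy a rule — partial ECs (e.g.
`3.2.1.-`) are treated as insufficient evidence. Predictions are therefore
monotone: adding enzymes can only flip negative → positive.

Observed API 50 CH tables use symbols `{+, −, w}`; the control row must be
all-negative or the table is rejected as corrupt. Weak acidification (`w`)
counts as positive by default, since weak fermentation is fermentation; the
policy is a flag, and flipping it provably changes only `w` cells.
Discordance between prediction and assay is first-class output, not an
error — on the bundled tables the two lactose discordances (strains
DSM 21502 and JCM 16395 ferment lactose without an annotated canonical
route) are exactly the biologically interesting cells, indicating an
unannotated alternative pathway. Carbohydrates without a rule (e.g.
L-arabinose, for which no pathway is present in any strain) are reported
"unscored" rather than force-predicted.

The bundled per-strain enzyme inventory
(`inst/extdata/lactococcus_ec_profiles.tsv`) is a curated reconstruction
from reported per-strain enzyme presence/absence statements, with synthetic
gene IDs; it is a fixture for exercising the concordance machinery, not a
re-derivable annotation.

## The synthetic genus

`simulate_pangenome()` generates the study conditions every stage is tested
under. Defaults: 5 genomes, 40 core families, a 30-family accessory pool
with presence probability 0.5 per genome, 5 private families per genome,
protein lengths ~ Normal(120, 25) truncated at 60 residues, within-family
protein divergence 0.2, genomic GC target 0.37, intergenic spacers
~ Poisson(100) nt. These are a deliberately reduced-scale image of a
ten-genome genus with an accessory-rich open pan-genome, small enough that
the exhaustive 120-permutation accumulation and the all-vs-all alignment
stay interactive while keeping every downstream property informative
(within-family identity ≈ 0.65, comfortably above the 0.5 rule; unrelated
families at background identity far below it).

Mechanics and their rationale:

* **Proteins first.** Each family has a random ancestral protein; the
  per-genome copy evolves along the generating tree by i.i.d. point
  substitution (uniform over the 19 alternative residues), with branch
  rates scaled so the mean root-to-tip divergence equals
  `within_family_divergence`. Evolving along the tree (rather than
  independently per genome) keeps the family partition exactly known while
  giving the concatenated core alignment genuine tree signal — the NJ
  topology check is a real test, not a tautology.
* **Nucleotide genomes** are GC-calibrated back-translations: synonymous
  codons are drawn with weights exp(θ·GC(codon)), θ solved by
  1-D root-finding so the expected genomic GC (coding + spacers) hits the
  target; the whole pan-sequence then evolves along the tree (branch length
  = substitution fraction), and each leaf genome keeps the segments of the
  families it carries. Expected observed identity between two leaves has
  the closed form 100·(1/4 + 3/4·∏(1 − 4b/3)) over the connecting path,
  which is stored as truth and compared against measured ANI (agreement
  within 1 percentage point is asserted).
* **The generating tree** defaults to a random topology with branch lengths
  Uniform(0.005, 0.03) drawn from the seed; a caller-supplied tree with
  branch lengths is accepted. A raw pairwise divergence matrix is *not*
  accepted: an arbitrary symmetric matrix need not be realizable by any
  tree, and the generator's guarantees (ANI truth, topology recovery) are
  tree-based.
* **Determinism.** All randomness flows from `sim_params$seed`; identical
  parameters give byte-identical FASTA and truth tables (tested).

What the simulator does *not* emulate — and hence what passing tests do not
show about real data: indels and rearrangements, horizontal transfer,
paralogy within genomes, codon-usage bias beyond GC, rate heterogeneity
across sites, and assembly artifacts (gaps, contamination). Real proteomes
also contain domain-sharing families for which the 50/50 rule and single
linkage can chain distinct functions together; the clustering tests certify
the implementation of the rule, not the biological adequacy of the rule.

## Problem sizes and degenerate inputs

The tests and the acceptance script run the synthetic genus at the default
scale above (~300 genes, ~30 kb genomes, 120 permutations, 100 bootstrap
replicates) plus a 100-kb genome for the ANI divergence checks; these sizes
were chosen so the full suite completes in about a minute while every
comparison retains statistical teeth. Degenerate inputs are first-class:
empty FASTA records, duplicate IDs, genomes with no A/C/G/T (GC undefined),
no positive-scoring alignment (explicit `no_hit`), fragments that are
mostly N, p = 1 under Poisson correction, taxon-set mismatches at
concatenation, missing ANI cells at demarcation, and malformed EC strings
all raise typed, named errors rather than propagating NA.

## Known limitations

* ANI requires the BLAST+ binaries on the PATH; there is no pure-R
  fallback, by design (a DP fallback at genome scale would be misleadingly
  slow rather than usable).
* Center-star alignment quality degrades for deeply diverged families;
  families near the 50% identity floor get conservative (gappy) alignments,
  which the pairwise-deletion distance absorbs but an ML user exporting the
  alignment should revisit.
* The open/closed pan-genome call is a threshold on a fitted exponent, not
  a model comparison; at G = 5 the exponent's sampling variability is
  visible (γ ≈ 0.26–0.29 across seeds on identical parameters).
* `core_fraction_percent` and the carbohydrate-core share are reported to
  one decimal, which is the resolution of the tables they are compared to.
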