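# lactopan

Comparative pan-genomics of a bacterial genus, built around the ten
*Lactococcus* type strains. The package implements, as tested R functions,
the full analysis chain used in genus-level genome surveys:

1. **Gene-family clustering** — all-vs-all Smith–Waterman comparison of
   predicted proteomes; two genes share a family when amino-acid identity is
   strictly >50% *and* the alignment covers strictly >50% of the longer
   sequence; families are the connected components (single linkage) of the
   resulting hit graph.
2. **Pan/core-genome dynamics** — accumulation curves pan(n) = |union| and
   core(n) = |intersection| over genome-addition orders, with a Heaps'
   power-law fit pan(n) = κ·nᵞ by ordinary least squares on (ln n, ln pan);
   γ > 0.05 calls the pan-genome open.
3. **Average nucleotide identity (ANI)** — Goris-style fragment ANI: 1020-bp
   query fragments locally aligned to the reference (blastn, both strands),
   fragments kept at ≥30% identity over ≥70% of their length, ANI = mean
   identity of kept fragments, symmetrized; single-linkage species clusters
   at ANI > 95% with UPGMA heatmap ordering.
4. **Core-gene phylogeny** — single-copy core families, center-star multiple
   alignment per family, concatenation, p/Poisson distances with pairwise
   gap deletion, neighbor-joining, and column-bootstrap supports.
5. **Carbohydrate phenotype prediction** — per-genome EC-number inventories
   evaluated against AND/OR pathway rules (e.g. raffinose ⇐ EC 3.2.1.26 AND
   EC 3.2.1.22; lactose ⇐ EC 3.2.1.23 OR (EC 2.7.1.207 AND EC 3.2.1.85)),
   scored cell-by-cell against an API 50 CH phenotype table.

A **synthetic pan-genome generator** (`simulate_pangenome()`) emits genomes,
proteomes and machine-readable ground truth (family partition, pan/core
counts, generating tree, expected pairwise identities), so every stage is
testable end-to-end without downloads. Bundled plain-text tables carry the
genomic features, core enzyme catalog, API 50 CH phenotypes and curated
enzyme inventories of the ten type strains.

## Worked example

```r
library(lactopan)

report <- run_pipeline(run_config(sim = sim_params(seed = 1L),
                                  permutations = 120L, bootstrap = 100L,
                                  seed = 1L))
print(report)
#> Pipeline run (seed 1): stages simulate, stats, families, pangenome, phylogeny, ani
#>   genomes 5 | pan 94 | core 42 | gamma 0.272 | ANI clusters 2
print(report$stages$pangenome$heaps)
#> Heaps fit: pan(n) = 60.42 * n^0.2719 (r^2 = 0.9996) -> open pan-genome
```

The simulated genus has 94 true gene families (42 core); clustering recovers
that partition exactly, the positive γ with r² ≈ 1 calls the pan-genome
open, and the NJ tree on the concatenated 42 single-copy core families
matches the generating tree (Robinson–Foulds distance 0; see
`analysis/05_phylogeny.R`).

On the bundled genus tables:

```r
tab <- lactococcus_genome_table()
summarize_genus(data.frame(genome_id = tab$strain, size_mb = tab$size_mb,
                           gc_percent = tab$gc_percent))
#> Genus summary over 10 genomes
#>   size: 1.99-2.61 Mb (mean 2.27; min DSM 20686, max DSM 21502)
#>   GC:   34.81-39.67% (mean 37.02; min DSM 20450, max ATCC 43920)
```

The mean genome size (2.27 Mb) and mean GC (37.02%) are the genus-level
descriptive statistics; `core_fraction_percent(643, ...)` gives the share of
each proteome in the 643-family core (24.0–34.6%).

## Analysis workflow

The numbered scripts under `analysis/` run the stages as a narrative
workflow on the synthetic genus, writing tables and figures under
`results/`:

```sh
Rscript analysis/01_simulate.R 1      # genus + ground truth
Rscript analysis/02_gene_families.R 1 # clustering vs truth
Rscript analysis/03_pangenome.R 1     # accumulation + Heaps fit
Rscript analysis/04_ani.R 1           # ANI matrix + species demarcation
Rscript analysis/05_phylogeny.R 1     # core NJ tree + bootstrap
Rscript analysis/06_metabolism.R      # phenotype prediction + concordance
```

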