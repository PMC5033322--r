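# specirc

Genome-scale species circumscription for groups of highly phylogenetically
related bacterial strains.

Tight species groups — sibling species sharing ≳ 99% 16S rRNA identity —
defeat single-marker barcoding, and public databases are full of strains
assigned to the wrong species as a result. `specirc` implements an
integrated whole-genome workflow for demarcating species in such groups and
for choosing the marker genes that separate them best:

1. **ANI correlation clustering** — fragment-based average nucleotide
   identity (ANIb: 1020-nt query fragments, retained at ≥ 30% identity over
   ≥ 70% coverage; ANI = mean identity of retained fragments), followed by
   Pearson correlation of the strains' ANI profiles and hierarchical
   clustering on `1 − r`. GBDP-style genome distances
   (`d0 = 1 − 2ΣL/(lq+ls)`, `d4 = 1 − Σid/ΣL`, `d6 = 1 − 2Σid/(lq+ls)`)
   are available for in-silico DDH workflows.
2. **Core-genome phylogenomics** — reciprocal-best-hit orthologs against a
   reference proteome (exact Smith–Waterman, BLOSUM62, e ≤ 1e-30), per-family
   alignment (MAFFT), concatenation, Gblocks-style conserved-block trimming,
   K80/JC69/p distances via `ape`, and neighbor-joining trees with column
   bootstrap.
3. **Function-repertoire clustering** — Markov-clustering orthogroups
   (e ≤ 1e-5), binary strain × function matrices, core/pan/private counts,
   UPGMA on Manhattan distances with bootstrap probabilities, and
   phylogenomic-vs-functional dendrogram comparison (cophenetic r, Baker's
   gamma, tanglegram entanglement) that surfaces **ecotype candidates**:
   strains whose repertoire placement departs from their core-genome
   placement.
4. **Random-forest marker ranking** — strains described by the G × O
   genetic distances between their core-gene copies and every reference
   organism's copies; a forest (100 000 trees, seed 12345 by default) is
   trained on labelled strains, genes are ranked by out-of-bag permutation
   importance, and per-gene forests measure each gene's stand-alone
   misclassification rate.
5. **Single-marker PCA classification** — PCA on the top marker's distance
   variables, per-species 95% confidence ellipses
   (`(x−μ)ᵀΣ⁻¹(x−μ) ≤ χ²₂(0.95)`), and **outclass detection**: a strain
   outside every ellipse signals a species not represented among the
   references.

A seeded clade simulator (`simulate_clade()`) generates synthetic strain
sets — species clusters with configurable within/between divergence,
per-gene rate heterogeneity, uneven radiations, gene gain/loss repertoires
and ecotype injection — so the entire pipeline is testable end to end with
no downloads.

## Worked example

```r
library(specirc)

cfg <- clade_sim_config(n_species = 3, strains_per_species = 3,
                        n_core_genes = 5, gene_length_range = c(330, 450),
                        within_species_divergence = 0.01,
                        between_species_divergence = 0.08,
                        n_filler_nt = 510, n_accessory_genes_per_species = 2,
                        seed = 7)
sim <- simulate_clade(cfg)
report <- run_pipeline(sim$strainset, pipeline_config(
  seed = 42, mlsa = list(n_boot = 30), repertoire = list(n_boot = 30),
  rank = list(n_trees = 300, per_gene = FALSE)))
print(report)
```

```
circumscription_report (seed 42 , config 63a61831 )
stages completed: ani, core, mlsa, repertoire, rank, classify 

ANI correlation clusters:
$`1`
[1] "sp01_01" "sp01_02" "sp01_03"

$`2`
[1] "sp02_01" "sp02_02" "sp02_03"

$`3`
[1] "sp03_01" "sp03_02" "sp03_03"


core genes: 5 
discordant (ecotype-candidate) strains: none 

test misclassification rate: 0 
top marker genes:
  rank gene       mean    variance   maximum  importance error_rate
1    1 g002 0.07784026 0.001761665 0.1155224 0.006574074         NA
2    2 g004 0.09744500 0.002850805 0.1439294 0.006327160         NA
3    3 g005 0.07443583 0.001659155 0.1150634 0.006018519         NA

marker: g002 
class_calls: 9 strains, 0 outclass, 0 ambiguous
   strain call ambiguous inside_n
1 sp01_01 sp01     FALSE        1
2 sp01_02 sp01     FALSE        1
3 sp01_03 sp01     FALSE        1
4 sp02_01 sp02     FALSE        1
5 sp02_02 sp02     FALSE        1
6 sp02_03 sp02     FALSE        1
7 sp03_01 sp03     FALSE        1
8 sp03_02 sp03     FALSE        1
9 sp03_03 sp03     FALSE        1
```

Reading the output: the three ANI correlation clusters recover the three
simulated species; the five shared gene families are core to every strain
(the species-private accessory genes are not); the functional dendrogram
agrees with the phylogenomic one (no ecotype candidates); the forest
classifies every held-out test strain correctly (misclassification 0);
gene `g002` ranks first by importance and is used as the PCA marker, under
which every strain falls inside its own species' 95% ellipse (no
outclasses). On real data, `load_strain_table()` +
`genome()` + `strain_set()` assemble the same input from FASTA assemblies,
CDS files and a strain metadata TSV (an example table for a 26-strain
*Bacillus pumilus*-group panel ships in `inst/extdata/bpumilus_strains.tsv`).

## Command line

A thin CLI wrapper ships in `inst/cli/specirc.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "specirc.R", package="specirc"))')" \
    simulate --out demo --seed 1
```
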