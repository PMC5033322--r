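---
title: "Genome-scale species circumscription: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-scale species circumscription: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specirc)
```

## The problem

Groups of very closely related bacterial species — sharing upwards of 99% 16S
rRNA identity — cannot be told apart by the usual single-marker barcodes, and
public genome databases consequently contain many misnamed strains. `specirc`
implements an integrated whole-genome workflow for demarcating species in
such groups: average nucleotide identity (ANI) with correlation clustering,
a core-gene phylogeny, clustering of encoded-function repertoires with
ecotype detection, random-forest ranking of core genes as phylogenetic
markers, and single-marker PCA classification with outclass detection. A
seeded clade simulator generates synthetic strain sets with known species
structure so that every stage of the pipeline can be validated end to end
without any external data.

## Fragment ANI (ANIb)

`compute_ani_pair()` follows the ANIb convention: the query genome is chopped
into consecutive 1020-nt fragments (a trailing fragment is kept when at
least half that length), each fragment is aligned against the subject
genome, and fragments are retained when their best hit reaches at least 30%
identity over at least 70% of the fragment. ANI is the mean identity of the
retained fragments; the aligned fraction is their summed length over the
query length. All three thresholds sit in `ani_params()`.

The built-in aligner is an exact semi-global dynamic program: the fragment
is aligned end to end while the subject contributes a free-floating window
(match +1, mismatch −1, linear gap −2; ambiguity codes never match). Two
consequences are worth noting:

* On indel-free genomes the optimal placement is the ungapped diagonal, so
  fragment identity equals the per-site match fraction exactly — this is
  what lets the test suite check the ANI engine against a direct per-site
  scan at 10⁻⁹ tolerance.
* Because the fragment is always fully aligned, the coverage filter is
  satisfied by construction, so retention additionally requires a positive
  alignment score. This plays the role that the coverage filter plays for
  local HSPs in BLAST-based ANIb: alignments of non-homologous sequence have
  strongly negative expected score and are discarded, rather than entering
  the mean with a meaningless gap-inflated "identity". An undefined ANI (no
  retained fragments) is reported as a flag, never as 0, since a silent 0
  would corrupt downstream profile correlations.

`correlation_clusters()` computes Pearson correlations between the strains'
directional ANI profiles (matrix rows, diagonal included) and orders or
partitions strains by hierarchical clustering on `1 − r` (complete linkage
by default; the linkage is configurable since published analyses rarely
state it). `gbdp_distances()` provides the genome-BLAST distance formulas
`d0`, `d4`, `d6` from the retained fragment alignments; the logistic mapping
from distance to a DNA–DNA-hybridization estimate is deliberately left to
the user (`ddh_estimate()` refuses to run without coefficients) because that
mapping is a fitted regression model maintained elsewhere, and shipping
stale coefficients would lend false authority.

## Core genes and the phylogenomic tree

Orthology is established at the protein level by reciprocal best hits
against a reference proteome (`reciprocal_best_hits()`,
`blast_core_genes()`), with a stringent e-value cutoff of 10⁻³⁰. The
built-in search is an exact Smith–Waterman with BLOSUM62 and affine gaps
(open 11, extend 1), with Karlin–Altschul-style bit scores and e-values
(gapped parameters λ = 0.267, K = 0.041, search space taken as the product
of sequence lengths). Exactness makes the search deterministic and
oracle-checkable; equivalence to any particular heuristic search tool is not
claimed. Ties between equal-scoring subjects are broken by bit score, then
e-value, then lexicographic subject id, so results are reproducible.
Families are kept only when every strain (including outgroups under the
default `scope = "all"`, which filters genes transferred horizontally after
speciation) carries an ortholog; nucleotide sequences are then pulled for
the distance stages, keeping distances nucleotide-based. With
`scope = "group"` the outgroup requirement is dropped; both modes exist
because published core definitions are often ambiguous on this point.

Families are aligned with MAFFT (`align_family()`; deterministic given its
inputs, with a `method = "none"` passthrough for pre-aligned input),
concatenated into a supermatrix with an explicit partition map, and trimmed
by a conserved-block procedure in the style of the classic Gblocks defaults:
with `n` taxa, a column is conserved at ⌊n/2⌋+1 identical residues and
highly conserved at ⌈0.85 n⌉; any-gap columns are removed, runs of more than
8 contiguous nonconserved columns are removed, blocks are trimmed to highly
conserved flanks, and blocks shorter than 10 columns are dropped. All four
thresholds are arguments.

Genetic distances (`genetic_distance()`) are computed with `ape::dist.dna`
under pairwise deletion; the default model is K80, with JC69 and the raw
p-distance selectable. K80 is the default of the distance function in the
package the workflow builds on, and pairwise deletion keeps per-gene
distances defined for partially trimmed families. Non-estimable distances
(logarithms of non-positive arguments at saturation) are flagged rather than
silently replaced. Tree inference (`nj_tree_with_bootstrap()`) is
distance-based neighbor joining with column-bootstrap supports; negative NJ
branch lengths are clamped to zero. Maximum-likelihood inference is
intentionally out of scope: the supermatrix and a RAxML-style partition file
can be exported (`write_phylip()`, `write_partitions()`) for an external ML
tool, keeping the package self-contained and deterministic.

## Function repertoires and ecotypes

`assign_orthogroups()` builds the all-vs-all protein similarity graph
(e ≤ 10⁻⁵, edge weight −log₁₀ e capped at 300, weights normalized per
strain pair by their mean) and partitions it by Markov clustering
(expansion, inflation 1.5, column renormalization to convergence). This
replaces a full OrthoMCL installation with the same graph-clustering core
and no external database; an annotated FASTA can be supplied as a best-hit
fallback for proteins that end up in no multi-member group, and the two
function namespaces are never merged — provenance tags (`orthogroup`,
`best_hit`, `singleton`) keep them apart, avoiding double counting.

The binary strain × function matrix feeds `function_set_counts()` (core,
pan and private counts per strain subset) and `cluster_repertoire()` —
Manhattan distance, which on binary profiles is the Hamming count, with
average-linkage (UPGMA) merging. Cluster supports are ordinary bootstrap
probabilities (the percentage of column-resampled replicates in which the
identical strain set reappears), not multiscale AU p-values: supports are
used descriptively here, and the multiscale machinery would add weight
without changing any decision the pipeline makes. This is a named
limitation.

`compare_dendrograms()` quantifies phylogenomic/functional agreement by the
cophenetic correlation, Baker's gamma (Spearman correlation of the depths of
each leaf pair's lowest common ancestor), and the tanglegram entanglement
after an alternating two-sided rotation heuristic (exact minimization is
NP-hard; the heuristic orders every node's children by the mean position of
their tips in the other tree and then keeps any single-node rotation that
strictly improves, repeated to convergence). Ecotype candidates are detected
as leaves whose k = 3 nearest-neighbour sets (by cophenetic distance, ties
broken by label for determinism) differ between the trees, ranked by
neighbourhood overlap: a strain whose function repertoire has drifted away
from its phylogenomic neighbours — through concerted gene loss and
horizontal acquisition — surfaces at the top of this list while its core-gene
placement is unchanged.

One caveat documented here because it shapes the tests: on noise-free
simulations the functional cophenetic distances take only two values
(0 within species, twice the accessory count between), while phylogenomic
patristic distances are continuous, so the cophenetic correlation of the
two dendrograms is necessarily slightly below 1 even at perfect structural
agreement. The tests therefore require near-perfect correlation (> 0.95)
plus exact cluster concordance instead of r = 1.

## Marker ranking by random forest

The feature construction mirrors the genome-scale marker-selection design:
for G core genes and O reference organisms, each strain is described by the
G × O genetic distances between its gene copies and every organism's copies
(109 genes × 26 organisms = 2834 variables at the published scale). A
random forest (the `randomForest` implementation of bagged CART with
majority vote) is trained on the training strains with out-of-bag
permutation importance; defaults follow the published settings — 100 000
trees, seed 12345, `mtry = ⌊√V⌋` — while the tests run scaled-down forests
of 1000 trees, a size at which the top-ranked gene is already stable in the
simulations used here. Gene-level importance aggregates the gene's O
per-variable importances; the aggregation (mean by default, sum and max
selectable) and the raw (unscaled) importance scale are recorded, since
published per-gene tables do not state either convention. Zero-variance
variables are withheld from the forest and assigned importance 0; a table
with no varying variable yields a majority-vote degenerate model (this also
protects against a `randomForest` hang on all-constant input). Per-gene
error rates retrain a fresh forest on each gene's O columns alone and score
it on the held-out test strains; `rank_genes()` orders by importance with
ties broken by lower error rate, then higher distance mean, then gene id.
Missing orthologs are never imputed — the affected strain's features are
flagged and per-gene prediction abstains — because imputed distances would
silently bias importance.

### The simulator's marker-ranking study design

The clade simulator (`simulate_clade()`) uses a star-within-star genealogy:
species ancestors diverge independently from a clade ancestor, strains from
their species ancestor, with i.i.d. per-site substitutions. This is
deliberately simpler than a coalescent — the pipeline's claims concern
recovery of discrete clusters, not branch lengths, and the star keeps truth
labels unambiguous and the per-site oracles exact (no indels by default;
substitutions are uniform over the three alternative bases). Species-level
random filler sequence makes whole-genome ANI distinct from core-gene
distance so both code paths are exercised. Defaults (1% within-species and
10% between-species divergence) reproduce the ANI bands seen in tight
species groups: ≳ 99% identity within a cluster and ≲ 90% between.

Three per-gene/per-species controls shape the marker-ranking experiments:

* `gene_rate_multipliers` scale a gene's overall substitution rate, from
  fast diagnostic genes down to ribosomal-protein-like near-invariant ones.
* `gene_species_signal` scales only the species-ancestor branches, so a
  gene can evolve (strain-level noise) while carrying little or no species
  signal. A single shared multiplier cannot express this: scaling a gene's
  rate scales its noise and its signal together, leaving the
  signal-to-noise ratio unchanged.
* `species_branch_scale` shortens selected species branches, producing an
  uneven radiation in which some species pairs are nearly identical —
  exactly the situation in real tight species groups, where a recently
  diverged pair is unresolvable by most loci.

The acceptance fixture for marker recovery uses 4 species × 4 strains
(3 train / 1 test per species), 900-nt genes, 1%/8% divergence, species 3
and 4 at branch scale 0.25, and a gene profile of one fast fully
informative diagnostic gene, eight slow genes with weak species signal
(0.2), and one near-invariant gene. The uneven radiation is what makes the
design identifiable: when every gene separates every species cleanly, CART
split gains saturate and permutation importances become statistically
indistinguishable — a flat-star design cannot make "the most diagnostic
gene ranks first" a stable property, whereas a close species pair that only
the diagnostic gene resolves makes that gene uniquely load-bearing. This
mirrors the scientific rationale for marker selection in the first place.
At 1000 trees the top rank reproduces in 17–18 of 20 independent
simulations (the residual flips are importance-estimation noise, which
vanishes with larger forests); the shipped tests fix the simulation seed.

What the simulator does not emulate — recombination, codon structure, indels,
rearrangement, uneven sampling, contamination — bounds what passing tests
show about real data: they validate the statistical machinery and its
contracts, not robustness to every artefact of real assemblies.

## Marker-gene PCA and outclass detection

`fit_marker_pca()` performs PCA on one marker gene's distance variables:
centred, unscaled (matching the default of the PCA routine the workflow
builds on; `scale.` is available), covariance eigendecomposition, and a
deterministic sign convention (each component's largest-magnitude loading is
made positive). The default refits the PCA jointly over references and new
strains, the published workflow's approach; projection onto a stored model
is available for streaming use. Variables default to distances to all
fitted strains (`variables = "all"`), with a references-only mode, because
published variable sets are ambiguous between the two; the choice is
stamped into the result.

Per-class 95% ellipses (`class_ellipses()`) are normal-theory χ²₂ contours
of each class's score covariance in PC1/PC2, defined only for classes with
at least 3 members (smaller classes are reported, not silently dropped);
a singular covariance receives a 10⁻⁹ ridge with a warning. A strain inside
no ellipse is an **outclass** — the signature of a species not represented
among the references; a strain inside several ellipses is called by
Mahalanobis distance and flagged ambiguous rather than silently resolved,
since the call there genuinely depends on the confidence level.

## Pipeline, reproducibility and scale

`run_pipeline()` executes the stages in dependency order, records stage
failures without aborting the bundle, skips dependents of a failed stage,
and stamps the report with the seed and a hash of the effective
configuration. The configuration (`pipeline_config()`) carries every
threshold above; it round-trips through YAML (`write_pipeline_config()` /
`read_pipeline_config()`) — YAML rather than another markup because it is
the configuration format the surrounding R toolchain already supports. All
stochastic stages (bootstraps, forests) derive their seeds from the master
seed, so a rerun with the same configuration is reproducible; the forest
seed itself defaults to the published 12345.

Problem sizes in the shipped tests are chosen for a laptop-class run:
genomes of a few kilobases over 6–16 strains, 5–10 core genes, forests of
1000 trees, bootstraps of 50–200 replicates, 20-seed replication loops for
the stochastic claims, and the 109 × 26 feature-construction check at its
full published width (2834 variables) but with short synthetic genes. The
statistical contracts being tested are size-invariant; the sizes only set
the precision of the stochastic checks.

## Known limitations

* ANI's built-in aligner is exact but quadratic; genome-scale inputs beyond
  a few hundred kilobases per strain call for the external BLAST adapter
  pattern rather than the built-in engine.
* Bootstrap supports on repertoire dendrograms are plain BP, not AU values.
* The MCL orthogrouping operates on a dense similarity matrix — appropriate
  for hundreds to a few thousand proteins, not for full pan-genome graphs.
* No indel model by default in the simulator; the per-site oracles rely on
  collinearity.
* The distance→DDH logistic mapping ships without coefficients by design.
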