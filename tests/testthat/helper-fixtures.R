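# Shared fixtures and independent oracles used across the suite.

# small clade used by several module tests (no filler keeps ANI == core)
small_clade <- function(seed = 7, filler = 600) {
  clade_sim_config(
    n_species = 3, strains_per_species = 3, n_core_genes = 6,
    gene_length_range = c(300, 450), within_species_divergence = 0.01,
    between_species_divergence = 0.08, n_filler_nt = filler, seed = seed)
}

# per-site identity between equal-length sequences (ambiguity = mismatch):
# direct R scan, independent of the C++ aligner
per_site_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  ok <- va %in% c("A", "C", "G", "T") & va == vb
  sum(ok) / length(va)
}

# naive UPGMA (average linkage) from a distance matrix; returns the merge
# heights as a cophenetic matrix -- brute-force oracle for hclust/average
naive_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  labels <- rownames(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, length(clusters))
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  dm <- d
  repeat {
    idx <- which(active)
    if (length(idx) < 2) break
    best <- c(NA, NA); best_d <- Inf
    for (i in idx) for (j in idx) {
      if (i < j && dm[i, j] < best_d) { best_d <- dm[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- best_d; coph[b, a] <- best_d
    }
    # average linkage update (weighted by cluster sizes = Lance-Williams UPGMA)
    ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
    for (k in idx) {
      if (k == i || k == j) next
      dm[i, k] <- (ni * dm[i, k] + nj * dm[j, k]) / (ni + nj)
      dm[k, i] <- dm[i, k]
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    active[j] <- FALSE
  }
  coph
}

# simulate a single marker-gene family over reference species plus queries
# from one unrepresented species (for the PCA outclass tests)
sim_marker_family <- function(seed, n_ref_species = 2, strains_per = 6,
                              n_query = 2, gene_len = 900,
                              sp_div = 0.04, strain_div = 0.005) {
  set.seed(seed)
  anc <- specirc:::random_gene(gene_len)
  fam <- character(); labs <- character(); queries <- character()
  for (i in seq_len(n_ref_species)) {
    spg <- specirc:::mutate_seq(anc, sp_div)
    for (j in seq_len(strains_per)) {
      id <- sprintf("sp%02d_%02d", i, j)
      fam[id] <- specirc:::mutate_seq(spg, strain_div)
      labs[id] <- sprintf("sp%02d", i)
    }
  }
  spg <- specirc:::mutate_seq(anc, sp_div)
  for (j in seq_len(n_query)) {
    id <- sprintf("novel_%02d", j)
    fam[id] <- specirc:::mutate_seq(spg, strain_div)
    queries <- c(queries, id)
  }
  list(family = fam, labels = labs, queries = queries)
}

# the marker-ranking study fixture: uneven radiation with one fast
# diagnostic gene, eight slow partially informative genes and one
# near-invariant (ribosomal-protein-like) gene
marker_rank_fixture <- function(seed = 1) {
  cfg <- clade_sim_config(
    n_species = 4, strains_per_species = 4, n_core_genes = 10,
    gene_length_range = c(900, 900), within_species_divergence = 0.01,
    between_species_divergence = 0.08,
    gene_rate_multipliers = c(1, rep(1, 8), 0.001),
    gene_species_signal = c(1, rep(0.2, 8), 1),
    species_branch_scale = c(1, 1, 0.25, 0.25),
    n_filler_nt = 0, seed = seed)
  sim <- simulate_clade(cfg)
  set <- sim$strainset
  core <- blast_core_genes(set$genomes[[1]], set)
  ft <- build_feature_table(core, align = TRUE)
  labels <- setNames(set$strains$species, set$strains$id)
  ids <- set$strains$id
  train <- ids[grepl("_0[1-3]$", ids)]  # 3 of 4 strains per species train
  list(sim = sim, core = core, ft = ft, labels = labels,
       train = train, test = setdiff(ids, train))
}
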