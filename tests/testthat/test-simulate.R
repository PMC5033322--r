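test_that("zero within-species divergence gives identical strain genomes", {
  cfg <- clade_sim_config(n_species = 2, strains_per_species = 2,
                          n_core_genes = 4, gene_length_range = c(150, 300),
                          within_species_divergence = 0,
                          between_species_divergence = 0.08,
                          n_filler_nt = 200, seed = 3)
  sim <- simulate_clade(cfg)
  g <- sim$strainset$genomes
  expect_identical(g[["sp01_01"]]$contigs, g[["sp01_02"]]$contigs)
  expect_identical(g[["sp02_01"]]$contigs, g[["sp02_02"]]$contigs)
  expect_false(identical(g[["sp01_01"]]$contigs, g[["sp02_01"]]$contigs))
})

test_that("the simulator is deterministic under its seed", {
  cfg <- small_clade(seed = 12)
  a <- simulate_clade(cfg)
  b <- simulate_clade(cfg)
  expect_identical(a$strainset, b$strainset)
  expect_identical(a$genes, b$genes)
})

test_that("within-species identity exceeds between-species identity", {
  cfg <- clade_sim_config(n_species = 3, strains_per_species = 2,
                          n_core_genes = 5, gene_length_range = c(300, 500),
                          within_species_divergence = 0.01,
                          between_species_divergence = 0.08,
                          n_filler_nt = 0, seed = 21)
  sim <- simulate_clade(cfg)
  contigs <- vapply(sim$strainset$genomes, function(g) g$contigs[[1]],
                    character(1))
  sp <- setNames(sim$truth$species, sim$truth$id)
  ids <- names(contigs)
  within <- c(); between <- c()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    idy <- per_site_identity(contigs[[i]], contigs[[j]])
    if (sp[ids[i]] == sp[ids[j]]) within <- c(within, idy)
    else between <- c(between, idy)
  }
  expect_gt(min(within), max(between))
})

test_that("between-species ANI decreases monotonically with divergence", {
  means <- vapply(c(0.03, 0.06, 0.10), function(div) {
    cfg <- clade_sim_config(n_species = 2, strains_per_species = 2,
                            n_core_genes = 4, gene_length_range = c(450, 600),
                            within_species_divergence = 0.005,
                            between_species_divergence = div,
                            n_filler_nt = 0, seed = 31)
    sim <- simulate_clade(cfg)
    g <- sim$strainset$genomes
    mean(c(compute_ani_pair(g[["sp01_01"]], g[["sp02_01"]])$ani,
           compute_ani_pair(g[["sp02_01"]], g[["sp01_01"]])$ani))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("gene rate multipliers drive pairwise distance ranks", {
  G <- 20
  mult <- exp(seq(log(0.05), log(2), length.out = G))
  cfg <- clade_sim_config(n_species = 3, strains_per_species = 2,
                          n_core_genes = G, gene_length_range = c(600, 600),
                          within_species_divergence = 0.01,
                          between_species_divergence = 0.08,
                          gene_rate_multipliers = mult,
                          n_filler_nt = 0, seed = 41)
  sim <- simulate_clade(cfg)
  genomes <- sim$strainset$genomes
  mean_p <- vapply(sprintf("g%03d", seq_len(G)), function(gid) {
    seqs <- vapply(genomes, function(g) g$cds$nuc[g$cds$gene_id == gid],
                   character(1))
    pairs <- combn(length(seqs), 2)
    mean(vapply(seq_len(ncol(pairs)), function(k)
      1 - per_site_identity(seqs[[pairs[1, k]]], seqs[[pairs[2, k]]]),
      numeric(1)))
  }, numeric(1))
  expect_gt(cor(mean_p, mult, method = "spearman"), 0.9)
})

test_that("mutate_single_gene_copy hits the expected substitution load", {
  gene <- specirc:::random_gene(999)
  expect_identical(mutate_single_gene_copy(gene, 0, seed = 1), gene)
  m1 <- mutate_single_gene_copy(gene, 0.1, seed = 5)
  m2 <- mutate_single_gene_copy(gene, 0.1, seed = 5)
  expect_identical(m1, m2)
  expect_equal(nchar(m1), nchar(gene))
  n_changed <- round((1 - per_site_identity(gene, m1)) * nchar(gene))
  # binomial(999, 0.1): allow 4 sd
  expect_lt(abs(n_changed - 99.9), 4 * sqrt(999 * 0.1 * 0.9))
})

test_that("function matrix has the stated block structure and ecotype edits", {
  labs <- setNames(rep(c("spA", "spB"), each = 4),
                   paste0(rep(c("a", "b"), each = 4), 1:4))
  cfg <- clade_sim_config(n_species = 2, strains_per_species = 4,
                          n_core_genes = 2,
                          n_accessory_functions_per_species = 30,
                          repertoire_noise = 0, seed = 9)
  m <- simulate_function_matrix(labs, n_core_functions = 50, cfg)
  expect_true(all(rowSums(m) == 50 + 30))
  expect_equal(sum(dist(m[names(labs)[labs == "spA"], ],
                        method = "manhattan")), 0)

  cfg_e <- clade_sim_config(n_species = 2, strains_per_species = 4,
                            n_core_genes = 2,
                            n_accessory_functions_per_species = 30,
                            repertoire_noise = 0,
                            ecotype_spec = list(strain = "a2", n_lost = 171,
                                                n_gained = 28), seed = 9)
  me <- simulate_function_matrix(labs, n_core_functions = 400, cfg_e)
  expect_equal(sum(me["a2", ] != me["a1", ]), 199L)

  cfg_bad <- clade_sim_config(n_species = 2, strains_per_species = 4,
                              n_core_genes = 2,
                              ecotype_spec = list(strain = "zz", n_lost = 1,
                                                  n_gained = 1), seed = 9)
  expect_error(simulate_function_matrix(labs, 10, cfg_bad), "zz")
})

test_that("config validation enforces divergence ordering and sizes", {
  expect_error(clade_sim_config(n_species = 1), "n_species")
  expect_error(clade_sim_config(within_species_divergence = 0.1,
                                between_species_divergence = 0.05),
               "within < between")
  expect_error(clade_sim_config(n_core_genes = 3,
                                gene_rate_multipliers = c(1, -1, 1)),
               "positive")
})
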