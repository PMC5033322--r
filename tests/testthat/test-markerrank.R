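test_that("feature tables have exactly G x O columns with zero self-distance", {
  # property over random G, O on synthetic aligned families
  set.seed(14)
  for (k in 1:3) {
    G <- sample(2:6, 1); O <- sample(3:7, 1)
    orgs <- sprintf("o%02d", seq_len(O))
    fams <- lapply(seq_len(G), function(g) {
      anc <- specirc:::random_gene(240)
      setNames(vapply(orgs, function(o) specirc:::mutate_seq(anc, 0.05),
                      character(1)), orgs)
    })
    names(fams) <- sprintf("g%03d", seq_len(G))
    ft <- build_feature_table(fams, model = "p")
    expect_equal(ncol(ft), G * O)
    expect_equal(nrow(ft), O)
    for (o in orgs)
      expect_true(all(ft[o, paste(names(fams), o, sep = "|")] == 0))
  }
})

test_that("hand-computed p-distances fill a 2x3 toy feature table", {
  f1 <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAC", c = "AACCAAAAAA")
  f2 <- c(a = "GGGGGGGGGG", b = "GGGGGGGGGG", c = "TTTTTGGGGG")
  ft <- build_feature_table(list(g1 = f1, g2 = f2), model = "p")
  expect_equal(ncol(ft), 6L)
  expect_equal(unname(ft["a", "g1|b"]), 0.1)
  expect_equal(unname(ft["b", "g1|c"]), 0.3)
  expect_equal(unname(ft["a", "g2|c"]), 0.5)
  expect_equal(unname(ft["a", "g2|b"]), 0)
})

test_that("gene distance statistics use all unordered pairs", {
  f <- c(x = "AAAAAAAAAA", y = "AAAAAAAAAC", z = "CCCCAAAAAA")
  # pairwise p-distances: xy = 0.1, xz = 0.4, yz = 0.5
  st <- gene_distance_stats(list(g1 = f), model = "p")
  vals <- c(0.1, 0.4, 0.5)
  expect_equal(st$mean, mean(vals))
  expect_equal(st$maximum, max(vals))
  expect_equal(st$variance, var(vals))  # sample variance over the 3 pairs

  ident <- c(x = "ACGT", y = "ACGT", z = "ACGT")
  st0 <- gene_distance_stats(list(g1 = ident), model = "p")
  expect_equal(unlist(st0[c("mean", "variance", "maximum")],
                      use.names = FALSE), c(0, 0, 0))
})

test_that("forests are deterministic under seed and reject bad input", {
  fx <- marker_rank_fixture(seed = 1)
  f1 <- train_species_forest(fx$ft, fx$labels, fx$train, n_trees = 200,
                             seed = 99)
  f2 <- train_species_forest(fx$ft, fx$labels, fx$train, n_trees = 200,
                             seed = 99)
  expect_identical(f1$var_importance, f2$var_importance)
  one_class <- fx$labels
  one_class[] <- "same"
  expect_error(train_species_forest(fx$ft, one_class, fx$train,
                                    n_trees = 10), "single class")
  expect_error(evaluate_forest(f1, fx$ft, character(), fx$labels), "empty")
})

test_that("the diagnostic gene dominates importance; noise genes do not", {
  # one perfectly diagnostic gene, nine genes with no species signal
  hits <- 0L
  for (sd in 1:20) {
    cfg <- clade_sim_config(
      n_species = 4, strains_per_species = 4, n_core_genes = 10,
      gene_length_range = c(600, 600), within_species_divergence = 0.01,
      between_species_divergence = 0.08,
      gene_rate_multipliers = rep(1, 10),
      gene_species_signal = c(1, rep(0, 9)),
      n_filler_nt = 0, seed = sd)
    sim <- simulate_clade(cfg)
    fams <- lapply(sim$strainset$genomes[[1]]$cds$gene_id, function(gid)
      vapply(sim$strainset$genomes, function(g)
        g$cds$nuc[g$cds$gene_id == gid], character(1)))
    names(fams) <- sim$strainset$genomes[[1]]$cds$gene_id
    ft <- build_feature_table(fams, model = "K80")
    labels <- setNames(sim$truth$species, sim$truth$id)
    train <- sim$strainset$strains$id[sim$strainset$strains$role == "train"]
    f <- train_species_forest(ft, labels, train, n_trees = 500, seed = 12345)
    hits <- hits + (names(which.max(f$gene_importance)) == "g001")
  }
  expect_gte(hits, 19L)
})

test_that("permuted labels produce no systematic importance signal", {
  fx <- marker_rank_fixture(seed = 2)
  set.seed(77)
  diag_imp <- vapply(1:8, function(i) {
    shuffled <- setNames(sample(fx$labels), names(fx$labels))
    f <- train_species_forest(fx$ft, shuffled, fx$train, n_trees = 300,
                              seed = 1000 + i)
    unname(f$gene_importance["g001"])
  }, numeric(1))
  # sign test: under the null, positives ~ Binomial(8, 1/2); 8/8 positive
  # would be evidence of residual signal
  expect_lt(sum(diag_imp > 0), 8L)
  expect_lt(mean(abs(diag_imp)), 0.05)
})

test_that("single-gene forests separate diagnostic from chance-level genes", {
  fx <- marker_rank_fixture(seed = 1)
  rates <- per_gene_error_rates(fx$ft, fx$labels, fx$train, fx$test,
                                n_trees = 500, seed = 12345)
  expect_true(all(rates$error_rate >= 0 & rates$error_rate <= 1))
  expect_equal(rates$error_rate[rates$gene == "g001"], 0)
  # the near-invariant gene predicts at chance level (majority vote over
  # 4 balanced classes: 3 of 4 test strains wrong)
  expect_gte(rates$error_rate[rates$gene == "g010"], 0.5)
})

test_that("gene ranking orders by importance with the stated tie-breaks", {
  st <- data.frame(gene = c("a", "b", "c", "d"),
                   mean = c(0.1, 0.3, 0.2, 0.2),
                   variance = c(0, 0, 0, 0),
                   maximum = c(0.2, 0.5, 0.4, 0.4))
  imp <- c(a = 0.5, b = 0.5, c = 0.5, d = 0.9)
  er <- data.frame(gene = c("a", "b", "c", "d"),
                   error_rate = c(0.2, 0.1, 0.1, 0))
  rk <- rank_genes(st, imp, er)
  # d first on importance; b and c tie on importance and error,
  # broken by higher mean (b); a last on higher error
  expect_equal(rk$gene, c("d", "b", "c", "a"))
  expect_equal(rk$rank, 1:4)
})

test_that("importance tracks true gene diagnosticity on a rate spread", {
  cfg <- clade_sim_config(
    n_species = 4, strains_per_species = 4, n_core_genes = 8,
    gene_length_range = c(600, 600), within_species_divergence = 0.01,
    between_species_divergence = 0.08,
    gene_rate_multipliers = rep(1, 8),
    gene_species_signal = c(1, 0.8, 0.6, 0.45, 0.3, 0.2, 0.1, 0),
    n_filler_nt = 0, seed = 3)
  sim <- simulate_clade(cfg)
  fams <- lapply(sim$strainset$genomes[[1]]$cds$gene_id, function(gid)
    vapply(sim$strainset$genomes, function(g)
      g$cds$nuc[g$cds$gene_id == gid], character(1)))
  names(fams) <- sim$strainset$genomes[[1]]$cds$gene_id
  ft <- build_feature_table(fams, model = "K80")
  labels <- setNames(sim$truth$species, sim$truth$id)
  train <- sim$strainset$strains$id[sim$strainset$strains$role == "train"]
  f <- train_species_forest(ft, labels, train, n_trees = 1000, seed = 12345)
  truth_rank <- sim$genes$diagnosticity_rank
  got_rank <- rank(-f$gene_importance[sim$genes$gene_id])
  expect_gt(cor(truth_rank, got_rank, method = "spearman"), 0.8)
})
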