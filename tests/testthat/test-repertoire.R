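sim_proteomes <- function(seed = 3, n_strains = 4, n_genes = 6,
                          divergence = 0.06, private = TRUE) {
  set.seed(seed)
  anc_nuc <- vapply(rep(300, n_genes), specirc:::random_gene, character(1))
  out <- list()
  for (s in seq_len(n_strains)) {
    nuc <- vapply(anc_nuc, specirc:::mutate_seq, character(1),
                  divergence = divergence)
    prots <- translate_cds(nuc)
    names(prots) <- sprintf("g%02d", seq_len(n_genes))
    if (private && s == 1) {
      extra <- translate_cds(specirc:::random_gene(300))
      prots <- c(prots, setNames(extra, "priv1"))
    }
    out[[sprintf("s%02d", s)]] <- prots
  }
  out
}

test_that("orthogroups recover simulated families exactly", {
  prots <- sim_proteomes(seed = 3)
  og <- assign_orthogroups(prots)
  grp_of <- setNames(og$group, og$protein_id)
  for (g in sprintf("g%02d", 1:6)) {
    members <- paste(names(prots), g, sep = "|")
    expect_equal(length(unique(grp_of[members])), 1L)
  }
  sizes <- table(og$group)
  expect_equal(sort(unname(as.integer(sizes)), decreasing = TRUE),
               c(rep(4L, 6), 1L))  # six 4-strain families + one private
})

test_that("orthogroup partition is invariant to proteome order", {
  prots <- sim_proteomes(seed = 8)
  og1 <- assign_orthogroups(prots)
  og2 <- assign_orthogroups(rev(prots))
  part <- function(og) {
    key <- split(og$protein_id, og$group)
    sort(vapply(key, function(p) paste(sort(p), collapse = ";"), character(1)))
  }
  expect_identical(unname(part(og1)), unname(part(og2)))
})

test_that("unrelated protein sets form no cross-set groups", {
  a <- sim_proteomes(seed = 5, n_strains = 2, n_genes = 3, private = FALSE)
  b <- sim_proteomes(seed = 99, n_strains = 2, n_genes = 3, private = FALSE)
  names(b) <- c("t01", "t02")
  # make b genuinely unrelated: fresh random genes
  set.seed(100)
  b <- lapply(b, function(p) {
    q <- vapply(rep(300, length(p)), function(L)
      translate_cds(specirc:::random_gene(L)), character(1))
    names(q) <- names(p); q
  })
  og <- assign_orthogroups(c(a, b))
  grp <- split(og$strain, og$group)
  cross <- vapply(grp, function(s)
    any(s %in% names(a)) && any(s %in% names(b)), logical(1))
  expect_false(any(cross))
})

test_that("function matrix matches simulator truth and has no empty columns", {
  prots <- sim_proteomes(seed = 3)
  og <- assign_orthogroups(prots)
  fm <- build_function_matrix(og, prots)
  expect_true(all(fm %in% c(0L, 1L)))
  expect_true(all(colSums(fm) > 0))
  expect_equal(nrow(fm), 4L)
  expect_equal(ncol(fm), 7L)       # 6 shared + 1 private singleton
  prov <- attr(fm, "provenance")
  expect_setequal(unique(prov$provenance), c("orthogroup", "singleton"))
  # the private protein maps to a singleton column present only in s01
  singleton_col <- prov$function_id[prov$provenance == "singleton"]
  expect_equal(sum(fm[, singleton_col]), 1L)
  expect_equal(unname(fm["s01", singleton_col]), 1L)
})

test_that("function set counts follow their definitions", {
  m <- matrix(1L, 3, 5, dimnames = list(c("a", "b", "c"), paste0("f", 1:5)))
  fc <- function_set_counts(m)
  expect_equal(fc$pan, 5L)
  expect_equal(fc$counts$core, 5L)

  m2 <- m; m2["c", "f5"] <- 0L; m2["a", "f4"] <- 0L
  fc2 <- function_set_counts(m2, subsets = list(ab = c("a", "b"),
                                                c = "c"))
  expect_equal(fc2$counts$core[fc2$counts$subset == "ab"], 4L)   # f4 lost
  expect_equal(fc2$counts$private[fc2$counts$subset == "ab"], 1L) # f5
  expect_error(function_set_counts(m, subsets = list(empty = character())),
               "empty")
})

test_that("ecotype loses core and gains private functions at the published ecotype scale", {
  labs <- setNames(rep(c("spA", "spB", "spC"), each = 5),
                   sprintf("%s_%d", rep(c("A", "B", "C"), each = 5), 1:5))
  cfg <- clade_sim_config(n_species = 3, strains_per_species = 5,
                          n_core_genes = 2,
                          n_accessory_functions_per_species = 80,
                          repertoire_noise = 0,
                          ecotype_spec = list(strain = "B_3", n_lost = 171,
                                              n_gained = 28), seed = 4)
  m <- simulate_function_matrix(labs, n_core_functions = 400, cfg)
  fc <- function_set_counts(m, subsets = list(spB = names(labs)[labs == "spB"],
                                              eco = "B_3"))
  core_B <- fc$counts$core[fc$counts$subset == "spB"]
  expect_equal(400 + 80 - core_B, 171)            # ecotype lacks 171 of core
  expect_equal(fc$counts$private[fc$counts$subset == "eco"], 28L)
})

test_that("UPGMA on Manhattan distances matches hand and brute-force oracles", {
  m <- rbind(s1 = c(0, 0, 0), s2 = c(0, 0, 1), s3 = c(1, 1, 1))
  dend <- cluster_repertoire(m, n_boot = 50, seed = 1)
  hc <- dend$hclust
  # first merge is {s1, s2} at height 1
  expect_equal(sort(hc$labels[-hc$merge[1, ]]), c("s1", "s2"))
  expect_equal(hc$height[1], 1)
  expect_equal(hc$height[2], 2.5)  # average of d(1,3)=3 and d(2,3)=2

  # brute force on random binary matrices
  for (sd in 1:3) {
    set.seed(sd)
    mm <- matrix(rbinom(8 * 20, 1, 0.4), 8, 20,
                 dimnames = list(paste0("r", 1:8), NULL))
    dend2 <- cluster_repertoire(mm, n_boot = 10, seed = 1)
    got <- as.matrix(cophenetic(dend2$hclust))
    want <- naive_upgma_cophenetic(as.matrix(dist(mm, method = "manhattan")))
    expect_equal(got[rownames(want), colnames(want)], want,
                 tolerance = 1e-9)
    # Manhattan on binary rows equals the Hamming count
    expect_equal(as.matrix(dist(mm, method = "manhattan"))[1, 2],
                 sum(mm[1, ] != mm[2, ]))
    # merge heights never decrease
    expect_true(!is.unsorted(dend2$hclust$height))
  }
})

test_that("noise-free repertoires cluster by species with full support", {
  labs <- setNames(rep(c("spA", "spB", "spC"), each = 4),
                   sprintf("%s_%d", rep(c("A", "B", "C"), each = 4), 1:4))
  cfg <- clade_sim_config(n_species = 3, strains_per_species = 4,
                          n_core_genes = 2,
                          n_accessory_functions_per_species = 40,
                          repertoire_noise = 0, seed = 2)
  m <- simulate_function_matrix(labs, n_core_functions = 100, cfg)
  dend <- cluster_repertoire(m, n_boot = 200, seed = 5)
  cl <- cutree(dend$hclust, k = 3)
  expect_equal(length(unique(paste(cl, labs[names(cl)]))), 3L)
  sets <- specirc:::cluster_sets(dend$hclust)
  full_species <- vapply(sets, function(s)
    length(s) == 4 && length(unique(labs[s])) == 1, logical(1))
  expect_true(all(dend$bp[full_species] == 100))
})

test_that("dendrogram comparison metrics behave on identical and edited trees", {
  labs <- setNames(rep(c("spA", "spB", "spC"), each = 4),
                   sprintf("%s_%d", rep(c("A", "B", "C"), each = 4), 1:4))
  cfg <- clade_sim_config(n_species = 3, strains_per_species = 4,
                          n_core_genes = 2,
                          n_accessory_functions_per_species = 40,
                          repertoire_noise = 0, seed = 6)
  m <- simulate_function_matrix(labs, n_core_functions = 60, cfg)
  d1 <- cluster_repertoire(m, n_boot = 10, seed = 1)
  d2 <- cluster_repertoire(m[rev(rownames(m)), ], n_boot = 10, seed = 1)
  cmp <- compare_dendrograms(d1, d2)
  expect_equal(cmp$cophenetic_correlation, 1, tolerance = 1e-9)
  expect_lt(cmp$entanglement, 0.05)
  expect_false(any(cmp$discordant$discordant))

  # move one strain's repertoire onto another species' profile
  m3 <- m
  m3["A_2", ] <- m["B_1", ]
  d3 <- cluster_repertoire(m3, n_boot = 10, seed = 1)
  cmp2 <- compare_dendrograms(d1, d3)
  disc <- cmp2$discordant
  expect_true(disc$discordant[disc$strain == "A_2"])
  expect_equal(disc$strain[1], "A_2")
  expect_lt(cmp2$bakers_gamma, 1)

  expect_error(compare_dendrograms(d1, cluster_repertoire(
    m[1:10, ], n_boot = 5, seed = 1)), "leaf sets differ")
})
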