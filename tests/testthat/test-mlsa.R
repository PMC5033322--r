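test_that("aligning identical or substitution-only families is gap-free", {
  fam <- c(s1 = "ATGACGTACGGT", s2 = "ATGACGTACGGT", s3 = "ATGACGTACGGT")
  aln <- align_family(fam)
  expect_true(all(nchar(aln) == 12))
  expect_false(any(grepl("-", aln)))

  fam2 <- c(s1 = "ATGACGTACGGTATGACG", s2 = "ATGACCTACGGTATGACG")
  aln2 <- align_family(fam2)
  expect_equal(unique(nchar(aln2)), 18L)
  expect_equal(sum(strsplit(aln2[[1]], "")[[1]] !=
                     strsplit(aln2[[2]], "")[[1]]), 1L)
  # ungapping reproduces the inputs
  expect_identical(as.vector(gsub("-", "", aln2)), unname(fam2))
})

test_that("aligner recovers a clean deletion and matches the DP oracle", {
  set.seed(6)
  base <- specirc:::random_gene(120)
  del <- paste0(substr(base, 1, 50), substr(base, 61, 120))
  aln <- align_family(c(a = base, b = del))
  expect_gte(nchar(aln[[1]]), 120L)
  expect_identical(gsub("-", "", aln[["b"]]), del)
  # oracle: optimal affine-gap global alignment score via Biostrings
  ora <- Biostrings::pairwiseAlignment(base, del, type = "global",
                                       gapOpening = 10, gapExtension = 0.5)
  expect_equal(nchar(aln[[1]]),
               nchar(as.character(Biostrings::alignedPattern(ora))))
})

test_that("concatenation tiles partitions exactly and checks taxa", {
  taxa <- c("t1", "t2", "t3")
  mk <- function(w) structure(
    setNames(vapply(taxa, function(x) paste(rep("A", w), collapse = ""),
                    character(1)), taxa), class = "alignment")
  sm <- concatenate_alignments(list(f1 = mk(10), f2 = mk(20), f3 = mk(30)))
  expect_equal(nchar(sm$seqs[[1]]), 60L)
  expect_equal(sm$partitions$start, c(1, 11, 31))
  expect_equal(sm$partitions$end, c(10, 30, 60))
  bad <- mk(5)[1:2]
  class(bad) <- "alignment"
  expect_error(concatenate_alignments(list(mk(10), bad)), "t3")
  one <- concatenate_alignments(list(f1 = mk(10)))
  expect_equal(unname(one$seqs), unname(unclass(mk(10))))
})

test_that("conserved-block trimming applies the stated rules", {
  # 10 identical rows: everything is highly conserved, nothing is trimmed
  rows <- rep(paste(rep("ACGT", 10), collapse = ""), 10)
  names(rows) <- paste0("t", 1:10)
  aln <- structure(rows, class = "alignment", family_id = "f")
  sm <- trim_conserved_blocks(aln)
  expect_equal(nchar(sm$seqs[[1]]), 40L)

  # an all-gap 12-column region is removed (gap rule + block split)
  rows2 <- rows
  rows2[1:10] <- paste0(substr(rows, 1, 14),
                        paste(rep("-", 12), collapse = ""),
                        substr(rows, 27, 40))
  aln2 <- structure(rows2, class = "alignment", family_id = "f")
  sm2 <- trim_conserved_blocks(aln2)
  expect_equal(nchar(sm2$seqs[[1]]), 28L)
  expect_false(any(grepl("-", sm2$seqs)))

  # a 9-column nonconserved run (> CP = 8) is removed, flanking conserved
  # blocks of >= 10 columns survive
  # cyclic letters make every column in 16..24 nonconserved by design
  # (each of the 10 rows is phase-shifted, so no residue reaches IS = 6)
  alphabet <- c("A", "C", "G", "T")
  rows3 <- vapply(seq_along(rows), function(r) {
    v <- strsplit(rows[[r]], "")[[1]]
    for (i in 16:24) v[i] <- alphabet[((i + r) %% 4) + 1]
    paste(v, collapse = "")
  }, character(1))
  names(rows3) <- names(rows)
  aln3 <- structure(rows3, class = "alignment", family_id = "f")
  sm3 <- trim_conserved_blocks(aln3)
  kept <- attr(sm3, "kept_columns")
  expect_true(all(kept <= 15 | kept >= 25))
  expect_gte(nchar(sm3$seqs[[1]]), 20L)

  # trimming never increases columns; kept columns are ordered originals
  expect_true(!is.unsorted(kept))
})

test_that("genetic distances match the closed-form models", {
  # 100 sites, 10 transversion mismatches (A vs C)
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("C", 10), rep("A", 90)), collapse = "")
  aln <- c(x = s1, y = s2)
  expect_equal(genetic_distance(aln, "p")["x", "y"], 0.10)
  expect_equal(genetic_distance(aln, "JC69")["x", "y"],
               -3 / 4 * log(1 - 4 * 0.1 / 3), tolerance = 1e-9)
  expect_equal(genetic_distance(aln, "K80")["x", "y"],
               -1 / 2 * log(1 - 0.1) - 1 / 4 * log(1 - 0.2),
               tolerance = 1e-9)
  # identical rows are at distance zero under every model
  same <- c(x = s1, y = s1)
  for (m in c("p", "JC69", "K80"))
    expect_equal(genetic_distance(same, m)["x", "y"], 0)
  # JC69 is strictly increasing in p
  p_grid <- seq(0.02, 0.70, by = 0.04)
  jc <- -3 / 4 * log(1 - 4 * p_grid / 3)
  expect_true(all(diff(jc) > 0))
})

test_that("NJ recovers an additive quartet exactly and supports bootstrap", {
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- ape::nj(as.dist(d))
  # four-point condition holds, so NJ must reproduce the generating tree:
  # split {A,B}|{C,D} with leaf branches 1,2,3,4 and internal branch 1
  expect_true(ape::is.monophyletic(ape::root(tr, "D"), c("A", "B")))
  patristic <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(unname(patristic), unname(d), tolerance = 1e-9)

  # tree from sequences: species monophyly and bootstrap on internal edges
  sim <- simulate_clade(small_clade(seed = 13, filler = 0))
  core <- blast_core_genes(sim$strainset$genomes[[1]], sim$strainset)
  alns <- lapply(names(core$families), function(g)
    align_family(core$families[[g]], family_id = g))
  sm <- concatenate_alignments(alns)
  tree <- nj_tree_with_bootstrap(sm, model = "K80", n_boot = 100, seed = 4)
  for (sp in unique(sim$truth$species)) {
    tips <- sim$truth$id[sim$truth$species == sp]
    expect_true(ape::is.monophyletic(tree, tips))
  }
  sup <- suppressWarnings(as.numeric(tree$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
})

test_that("bootstrap supports are invariant to taxon order", {
  sim <- simulate_clade(small_clade(seed = 19, filler = 0))
  core <- blast_core_genes(sim$strainset$genomes[[1]], sim$strainset)
  alns <- lapply(names(core$families), function(g)
    align_family(core$families[[g]], family_id = g))
  sm <- concatenate_alignments(alns)
  sm_perm <- sm
  set.seed(1)
  sm_perm$seqs <- sm_perm$seqs[sample(length(sm_perm$seqs))]
  t1 <- nj_tree_with_bootstrap(sm, n_boot = 60, seed = 9)
  t2 <- nj_tree_with_bootstrap(sm_perm, n_boot = 60, seed = 9)
  sup <- function(tr) {
    parts <- ape::prop.part(tr)
    labs <- attr(parts, "labels")
    keys <- vapply(parts, function(p) paste(sort(labs[p]), collapse = ","),
                   character(1))
    setNames(tr$node.label, keys)
  }
  s1 <- sup(t1); s2 <- sup(t2)
  shared <- intersect(names(s1), names(s2))
  expect_gt(length(shared), 2L)
  expect_equal(suppressWarnings(as.numeric(s1[shared])),
               suppressWarnings(as.numeric(s2[shared])), tolerance = 15)
})

test_that("supermatrix exports round-trip", {
  taxa <- paste0("t", 1:4)
  rows <- setNames(rep("ACGTACGTAC", 4), taxa)
  sm <- concatenate_alignments(list(
    f1 = structure(rows, class = "alignment", family_id = "f1")))
  fp <- withr::local_tempfile(fileext = ".phy")
  write_phylip(sm, fp)
  lines <- readLines(fp)
  expect_match(lines[1], "^4 10$")
  pf <- withr::local_tempfile(fileext = ".txt")
  write_partitions(sm, pf)
  expect_match(readLines(pf), "DNA, f1 = 1-10")
})
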