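#' Configuration for the clade simulator
#'
#' Describes a synthetic clade of `n_species` bacterial species, each with a
#' set of strains, evolving a shared complement of core genes along a
#' star-within-star genealogy: species ancestors diverge independently from
#' the clade ancestor, and strains diverge independently from their species
#' ancestor. Per-gene rate multipliers create the spread observed in real
#' core genomes, from fast, species-diagnostic genes down to
#' ribosomal-protein-like near-invariant ones.
#'
#' Divergences are expected per-site substitution proportions between two
#' strains (the species branch carries half of `between_species_divergence`,
#' the strain branch half of `within_species_divergence`, each scaled by the
#' gene's rate multiplier). The defaults (1% within, 10% between) reproduce
#' the ANI bands typical of closely related species groups: roughly >98%
#' identity within a species cluster and around or below 90% between
#' clusters.
#'
#' @param n_species Number of species (>= 2).
#' @param strains_per_species Integer, or integer vector of length
#'   `n_species`.
#' @param n_core_genes Number of shared core genes.
#' @param gene_length_range Min/max gene length in nt (rounded to codons).
#' @param within_species_divergence Expected pairwise divergence between two
#'   strains of one species, for a gene with multiplier 1.
#' @param between_species_divergence Expected pairwise divergence between
#'   strains of different species, for a gene with multiplier 1. Must exceed
#'   the within-species value; both at most 0.5.
#' @param gene_rate_multipliers Positive per-gene scalars (length
#'   `n_core_genes`); default all 1. Larger values yield faster-evolving,
#'   more species-diagnostic genes.
#' @param gene_species_signal Per-gene multipliers in \[0, 1\] applied to the
#'   species-ancestor branches only (default all 1). Setting a gene's value
#'   to 0 makes its variation purely strain-level noise: the gene evolves
#'   but carries no species signal, emulating loci whose divergence does not
#'   track speciation.
#' @param species_branch_scale Per-species multipliers (length `n_species`,
#'   default all 1) on the species-ancestor branch lengths, allowing an
#'   uneven radiation in which some species pairs are much closer than
#'   others (as in real species groups where recently diverged species are
#'   nearly identical). A pair's expected divergence is
#'   `between/2 * (scale_i + scale_j)` for a gene with multiplier 1.
#' @param n_accessory_genes_per_species Number of species-private accessory
#'   genes added to each genome's CDS complement (default 0). These are
#'   independent random genes shared by a species' strains (mutated at the
#'   within-species rate), giving the function-repertoire stages real
#'   species structure to recover.
#' @param n_accessory_functions_per_species Species-private function count
#'   used by [simulate_function_matrix()].
#' @param repertoire_noise Per-cell flip probability for the function
#'   matrix.
#' @param ecotype_spec Optional `list(strain, n_lost, n_gained)` describing
#'   an ecotype strain with excess function loss/gain.
#' @param n_filler_nt Length of species-level random filler sequence
#'   appended to each genome (shared within a species, independent between
#'   species), so that whole-genome identity is not identical to core-gene
#'   distance.
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `clade_sim_config`.
#' @export
clade_sim_config <- function(n_species = 4L, strains_per_species = 4L,
                             n_core_genes = 10L,
                             gene_length_range = c(300L, 900L),
                             within_species_divergence = 0.01,
                             between_species_divergence = 0.10,
                             gene_rate_multipliers = NULL,
                             gene_species_signal = NULL,
                             species_branch_scale = NULL,
                             n_accessory_genes_per_species = 0L,
                             n_accessory_functions_per_species = 80L,
                             repertoire_noise = 0.005,
                             ecotype_spec = NULL,
                             n_filler_nt = 1500L,
                             seed = 1L) {
  if (n_species < 2L) stop("n_species must be >= 2")
  if (!(within_species_divergence >= 0 &&
        within_species_divergence < between_species_divergence &&
        between_species_divergence <= 0.5))
    stop("need 0 <= within < between <= 0.5 divergence")
  if (length(strains_per_species) == 1L)
    strains_per_species <- rep(as.integer(strains_per_species), n_species)
  if (length(strains_per_species) != n_species)
    stop("strains_per_species must have length 1 or n_species")
  if (is.null(gene_rate_multipliers))
    gene_rate_multipliers <- rep(1, n_core_genes)
  if (length(gene_rate_multipliers) != n_core_genes)
    stop("gene_rate_multipliers must have length n_core_genes")
  if (any(gene_rate_multipliers <= 0))
    stop("gene_rate_multipliers must be positive")
  if (is.null(gene_species_signal))
    gene_species_signal <- rep(1, n_core_genes)
  if (length(gene_species_signal) != n_core_genes)
    stop("gene_species_signal must have length n_core_genes")
  if (any(gene_species_signal < 0 | gene_species_signal > 1))
    stop("gene_species_signal values must be in [0, 1]")
  if (is.null(species_branch_scale))
    species_branch_scale <- rep(1, n_species)
  if (length(species_branch_scale) != n_species ||
      any(species_branch_scale <= 0))
    stop("species_branch_scale must be ", n_species, " positive values")
  if (!is.null(ecotype_spec)) {
    if (!all(c("strain", "n_lost", "n_gained") %in% names(ecotype_spec)))
      stop("ecotype_spec needs fields strain, n_lost, n_gained")
  }
  structure(list(
    n_species = as.integer(n_species),
    strains_per_species = strains_per_species,
    n_core_genes = as.integer(n_core_genes),
    gene_length_range = gene_length_range,
    within_species_divergence = within_species_divergence,
    between_species_divergence = between_species_divergence,
    gene_rate_multipliers = gene_rate_multipliers,
    gene_species_signal = gene_species_signal,
    species_branch_scale = species_branch_scale,
    n_accessory_genes_per_species = as.integer(n_accessory_genes_per_species),
    n_accessory_functions_per_species =
      as.integer(n_accessory_functions_per_species),
    repertoire_noise = repertoire_noise,
    ecotype_spec = ecotype_spec,
    n_filler_nt = as.integer(n_filler_nt),
    seed = as.integer(seed)), class = "clade_sim_config")
}

# sense codons of the standard code (no stop codons in ancestral genes)
sense_codons <- function() {
  all <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                               paste0), c("T", "C", "A", "G"), paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

random_gene <- function(len_nt) {
  paste(sample(sense_codons(), len_nt %/% 3L, replace = TRUE), collapse = "")
}

# i.i.d. per-site substitution at the given expected proportion; uniform
# choice among the three alternative bases. Uses the current RNG stream.
mutate_seq <- function(seq, divergence) {
  if (divergence <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(bases)) < divergence)
  if (length(hit) > 0L) {
    alt <- c("A", "C", "G", "T")
    for (i in hit) {
      choices <- alt[alt != bases[i]]
      bases[i] <- choices[sample.int(3L, 1L)]
    }
  }
  paste(bases, collapse = "")
}

#' Mutate a single gene copy
#'
#' Applies i.i.d. per-site substitutions at the given expected proportion
#' (uniform over the three alternative bases); length is preserved and no
#' indels are introduced.
#'
#' @param gene Nucleotide sequence.
#' @param divergence Expected fraction of changed sites, in \[0, 0.75\].
#' @param seed Optional integer seed; same seed gives identical output.
#' @return Mutated sequence.
#' @export
mutate_single_gene_copy <- function(gene, divergence, seed = NULL) {
  if (divergence < 0 || divergence > 0.75)
    stop("divergence must be in [0, 0.75]")
  if (!is.null(seed)) set.seed(seed)
  mutate_seq(gene, divergence)
}

#' Simulate a clade of bacterial strains
#'
#' Generates genomes as concatenations of simulated core genes plus
#' species-level random filler, along a star-within-star genealogy (see
#' [clade_sim_config()]). Returns the strain set together with the true
#' species labels and the per-gene true diagnosticity ranks (rank 1 = the
#' fastest-evolving, most diagnostic gene).
#'
#' Roles are assigned deterministically: within each species the first
#' `ceiling(n/2)` strains are `train`, the rest `test`.
#'
#' @param cfg A [clade_sim_config()].
#' @return A list of class `clade_sim` with elements `strainset`
#'   ([strain_set()]), `truth` (data frame `id`, `species`), `genes` (data
#'   frame `gene_id`, `length`, `rate_multiplier`, `diagnosticity_rank`) and
#'   `config`.
#' @export
simulate_clade <- function(cfg) {
  stopifnot(inherits(cfg, "clade_sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_core_genes
  len_pool <- seq(cfg$gene_length_range[1], cfg$gene_length_range[2])
  lens <- len_pool[sample.int(length(len_pool), G, replace = TRUE)]
  lens <- pmax(3L, (lens %/% 3L) * 3L)
  gene_ids <- sprintf("g%03d", seq_len(G))
  anc <- vapply(lens, random_gene, character(1))
  names(anc) <- gene_ids

  sp_div <- pmin(0.75, cfg$between_species_divergence / 2 *
                   cfg$gene_rate_multipliers * cfg$gene_species_signal)
  st_div <- pmin(0.75, cfg$within_species_divergence / 2 *
                   cfg$gene_rate_multipliers)

  strains <- list(); genomes <- list(); truth <- list()
  for (i in seq_len(cfg$n_species)) {
    sp <- sprintf("sp%02d", i)
    sp_genes <- vapply(seq_len(G), function(g)
      mutate_seq(anc[[g]], min(0.75, sp_div[g] * cfg$species_branch_scale[i])),
      character(1))
    filler <- if (cfg$n_filler_nt > 0L)
      paste(sample(c("A", "C", "G", "T"), cfg$n_filler_nt, replace = TRUE),
            collapse = "") else ""
    n_acc <- cfg$n_accessory_genes_per_species
    acc_genes <- if (n_acc > 0L)
      setNames(vapply(rep(300L, n_acc), random_gene, character(1)),
               sprintf("acc_%s_%02d", sp, seq_len(n_acc)))
    else character()
    n_str <- cfg$strains_per_species[i]
    for (j in seq_len(n_str)) {
      id <- sprintf("%s_%02d", sp, j)
      st_genes <- vapply(seq_len(G),
                         function(g) mutate_seq(sp_genes[g], st_div[g]),
                         character(1))
      st_acc <- vapply(acc_genes, mutate_seq, character(1),
                       divergence = cfg$within_species_divergence / 2)
      contig <- paste(c(st_genes, st_acc, filler), collapse = "")
      cds <- data.frame(gene_id = c(gene_ids, names(acc_genes)),
                        nuc = c(st_genes, unname(st_acc)),
                        stringsAsFactors = FALSE)
      genomes[[id]] <- genome(id, c(chr = contig), cds)
      role <- if (j <= ceiling(n_str / 2)) "train" else "test"
      strains[[length(strains) + 1L]] <-
        data.frame(id = id, species = sp, role = role,
                   stringsAsFactors = FALSE)
    }
  }
  strains <- do.call(rbind, strains)
  signal <- cfg$gene_rate_multipliers * cfg$gene_species_signal *
    cfg$between_species_divergence
  genes <- data.frame(
    gene_id = gene_ids, length = lens,
    rate_multiplier = cfg$gene_rate_multipliers,
    species_signal = cfg$gene_species_signal,
    diagnosticity_rank = rank(-signal, ties.method = "min"),
    stringsAsFactors = FALSE)
  structure(list(
    strainset = strain_set(strains, genomes),
    truth = strains[, c("id", "species")],
    genes = genes,
    config = cfg), class = "clade_sim")
}

#' @export
print.clade_sim <- function(x, ...) {
  cat("clade_sim:", x$config$n_species, "species,",
      nrow(x$truth), "strains,", x$config$n_core_genes, "core genes",
      "(seed", paste0(x$config$seed, ")"), "\n")
  invisible(x)
}

#' Simulate a binary function-repertoire matrix
#'
#' Core functions are present in every strain; each species carries a
#' private accessory block; an optional ecotype strain additionally loses
#' `n_lost` core functions and gains `n_gained` functions private to itself
#' (applied before noise, so with `repertoire_noise = 0` the ecotype differs
#' from its species profile in exactly `n_lost + n_gained` cells). Each cell
#' is then flipped independently with probability `repertoire_noise`.
#'
#' @param labels Named character vector mapping strain id to species, or a
#'   data frame with columns `id` and `species`.
#' @param n_core_functions Number of functions present in all strains.
#' @param cfg A [clade_sim_config()] supplying accessory counts, noise,
#'   ecotype and seed.
#' @return Binary matrix (strains x functions) of class `function_matrix`.
#' @export
simulate_function_matrix <- function(labels, n_core_functions, cfg) {
  stopifnot(inherits(cfg, "clade_sim_config"))
  if (is.data.frame(labels)) labels <- setNames(labels$species, labels$id)
  set.seed(cfg$seed)
  strains <- names(labels)
  species <- unique(labels)
  a <- cfg$n_accessory_functions_per_species
  eco <- cfg$ecotype_spec
  if (!is.null(eco) && !(eco$strain %in% strains))
    stop("ecotype strain not among labels: ", eco$strain)
  if (!is.null(eco) && eco$n_lost > n_core_functions)
    stop("ecotype n_lost exceeds n_core_functions")

  core_ids <- sprintf("core_%04d", seq_len(n_core_functions))
  acc_ids <- unlist(lapply(species, function(sp)
    sprintf("acc_%s_%03d", sp, seq_len(a))))
  gain_ids <- if (!is.null(eco) && eco$n_gained > 0L)
    sprintf("eco_gain_%03d", seq_len(eco$n_gained)) else character()
  fun_ids <- c(core_ids, acc_ids, gain_ids)

  m <- matrix(0L, nrow = length(strains), ncol = length(fun_ids),
              dimnames = list(strains, fun_ids))
  m[, core_ids] <- 1L
  for (sp in species)
    m[strains[labels == sp], sprintf("acc_%s_%03d", sp, seq_len(a))] <- 1L
  if (!is.null(eco)) {
    if (eco$n_lost > 0L)
      m[eco$strain, core_ids[seq_len(eco$n_lost)]] <- 0L
    if (eco$n_gained > 0L)
      m[eco$strain, gain_ids] <- 1L
  }
  if (cfg$repertoire_noise > 0) {
    flips <- matrix(runif(length(m)) < cfg$repertoire_noise, nrow = nrow(m))
    m[flips] <- 1L - m[flips]
  }
  structure(m, class = c("function_matrix", class(m)),
            provenance = data.frame(function_id = fun_ids,
                                    provenance = "simulated",
                                    stringsAsFactors = FALSE))
}
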