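# Karlin-Altschul style statistics for gapped BLOSUM62 (open 11, extend 1):
# the standard gapped parameters lambda = 0.267, K = 0.041. Effective search
# space is taken as the plain product of sequence lengths, adequate at the
# scale this built-in search is intended for.
ka_lambda <- 0.267
ka_K <- 0.041

ka_bitscore <- function(raw) (ka_lambda * raw - log(ka_K)) / log(2)
ka_evalue <- function(raw, m, n) m * n * 2^(-ka_bitscore(raw))

#' Protein similarity search (all queries vs a database)
#'
#' Exact Smith-Waterman local alignment with BLOSUM62 and affine gaps
#' (open 11, extend 1), with Karlin-Altschul-style bit scores and e-values.
#' Only hits with `e_value <= e_cutoff` are reported. Deterministic and
#' oracle-checkable; equivalence to any particular heuristic search tool is
#' not claimed.
#'
#' @param queries,db Named character vectors of protein sequences.
#' @param e_cutoff E-value cutoff (default 1e-30, the stringent core-gene
#'   setting; use 1e-5 for orthogroup graphs).
#' @return Data frame of hits: `query_id`, `subject_id`, `percent_identity`,
#'   `alignment_length`, `bitscore`, `e_value`, `score`.
#' @export
search_all <- function(queries, db, e_cutoff = 1e-30) {
  if (length(queries) == 0L || length(db) == 0L)
    return(data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(),
                      alignment_length = numeric(), bitscore = numeric(),
                      e_value = numeric(), score = numeric()))
  if (is.null(names(queries)) || is.null(names(db)))
    stop("queries and db must be named")
  res <- .sw_all_pairs_cpp(unname(queries), unname(db), blosum62(), 11, 1)
  hits <- data.frame(
    query_id = names(queries)[res$query],
    subject_id = names(db)[res$subject],
    percent_identity = ifelse(res$columns > 0,
                              100 * res$identities / res$columns, 0),
    alignment_length = res$columns,
    bitscore = ka_bitscore(res$score),
    e_value = ka_evalue(res$score, res$query_length, res$subject_length),
    score = res$score,
    stringsAsFactors = FALSE)
  hits <- hits[hits$e_value <= e_cutoff & hits$alignment_length >= 1, ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Best hit per query: max bitscore, then min e-value, then lexicographically
# smallest subject id.
best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$query_id, -hits$bitscore, hits$e_value, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$query_id), , drop = FALSE]
}

#' Reciprocal best hits between two proteomes
#'
#' A pair `(a, b)` is an ortholog pair iff `b` is the best hit of `a` in
#' proteome B and `a` is the best hit of `b` in proteome A, both under the
#' e-value cutoff. Ties are broken by bit score, then e-value, then subject
#' id, so the result is deterministic.
#'
#' @param proteome_a,proteome_b Named character vectors of proteins.
#' @param e_cutoff E-value cutoff (default 1e-30).
#' @return Data frame with columns `gene_a`, `gene_b` and the forward-hit
#'   statistics.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b, e_cutoff = 1e-30) {
  if (length(proteome_a) == 0L || length(proteome_b) == 0L)
    stop("both proteomes must be non-empty")
  fwd <- best_hits(search_all(proteome_a, proteome_b, e_cutoff))
  rev <- best_hits(search_all(proteome_b, proteome_a, e_cutoff))
  if (nrow(fwd) == 0L || nrow(rev) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      percent_identity = numeric(),
                      alignment_length = numeric(), bitscore = numeric(),
                      e_value = numeric()))
  rev_map <- setNames(rev$subject_id, rev$query_id)
  keep <- !is.na(rev_map[fwd$subject_id]) &
    rev_map[fwd$subject_id] == fwd$query_id
  out <- fwd[keep, , drop = FALSE]
  data.frame(gene_a = out$query_id, gene_b = out$subject_id,
             percent_identity = out$percent_identity,
             alignment_length = out$alignment_length,
             bitscore = out$bitscore, e_value = out$e_value,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Detect the reciprocal-best-hit core gene set
#'
#' Uses every CDS of a reference genome as queries for reciprocal-best-hit
#' searches against each strain's proteome. Gene families are kept iff an
#' ortholog exists in every strain considered. With `scope = "all"` the
#' outgroups are included (filtering out genes transferred horizontally
#' after speciation); with `scope = "group"` only non-outgroup strains must
#' carry the gene, and families contain only those strains.
#'
#' @param reference A [genome()] with CDS (nucleotide and protein).
#' @param set A [strain_set()].
#' @param e_cutoff E-value cutoff (default 1e-30).
#' @param scope `"all"` (default) or `"group"`.
#' @return Object of class `core_gene_set`: list with `families` (named list
#'   of `list(gene_id, nuc, prot)`, sequences named by strain), `strains`
#'   and `reference`.
#' @export
blast_core_genes <- function(reference, set, e_cutoff = 1e-30,
                             scope = c("all", "group")) {
  stopifnot(inherits(reference, "genome"), inherits(set, "strain_set"))
  scope <- match.arg(scope)
  if (is.null(reference$cds) || nrow(reference$cds) == 0L)
    stop("reference genome has no CDS")
  ids <- set$strains$id
  if (scope == "group") ids <- setdiff(ids, set$outgroups)
  ref_prot <- setNames(reference$cds$prot, reference$cds$gene_id)
  ref_nuc <- setNames(reference$cds$nuc, reference$cds$gene_id)

  ortho <- list()  # ref gene -> strain -> strain gene id
  for (id in ids) {
    prot <- proteome_of(set, id)
    rbh <- reciprocal_best_hits(ref_prot, prot, e_cutoff)
    ortho[[id]] <- setNames(rbh$gene_b, rbh$gene_a)
  }
  core_genes <- names(ref_prot)
  for (id in ids)
    core_genes <- core_genes[core_genes %in% names(ortho[[id]])]
  families <- lapply(core_genes, function(g) {
    nuc <- vapply(ids, function(id) {
      cds <- set$genomes[[id]]$cds
      cds$nuc[match(ortho[[id]][[g]], cds$gene_id)]
    }, character(1))
    prot <- vapply(ids, function(id) {
      cds <- set$genomes[[id]]$cds
      cds$prot[match(ortho[[id]][[g]], cds$gene_id)]
    }, character(1))
    list(gene_id = g, nuc = setNames(nuc, ids), prot = setNames(prot, ids),
         members = setNames(vapply(ids, function(id) ortho[[id]][[g]],
                                   character(1)), ids))
  })
  names(families) <- core_genes
  structure(list(families = families, strains = ids,
                 reference = reference$strain_id,
                 reference_nuc = ref_nuc[core_genes]),
            class = "core_gene_set")
}

#' @export
print.core_gene_set <- function(x, ...) {
  cat("core_gene_set:", length(x$families), "families across",
      length(x$strains), "strains (reference:", x$reference, ")\n")
  invisible(x)
}

#' Write core gene families as FASTA, one file per family
#'
#' @param core A `core_gene_set`.
#' @param dir Output directory (created if needed).
#' @param what `"nuc"` or `"prot"`.
#' @export
write_core_families <- function(core, dir, what = c("nuc", "prot")) {
  what <- match.arg(what)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(core$families))
    write_fasta(core$families[[g]][[what]],
                file.path(dir, paste0(g, ".fasta")))
  invisible(dir)
}
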