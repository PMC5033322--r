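#' ANIb fragment parameters
#'
#' The ANIb convention: the query genome is chopped into consecutive
#' fragments of `fragment_length` nt (the trailing partial fragment is kept
#' when at least half that length), each fragment is locally aligned to the
#' subject, and fragments are retained when their best hit reaches at least
#' `min_identity_pct` percent identity over at least `min_fragment_coverage`
#' of the fragment. ANI is the mean identity of retained fragments.
#'
#' @param fragment_length Fragment size in nt (default 1020).
#' @param min_identity_pct Minimum percent identity for retention.
#' @param min_fragment_coverage Minimum aligned fraction of the fragment.
#' @return An object of class `ani_params`.
#' @export
ani_params <- function(fragment_length = 1020L, min_identity_pct = 30,
                       min_fragment_coverage = 0.70) {
  if (fragment_length < 100L) stop("fragment_length must be >= 100")
  if (min_identity_pct < 0 || min_identity_pct > 100)
    stop("min_identity_pct must be in [0, 100]")
  if (min_fragment_coverage < 0 || min_fragment_coverage > 1)
    stop("min_fragment_coverage must be in [0, 1]")
  structure(list(fragment_length = as.integer(fragment_length),
                 min_identity_pct = min_identity_pct,
                 min_fragment_coverage = min_fragment_coverage),
            class = "ani_params")
}

chop_fragments <- function(contigs, fl) {
  out <- list()
  for (ci in seq_along(contigs)) {
    s <- contigs[[ci]]
    n <- nchar(s)
    starts <- seq(1L, n, by = fl)
    for (st in starts) {
      en <- min(st + fl - 1L, n)
      if (en - st + 1L >= fl / 2)
        out[[length(out) + 1L]] <- list(contig = names(contigs)[ci] %||% ci,
                                        start = st, end = en,
                                        seq = substr(s, st, en))
    }
  }
  out
}

#' Directional fragment-based ANI between two genomes
#'
#' Each query fragment is aligned to every subject contig with the built-in
#' exact semi-global aligner (fragment end-to-end, free subject ends) and
#' its best placement kept. The semi-global backend always aligns the full
#' fragment, so the coverage filter is satisfied by construction; retention
#' therefore requires a positive alignment score (the standard evidence-of-
#' homology criterion, playing the role that short local HSPs failing the
#' coverage filter play in BLAST-based ANIb) in addition to the identity
#' threshold. On indel-free genomes the optimal placement is ungapped and
#' identity equals the per-site match fraction exactly.
#'
#' When no fragment passes the filters the ANI is undefined (`NA` with
#' `undefined = TRUE`), never silently 0.
#'
#' @param query,subject [genome()] objects (or named character vectors of
#'   contigs).
#' @param params An [ani_params()].
#' @return List of class `ani_pair` with `ani` (percent), `aligned_fraction`,
#'   `hsps` (per-fragment alignment table, reusable for GBDP distances) and
#'   `undefined`.
#' @export
compute_ani_pair <- function(query, subject, params = ani_params()) {
  qc <- if (inherits(query, "genome")) query$contigs else toupper(query)
  sc <- if (inherits(subject, "genome")) subject$contigs else toupper(subject)
  if (sum(nchar(qc)) == 0L || sum(nchar(sc)) == 0L)
    stop("empty genome")
  frags <- chop_fragments(qc, params$fragment_length)
  if (length(frags) == 0L) stop("query yields no fragments")
  rows <- vector("list", length(frags))
  for (i in seq_along(frags)) {
    f <- frags[[i]]
    best <- NULL
    for (sj in seq_along(sc)) {
      al <- .align_semiglobal_cpp(f$seq, sc[[sj]])
      if (is.null(best) || al$score > best$score) {
        best <- al
        best$subject_contig <- names(sc)[sj] %||% sj
      }
    }
    idy <- 100 * best$matches / best$columns
    cov <- (best$query_length) / nchar(f$seq)  # full-query alignment
    rows[[i]] <- data.frame(
      fragment = i, contig = f$contig, start = f$start, end = f$end,
      subject_contig = best$subject_contig,
      sstart = best$sstart, send = best$send,
      columns = best$columns, identities = best$matches,
      identity_pct = idy, coverage = cov,
      score = best$score,
      retained = best$score > 0 &&
        idy >= params$min_identity_pct &&
        cov >= params$min_fragment_coverage,
      stringsAsFactors = FALSE)
  }
  hsps <- do.call(rbind, rows)
  kept <- hsps[hsps$retained, , drop = FALSE]
  qlen <- sum(nchar(qc))
  if (nrow(kept) == 0L) {
    res <- list(ani = NA_real_, aligned_fraction = 0, hsps = hsps,
                undefined = TRUE, params = params)
  } else {
    res <- list(ani = mean(kept$identity_pct),
                aligned_fraction = sum(kept$end - kept$start + 1L) / qlen,
                hsps = hsps, undefined = FALSE, params = params)
  }
  class(res) <- "ani_pair"
  res
}

#' @export
print.ani_pair <- function(x, ...) {
  if (x$undefined) {
    cat("ANI: undefined (no fragment passed the identity/coverage filter)\n")
  } else {
    cat(sprintf("ANI: %.2f%% over %.1f%% of the query (%d/%d fragments)\n",
                x$ani, 100 * x$aligned_fraction, sum(x$hsps$retained),
                nrow(x$hsps)))
  }
  invisible(x)
}

#' All-pairs directional ANI matrix for a strain set
#'
#' Computes every ordered pair independently (the matrix is asymmetric in
#' general); the diagonal is set to 100 with aligned fraction 1. Undefined
#' cells are `NA` and flagged.
#'
#' @param set A [strain_set()].
#' @param params An [ani_params()].
#' @return Object of class `ani_matrix`: list with `ani` and
#'   `aligned_fraction` matrices and the parameters used.
#' @export
ani_matrix <- function(set, params = ani_params()) {
  stopifnot(inherits(set, "strain_set"))
  ids <- set$strains$id
  if (length(ids) < 2L) stop("need at least 2 strains")
  n <- length(ids)
  ani <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  af <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(ani) <- 100; diag(af) <- 1
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    p <- compute_ani_pair(set$genomes[[ids[i]]], set$genomes[[ids[j]]], params)
    ani[i, j] <- p$ani
    af[i, j] <- p$aligned_fraction
  }
  structure(list(ani = ani, aligned_fraction = af, params = params),
            class = "ani_matrix")
}

#' @export
print.ani_matrix <- function(x, digits = 2, ...) {
  cat("ani_matrix:", nrow(x$ani), "strains")
  und <- sum(is.na(x$ani))
  if (und > 0) cat(" (", und, "undefined cells)")
  cat("\n")
  print(round(x$ani, digits))
  invisible(x)
}

#' Write an ANI matrix as TSV (strains x strains, percentages)
#'
#' @param m An [ani_matrix()] (or plain matrix).
#' @param path Output path.
#' @param digits Decimal places.
#' @export
write_ani_tsv <- function(m, path, digits = 2) {
  mat <- if (inherits(m, "ani_matrix")) m$ani else m
  tab <- data.frame(strain = rownames(mat), round(mat, digits),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pearson-correlation clustering of ANI profiles
#'
#' Each strain's profile is its row of the directional ANI matrix
#' (including the diagonal). Pearson correlation between profiles is
#' computed for every strain pair, and the strains are ordered and
#' optionally partitioned by hierarchical clustering on `1 - r`.
#'
#' @param m An [ani_matrix()] or plain numeric matrix.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @param k Number of clusters (optional).
#' @param h Height threshold on `1 - r` (optional, used if `k` is `NULL`).
#' @param pairwise_complete Allow `NA` cells, correlating over pairwise
#'   complete observations.
#' @return List of class `ani_correlation` with `corr`, `order`, `hclust`
#'   and `clusters` (or `NULL`), plus `degenerate` (strains with constant
#'   profiles whose correlations are undefined).
#' @export
correlation_clusters <- function(m, linkage = "complete", k = NULL, h = NULL,
                                 pairwise_complete = FALSE) {
  mat <- if (inherits(m, "ani_matrix")) m$ani else m
  if (any(is.na(mat)) && !pairwise_complete)
    stop("ANI matrix has undefined cells; set pairwise_complete = TRUE ",
         "or recompute")
  profiles <- t(mat)  # columns of t(mat) are the row-profiles
  sds <- apply(mat, 1, sd, na.rm = TRUE)
  degenerate <- rownames(mat)[sds == 0 | is.na(sds)]
  use <- if (pairwise_complete) "pairwise.complete.obs" else "everything"
  r <- suppressWarnings(cor(profiles, use = use))
  ok <- setdiff(rownames(mat), degenerate)
  if (length(ok) < 2L) stop("fewer than 2 strains with non-constant profiles")
  r_ok <- r[ok, ok]
  hc <- hclust(as.dist(1 - r_ok), method = linkage)
  clusters <- NULL
  if (!is.null(k)) clusters <- cutree(hc, k = k)
  else if (!is.null(h)) clusters <- cutree(hc, h = h)
  structure(list(corr = r, order = ok[hc$order], hclust = hc,
                 clusters = clusters, degenerate = degenerate,
                 linkage = linkage),
            class = "ani_correlation")
}

#' @export
print.ani_correlation <- function(x, ...) {
  cat("ani_correlation:", nrow(x$corr), "strains, linkage =", x$linkage, "\n")
  if (!is.null(x$clusters)) {
    cat("clusters:\n")
    print(split(names(x$clusters), x$clusters))
  }
  invisible(x)
}

#' Genome-BLAST distance formulas (GBDP style)
#'
#' Computes the whole-sequence-length distance formulas from a set of HSPs
#' (high-scoring pairs) between two genomes: `d0 = 1 - 2*sum(L)/(lq+ls)`,
#' `d4 = 1 - sum(id)/sum(L)` and `d6 = 1 - 2*sum(id)/(lq+ls)`, where `L` is
#' HSP alignment length and `id` the identity count. With no HSPs, `d0` and
#' `d6` are 1 and `d4` is undefined.
#'
#' @param hsps An `ani_pair` (its retained fragments are used) or a data
#'   frame with columns `columns` (alignment length) and `identities`.
#' @param len_q,len_s Total genome lengths of query and subject.
#' @return Object of class `gbdp_distances` with `d0`, `d4`, `d6`,
#'   `hsp_total_length`, `identity_total` and `genome_lengths`.
#' @export
gbdp_distances <- function(hsps, len_q, len_s) {
  if (inherits(hsps, "ani_pair"))
    hsps <- hsps$hsps[hsps$hsps$retained, , drop = FALSE]
  if (!all(c("columns", "identities") %in% names(hsps)))
    stop("hsps needs columns 'columns' and 'identities'")
  L <- sum(hsps$columns)
  id <- sum(hsps$identities)
  d0 <- max(0, min(1, 1 - 2 * L / (len_q + len_s)))
  d4 <- if (L == 0) NA_real_ else max(0, min(1, 1 - id / L))
  d6 <- max(0, min(1, 1 - 2 * id / (len_q + len_s)))
  structure(list(d0 = d0, d4 = d4, d6 = d6, hsp_total_length = L,
                 identity_total = id, genome_lengths = c(len_q, len_s)),
            class = "gbdp_distances")
}

#' Map a genome distance to a DDH estimate
#'
#' Applies a user-supplied logistic mapping `100 * plogis(intercept +
#' slope * d)` from a GBDP distance to a percent DNA-DNA hybridization
#' estimate. No default coefficients are shipped: the mapping is a fitted
#' model outside the scope of this package, so it must be provided
#' explicitly.
#'
#' @param d A distance in \[0, 1\].
#' @param mapping `list(intercept =, slope =)` of logistic coefficients.
#' @return Percent DDH estimate.
#' @export
ddh_estimate <- function(d, mapping = NULL) {
  if (is.null(mapping) || is.null(mapping$intercept) || is.null(mapping$slope))
    stop("ddh_estimate requires a user-supplied logistic mapping ",
         "(list(intercept =, slope =)); no default coefficients are shipped")
  100 * stats::plogis(mapping$intercept + mapping$slope * d)
}
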