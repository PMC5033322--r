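#' Align one gene family
#'
#' Multiple alignment of a family's nucleotide sequences. The default
#' backend is the external MAFFT aligner (deterministic given its inputs);
#' `method = "none"` accepts pre-aligned, equal-length input unchanged.
#'
#' @param family Named character vector of nucleotide sequences, or a family
#'   entry from a `core_gene_set` (its `nuc` component is used).
#' @param method `"mafft"` (default) or `"none"`.
#' @param family_id Optional family label carried on the result.
#' @return Named character vector of equal-length aligned rows (gap `-`),
#'   class `alignment`.
#' @export
align_family <- function(family, method = c("mafft", "none"),
                         family_id = NULL) {
  method <- match.arg(method)
  if (is.list(family) && !is.null(family$nuc)) {
    family_id <- family_id %||% family$gene_id
    family <- family$nuc
  }
  if (length(family) < 2L) stop("need at least 2 sequences to align")
  if (any(nchar(family) == 0L)) stop("empty sequence in family")
  if (method == "none") {
    if (length(unique(nchar(family))) != 1L)
      stop("method = 'none' requires equal-length (pre-aligned) sequences")
    aln <- toupper(family)
  } else {
    if (Sys.which("mafft") == "")
      stop("mafft not found on PATH; use method = 'none' for pre-aligned ",
           "input")
    fin <- tempfile(fileext = ".fasta")
    fout <- tempfile(fileext = ".fasta")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    write_fasta(family, fin)
    status <- system2("mafft", c("--quiet", "--nuc", "--retree", "2",
                                 "--maxiterate", "0", fin),
                      stdout = fout, stderr = FALSE)
    if (status != 0L) stop("mafft failed with status ", status)
    aln <- read_fasta(fout)[names(family)]
  }
  structure(aln, class = "alignment", family_id = family_id)
}

# strip gaps
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Concatenate per-family alignments into a supermatrix
#'
#' Columns are appended in the given family order; the partition map
#' records each family's column range (1-based, inclusive).
#'
#' @param alignments List of [align_family()] results (or named character
#'   vectors of equal-length rows). All must share one taxa set.
#' @return Object of class `supermatrix`: list with `seqs` (named character
#'   vector) and `partitions` (data frame `family_id`, `start`, `end`).
#' @export
concatenate_alignments <- function(alignments) {
  if (length(alignments) == 0L) stop("no alignments given")
  taxa <- names(alignments[[1]])
  for (i in seq_along(alignments)) {
    miss <- union(setdiff(taxa, names(alignments[[i]])),
                  setdiff(names(alignments[[i]]), taxa))
    if (length(miss) > 0L)
      stop("taxa mismatch in alignment ", i, ": ",
           paste(miss, collapse = ", "))
  }
  fam_ids <- vapply(seq_along(alignments), function(i)
    attr(alignments[[i]], "family_id") %||% names(alignments)[i] %||%
      paste0("family_", i), character(1))
  widths <- vapply(alignments, function(a) nchar(a[[1]]), numeric(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1
  seqs <- vapply(taxa, function(tx)
    paste(vapply(alignments, function(a) unname(a[[tx]]), character(1)),
          collapse = ""), character(1))
  structure(list(seqs = setNames(seqs, taxa),
                 partitions = data.frame(family_id = fam_ids,
                                         start = starts, end = ends,
                                         stringsAsFactors = FALSE)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("supermatrix:", length(x$seqs), "taxa,", nchar(x$seqs[[1]]),
      "columns,", nrow(x$partitions), "partitions\n")
  invisible(x)
}

sm_matrix <- function(sm) {
  do.call(rbind, strsplit(sm$seqs, ""))
}

matrix_to_sm <- function(mat, partitions) {
  seqs <- apply(mat, 1, paste, collapse = "")
  structure(list(seqs = setNames(seqs, rownames(mat)),
                 partitions = partitions), class = "supermatrix")
}

#' Trim a supermatrix to conserved blocks
#'
#' Conserved-block selection in the style of the classic Gblocks procedure.
#' With `n` taxa, a column is *conserved* when at least `is_min` (default
#' `floor(n/2) + 1`) rows share one residue, and *highly conserved* when at
#' least `fs_min` (default `ceiling(0.85 n)`) do. The procedure (default
#' mode) then:
#' \enumerate{
#'   \item removes every column containing a gap;
#'   \item removes runs of more than `cp` (default 8) contiguous
#'     nonconserved columns;
#'   \item trims each remaining block from both ends until its flanks are
#'     highly conserved;
#'   \item drops blocks shorter than `bl` (default 10) columns.
#' }
#' The partition map is updated; families losing all their columns are
#' dropped from it.
#'
#' @param sm A [concatenate_alignments()] supermatrix (or single
#'   `alignment`).
#' @param is_min,fs_min,cp,bl Threshold overrides (see above).
#' @return Trimmed `supermatrix` with attribute `kept_columns` (original
#'   column indices retained).
#' @export
trim_conserved_blocks <- function(sm, is_min = NULL, fs_min = NULL,
                                  cp = 8L, bl = 10L) {
  if (inherits(sm, "alignment"))
    sm <- concatenate_alignments(list(sm))
  mat <- sm_matrix(sm)
  n <- nrow(mat); L <- ncol(mat)
  if (L == 0L) stop("empty supermatrix")
  is_min <- is_min %||% (floor(n / 2) + 1L)
  fs_min <- fs_min %||% ceiling(0.85 * n)

  has_gap <- apply(mat, 2, function(col) any(col == "-"))
  max_count <- apply(mat, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0L) 0L else max(table(col))
  })
  status <- ifelse(has_gap | max_count < is_min, 0L,
                   ifelse(max_count >= fs_min, 2L, 1L))

  keep <- !has_gap
  # runs of > cp contiguous nonconserved columns among the kept sequence
  idx <- which(keep)
  if (length(idx) > 0L) {
    noncons <- status[idx] == 0L
    r <- rle(noncons)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values))
      if (r$values[k] && r$lengths[k] > cp)
        keep[idx[starts[k]:ends[k]]] <- FALSE
  }
  # blocks: retained columns contiguous in the original alignment
  idx <- which(keep)
  if (length(idx) > 0L) {
    block_id <- cumsum(c(1L, diff(idx) != 1L))
    for (b in unique(block_id)) {
      cols <- idx[block_id == b]
      # trim flanks to highly conserved ends
      while (length(cols) > 0L && status[cols[1]] != 2L) cols <- cols[-1]
      while (length(cols) > 0L && status[cols[length(cols)]] != 2L)
        cols <- cols[-length(cols)]
      drop <- setdiff(idx[block_id == b], cols)
      keep[drop] <- FALSE
      if (length(cols) > 0L && length(cols) < bl) keep[cols] <- FALSE
    }
  }

  kept <- which(keep)
  if (length(kept) == 0L) {
    warning("all columns removed by trimming")
    return(structure(list(seqs = setNames(rep("", n), rownames(mat)),
                          partitions = sm$partitions[0, ]),
                     class = "supermatrix", kept_columns = integer()))
  }
  newmat <- mat[, kept, drop = FALSE]
  rownames(newmat) <- names(sm$seqs)
  # updated partition map
  parts <- sm$partitions
  counts <- vapply(seq_len(nrow(parts)), function(i)
    sum(kept >= parts$start[i] & kept <= parts$end[i]), numeric(1))
  keep_fam <- counts > 0
  ends <- cumsum(counts[keep_fam])
  newparts <- data.frame(family_id = parts$family_id[keep_fam],
                         start = ends - counts[keep_fam] + 1,
                         end = ends, stringsAsFactors = FALSE)
  out <- matrix_to_sm(newmat, newparts)
  attr(out, "kept_columns") <- kept
  out
}

#' Pairwise genetic distances from an alignment
#'
#' Distances via the `ape` package with pairwise deletion of gapped or
#' ambiguous sites. Models: `"p"` (raw proportion of differing sites),
#' `"JC69"` (`-3/4 log(1 - 4p/3)`) and `"K80"` (default;
#' `-1/2 log(1-2P-Q) - 1/4 log(1-2Q)` with `P`, `Q` the transition and
#' transversion proportions). Non-estimable distances (logarithm of a
#' non-positive number) come back as `NaN` and are flagged.
#'
#' @param aln An `alignment`, `supermatrix`, or named character vector of
#'   equal-length sequences.
#' @param model `"K80"`, `"JC69"` or `"p"`.
#' @return Symmetric numeric matrix with zero diagonal, attribute `model`;
#'   attribute `flagged` lists pairs with undefined distances.
#' @export
genetic_distance <- function(aln, model = c("K80", "JC69", "p")) {
  model <- match.arg(model)
  seqs <- if (inherits(aln, "supermatrix")) aln$seqs else unclass(aln)
  if (length(seqs) < 2L) stop("need at least 2 taxa")
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must be aligned (equal length)")
  mat <- do.call(rbind, strsplit(tolower(seqs), ""))
  rownames(mat) <- names(seqs)
  bin <- ape::as.DNAbin(mat)
  ape_model <- c(p = "raw", JC69 = "JC69", K80 = "K80")[[model]]
  d <- as.matrix(ape::dist.dna(bin, model = ape_model,
                               pairwise.deletion = TRUE))
  bad <- which(!is.finite(d) & upper.tri(d), arr.ind = TRUE)
  flagged <- if (nrow(bad) > 0L)
    data.frame(a = rownames(d)[bad[, 1]], b = colnames(d)[bad[, 2]],
               stringsAsFactors = FALSE)
  else NULL
  attr(d, "model") <- model
  attr(d, "flagged") <- flagged
  d
}

#' Neighbor-joining tree with column bootstrap
#'
#' Neighbor joining (Saitou-Nei criterion, via `ape::nj`) on the model
#' distance matrix of the supermatrix; negative branch lengths are clamped
#' to zero. Support values are the percentage of column-resampled replicates
#' containing each internal bipartition, stored as internal node labels.
#'
#' @param sm A `supermatrix` (or `alignment`).
#' @param model Distance model, see [genetic_distance()].
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for resampling.
#' @return An `ape::phylo` tree; internal node labels hold bootstrap
#'   percentages (root label empty).
#' @export
nj_tree_with_bootstrap <- function(sm, model = "K80", n_boot = 1000L,
                                   seed = 1L) {
  seqs <- if (inherits(sm, "supermatrix")) sm$seqs else unclass(sm)
  if (length(seqs) < 4L) stop("need at least 4 taxa")
  d <- genetic_distance(seqs, model = model)
  if (any(!is.finite(d)))
    stop("distance matrix has undefined entries under model ", model,
         "; consider model = 'p'")
  tree <- ape::nj(as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0

  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  set.seed(seed)
  boots <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    db <- genetic_distance(apply(mat[, cols, drop = FALSE], 1, paste,
                                 collapse = ""), model = model)
    if (any(!is.finite(db))) db[!is.finite(db)] <- max(db[is.finite(db)])
    tb <- ape::nj(as.dist(db))
    tb$edge.length[tb$edge.length < 0] <- 0
    boots[[b]] <- tb
  }
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_boot)
  support[1] <- NA  # root of the unrooted representation
  tree$node.label <- ifelse(is.na(support), "", as.character(support))
  attr(tree, "n_boot") <- n_boot
  attr(tree, "model") <- model
  tree
}

#' Write a supermatrix as relaxed PHYLIP
#' @param sm A `supermatrix`.
#' @param path Output path.
#' @export
write_phylip <- function(sm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(sm$seqs), nchar(sm$seqs[[1]])), con)
  writeLines(sprintf("%s  %s", names(sm$seqs), sm$seqs), con)
  invisible(path)
}

#' Write a RAxML-style partition file (1-based inclusive ranges)
#' @param sm A `supermatrix`.
#' @param path Output path.
#' @export
write_partitions <- function(sm, path) {
  writeLines(sprintf("DNA, %s = %d-%d", sm$partitions$family_id,
                     sm$partitions$start, sm$partitions$end), path)
  invisible(path)
}
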