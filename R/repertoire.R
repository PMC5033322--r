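#' Assign proteins to orthogroups by Markov clustering
#'
#' Builds the all-vs-all protein similarity graph (e-value at most
#' `e_cutoff`; edge weight `-log10(e)` capped at 300, weights normalized per
#' strain pair by their mean, in the OrthoMCL manner) and partitions it by
#' Markov clustering: column-normalize, then iterate expansion (matrix
#' squaring) and inflation (element-wise power, renormalize) to convergence.
#' When a strain contributes several members to one group, the member with
#' the lowest e-value against the rest of the group is marked as the
#' representative. Proteins with no edges become singleton groups.
#'
#' @param proteomes Named list (strain -> named character vector of
#'   proteins).
#' @param e_cutoff E-value cutoff (default 1e-5).
#' @param inflation MCL inflation parameter (default 1.5).
#' @param max_iter,tol Convergence controls.
#' @return Data frame of class `orthogroups`: `protein_id` (strain|gene),
#'   `strain`, `gene`, `group`, `representative`.
#' @export
assign_orthogroups <- function(proteomes, e_cutoff = 1e-5, inflation = 1.5,
                               max_iter = 100L, tol = 1e-6) {
  if (length(proteomes) < 2L) stop("need at least 2 proteomes")
  if (is.null(names(proteomes))) stop("proteomes must be named by strain")
  strains <- rep(names(proteomes), lengths(proteomes))
  genes <- unlist(lapply(proteomes, names), use.names = FALSE)
  seqs <- unlist(proteomes, use.names = FALSE)
  pid <- paste(strains, genes, sep = "|")
  n <- length(pid)

  hits <- search_all(setNames(seqs, pid), setNames(seqs, pid), e_cutoff)
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  W <- matrix(0, n, n, dimnames = list(pid, pid))
  E <- matrix(NA_real_, n, n, dimnames = list(pid, pid))  # e-values
  if (nrow(hits) > 0L) {
    w <- pmin(300, -log10(pmax(hits$e_value, 1e-300)))
    qi <- match(hits$query_id, pid); si <- match(hits$subject_id, pid)
    W[cbind(qi, si)] <- w
    E[cbind(qi, si)] <- hits$e_value
    W <- pmax(W, t(W))  # symmetrize
    # per strain-pair mean normalization
    sp_q <- strains[row(W)]; sp_s <- strains[col(W)]
    pair_key <- ifelse(sp_q <= sp_s, paste(sp_q, sp_s), paste(sp_s, sp_q))
    nz <- W > 0
    if (any(nz)) {
      means <- tapply(W[nz], pair_key[nz], mean)
      W[nz] <- W[nz] / means[pair_key[nz]]
    }
  }

  connected <- which(rowSums(W) > 0)
  groups <- rep(NA_character_, n)
  if (length(connected) > 0L) {
    M <- W[connected, connected, drop = FALSE]
    diag(M) <- 1  # self loops, standard MCL initialization
    normalize <- function(m) sweep(m, 2, pmax(colSums(m), .Machine$double.eps),
                                   "/")
    M <- normalize(M)
    for (it in seq_len(max_iter)) {
      M2 <- M %*% M              # expansion
      M2 <- normalize(M2^inflation)  # inflation
      M2[M2 < 1e-12] <- 0
      M2 <- normalize(M2)
      if (max(abs(M2 - M)) < tol) { M <- M2; break }
      M <- M2
    }
    # clusters: connected components over the attractor structure
    adj <- (M > 1e-8) | (t(M) > 1e-8)
    comp <- components_of(adj)
    groups[connected] <- paste0("c", comp)
  }
  # singletons
  lone <- which(is.na(groups))
  groups[lone] <- paste0("s", seq_along(lone))
  # stable group naming by first member in input order
  first <- tapply(seq_len(n), groups, min)
  relabel <- setNames(sprintf("OG%04d", rank(first, ties.method = "first")),
                      names(first))
  groups <- unname(relabel[groups])

  out <- data.frame(protein_id = pid, strain = strains, gene = genes,
                    group = groups, representative = TRUE,
                    stringsAsFactors = FALSE)
  # representative per (strain, group): lowest e-value to the group
  for (g in unique(out$group[duplicated(paste(out$strain, out$group))])) {
    members <- which(out$group == g)
    for (s in unique(out$strain[members])) {
      mine <- members[out$strain[members] == s]
      if (length(mine) < 2L) next
      others <- setdiff(members, mine)
      best_e <- vapply(mine, function(i) {
        e <- E[i, others]
        if (all(is.na(e))) Inf else min(e, na.rm = TRUE)
      }, numeric(1))
      out$representative[mine] <- FALSE
      out$representative[mine[which.min(best_e)]] <- TRUE
    }
  }
  class(out) <- c("orthogroups", "data.frame")
  out
}

# connected components of a logical adjacency matrix (union-find)
components_of <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i, parent) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in which(adj[i, ])) {
    ri <- find(i, parent); rj <- find(j, parent)
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), function(i) find(i, parent), integer(1))
  match(roots, unique(roots))
}

#' Build a binary function matrix from orthogroups
#'
#' One function column per multi-protein orthogroup. Singleton proteins are
#' matched against an optional annotated fallback database (best hit under
#' `fallback_e`) and inherit that function id; otherwise they become
#' singleton functions. The two namespaces are kept apart via the
#' provenance table (orthogroup | best_hit | singleton). A cell is 1 iff the
#' strain has at least one member.
#'
#' @param groups An [assign_orthogroups()] result.
#' @param proteomes The proteomes used (needed to look up singleton
#'   sequences when a fallback database is supplied).
#' @param fallback_db Optional named character vector of annotated proteins.
#' @param fallback_e E-value cutoff for the fallback search (default 1e-5).
#' @return Binary matrix (strains x functions) of class `function_matrix`
#'   with a `provenance` attribute.
#' @export
build_function_matrix <- function(groups, proteomes = NULL,
                                  fallback_db = NULL, fallback_e = 1e-5) {
  stopifnot(inherits(groups, "orthogroups"))
  strains <- unique(groups$strain)
  size <- table(groups$group)
  multi <- names(size)[size > 1L]
  single <- names(size)[size == 1L]

  fun_of <- setNames(groups$group, groups$protein_id)  # default: own group
  prov <- setNames(rep("orthogroup", length(multi)), multi)
  if (length(single) > 0L) {
    for (g in single) {
      p <- groups$protein_id[groups$group == g]
      assigned <- FALSE
      if (!is.null(fallback_db) && !is.null(proteomes)) {
        seq <- proteomes[[groups$strain[groups$group == g]]][[
          groups$gene[groups$group == g]]]
        hit <- best_hits(search_all(setNames(seq, p), fallback_db,
                                    fallback_e))
        if (nrow(hit) == 1L) {
          fun_of[p] <- paste0("DB:", hit$subject_id)
          prov[paste0("DB:", hit$subject_id)] <- "best_hit"
          assigned <- TRUE
        }
      }
      if (!assigned) prov[g] <- "singleton"
    }
  }
  funs <- sort(unique(unname(fun_of)))
  m <- matrix(0L, length(strains), length(funs),
              dimnames = list(strains, funs))
  idx <- cbind(match(groups$strain, strains),
               match(fun_of[groups$protein_id], funs))
  m[idx] <- 1L
  stopifnot(all(colSums(m) > 0L))
  structure(m, class = c("function_matrix", class(m)),
            provenance = data.frame(function_id = funs,
                                    provenance = unname(prov[funs]),
                                    stringsAsFactors = FALSE))
}

#' Core / pan / private function counts
#'
#' For each named strain subset: `core` counts functions present in every
#' subset member; `private` counts functions absent from every strain
#' outside the subset. `pan` is the number of functions present in at least
#' one strain overall.
#'
#' @param m A `function_matrix`.
#' @param subsets Named list of strain id vectors (default: one subset with
#'   all strains).
#' @return List with `pan` and a data frame `counts` (`subset`, `core`,
#'   `private`).
#' @export
function_set_counts <- function(m, subsets = NULL) {
  strains <- rownames(m)
  if (is.null(subsets)) subsets <- list(all = strains)
  counts <- lapply(names(subsets), function(nm) {
    ss <- subsets[[nm]]
    if (length(ss) == 0L) stop("empty subset: ", nm)
    if (!all(ss %in% strains))
      stop("unknown strain(s) in subset ", nm, ": ",
           paste(setdiff(ss, strains), collapse = ", "))
    inside <- m[ss, , drop = FALSE]
    outside <- m[setdiff(strains, ss), , drop = FALSE]
    data.frame(subset = nm,
               core = sum(colSums(inside) == length(ss)),
               private = if (nrow(outside) == 0L) sum(colSums(inside) > 0L)
                         else sum(colSums(outside) == 0L &
                                  colSums(inside) > 0L),
               stringsAsFactors = FALSE)
  })
  list(pan = sum(colSums(m) > 0L), counts = do.call(rbind, counts))
}

#' Cluster function repertoires (UPGMA on Manhattan distance)
#'
#' Manhattan distance between binary strain profiles (equal to the Hamming
#' count), average-linkage merging, and per-cluster bootstrap probabilities:
#' the percentage of column-resampled replicates in which the identical
#' strain set reappears as a cluster.
#'
#' @param m A `function_matrix` (strains x functions, 0/1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for resampling.
#' @return Object of class `repertoire_dendrogram`: list with `hclust`,
#'   `bp` (per-merge bootstrap percentages) and settings.
#' @export
cluster_repertoire <- function(m, n_boot = 1000L, seed = 1L) {
  if (nrow(m) < 3L) stop("need at least 3 strains")
  hc <- hclust(dist(m, method = "manhattan"), method = "average")
  orig <- cluster_sets(hc)
  counts <- numeric(length(orig))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    hb <- hclust(dist(m[, cols, drop = FALSE], method = "manhattan"),
                 method = "average")
    bs <- cluster_sets(hb)
    keys <- vapply(bs, paste, character(1), collapse = "\r")
    counts <- counts + (vapply(orig, paste, character(1), collapse = "\r")
                        %in% keys)
  }
  structure(list(hclust = hc, bp = round(100 * counts / n_boot),
                 dist_method = "manhattan", linkage = "average",
                 n_boot = n_boot, seed = seed),
            class = "repertoire_dendrogram")
}

# leaf sets of each internal merge of an hclust, sorted for comparison
cluster_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    leaves <- c(
      if (kids[1] < 0) hc$labels[-kids[1]] else sets[[kids[1]]],
      if (kids[2] < 0) hc$labels[-kids[2]] else sets[[kids[2]]])
    sets[[i]] <- sort(leaves)
  }
  sets
}

#' @export
print.repertoire_dendrogram <- function(x, ...) {
  cat("repertoire_dendrogram:", length(x$hclust$labels),
      "strains (Manhattan / average linkage,", x$n_boot,
      "bootstrap replicates)\n")
  invisible(x)
}

as_phylo_any <- function(x) {
  if (inherits(x, "repertoire_dendrogram")) return(ape::as.phylo(x$hclust))
  if (inherits(x, "hclust")) return(ape::as.phylo(x))
  if (inherits(x, "phylo")) return(x)
  stop("cannot interpret input as a tree/dendrogram")
}

cophenetic_any <- function(x) {
  if (inherits(x, "repertoire_dendrogram"))
    return(as.matrix(cophenetic(x$hclust)))
  if (inherits(x, "hclust")) return(as.matrix(cophenetic(x)))
  if (inherits(x, "phylo")) return(ape::cophenetic.phylo(x))
  stop("cannot interpret input as a tree/dendrogram")
}

entanglement_of <- function(o1, o2) {
  n <- length(o1)
  pos2 <- match(o1, o2)
  worst <- sum(abs(seq_len(n) - rev(seq_len(n))))
  if (worst == 0) return(0)
  sum(abs(seq_len(n) - pos2)) / worst
}

# nested-list (topology-only) view of a phylo tree, for safe rotations
as_nested <- function(tr) {
  n_tip <- length(tr$tip.label)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  rec <- function(node) {
    if (node <= n_tip) return(tr$tip.label[node])
    lapply(kids[[as.character(node)]], rec)
  }
  rec(n_tip + 1L)
}

nested_leaves <- function(x) {
  if (is.character(x)) x else unlist(lapply(x, nested_leaves))
}

# one-sided untangling pass: reorder every node's children by the mean
# position of their tips in the other tree's current leaf order (the
# standard "step" rotation heuristic)
order_nested <- function(x, target) {
  if (is.character(x)) return(x)
  kids <- lapply(x, order_nested, target = target)
  pos <- vapply(kids, function(k) mean(target[nested_leaves(k)]), numeric(1))
  kids[order(pos)]
}

nested_paths <- function(x, prefix = integer()) {
  if (is.character(x)) return(list())
  c(list(prefix),
    unlist(lapply(seq_along(x), function(i)
      nested_paths(x[[i]], c(prefix, i))), recursive = FALSE))
}

flip_at <- function(x, path) {
  if (length(path) == 0L) return(rev(x))
  x[[path[1]]] <- flip_at(x[[path[1]]], path[-1])
  x
}

# greedy sweep: reverse any node's children if that strictly lowers the
# entanglement against the fixed other-side leaf order (resolves ties the
# mean-position ordering cannot)
greedy_nested <- function(x, other_order) {
  best <- entanglement_of(nested_leaves(x), other_order)
  for (path in nested_paths(x)) {
    cand <- flip_at(x, path)
    e <- entanglement_of(nested_leaves(cand), other_order)
    if (e < best - 1e-12) { x <- cand; best <- e }
  }
  x
}

# depth (edges from root) of every node of a phylo
node_depths <- function(tr) {
  n_node <- length(tr$tip.label) + tr$Nnode
  depth <- rep(NA_real_, n_node)
  root <- length(tr$tip.label) + 1L
  depth[root] <- 0
  tr <- ape::reorder.phylo(tr, "cladewise")
  for (k in seq_len(nrow(tr$edge)))
    depth[tr$edge[k, 2]] <- depth[tr$edge[k, 1]] + 1
  depth
}

#' Compare phylogenomic and functional dendrograms
#'
#' Computes the cophenetic correlation (Pearson r between the two
#' cophenetic-distance vectors over leaf pairs), Baker's gamma (Spearman
#' rank correlation of the depths of each leaf pair's lowest common
#' ancestor), the entanglement of the tanglegram after a two-sided
#' alternating rotation heuristic, and the list of discordant strains:
#' leaves whose `k` nearest neighbours (by cophenetic distance, ties broken
#' by label) differ between the two trees, ranked by neighbourhood overlap
#' (the top discordant strain is the ecotype candidate).
#'
#' @param d_phylo,d_func Trees/dendrograms over the same leaves: `phylo`,
#'   `hclust` or [cluster_repertoire()] objects.
#' @param k Neighbourhood size for the discordance detector (default 3).
#' @param passes Untangling passes per side (default 2).
#' @return Object of class `dendrogram_comparison` with
#'   `cophenetic_correlation`, `bakers_gamma`, `entanglement` and
#'   `discordant` (data frame `strain`, `overlap`, `discordant`, sorted most
#'   discordant first).
#' @export
compare_dendrograms <- function(d_phylo, d_func, k = 3L, passes = 2L) {
  c1 <- cophenetic_any(d_phylo)
  c2 <- cophenetic_any(d_func)
  leaves <- sort(rownames(c1))
  if (!setequal(rownames(c1), rownames(c2)))
    stop("leaf sets differ: ",
         paste(union(setdiff(rownames(c1), rownames(c2)),
                     setdiff(rownames(c2), rownames(c1))), collapse = ", "))
  c1 <- c1[leaves, leaves]; c2 <- c2[leaves, leaves]
  lower <- lower.tri(c1)
  # a flat dendrogram (all pairwise cophenetic distances equal) has no
  # dispersion to correlate against; report NA rather than warn
  coph_r <- if (sd(c1[lower]) == 0 || sd(c2[lower]) == 0) NA_real_
            else cor(c1[lower], c2[lower])

  t1 <- as_phylo_any(d_phylo); t2 <- as_phylo_any(d_func)
  # Baker's gamma from LCA depths
  gamma <- {
    g1 <- lca_depth_vector(t1, leaves)
    g2 <- lca_depth_vector(t2, leaves)
    suppressWarnings(cor(g1, g2, method = "spearman"))
  }
  # entanglement after alternating two-sided untangling
  n1 <- as_nested(t1); n2 <- as_nested(t2)
  # canonical initialization: ladderize both sides to the sorted leaf
  # order, so ties broken differently by the two clusterings start aligned
  canon <- setNames(seq_along(leaves), sort(leaves))
  n1 <- order_nested(n1, canon)
  n2 <- order_nested(n2, canon)
  ent <- entanglement_of(nested_leaves(n1), nested_leaves(n2))
  for (p in seq_len(max(passes, 2L))) {
    o2 <- nested_leaves(n2)
    n1 <- order_nested(n1, setNames(seq_along(o2), o2))
    n1 <- greedy_nested(n1, o2)
    o1 <- nested_leaves(n1)
    n2 <- order_nested(n2, setNames(seq_along(o1), o1))
    n2 <- greedy_nested(n2, o1)
    new_ent <- entanglement_of(nested_leaves(n1), nested_leaves(n2))
    if (new_ent >= ent - 1e-12) { ent <- min(ent, new_ent); break }
    ent <- new_ent
  }

  # ties in cophenetic distance broken by label order for determinism
  nn_sets1 <- lapply(leaves, function(l) {
    d <- c1[l, setdiff(leaves, l)]
    ord <- order(d, names(d))
    names(d)[ord][seq_len(min(k, length(d)))]
  })
  nn_sets2 <- lapply(leaves, function(l) {
    d <- c2[l, setdiff(leaves, l)]
    ord <- order(d, names(d))
    names(d)[ord][seq_len(min(k, length(d)))]
  })
  overlap <- vapply(seq_along(leaves), function(i)
    length(intersect(nn_sets1[[i]], nn_sets2[[i]])) / k, numeric(1))
  disc <- data.frame(strain = leaves, overlap = overlap,
                     discordant = overlap < 1, stringsAsFactors = FALSE)
  disc <- disc[order(disc$overlap, disc$strain), ]
  rownames(disc) <- NULL
  structure(list(cophenetic_correlation = coph_r, bakers_gamma = gamma,
                 entanglement = ent, discordant = disc,
                 trees = list(t1, t2)),
            class = "dendrogram_comparison")
}

lca_depth_vector <- function(tr, leaves) {
  depth <- node_depths(tr)
  lca <- ape::mrca(tr)
  lca <- lca[leaves, leaves]
  depth[lca[lower.tri(lca)]]
}

#' @export
print.dendrogram_comparison <- function(x, ...) {
  cat(sprintf(paste0("dendrogram_comparison: cophenetic r = %.3f, ",
                     "Baker's gamma = %.3f, entanglement = %.3f\n"),
              x$cophenetic_correlation, x$bakers_gamma, x$entanglement))
  d <- x$discordant[x$discordant$discordant, ]
  if (nrow(d) > 0L)
    cat("discordant strains:", paste(d$strain, collapse = ", "), "\n")
  else cat("no discordant strains\n")
  invisible(x)
}

#' Write a function matrix as TSV
#' @param m A `function_matrix`.
#' @param path Output path.
#' @export
write_function_matrix <- function(m, path) {
  tab <- data.frame(strain = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
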