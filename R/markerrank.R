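#' Build the gene-distance feature table
#'
#' For each row strain `s`, core gene `g` and reference organism `o`, the
#' feature `v(g, o)` is the genetic distance between `s`'s copy of `g` and
#' `o`'s copy, so the table has exactly `G x O` columns (genes-major,
#' organisms-minor; names `gene|organism`). Distances to the strain itself
#' are zero for reference rows.
#'
#' @param core A `core_gene_set` (families must be aligned, or set
#'   `align = TRUE` to align them with MAFFT first). A named list of aligned
#'   families (named character vectors) is also accepted.
#' @param organisms Reference organism ids (columns); default all strains in
#'   `core`.
#' @param model Distance model (see [genetic_distance()]); stamped into the
#'   result.
#' @param rows Row strain ids; default all strains in `core`.
#' @param align Align families with [align_family()] when their sequences
#'   have unequal lengths.
#' @return Numeric matrix of class `feature_table` with attributes `genes`,
#'   `organisms`, `model`.
#' @export
build_feature_table <- function(core, organisms = NULL, model = "K80",
                                rows = NULL, align = FALSE) {
  fams <- family_alignments(core, align)
  strains <- names(fams[[1]])
  organisms <- organisms %||% strains
  rows <- rows %||% strains
  genes <- names(fams)
  cols <- as.vector(t(outer(genes, organisms, paste, sep = "|")))
  ft <- matrix(NA_real_, length(rows), length(genes) * length(organisms),
               dimnames = list(rows, cols))
  for (g in genes) {
    d <- genetic_distance(fams[[g]], model = model)
    ft[, paste(g, organisms, sep = "|")] <- d[rows, organisms]
  }
  structure(ft, class = c("feature_table", class(ft)), genes = genes,
            organisms = organisms, model = model)
}

# normalize a core_gene_set / list of families into aligned named vectors
family_alignments <- function(core, align = FALSE) {
  fams <- if (inherits(core, "core_gene_set"))
    lapply(core$families, `[[`, "nuc")
  else core
  if (length(fams) == 0L) stop("no gene families")
  out <- lapply(names(fams), function(g) {
    f <- fams[[g]]
    if (length(unique(nchar(f))) != 1L) {
      if (!align)
        stop("family ", g, " is not aligned; set align = TRUE")
      f <- align_family(f, family_id = g)
    }
    f
  })
  names(out) <- names(fams)
  out
}

#' Per-gene distance statistics
#'
#' Mean, variance and maximum of the genetic distances over all unordered
#' strain pairs of each gene family. The variance is the sample variance
#' (denominator `n - 1` over the pair distances).
#'
#' @inheritParams build_feature_table
#' @return Data frame `gene`, `mean`, `variance`, `maximum`.
#' @export
gene_distance_stats <- function(core, model = "K80", align = FALSE) {
  fams <- family_alignments(core, align)
  rows <- lapply(names(fams), function(g) {
    d <- genetic_distance(fams[[g]], model = model)
    v <- d[lower.tri(d)]
    data.frame(gene = g, mean = mean(v), variance = var(v), maximum = max(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

gene_of_column <- function(cols) sub("\\|.*$", "", cols)

#' Train the random-forest species classifier
#'
#' Bagged classification trees with majority vote and out-of-bag
#' permutation importance (mean decrease in accuracy), trained on the
#' training rows of the feature table only. Gene-level importance
#' aggregates each gene's per-organism variable importances (mean by
#' default; sum and max selectable). Deterministic under `seed`.
#'
#' @param ft A [build_feature_table()] result.
#' @param labels Named character vector mapping strain id to species.
#' @param train_rows Strain ids used for training.
#' @param n_trees Number of trees (default 100000).
#' @param seed RNG seed (default 12345).
#' @param mtry Variables tried per split; default `floor(sqrt(ncol(ft)))`.
#' @param aggregate Gene-level aggregation of variable importances.
#' @return Object of class `species_forest` with the fitted forest,
#'   per-variable and per-gene importances, and the training configuration.
#' @export
train_species_forest <- function(ft, labels, train_rows,
                                 n_trees = 100000L, seed = 12345L,
                                 mtry = NULL,
                                 aggregate = c("mean", "sum", "max")) {
  aggregate <- match.arg(aggregate)
  if (!all(train_rows %in% rownames(ft)))
    stop("train rows missing from feature table")
  y <- factor(labels[train_rows])
  if (nlevels(y) < 2L) stop("training rows span a single class")
  x <- ft[train_rows, , drop = FALSE]
  if (any(is.na(x))) stop("training features contain missing values")
  # constant (zero-variance) variables carry no training signal: they get
  # importance 0 and are withheld from the forest. A table with no varying
  # variable at all yields a degenerate majority-vote model.
  varying <- colnames(x)[apply(x, 2, function(col) var(col) > 0)]
  var_imp <- setNames(rep(0, ncol(ft)), colnames(ft))
  agg_fun <- switch(aggregate, mean = mean, sum = sum, max = max)
  if (length(varying) == 0L) {
    tab <- sort(table(y), decreasing = TRUE)
    majority <- sort(names(tab)[tab == max(tab)])[1]
    gene_imp <- tapply(var_imp, gene_of_column(names(var_imp)), agg_fun)
    gene_imp <- gene_imp[unique(gene_of_column(colnames(ft)))]
    return(structure(list(rf = NULL, degenerate = TRUE, majority = majority,
                          var_importance = var_imp,
                          gene_importance = gene_imp, varying = varying,
                          classes = levels(y), train_rows = train_rows,
                          config = list(n_trees = n_trees, seed = seed,
                                        mtry = NA_integer_,
                                        aggregate = aggregate)),
                     class = "species_forest"))
  }
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  mtry <- min(mtry, length(varying))
  set.seed(seed)
  rf <- randomForest::randomForest(x = x[, varying, drop = FALSE], y = y,
                                   ntree = n_trees, mtry = mtry,
                                   importance = TRUE)
  var_imp[varying] <- rf$importance[, "MeanDecreaseAccuracy"]
  gene_imp <- tapply(var_imp, gene_of_column(names(var_imp)), agg_fun)
  gene_imp <- gene_imp[unique(gene_of_column(colnames(ft)))]
  structure(list(rf = rf, degenerate = FALSE, majority = NULL,
                 var_importance = var_imp, gene_importance = gene_imp,
                 varying = varying,
                 classes = levels(y), train_rows = train_rows,
                 config = list(n_trees = n_trees, seed = seed, mtry = mtry,
                               aggregate = aggregate)),
            class = "species_forest")
}

#' @export
print.species_forest <- function(x, ...) {
  cat("species_forest:", x$config$n_trees, "trees, mtry =", x$config$mtry,
      ", classes:", paste(x$classes, collapse = ", "), "\n")
  top <- head(sort(x$gene_importance, decreasing = TRUE), 5)
  cat("top genes by importance:",
      paste(sprintf("%s (%.4f)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a species forest on a test set
#'
#' @param model A [train_species_forest()] result.
#' @param ft The feature table (same columns as at training).
#' @param test_rows Strain ids to predict.
#' @param truth Named character vector of true species for the test rows.
#' @return List with `confusion` (truth x predicted table over the union of
#'   classes), `misclassification_rate` and `predictions`.
#' @export
evaluate_forest <- function(model, ft, test_rows, truth) {
  if (length(test_rows) == 0L) stop("empty test set")
  if (!all(test_rows %in% rownames(ft)))
    stop("test rows missing from feature table")
  pred <- if (isTRUE(model$degenerate))
    rep(model$majority, length(test_rows))
  else predict(model$rf, ft[test_rows, model$varying, drop = FALSE])
  truth_v <- truth[test_rows]
  classes <- union(model$classes, unique(truth_v))
  confusion <- table(truth = factor(truth_v, levels = classes),
                     predicted = factor(as.character(pred),
                                        levels = classes))
  list(confusion = confusion,
       misclassification_rate = mean(as.character(pred) != truth_v),
       predictions = setNames(as.character(pred), test_rows))
}

#' Per-gene single-marker error rates
#'
#' For each gene, a fresh forest is trained on that gene's per-organism
#' distance columns only (same training rows and seed) and its test-set
#' misclassification rate recorded.
#'
#' @inheritParams train_species_forest
#' @param test_rows,truth Test strain ids and their true species.
#' @return Data frame `gene`, `error_rate`.
#' @export
per_gene_error_rates <- function(ft, labels, train_rows, test_rows,
                                 truth = labels, n_trees = 100000L,
                                 seed = 12345L) {
  genes <- unique(gene_of_column(colnames(ft)))
  rates <- vapply(genes, function(g) {
    cols <- which(gene_of_column(colnames(ft)) == g)
    sub <- ft[, cols, drop = FALSE]
    m <- train_species_forest(sub, labels, train_rows, n_trees = n_trees,
                              seed = seed,
                              mtry = max(1L, floor(sqrt(length(cols)))))
    evaluate_forest(m, sub, test_rows, truth)$misclassification_rate
  }, numeric(1))
  data.frame(gene = genes, error_rate = unname(rates),
             stringsAsFactors = FALSE)
}

#' Rank genes as phylogenetic markers
#'
#' Orders genes by random-forest importance (descending), breaking ties by
#' lower single-gene error rate, then higher distance mean, then gene id.
#'
#' @param stats A [gene_distance_stats()] data frame.
#' @param forest A [train_species_forest()] model (source of gene
#'   importances), or a named numeric vector of gene importances.
#' @param error_rates Optional [per_gene_error_rates()] data frame.
#' @return Data frame of class `gene_ranking`: `rank`, `gene`, `mean`,
#'   `variance`, `maximum`, `importance`, `error_rate`.
#' @export
rank_genes <- function(stats, forest, error_rates = NULL) {
  imp <- if (inherits(forest, "species_forest")) forest$gene_importance
         else forest
  tab <- stats
  tab$importance <- as.numeric(imp[tab$gene])
  tab$error_rate <- if (!is.null(error_rates))
    error_rates$error_rate[match(tab$gene, error_rates$gene)]
  else NA_real_
  err_key <- ifelse(is.na(tab$error_rate), Inf, tab$error_rate)
  ord <- order(-tab$importance, err_key, -tab$mean, tab$gene)
  tab <- tab[ord, c("gene", "mean", "variance", "maximum", "importance",
                    "error_rate")]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  class(tab) <- c("gene_ranking", "data.frame")
  tab
}

#' Write a gene ranking as TSV
#' @param ranking A `gene_ranking`.
#' @param path Output path.
#' @export
write_gene_ranking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
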