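#' Pipeline configuration
#'
#' Collects every stage's parameters with defaults matching the published
#' study settings (ANIb 1020-nt fragments, core-gene e-value 1e-30,
#' orthogroup e-value 1e-5, 100000 trees with forest seed 12345, 0.95
#' ellipse level). Any field can be overridden via the `...` stage lists;
#' the master `seed` drives every stochastic stage (stage seeds are derived
#' from it deterministically).
#'
#' @param stages Character vector of stages to run, a subset of
#'   `c("ani", "core", "mlsa", "repertoire", "rank", "classify")`.
#' @param seed Master seed.
#' @param ani,core,mlsa,repertoire,rank,classify Named lists overriding
#'   stage parameters.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("ani", "core", "mlsa", "repertoire",
                                       "rank", "classify"),
                            seed = 1L, ani = list(), core = list(),
                            mlsa = list(), repertoire = list(),
                            rank = list(), classify = list()) {
  all_stages <- c("ani", "core", "mlsa", "repertoire", "rank", "classify")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  defaults <- list(
    ani = list(fragment_length = 1020L, min_identity_pct = 30,
               min_fragment_coverage = 0.70, linkage = "complete", k = NULL),
    core = list(e_cutoff = 1e-30, scope = "all", reference = NULL),
    mlsa = list(model = "K80", trim = TRUE, n_boot = 100L),
    repertoire = list(e_cutoff = 1e-5, inflation = 1.5, n_boot = 100L,
                      k_nn = 3L),
    rank = list(model = "K80", n_trees = 100000L, forest_seed = 12345L,
                aggregate = "mean", per_gene = TRUE),
    classify = list(marker = NULL, level = 0.95, variables = "all",
                    model = "K80"))
  merge1 <- function(def, ovr) { def[names(ovr)] <- ovr; def }
  cfg <- list(stages = stages, seed = as.integer(seed),
              ani = merge1(defaults$ani, ani),
              core = merge1(defaults$core, core),
              mlsa = merge1(defaults$mlsa, mlsa),
              repertoire = merge1(defaults$repertoire, repertoire),
              rank = merge1(defaults$rank, rank),
              classify = merge1(defaults$classify, classify))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file path.
#' @return For `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(unclass(cfg)), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

#' Run the circumscription pipeline end-to-end
#'
#' Executes the enabled stages in dependency order: (i) ANI matrix and
#' correlation clusters, (ii) reciprocal-best-hit core genes, (iii)
#' core-gene supermatrix, trimming and NJ tree with bootstrap, (iv)
#' orthogroup function matrix, repertoire dendrogram and
#' phylogenomic/functional comparison with discordant (ecotype-candidate)
#' strains, (v) random-forest gene ranking with test-set confusion, (vi)
#' marker-gene PCA classification with outclass detection. A stage failure
#' is recorded and its dependents are skipped; the bundle is stamped with
#' the configuration hash and seed.
#'
#' @param set A [strain_set()]; strain roles drive the train/test split and
#'   `query` strains are the ones classified against the references.
#' @param cfg A [pipeline_config()].
#' @return Object of class `circumscription_report`.
#' @export
run_pipeline <- function(set, cfg = pipeline_config()) {
  stopifnot(inherits(set, "strain_set"), inherits(cfg, "pipeline_config"))
  res <- list(); errors <- list()
  run_stage <- function(name, deps, fun) {
    if (!(name %in% cfg$stages)) return(invisible(NULL))
    missing_dep <- deps[!deps %in% names(res)]
    if (length(missing_dep) > 0L) {
      errors[[name]] <<- paste("skipped; missing dependency:",
                               paste(missing_dep, collapse = ", "))
      return(invisible(NULL))
    }
    out <- tryCatch(fun(), error = function(e) e)
    if (inherits(out, "error")) errors[[name]] <<- conditionMessage(out)
    else res[[name]] <<- out
    invisible(NULL)
  }
  labels <- setNames(set$strains$species, set$strains$id)
  roles <- setNames(set$strains$role, set$strains$id)
  ref_species <- unique(labels[roles %in% c("train", "test")])

  run_stage("ani", character(), function() {
    p <- ani_params(cfg$ani$fragment_length, cfg$ani$min_identity_pct,
                    cfg$ani$min_fragment_coverage)
    am <- ani_matrix(set, p)
    k <- cfg$ani$k %||% length(ref_species)
    cc <- correlation_clusters(am, linkage = cfg$ani$linkage, k = k)
    list(matrix = am, correlation = cc)
  })
  run_stage("core", character(), function() {
    ref_id <- cfg$core$reference %||%
      (if (length(set$outgroups)) set$outgroups[1] else set$strains$id[1])
    blast_core_genes(set$genomes[[ref_id]], set, cfg$core$e_cutoff,
                     cfg$core$scope)
  })
  run_stage("mlsa", "core", function() {
    fams <- family_alignments(res$core, align = TRUE)
    alns <- lapply(names(fams), function(g)
      structure(fams[[g]], class = "alignment", family_id = g))
    sm <- concatenate_alignments(alns)
    if (isTRUE(cfg$mlsa$trim)) sm <- trim_conserved_blocks(sm)
    tree <- nj_tree_with_bootstrap(sm, model = cfg$mlsa$model,
                                   n_boot = cfg$mlsa$n_boot,
                                   seed = cfg$seed + 1L)
    list(supermatrix = sm, tree = tree)
  })
  run_stage("repertoire", "mlsa", function() {
    proteomes <- lapply(setNames(set$strains$id, set$strains$id),
                        function(id) proteome_of(set, id))
    og <- assign_orthogroups(proteomes, cfg$repertoire$e_cutoff,
                             cfg$repertoire$inflation)
    fm <- build_function_matrix(og, proteomes)
    dend <- cluster_repertoire(fm, n_boot = cfg$repertoire$n_boot,
                               seed = cfg$seed + 2L)
    cmp <- compare_dendrograms(res$mlsa$tree, dend,
                               k = cfg$repertoire$k_nn)
    list(orthogroups = og, function_matrix = fm, dendrogram = dend,
         comparison = cmp)
  })
  run_stage("rank", "core", function() {
    ft <- build_feature_table(res$core, model = cfg$rank$model,
                              align = TRUE)
    train_rows <- names(roles)[roles == "train"]
    test_rows <- names(roles)[roles == "test"]
    forest <- train_species_forest(ft, labels, train_rows,
                                   n_trees = cfg$rank$n_trees,
                                   seed = cfg$rank$forest_seed,
                                   aggregate = cfg$rank$aggregate)
    eval <- evaluate_forest(forest, ft, test_rows, labels)
    stats <- gene_distance_stats(res$core, model = cfg$rank$model,
                                 align = TRUE)
    per_gene <- if (isTRUE(cfg$rank$per_gene))
      per_gene_error_rates(ft, labels, train_rows, test_rows,
                           n_trees = cfg$rank$n_trees,
                           seed = cfg$rank$forest_seed)
    else NULL
    list(feature_table = ft, forest = forest, evaluation = eval,
         ranking = rank_genes(stats, forest, per_gene))
  })
  run_stage("classify", c("core", "rank"), function() {
    marker <- cfg$classify$marker %||% res$rank$ranking$gene[1]
    fam <- res$core$families[[marker]]
    if (is.null(fam)) stop("marker gene not in core set: ", marker)
    pca <- fit_marker_pca(fam$nuc, model = cfg$classify$model,
                          variables = cfg$classify$variables,
                          references = names(roles)[roles != "query"],
                          align = TRUE)
    ell <- class_ellipses(pca, labels[roles %in% c("train", "test")],
                          level = cfg$classify$level)
    calls <- classify_strains(pca, ell)
    list(marker = marker, pca = pca, ellipses = ell, calls = calls)
  })

  structure(list(stages = res, errors = errors, config = cfg,
                 seed = cfg$seed, config_hash = config_hash(cfg)),
            class = "circumscription_report")
}

#' @export
print.circumscription_report <- function(x, ...) {
  cat("circumscription_report (seed", x$seed, ", config",
      substr(x$config_hash, 1, 8), ")\n")
  cat("stages completed:", paste(names(x$stages), collapse = ", "), "\n")
  if (length(x$errors))
    for (nm in names(x$errors))
      cat("stage", nm, "failed:", x$errors[[nm]], "\n")
  if (!is.null(x$stages$ani) && !is.null(x$stages$ani$correlation$clusters)) {
    cat("\nANI correlation clusters:\n")
    print(split(names(x$stages$ani$correlation$clusters),
                x$stages$ani$correlation$clusters))
  }
  if (!is.null(x$stages$core))
    cat("\ncore genes:", length(x$stages$core$families), "\n")
  if (!is.null(x$stages$repertoire)) {
    d <- x$stages$repertoire$comparison$discordant
    # strong discordance only: weak (2-of-3 neighbour) mismatches are
    # routinely produced by within-species cophenetic ties
    d <- d[d$discordant & d$overlap <= 1 / 3, ]
    cat("discordant (ecotype-candidate) strains:",
        if (nrow(d)) paste(d$strain, collapse = ", ") else "none", "\n")
  }
  if (!is.null(x$stages$rank)) {
    cat("\ntest misclassification rate:",
        x$stages$rank$evaluation$misclassification_rate, "\n")
    cat("top marker genes:\n")
    print(utils::head(x$stages$rank$ranking, 3))
  }
  if (!is.null(x$stages$classify)) {
    cat("\nmarker:", x$stages$classify$marker, "\n")
    print(x$stages$classify$calls)
  }
  invisible(x)
}
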