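#' PCA on a single marker gene's distance variables
#'
#' The variables are the genetic distances from each fitted strain's copy
#' of the marker gene to every reference organism's copy (`variables =
#' "all"` uses all fitted strains as references, `"references"` a supplied
#' subset). Data are centred per variable but not scaled by default, and the
#' covariance eigendecomposition is used. A deterministic sign convention is
#' applied: within each component, the loading of largest magnitude is made
#' positive.
#'
#' @param family Named character vector of the marker gene's aligned
#'   nucleotide sequences across all strains to fit (or a `core_gene_set`
#'   family entry).
#' @param model Distance model (see [genetic_distance()]).
#' @param variables `"all"` (default) or `"references"`.
#' @param references Reference organism ids when
#'   `variables = "references"`.
#' @param scale. Scale variables to unit variance before PCA.
#' @param align Align the family with MAFFT when sequences have unequal
#'   lengths.
#' @return Object of class `marker_pca`: scores, loadings,
#'   explained-variance fractions, the variable set and a `degenerate` flag
#'   (all strains identical).
#' @export
fit_marker_pca <- function(family, model = "K80",
                           variables = c("all", "references"),
                           references = NULL, scale. = FALSE,
                           align = FALSE) {
  variables <- match.arg(variables)
  if (is.list(family) && !is.null(family$nuc)) family <- family$nuc
  if (length(family) < 3L) stop("need at least 3 strains")
  if (length(unique(nchar(family))) != 1L) {
    if (!align) stop("marker family is not aligned; set align = TRUE")
    family <- align_family(family)
  }
  d <- genetic_distance(family, model = model)
  strains <- rownames(d)
  orgs <- if (variables == "all") strains else {
    if (is.null(references)) stop("references required")
    if (!all(references %in% strains))
      stop("unknown reference organism(s): ",
           paste(setdiff(references, strains), collapse = ", "))
    references
  }
  X <- d[strains, orgs, drop = FALSE]
  total_var <- sum(apply(X, 2, var))
  degenerate <- total_var < .Machine$double.eps
  if (degenerate) {
    ncomp <- min(nrow(X), ncol(X))
    scores <- matrix(0, nrow(X), ncomp,
                     dimnames = list(strains,
                                     paste0("PC", seq_len(ncomp))))
    return(structure(list(scores = scores, loadings = NULL,
                          explained = rep(NA_real_, ncomp),
                          center = colMeans(X), variables = orgs,
                          strains = strains, model = model,
                          variables_mode = variables,
                          degenerate = TRUE),
                     class = "marker_pca"))
  }
  p <- prcomp(X, center = TRUE, scale. = scale.)
  # sign convention: largest-magnitude loading positive per component
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  explained <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, loadings = p$rotation, explained = explained,
                 center = p$center, scale = if (scale.) p$scale else NULL,
                 variables = orgs, strains = strains, model = model,
                 variables_mode = variables, degenerate = FALSE,
                 prcomp = p),
            class = "marker_pca")
}

#' @export
print.marker_pca <- function(x, ...) {
  if (x$degenerate) {
    cat("marker_pca: degenerate (zero total variance),",
        length(x$strains), "strains\n")
  } else {
    cat(sprintf("marker_pca: %d strains, %d variables; PC1 %.1f%%, PC2 %.1f%%\n",
                length(x$strains), length(x$variables),
                100 * x$explained[1], 100 * x$explained[2]))
  }
  invisible(x)
}

#' Per-class 95% confidence ellipses in PC1/PC2 space
#'
#' Normal-theory ellipses: for each class with at least 3 members, the
#' ellipse is `{x : (x - mu)' S^{-1} (x - mu) <= chi2_2(level)}` with `mu`
#' the class mean and `S` the class score covariance in the first two
#' components. Singular covariances receive a tiny ridge (with a warning).
#' Classes with fewer than 3 members yield no ellipse and are reported in
#' the `skipped` attribute.
#'
#' @param m A [fit_marker_pca()] model.
#' @param labels Named character vector (strain -> class) for the fitted
#'   reference strains; strains absent from `labels` are ignored.
#' @param level Confidence level (default 0.95).
#' @param ridge Ridge added to a singular covariance.
#' @return List of class `class_ellipses`; each element has `label`,
#'   `center`, `cov`, `level`, `n`.
#' @export
class_ellipses <- function(m, labels, level = 0.95, ridge = 1e-9) {
  stopifnot(inherits(m, "marker_pca"))
  if (m$degenerate) stop("cannot draw ellipses on a degenerate PCA")
  labs <- labels[names(labels) %in% m$strains]
  out <- list(); skipped <- character()
  for (cl in unique(labs)) {
    members <- names(labs)[labs == cl]
    if (length(members) < 3L) { skipped <- c(skipped, cl); next }
    sc <- m$scores[members, 1:2, drop = FALSE]
    S <- cov(sc)
    scale2 <- max(diag(S), ridge)
    if (!is.finite(determinant_2x2(S)) ||
        determinant_2x2(S) <= 1e-10 * scale2^2) {
      warning("singular covariance for class ", cl, "; ridge added")
      r <- max(ridge, 1e-6 * scale2)
      while (!is_invertible_2x2(S + diag(r, 2))) r <- r * 10
      S <- S + diag(r, 2)
    }
    out[[cl]] <- list(label = cl, center = colMeans(sc), cov = S,
                      level = level, n = length(members))
  }
  if (length(out) == 0L) stop("no class has >= 3 members")
  structure(out, class = "class_ellipses", skipped = skipped, level = level)
}

determinant_2x2 <- function(S) S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]

is_invertible_2x2 <- function(S) {
  !inherits(tryCatch(solve(S), error = function(e) e), "error")
}

#' @export
print.class_ellipses <- function(x, ...) {
  cat("class_ellipses (level", attr(x, "level"), "):",
      paste(sprintf("%s (n=%d)", names(x),
                    vapply(x, `[[`, numeric(1), "n")), collapse = ", "),
      "\n")
  sk <- attr(x, "skipped")
  if (length(sk)) cat("no ellipse (fewer than 3 members):",
                      paste(sk, collapse = ", "), "\n")
  invisible(x)
}

#' Classify strains against class ellipses
#'
#' A strain inside exactly one ellipse is called that class; inside several
#' it is called the class with the smallest Mahalanobis distance and
#' flagged ambiguous; inside none it is an outclass, signalling a species
#' not represented among the references.
#'
#' @param m A [fit_marker_pca()] model (fitted jointly over references and
#'   queries, the default workflow).
#' @param ellipses A [class_ellipses()] result.
#' @param strains Strain ids to call (default: all fitted strains).
#' @return Data frame of class `class_calls`: `strain`, `call`,
#'   `ambiguous`, `inside_n`, plus one squared-Mahalanobis-distance column
#'   per class (`d2_<class>`).
#' @export
classify_strains <- function(m, ellipses, strains = NULL) {
  stopifnot(inherits(m, "marker_pca"), inherits(ellipses, "class_ellipses"))
  strains <- strains %||% m$strains
  miss <- setdiff(strains, m$strains)
  if (length(miss) > 0L)
    stop("strain(s) not fitted in the PCA: ", paste(miss, collapse = ", "))
  cutoff <- qchisq(attr(ellipses, "level"), df = 2)
  classes <- names(ellipses)
  d2 <- sapply(classes, function(cl)
    mahalanobis(m$scores[strains, 1:2, drop = FALSE],
                ellipses[[cl]]$center, ellipses[[cl]]$cov))
  d2 <- matrix(d2, nrow = length(strains),
               dimnames = list(strains, classes))
  inside <- d2 <= cutoff
  call <- character(length(strains)); ambiguous <- logical(length(strains))
  for (i in seq_along(strains)) {
    hit <- classes[inside[i, ]]
    if (length(hit) == 0L) {
      call[i] <- "outclass"
    } else if (length(hit) == 1L) {
      call[i] <- hit
    } else {
      call[i] <- classes[which.min(d2[i, ])]
      ambiguous[i] <- TRUE
    }
  }
  out <- data.frame(strain = strains, call = call, ambiguous = ambiguous,
                    inside_n = rowSums(inside), stringsAsFactors = FALSE)
  d2df <- as.data.frame(d2)
  names(d2df) <- paste0("d2_", classes)
  out <- cbind(out, d2df)
  rownames(out) <- NULL
  class(out) <- c("class_calls", "data.frame")
  out
}

#' @export
print.class_calls <- function(x, ...) {
  n_out <- sum(x$call == "outclass")
  cat("class_calls:", nrow(x), "strains,", n_out, "outclass,",
      sum(x$ambiguous), "ambiguous\n")
  print.data.frame(x[, c("strain", "call", "ambiguous", "inside_n")])
  invisible(x)
}
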