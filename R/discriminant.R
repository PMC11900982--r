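# Discriminant 13C-ITUM: standardized PCA over isotopologue enrichment
# variables, PC1-loading selection, co-enrichment correlation on
# SJ/SJH samples, hierarchical clustering and network export.

#' Assemble the isotopologue enrichment matrix
#'
#' One column per isotopologue variable, named `<code>_M<k>` (e.g.
#' `S_M0..S_M3` for serine), one row per sample; values are corrected
#' fractional enrichments on the 0-100 scale. Metabolites whose mean
#' total enrichment in the reference group does not exceed
#' `min_enrichment` are excluded (by default only metabolites with zero
#' enrichment drop out; the floor is configurable because an enrichment
#' significance criterion is a study-level choice).
#'
#' @param mids list of corrected `mid` objects sharing sample columns.
#' @param design study design (required to scope groups and apply the
#'   enrichment rule).
#' @param groups groups whose samples form the rows (default HJ, SJ,
#'   SJH).
#' @param min_enrichment enrichment floor in percent (default 0).
#' @param enrichment_group group in which enrichment is required
#'   (default `"SJH"`; skipped when absent from the design).
#' @return numeric matrix samples x variables, attribute `"variables"` a
#'   data.frame mapping column -> (metabolite, k).
#' @export
build_enrichment_matrix <- function(mids, design,
                                    groups = c("HJ", "SJ", "SJH"),
                                    min_enrichment = 0,
                                    enrichment_group = "SJH") {
  design <- design[design$group %in% groups, , drop = FALSE]
  if (!nrow(design)) stopf("no samples in groups: %s",
                           paste(groups, collapse = ", "))
  samples <- design$sample_id
  cols <- list()
  vars <- list()
  for (m in mids) {
    if (!isTRUE(m$corrected))
      stopf("MID for %s is not natural-abundance corrected", m$metabolite)
    miss <- setdiff(samples, colnames(m$fractions))
    if (length(miss))
      stopf("MID for %s lacks sample(s): %s", m$metabolite,
            paste(miss, collapse = ", "))
    if (enrichment_group %in% design$group) {
      eg <- design$sample_id[design$group == enrichment_group]
      if (mean(total_enrichment(m)[eg]) <= min_enrichment) next
    }
    n <- nrow(m$fractions) - 1
    nm <- sprintf("%s_M%d", m$code, 0:n)
    cols[[m$metabolite]] <- t(m$fractions[, samples, drop = FALSE])
    colnames(cols[[m$metabolite]]) <- nm
    vars[[m$metabolite]] <- data.frame(variable = nm,
                                       metabolite = m$metabolite,
                                       k = 0:n, stringsAsFactors = FALSE)
  }
  if (!length(cols)) stopf("no metabolite passed the enrichment rule")
  em <- do.call(cbind, cols)
  rownames(em) <- samples
  attr(em, "variables") <- do.call(rbind, c(vars, make.row.names = FALSE))
  attr(em, "groups") <- stats::setNames(design$group, design$sample_id)
  em
}

#' Parse an isotopologue variable name
#'
#' @param variable names like `"GSH_M4"`.
#' @return data.frame with `code` and `k`.
#' @export
parse_iso_variable <- function(variable) {
  m <- regmatches(variable, regexec("^(.*)_M(\\d+)$", variable))
  bad <- vapply(m, length, 1L) != 3
  if (any(bad)) stopf("unparseable variable name(s): %s",
                      paste(variable[bad], collapse = ", "))
  data.frame(variable = variable,
             code = vapply(m, `[`, "", 2),
             k = as.integer(vapply(m, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' Principal components analysis of enrichment variables
#'
#' Column-wise z-scoring (standardization) followed by SVD of the
#' centered matrix. Zero-variance columns are removed with a notice
#' before scaling. A deterministic sign convention is applied: the
#' largest-|loading| entry of every component is made positive.
#'
#' @param matrix samples x variables matrix (e.g. from
#'   [build_enrichment_matrix()]).
#' @param standardize z-score columns before decomposition (default
#'   TRUE; pass FALSE for data already on a common scale).
#' @param n_components number of components to keep (default all =
#'   `min(n samples - 1, n variables)`).
#' @return object of class `pca_result`: `scores` (samples x
#'   components), `loadings` (variables x components, orthonormal
#'   columns), `explained_variance_fraction`, `dropped` (zero-variance
#'   variables), `standardized`.
#' @export
run_pca <- function(matrix, standardize = TRUE, n_components = NULL) {
  if (nrow(matrix) < 2 || ncol(matrix) < 2)
    stopf("PCA needs >= 2 samples and >= 2 variables")
  v <- apply(matrix, 2, stats::var)
  dropped <- colnames(matrix)[v == 0]
  if (length(dropped)) {
    message(sprintf("run_pca: removed %d zero-variance variable(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    matrix <- matrix[, v > 0, drop = FALSE]
  }
  max_comp <- min(nrow(matrix) - 1L, ncol(matrix))
  n_components <- n_components %||% max_comp
  if (n_components > max_comp)
    stopf("requested %d components but only %d are defined", n_components,
          max_comp)
  pc <- stats::prcomp(matrix, center = TRUE, scale. = standardize)
  keep <- seq_len(min(n_components, ncol(pc$rotation)))
  load <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  for (j in seq_along(keep)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = load,
                 explained_variance_fraction = ev[keep],
                 dropped = dropped, standardized = standardize),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d samples x %d variables, %d component(s); PC1 %.1f%% of variance\n",
              nrow(x$scores), nrow(x$loadings), ncol(x$scores),
              100 * x$explained_variance_fraction[1]))
  invisible(x)
}

#' Select discriminating isotopologues from PCA loadings
#'
#' Ranks variables by |loading| on a component and keeps the top
#' contributors, either the top k or everything at or above a |loading|
#' quantile. The selection rule is echoed in the output metadata so the
#' downstream correlation stage records how its variable set was
#' chosen.
#'
#' @param pca a `pca_result`.
#' @param component component to rank on (default 1).
#' @param rule `"top:<k>"` or `"quantile:<q>"`; default
#'   `"quantile:0.75"` (top quartile by |loading|).
#' @return character vector of variable names ordered by decreasing
#'   |loading|; attributes `"rule"` and `"loadings"`.
#' @export
select_discriminant <- function(pca, component = 1,
                                rule = "quantile:0.75") {
  if (component > ncol(pca$loadings))
    stopf("component %d not available", component)
  l <- abs(pca$loadings[, component])
  ord <- order(l, decreasing = TRUE)
  parts <- strsplit(rule, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[1] %in% c("top", "quantile"))
    stopf("rule must be 'top:<k>' or 'quantile:<q>'")
  val <- as.numeric(parts[2])
  sel <- switch(parts[1],
    top = {
      if (val < 1) stopf("top-k selection needs k >= 1")
      names(l)[ord][seq_len(min(val, length(l)))]
    },
    quantile = {
      if (val < 0 || val > 1) stopf("quantile must lie in [0, 1]")
      cut <- stats::quantile(l, val)
      names(l)[ord][l[ord] >= cut]
    })
  if (!length(sel)) stopf("selection rule '%s' kept no variables", rule)
  structure(sel, rule = rule, loadings = l[sel])
}

#' Pairwise co-enrichment correlation matrix
#'
#' Pearson correlations between isotopologue enrichment variables over
#' the SJ and SJH samples (by default), with two-sided p-values from the
#' exact t transform at df = n - 2. In the co-culture reading a
#' positive r means co-enrichment in response to co-culture, a negative
#' r a bifurcation of labeled carbon.
#'
#' @param matrix enrichment matrix (samples x variables).
#' @param selected optional variable subset (e.g. from
#'   [select_discriminant()]).
#' @param design optional design to scope `groups`.
#' @param groups sample groups to include (default SJ and SJH).
#' @return object of class `coenrichment_network`: `r`, `p` (square
#'   matrices), `n` (samples used), `flagged` (zero-variance
#'   variables, whose r/p are NA).
#' @export
coenrichment_matrix <- function(matrix, selected = NULL, design = NULL,
                                groups = c("SJ", "SJH")) {
  x <- matrix
  if (!is.null(design)) {
    keep <- design$sample_id[design$group %in% groups]
    x <- x[intersect(rownames(x), keep), , drop = FALSE]
  } else if (!is.null(attr(matrix, "groups"))) {
    g <- attr(matrix, "groups")
    x <- x[names(g)[g %in% groups], , drop = FALSE]
  }
  if (!is.null(selected)) x <- x[, as.character(selected), drop = FALSE]
  if (nrow(x) < 3) stopf("need >= 3 samples across the groups")
  v <- apply(x, 2, stats::var)
  flagged <- colnames(x)[v == 0]
  r <- suppressWarnings(stats::cor(x))
  r[flagged, ] <- NA
  r[, flagged] <- NA
  p <- matrix(r_to_p(r, nrow(x)), nrow(r), dimnames = dimnames(r))
  diag(p)[!colnames(x) %in% flagged] <- 0
  structure(list(r = r, p = p, n = nrow(x), groups = groups,
                 flagged = flagged),
            class = "coenrichment_network")
}

#' @export
print.coenrichment_network <- function(x, ...) {
  cat(sprintf("<coenrichment_network> %d variables over %d samples (%s)\n",
              ncol(x$r), x$n, paste(x$groups, collapse = "/")))
  invisible(x)
}

#' Hierarchical clustering of a co-enrichment matrix
#'
#' Agglomerative clustering on distance `1 - r` (the standard distance
#' for correlation heatmaps), average linkage by default. Returns the
#' dendrogram leaf order and flat clusters at a configurable cut
#' height.
#'
#' @param network a `coenrichment_network` (or a square correlation
#'   matrix).
#' @param linkage `"average"` (default), `"complete"`, or `"ward.D2"`.
#' @param h cut height on the 1 - r scale (default 1: positive-r
#'   blocks).
#' @param k optional number of clusters (overrides `h`).
#' @return list with `hclust`, `leaf_order` (labels in dendrogram
#'   order) and `clusters` (named integer assignment).
#' @export
cluster_coenrichment <- function(network, linkage = "average", h = 1,
                                 k = NULL) {
  r <- if (inherits(network, "coenrichment_network")) network$r else network
  if (any(is.na(r)))
    stopf("correlation matrix has NA entries (zero-variance variables?); resolve flags first")
  if (ncol(r) == 1)
    return(list(hclust = NULL, leaf_order = colnames(r),
                clusters = stats::setNames(1L, colnames(r))))
  hc <- stats::hclust(stats::as.dist(1 - r), method = linkage)
  clusters <- if (is.null(k)) stats::cutree(hc, h = h)
              else stats::cutree(hc, k = k)
  list(hclust = hc, leaf_order = hc$labels[hc$order], clusters = clusters)
}

#' Export a co-enrichment network
#'
#' Writes the signed edge list (pairs with `|r| >= r_threshold`) as
#' delimited text, and optionally as GraphML.
#'
#' @param network a `coenrichment_network`.
#' @param r_threshold absolute-correlation threshold in `[0, 1]`.
#' @param path optional output path for the edge list.
#' @param graphml optional output path for a GraphML file.
#' @return data.frame `node1, node2, r, p, sign` (each unordered pair
#'   once, self-edges excluded).
#' @export
export_network <- function(network, r_threshold, path = NULL,
                           graphml = NULL) {
  if (r_threshold < 0 || r_threshold > 1)
    stopf("r_threshold must lie in [0, 1]")
  r <- network$r
  idx <- which(upper.tri(r) & !is.na(r) & abs(r) >= r_threshold,
               arr.ind = TRUE)
  edges <- data.frame(node1 = rownames(r)[idx[, 1]],
                      node2 = colnames(r)[idx[, 2]],
                      r = r[idx], p = network$p[idx],
                      sign = ifelse(r[idx] >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
  edges <- edges[order(-abs(edges$r)), , drop = FALSE]
  rownames(edges) <- NULL
  if (!is.null(path))
    utils::write.table(edges, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  edges
}

#' Read an exported edge list
#'
#' Inverse of the [export_network()] edge-list writer; the round trip
#' is lossless.
#'
#' @param path edge-list file path.
#' @return data.frame `node1, node2, r, p, sign`.
#' @export
read_network <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "numeric", "character"))
}
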