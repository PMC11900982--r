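# Gene-metabolite correlation-network integration: thresholded Pearson
# networks over DEG x significant-metabolite tables, gene neighborhoods
# and gene-gene submatrix clustering.

#' Pair expression and metabolomics samples
#'
#' Cross-platform replicate pairing is a design choice that sets the
#' correlation degrees of freedom, so it is explicit: by default samples
#' pair within group by replicate index; `"group-mean"` collapses each
#' group to one pair.
#'
#' @param expr_design,metab_design designs with `sample_id`, `group`,
#'   `replicate`.
#' @param strategy `"by-replicate-index"` (default) or `"group-mean"`.
#' @return data.frame `expr_sample, metab_sample, group`; attribute
#'   `"strategy"`.
#' @export
pair_samples <- function(expr_design, metab_design,
                         strategy = c("by-replicate-index",
                                      "group-mean")) {
  strategy <- match.arg(strategy)
  groups <- intersect(unique(expr_design$group),
                      unique(metab_design$group))
  if (!length(groups)) stopf("designs share no groups")
  if (strategy == "group-mean") {
    out <- data.frame(expr_sample = paste0("mean:", groups),
                      metab_sample = paste0("mean:", groups),
                      group = groups, stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, lapply(groups, function(g) {
      e <- expr_design[expr_design$group == g, , drop = FALSE]
      m <- metab_design[metab_design$group == g, , drop = FALSE]
      if (nrow(e) != nrow(m))
        stopf("group %s: %d expression vs %d metabolomics replicates; unpairable by replicate index",
              g, nrow(e), nrow(m))
      e <- e[order(e$replicate), , drop = FALSE]
      m <- m[order(m$replicate), , drop = FALSE]
      data.frame(expr_sample = e$sample_id, metab_sample = m$sample_id,
                 group = g, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
  }
  attr(out, "strategy") <- strategy
  out
}

#' Gene x metabolite correlation tables
#'
#' Pearson r for every (gene, metabolite) pair over the paired samples,
#' with two-sided p from the exact t transform at df = n - 2. Inputs
#' are expected to be pre-filtered upstream (DEGs at their adjusted-p
#' cut; significantly altered metabolites from the differential stage).
#' Zero-variance rows are flagged and their correlations set to NA.
#'
#' @param expr genes x samples matrix.
#' @param metab metabolites x samples matrix (or a [feature_matrix()]).
#' @param pairing pairing table from [pair_samples()].
#' @return list with `r`, `p` (genes x metabolites), `n`, `flagged`
#'   (list of zero-variance genes/metabolites).
#' @export
correlate_genes_metabolites <- function(expr, metab, pairing) {
  if (inherits(metab, "feature_matrix")) metab <- metab$counts
  miss_e <- setdiff(pairing$expr_sample, colnames(expr))
  miss_m <- setdiff(pairing$metab_sample, colnames(metab))
  if (length(miss_e)) stopf("expression matrix lacks sample(s): %s",
                            paste(miss_e, collapse = ", "))
  if (length(miss_m)) stopf("metabolite matrix lacks sample(s): %s",
                            paste(miss_m, collapse = ", "))
  n <- nrow(pairing)
  if (n < 3) stopf("need >= 3 paired samples")
  X <- t(expr[, pairing$expr_sample, drop = FALSE])
  Y <- t(metab[, pairing$metab_sample, drop = FALSE])
  zv_g <- colnames(X)[apply(X, 2, stats::var) == 0]
  zv_m <- colnames(Y)[apply(Y, 2, stats::var) == 0]
  r <- suppressWarnings(stats::cor(X, Y))
  if (length(zv_g)) r[zv_g, ] <- NA
  if (length(zv_m)) r[, zv_m] <- NA
  p <- matrix(r_to_p(r, n), nrow(r), dimnames = dimnames(r))
  list(r = r, p = p, n = n,
       flagged = list(genes = zv_g, metabolites = zv_m))
}

#' Two-stage filter to an omics network
#'
#' Retains (gene, metabolite) edges that are both highly significant
#' (`p < p_cut`) and very strong (`|r| > r_cut`); the stage order is
#' immaterial since the filters compose by conjunction. Defaults follow
#' the small-dataset discipline of p < 0.001 then |R| > 0.98.
#'
#' @param tables list with `r` and `p` from
#'   [correlate_genes_metabolites()].
#' @param p_cut p-value cut (default 0.001).
#' @param r_cut absolute-correlation cut (default 0.98).
#' @return object of class `omics_network`: `edges` (`gene, metabolite,
#'   r, p, sign`), `filters_applied`, and node/edge counts including
#'   the unique-gene count.
#' @export
filter_network <- function(tables, p_cut = 0.001, r_cut = 0.98) {
  keep <- !is.na(tables$r) & tables$p < p_cut & abs(tables$r) > r_cut
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(gene = rownames(tables$r)[idx[, 1]],
                      metabolite = colnames(tables$r)[idx[, 2]],
                      r = tables$r[idx], p = tables$p[idx],
                      sign = ifelse(tables$r[idx] >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
  edges <- edges[order(-abs(edges$r)), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 filters_applied = c(p_cut = p_cut, r_cut = r_cut),
                 n_edges = nrow(edges),
                 n_genes = length(unique(edges$gene)),
                 n_metabolites = length(unique(edges$metabolite)),
                 n_tests = sum(!is.na(tables$r))),
            class = "omics_network")
}

#' @export
print.omics_network <- function(x, ...) {
  cat(sprintf("<omics_network> %d edges (%d unique genes x %d metabolites) at p < %g, |r| > %g\n",
              x$n_edges, x$n_genes, x$n_metabolites,
              x$filters_applied["p_cut"], x$filters_applied["r_cut"]))
  invisible(x)
}

#' Gene neighborhood of a metabolite
#'
#' Genes connected to one metabolite in the filtered network, sorted by
#' decreasing |r|; exportable as a plain gene list for external
#' enrichment tools.
#'
#' @param network an `omics_network`.
#' @param metabolite metabolite id.
#' @param path optional path to write the gene list (one id per line).
#' @return data.frame `gene, r, p, sign` (empty, with a notice, when
#'   the metabolite has no edges).
#' @export
gene_neighborhood <- function(network, metabolite, path = NULL) {
  e <- network$edges[network$edges$metabolite == metabolite, ,
                     drop = FALSE]
  if (!nrow(e))
    message(sprintf("gene_neighborhood: no edges for '%s'", metabolite))
  out <- e[order(-abs(e$r)), c("gene", "r", "p", "sign"), drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) writeLines(out$gene, path)
  out
}

#' Gene-gene correlation submatrix with clustering
#'
#' Square Pearson matrix over a gene list (e.g. one metabolite's
#' neighborhood) with the same hierarchical clustering used for
#' co-enrichment matrices.
#'
#' @param expr genes x samples matrix.
#' @param gene_list genes to include (>= 2).
#' @param samples optional sample subset.
#' @param linkage clustering linkage (default `"average"`).
#' @return list with `r`, `p`, `clustering` (see
#'   [cluster_coenrichment()]).
#' @export
gene_gene_cluster <- function(expr, gene_list, samples = NULL,
                              linkage = "average") {
  if (length(gene_list) < 2) stopf("gene list must contain >= 2 genes")
  miss <- setdiff(gene_list, rownames(expr))
  if (length(miss)) stopf("genes absent from expression matrix: %s",
                          paste(miss, collapse = ", "))
  x <- t(expr[gene_list, samples %||% colnames(expr), drop = FALSE])
  r <- stats::cor(x)
  p <- matrix(r_to_p(r, nrow(x)), nrow(r), dimnames = dimnames(r))
  list(r = r, p = p,
       clustering = cluster_coenrichment(r, linkage = linkage))
}

#' Export an omics network
#'
#' Edge list as delimited text and optionally GraphML with typed nodes.
#'
#' @param network an `omics_network`.
#' @param path edge-list output path.
#' @param graphml optional GraphML output path.
#' @return `path`, invisibly.
#' @export
write_omics_network <- function(network, path, graphml = NULL) {
  utils::write.table(network$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      network$edges, directed = FALSE,
      vertices = data.frame(
        name = c(unique(network$edges$gene),
                 unique(network$edges$metabolite)),
        type = c(rep("gene", network$n_genes),
                 rep("metabolite", network$n_metabolites))))
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}
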