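#' Build the genes x samples allelic-proportion matrix
#'
#' Rows are genes, columns samples, entries the strain-A proportion
#' `p_a`; non-evaluable cells are NA.
#'
#' @param calls Per-gene-line call table from [call_allelic_state()].
#' @param gene_ids Optional subset/order of genes to include.
#' @return Numeric matrix with gene row names and sample column names.
#' @export
allele_proportion_matrix <- function(calls, gene_ids = NULL) {
  genes <- gene_ids %||% unique(calls$gene_id)
  samples <- unique(calls$sample_id)
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  ok <- calls$evaluable & calls$gene_id %in% genes
  m[cbind(match(calls$gene_id[ok], genes),
          match(calls$sample_id[ok], samples))] <- calls$p_a[ok]
  m
}

#' Hierarchically cluster the allelic-proportion matrix
#'
#' Agglomerative clustering of genes (rows) and samples (columns) with
#' Euclidean distance and average linkage.  Missing (non-evaluable)
#' cells are imputed at the neutral allelic value 0.5 for the distance
#' computation only.  Rows are pre-sorted by label so equal inputs give
#' identical merge orders regardless of input row order; rows with no
#' observed value are dropped with a warning.  A gene whose direction is
#' reversed relative to an otherwise uniform block (an Xist-like
#' pattern) separates onto its own outer branch.
#'
#' @param m Matrix from [allele_proportion_matrix()].
#' @param impute Value substituted for missing cells in the distance
#'   computation (default 0.5).
#' @return List with `row_hclust`, `col_hclust` (or NULL when fewer than
#'   two columns), `row_order`, `col_order` (label vectors).
#' @export
cluster_gene_matrix <- function(m, impute = 0.5) {
  all_missing <- rowSums(!is.na(m)) == 0
  if (any(all_missing)) {
    warning("cluster_gene_matrix: dropping ", sum(all_missing),
            " all-missing row(s)")
    m <- m[!all_missing, , drop = FALSE]
  }
  if (nrow(m) < 2)
    stop("cluster_gene_matrix: need at least 2 rows with data")
  m <- m[order(rownames(m)), , drop = FALSE]
  mi <- m
  mi[is.na(mi)] <- impute
  rh <- stats::hclust(stats::dist(mi), method = "average")
  ch <- NULL
  col_order <- colnames(m)
  if (ncol(m) >= 2) {
    ch <- stats::hclust(stats::dist(t(mi)), method = "average")
    col_order <- colnames(m)[ch$order]
  }
  list(row_hclust = rh, col_hclust = ch,
       row_order = rownames(m)[rh$order], col_order = col_order)
}

#' Export a clustering dendrogram as newick
#'
#' @param hc An `hclust` object (e.g. `row_hclust` from
#'   [cluster_gene_matrix()]).
#' @param path Optional file path; when given the tree is written there.
#' @return The newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  tree <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}
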