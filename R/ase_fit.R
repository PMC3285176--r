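#' Fit the allele-specific expression model to a cSNP-seq cohort
#'
#' The package's central entry point.  Runs the full caller over every
#' gene x cell line: per-SNP depth filtering, RPKM and evaluability,
#' strain-A allelic proportion with a two-sided exact binomial test
#' against the balanced null, per-gene-line categories, per-line analytic
#' FDR, and the cross-line pattern summary (strain-biased, random,
#' imprinted via reciprocal crosses).
#'
#' @param counts Per-SNP allele-count data frame (see
#'   [read_allele_counts()] for the columns).
#' @param expression Expression data frame (see [read_expression()]).
#' @param samples Sample metadata (see [read_samples()]).
#' @param genes Optional gene-model data frame with `gene_id`,
#'   `chromosome` used to annotate calls; defaults to chromosomes taken
#'   from `counts`.
#' @inheritParams call_allelic_state
#' @inheritParams summarize_genes
#' @return An object of class `"ase_fit"`: a list with `calls` (per
#'   gene-line), `patterns` (per gene, evaluable in at least
#'   `min_evaluable` lines), `fdr` (per line), `samples`, and `params`.
#' @seealso [summary.ase_fit()], [coef.ase_fit()], [plot.ase_fit()],
#'   [x_chromosome_report()], [paired_mono_bi_analysis()]
#' @examples
#' cohort <- generate_cohort(cohort_config(n_genes_autosomal = 200, seed = 1))
#' fit <- ase_fit(cohort$counts, cohort$expression, cohort$samples)
#' summary(fit)
#' @export
ase_fit <- function(counts, expression, samples, genes = NULL,
                    min_rpkm = 3, min_pooled_depth = 10,
                    snp_depth_min = 3, snp_depth_max = 2000,
                    alpha = 0.05, mono_cut = 0.85, trend_cut = 0.70,
                    min_evaluable = 2, use_trend_direction = FALSE) {
  chrom <- genes
  if (is.null(chrom) && "chromosome" %in% names(counts))
    chrom <- unique(counts[, c("gene_id", "chromosome")])
  calls <- call_allelic_state(counts, expression, gene_chromosomes = chrom,
                              min_rpkm = min_rpkm,
                              min_pooled_depth = min_pooled_depth,
                              snp_depth_min = snp_depth_min,
                              snp_depth_max = snp_depth_max,
                              alpha = alpha, mono_cut = mono_cut,
                              trend_cut = trend_cut)
  patterns <- summarize_genes(calls, samples, min_evaluable = min_evaluable,
                              use_trend_direction = use_trend_direction)
  fdr <- estimate_fdr(calls, mono_cut = mono_cut, alpha = alpha)
  structure(list(
    calls = calls, patterns = patterns, fdr = fdr, samples = samples,
    params = list(min_rpkm = min_rpkm, min_pooled_depth = min_pooled_depth,
                  snp_depth_min = snp_depth_min,
                  snp_depth_max = snp_depth_max, alpha = alpha,
                  mono_cut = mono_cut, trend_cut = trend_cut,
                  min_evaluable = min_evaluable)
  ), class = "ase_fit")
}

#' @export
print.ase_fit <- function(x, ...) {
  cat("Allele-specific expression fit\n")
  cat(sprintf("  %d gene-line calls across %d cell lines\n",
              nrow(x$calls), length(unique(x$calls$sample_id))))
  cat(sprintf("  %d genes evaluable in >= %d lines\n",
              nrow(x$patterns), x$params$min_evaluable))
  cat(sprintf("  thresholds: RPKM >= %g, pooled depth >= %g, mono >= %g,",
              x$params$min_rpkm, x$params$min_pooled_depth,
              x$params$mono_cut))
  cat(sprintf(" alpha = %g\n", x$params$alpha))
  invisible(x)
}

#' Summarize an ASE fit
#'
#' Headline cohort counts: per-line evaluable genes, monoallelic calls
#' and analytic FDR; genes monoallelic in at least one / two lines; and
#' the cross-line pattern table.
#'
#' @param object An `ase_fit`.
#' @param ... Unused.
#' @return An object of class `"summary.ase_fit"`.
#' @export
summary.ase_fit <- function(object, ...) {
  p <- object$patterns
  s <- list(
    per_line = object$fdr,
    n_summarized = nrow(p),
    n_mono_ge1 = sum(p$n_monoallelic >= 1),
    n_mono_ge2 = sum(p$n_monoallelic >= 2),
    pattern_table = table(p$pattern[p$n_monoallelic >= 2]),
    params = object$params
  )
  class(s) <- "summary.ase_fit"
  s
}

#' @export
print.summary.ase_fit <- function(x, ...) {
  cat("Allele-specific expression fit: cohort summary\n\nPer line:\n")
  print(x$per_line, row.names = FALSE)
  cat(sprintf("\nGenes evaluable in >= %d lines: %d\n",
              x$params$min_evaluable, x$n_summarized))
  cat(sprintf("  monoallelic in >= 1 line:  %d\n", x$n_mono_ge1))
  cat(sprintf("  monoallelic in >= 2 lines: %d\n", x$n_mono_ge2))
  cat("\nPatterns among genes monoallelic in >= 2 lines:\n")
  tab <- x$pattern_table[x$pattern_table > 0]
  for (nm in names(tab)) cat(sprintf("  %-22s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Allelic-proportion matrix of a fit
#'
#' @param object An `ase_fit`.
#' @param ... Unused.
#' @return Genes x samples matrix of strain-A proportions (NA where not
#'   evaluable), restricted to summarized genes.
#' @export
coef.ase_fit <- function(object, ...) {
  allele_proportion_matrix(object$calls, gene_ids = object$patterns$gene_id)
}

#' Heatmap-style image of the clustered allelic-proportion matrix
#'
#' Plots the strain-A proportion of genes monoallelic in at least
#' `min_lines` lines, rows and columns ordered by hierarchical
#' clustering.  Convenience output; the cluster orders themselves come
#' from [cluster_gene_matrix()].
#'
#' @param x An `ase_fit`.
#' @param min_lines Restrict to genes monoallelic in at least this many
#'   lines (default 1).
#' @param ... Passed to [graphics::image()].
#' @return The clustering (invisibly).
#' @export
plot.ase_fit <- function(x, min_lines = 1, ...) {
  genes <- x$patterns$gene_id[x$patterns$n_monoallelic >= min_lines]
  m <- allele_proportion_matrix(x$calls, gene_ids = genes)
  cl <- cluster_gene_matrix(m)
  mo <- m[cl$row_order, cl$col_order, drop = FALSE]
  graphics::image(seq_len(nrow(mo)), seq_len(ncol(mo)), mo,
                  col = grDevices::hcl.colors(64, "Blue-Red"),
                  zlim = c(0, 1), xlab = "genes (clustered)", ylab = "",
                  axes = FALSE, ...)
  graphics::axis(2, at = seq_len(ncol(mo)), labels = colnames(mo),
                 las = 1, tick = FALSE)
  graphics::box()
  invisible(cl)
}
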