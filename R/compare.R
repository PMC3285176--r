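#' Paired comparison of expression level under monoallelic vs biallelic state
#'
#' For every "mixed-pattern" gene — monoallelic in at least one evaluable
#' line and biallelic in at least one other — computes the difference of
#' the mean log2(RPKM) between its biallelic and monoallelic lines, then
#' summarizes across genes with a one-sample (paired) t-test.  The mean
#' transcript-level ratio is reported as
#' \eqn{100 \times 2^{-\overline{\Delta}}} percent, to be contrasted with
#' the 50\% expected under a pure allele-dosage model
#' ([dosage_model_expectation()]).
#'
#' @param calls Per-gene-line call table from [call_allelic_state()].
#'   Only evaluable lines with category `monoallelic` or `biallelic`
#'   contribute; trend and excluded lines are omitted.
#' @return List: `n_genes`, `mean_log2_difference` (biallelic minus
#'   monoallelic), `ci95` (length-2 vector), `paired_t_pvalue`,
#'   `mean_ratio_percent`, and `per_gene` data frame (`gene_id`,
#'   `mean_log2_rpkm_mono`, `mean_log2_rpkm_bi`, `log2_difference`).
#' @export
paired_mono_bi_analysis <- function(calls) {
  use <- calls[calls$evaluable &
                 calls$category %in% c("monoallelic", "biallelic"), ,
               drop = FALSE]
  l2 <- log2(use$rpkm)
  mono_mean <- tapply(l2[use$category == "monoallelic"],
                      use$gene_id[use$category == "monoallelic"], mean)
  bi_mean <- tapply(l2[use$category == "biallelic"],
                    use$gene_id[use$category == "biallelic"], mean)
  genes <- intersect(names(mono_mean), names(bi_mean))
  if (length(genes) < 2)
    stop("paired_mono_bi_analysis: fewer than 2 mixed-pattern genes")
  per_gene <- data.frame(
    gene_id = genes,
    mean_log2_rpkm_mono = as.numeric(mono_mean[genes]),
    mean_log2_rpkm_bi = as.numeric(bi_mean[genes]),
    stringsAsFactors = FALSE
  )
  per_gene$log2_difference <- per_gene$mean_log2_rpkm_bi -
    per_gene$mean_log2_rpkm_mono
  d <- per_gene$log2_difference
  m <- mean(d)
  if (stats::sd(d) > 1e-10 * max(1, abs(m))) {
    tt <- stats::t.test(d)
    ci <- as.numeric(tt$conf.int)
    pv <- tt$p.value
  } else {
    # all genes show the identical shift: degenerate CI, no test
    ci <- c(m, m)
    pv <- NA_real_
  }
  list(
    n_genes = length(genes),
    mean_log2_difference = m,
    ci95 = ci,
    paired_t_pvalue = pv,
    mean_ratio_percent = 100 * 2^(-m),
    per_gene = per_gene
  )
}

#' Per-line two-group comparison of monoallelic vs biallelic genes
#'
#' Within one cell line, contrasts the log2(RPKM) distribution of genes
#' called monoallelic against genes called biallelic: decile table,
#' group-mean difference and a Welch two-sample t-test.
#'
#' @param calls Per-gene-line call table restricted internally to
#'   `sample_id`.
#' @param sample_id Cell line to analyse.
#' @return List: `sample_id`, `n_mono`, `n_bi`, `quantiles` (data frame of
#'   10th–90th percentiles of log2 RPKM per group), `mean_log2_difference`
#'   (biallelic minus monoallelic), `welch_t_pvalue`.
#' @export
per_line_two_group_comparison <- function(calls, sample_id) {
  cs <- calls[calls$sample_id == sample_id & calls$evaluable, , drop = FALSE]
  mono <- log2(cs$rpkm[cs$category == "monoallelic"])
  bi <- log2(cs$rpkm[cs$category == "biallelic"])
  if (length(mono) == 0 || length(bi) == 0)
    stop("per_line_two_group_comparison: empty monoallelic or biallelic ",
         "group in sample '", sample_id, "'")
  probs <- seq(0.1, 0.9, by = 0.1)
  qs <- data.frame(
    quantile = probs,
    log2_rpkm_mono = as.numeric(stats::quantile(mono, probs)),
    log2_rpkm_bi = as.numeric(stats::quantile(bi, probs))
  )
  p <- if (length(mono) > 1 && length(bi) > 1)
    stats::t.test(bi, mono)$p.value else NA_real_
  list(
    sample_id = sample_id,
    n_mono = length(mono),
    n_bi = length(bi),
    quantiles = qs,
    mean_log2_difference = mean(bi) - mean(mono),
    welch_t_pvalue = p
  )
}

#' Transcript ratio expected under a pure allele-dosage model
#'
#' If silencing one of two equally and independently expressed alleles
#' were the only factor, a monoallelic gene would produce exactly half
#' the transcript of its biallelic state.  Exposed so reports can
#' contrast the observed monoallelic/biallelic ratio with this baseline;
#' an observed ratio above 0.5 indicates compensating regulation.
#'
#' @return 0.5.
#' @export
dosage_model_expectation <- function() 0.5
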