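#' Classify one gene-line by allelic proportion and exact-test p-value
#'
#' With \eqn{q = \max(p_A, 1 - p_A)} the majority-allele proportion:
#' \itemize{
#'   \item `monoallelic` when \eqn{q \ge} `mono_cut` and \eqn{p \le} `alpha`;
#'   \item `trend` when `trend_cut` \eqn{\le q <} `mono_cut` and
#'     \eqn{p \le} `alpha`;
#'   \item `biallelic` when \eqn{q <} `trend_cut`;
#'   \item `excluded` when \eqn{q \ge} `trend_cut` but \eqn{p >} `alpha`
#'     (imbalanced yet not significant, typically from low depth);
#'   \item `not_evaluable` when the gene-line fails the evaluability rule.
#' }
#' All boundary comparisons are inclusive as written; the categories are
#' exhaustive and mutually exclusive.  For monoallelic and trend calls,
#' `direction` names the majority allele's strain ("A" or "B").
#'
#' @param p_a Proportion of pooled reads from strain A (vector, in [0,1]).
#' @param p_value Two-sided exact binomial p-value (vector).
#' @param evaluable Logical vector.
#' @param alpha,mono_cut,trend_cut Thresholds (defaults 0.05, 0.85, 0.70).
#' @return Data frame with columns `category` (factor) and `direction`
#'   (character, NA unless monoallelic/trend).
#' @export
classify_gene_line <- function(p_a, p_value, evaluable,
                               alpha = 0.05, mono_cut = 0.85, trend_cut = 0.70) {
  q <- pmax(p_a, 1 - p_a)
  category <- rep(NA_character_, length(p_a))
  category[!evaluable] <- "not_evaluable"
  idx <- evaluable & !is.na(q)
  category[idx & q >= mono_cut & p_value <= alpha] <- "monoallelic"
  category[idx & q >= trend_cut & q < mono_cut & p_value <= alpha] <- "trend"
  category[idx & q < trend_cut] <- "biallelic"
  category[idx & q >= trend_cut & p_value > alpha] <- "excluded"
  direction <- ifelse(category %in% c("monoallelic", "trend"),
                      ifelse(p_a >= 0.5, "A", "B"), NA_character_)
  data.frame(
    category = factor(category, levels = ase_categories()),
    direction = direction,
    stringsAsFactors = FALSE
  )
}

#' Per-gene-line category labels
#'
#' @return Character vector of the five call categories, in order:
#'   monoallelic, trend, biallelic, excluded, not_evaluable.
#' @export
ase_categories <- function() {
  c("monoallelic", "trend", "biallelic", "excluded", "not_evaluable")
}

#' Per-gene-line allele-specific expression calls
#'
#' Runs the full per-gene-line caller: pools filtered SNP depths, computes
#' the strain-A allelic proportion and the two-sided exact binomial
#' p-value against the balanced null, and assigns a category.
#'
#' @inheritParams evaluability
#' @param gene_chromosomes Optional data frame `gene_id`, `chromosome` used
#'   to annotate calls.
#' @inheritParams classify_gene_line
#' @param snp_depth_min,snp_depth_max Per-SNP depth filter bounds passed to
#'   [filter_snp_depths()].
#' @return Data frame with one row per (gene, sample): `gene_id`,
#'   `sample_id`, `chromosome`, `k_strain_A`, `n`, `p_a`, `p_value`,
#'   `rpkm`, `evaluable`, `category`, `direction`.
#' @export
call_allelic_state <- function(counts, expression, gene_chromosomes = NULL,
                               min_rpkm = 3, min_pooled_depth = 10,
                               snp_depth_min = 3, snp_depth_max = 2000,
                               alpha = 0.05, mono_cut = 0.85, trend_cut = 0.70) {
  counts <- filter_snp_depths(counts, snp_depth_min, snp_depth_max)
  ev <- evaluability(expression, counts, min_rpkm, min_pooled_depth)
  n <- ev$pooled_snp_depth
  k <- ev$k_strain_A
  p_a <- ifelse(n > 0, k / n, NA_real_)
  p_value <- rep(NA_real_, length(n))
  p_value[n > 0] <- binom_pvalue_two_sided(k[n > 0], n[n > 0])
  cls <- classify_gene_line(p_a, p_value, ev$evaluable,
                            alpha = alpha, mono_cut = mono_cut,
                            trend_cut = trend_cut)
  chromosome <- NA_character_
  if (!is.null(gene_chromosomes))
    chromosome <- gene_chromosomes$chromosome[
      match(ev$gene_id, gene_chromosomes$gene_id)]
  data.frame(
    gene_id = ev$gene_id,
    sample_id = ev$sample_id,
    chromosome = chromosome,
    k_strain_A = k,
    n = n,
    p_a = p_a,
    p_value = p_value,
    rpkm = ev$rpkm,
    evaluable = ev$evaluable,
    category = cls$category,
    direction = cls$direction,
    stringsAsFactors = FALSE
  )
}

#' Analytic false-discovery rate for monoallelic calls, per cell line
#'
#' Under the balanced null every evaluable gene has a small but non-zero
#' probability of a spurious monoallelic call that depends only on its
#' pooled depth.  Summing those probabilities over the evaluable genes of
#' a line gives the expected number of false calls; dividing by the
#' observed number of monoallelic calls gives the estimated FDR.
#'
#' @param calls Per-gene-line call table from [call_allelic_state()],
#'   possibly covering several samples.
#' @inheritParams null_call_probability
#' @return Data frame with one row per sample: `sample_id`, `n_evaluable`,
#'   `n_monoallelic_calls`, `expected_false_calls`, `fdr` (NA when there
#'   are no monoallelic calls).
#' @export
estimate_fdr <- function(calls, mono_cut = 0.85, alpha = 0.05) {
  ev <- calls[calls$evaluable, , drop = FALSE]
  samples <- unique(calls$sample_id)
  out <- lapply(samples, function(s) {
    cs <- ev[ev$sample_id == s, , drop = FALSE]
    depth_tab <- table(cs$n)
    probs <- null_call_probability(as.integer(names(depth_tab)),
                                   mono_cut = mono_cut, alpha = alpha)
    expected <- sum(probs * as.integer(depth_tab))
    n_mono <- sum(cs$category == "monoallelic")
    data.frame(
      sample_id = s,
      n_evaluable = nrow(cs),
      n_monoallelic_calls = n_mono,
      expected_false_calls = expected,
      fdr = if (n_mono > 0) expected / n_mono else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
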