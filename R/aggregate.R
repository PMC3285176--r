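#' Cross-line allelic pattern taxonomy
#'
#' @return Character vector of the pattern labels assigned by
#'   [summarize_genes()]: strain-specific (`strainA_only`,
#'   `strainA_or_biallelic`, `strainB_only`, `strainB_or_biallelic`),
#'   haplotype-independent (`both_alleles_observed`), parent-of-origin
#'   (`imprinted_maternal`, `imprinted_paternal`) and `biallelic_all`.
#' @export
ase_patterns <- function() {
  c("strainA_only", "strainA_or_biallelic",
    "strainB_only", "strainB_or_biallelic",
    "both_alleles_observed",
    "imprinted_maternal", "imprinted_paternal",
    "biallelic_all")
}

#' Classify a gene's cross-line haplotype pattern
#'
#' Given the expressed-allele strain of every monoallelic line of one
#' gene, plus each such line's maternal strain, decides between
#' parent-of-origin (imprinted), haplotype-independent and strain-biased
#' patterns.  An imprinted call requires that every monoallelic line
#' expresses the allele of the same parental origin *and* that both
#' reciprocal-cross directions are represented among those lines — this
#' is what decouples strain from parental origin.
#'
#' @param mono_strain Character vector ("A"/"B"): expressed strain in each
#'   monoallelic line.
#' @param maternal_strain Character vector ("A"/"B"): maternal strain of
#'   the same lines (cross direction).
#' @param any_biallelic_line Logical: does the gene have at least one
#'   evaluable line called biallelic (or non-monoallelic)?
#' @return One pattern label from [ase_patterns()] (never
#'   `biallelic_all`, which requires zero monoallelic lines).
#' @export
classify_haplotype_pattern <- function(mono_strain, maternal_strain,
                                       any_biallelic_line) {
  if (length(mono_strain) == 0L)
    stop("classify_haplotype_pattern: need at least one monoallelic line")
  if (anyNA(maternal_strain))
    stop("classify_haplotype_pattern: maternal_strain missing for a ",
         "monoallelic line; cannot evaluate parental origin")
  origin <- ifelse(mono_strain == maternal_strain, "maternal", "paternal")
  if (length(unique(origin)) == 1L &&
      length(unique(maternal_strain)) == 2L)
    return(paste0("imprinted_", origin[1L]))
  strains <- unique(mono_strain)
  if (length(strains) == 2L) return("both_alleles_observed")
  if (any_biallelic_line)
    paste0("strain", strains, "_or_biallelic")
  else
    paste0("strain", strains, "_only")
}

#' Summarize per-line calls into per-gene cross-line patterns
#'
#' Counts evaluable and monoallelic lines per gene, drops genes evaluable
#' in fewer than `min_evaluable` lines, and assigns each remaining gene a
#' pattern from [ase_patterns()].  Trend and excluded lines count as
#' evaluable but not monoallelic, and (by default) contribute no
#' direction evidence; set `use_trend_direction = TRUE` to let trend
#' lines vote on the haplotype pattern.
#'
#' @param calls Per-gene-line call table from [call_allelic_state()].
#' @param samples Sample metadata data frame: `sample_id`,
#'   `maternal_strain` ("A" or "B").
#' @param min_evaluable Minimum evaluable lines to keep a gene (default 2).
#' @param use_trend_direction Also use trend-category lines as direction
#'   evidence (default FALSE).
#' @return Data frame with one row per retained gene: `gene_id`,
#'   `chromosome`, `n_evaluable`, `n_monoallelic`, `n_biallelic`,
#'   `pattern`, plus one `cat_<sample>` and `dir_<sample>` column pair per
#'   sample.
#' @export
summarize_genes <- function(calls, samples, min_evaluable = 2,
                            use_trend_direction = FALSE) {
  key <- paste(calls$gene_id, calls$sample_id, sep = "\r")
  if (anyDuplicated(key))
    stop("summarize_genes: duplicate (gene_id, sample_id) rows in calls")
  if (!all(c("sample_id", "maternal_strain") %in% names(samples)))
    stop("summarize_genes: samples needs sample_id and maternal_strain")

  sample_ids <- unique(calls$sample_id)
  genes <- unique(calls$gene_id)
  idx <- matrix(match(paste(rep(genes, times = length(sample_ids)),
                            rep(sample_ids, each = length(genes)),
                            sep = "\r"), key),
                nrow = length(genes))
  cat_m <- matrix(as.character(calls$category)[idx], nrow = length(genes))
  dir_m <- matrix(calls$direction[idx], nrow = length(genes))
  eval_m <- !is.na(cat_m) & cat_m != "not_evaluable"

  n_eval <- rowSums(eval_m)
  n_mono <- rowSums(cat_m == "monoallelic", na.rm = TRUE)
  n_bi <- rowSums(cat_m == "biallelic", na.rm = TRUE)
  keep <- n_eval >= min_evaluable
  maternal <- samples$maternal_strain[match(sample_ids, samples$sample_id)]

  evidence <- c("monoallelic", if (use_trend_direction) "trend")
  pattern <- vapply(which(keep), function(i) {
    use <- !is.na(cat_m[i, ]) & cat_m[i, ] %in% evidence
    if (!any(use)) return("biallelic_all")
    classify_haplotype_pattern(
      mono_strain = dir_m[i, use],
      maternal_strain = maternal[use],
      any_biallelic_line = n_mono[i] < n_eval[i]
    )
  }, character(1))

  chromosome <- calls$chromosome[match(genes, calls$gene_id)]
  out <- data.frame(
    gene_id = genes[keep],
    chromosome = chromosome[keep],
    n_evaluable = n_eval[keep],
    n_monoallelic = as.integer(n_mono[keep]),
    n_biallelic = as.integer(n_bi[keep]),
    pattern = factor(pattern, levels = ase_patterns()),
    stringsAsFactors = FALSE
  )
  for (j in seq_along(sample_ids)) {
    out[[paste0("cat_", sample_ids[j])]] <- cat_m[keep, j]
    out[[paste0("dir_", sample_ids[j])]] <- dir_m[keep, j]
  }
  out
}

#' X-chromosome inactivation report
#'
#' In clonal female F1 cells one X is inactivated per clone, so X-linked
#' genes should be monoallelic with a shared per-line direction.  For
#' each line the consensus active X is the majority expressed strain over
#' monoallelic X genes (the Xist-like gene excluded, since it is
#' transcribed from the *inactive* X and must show the reverse
#' direction).  Escape candidates are X genes that fail to follow the
#' consensus — biallelic, or significantly expressed from the inactive X
#' — in at least `escape_min_lines` evaluable lines.
#'
#' @param calls Per-gene-line call table restricted by the function to
#'   rows with `chromosome == x_chromosome`.
#' @param xist_gene_id Gene id of the Xist-like gene (optional, NA to skip
#'   the reversal check).
#' @param x_chromosome Chromosome label for the X (default "X").
#' @param escape_min_lines Evaluable non-conforming lines needed to list a
#'   gene as escape candidate (default 2).
#' @return List with `per_line` (data frame: `sample_id`, `active_x`
#'   consensus strain, counts of monoallelic/evaluable X genes,
#'   `xist_reversed`), `escape_candidates` (character vector),
#'   `n_evaluable_ge1`, `n_evaluable_ge2`, `n_monoallelic_ge1`.
#' @export
x_chromosome_report <- function(calls, xist_gene_id = NA,
                                x_chromosome = "X", escape_min_lines = 2) {
  x <- calls[!is.na(calls$chromosome) & calls$chromosome == x_chromosome, ,
             drop = FALSE]
  if (!any(x$evaluable)) {
    warning("x_chromosome_report: no evaluable X-linked gene-lines")
    return(list(per_line = data.frame(), escape_candidates = character(0),
                n_evaluable_ge1 = 0L, n_evaluable_ge2 = 0L,
                n_monoallelic_ge1 = 0L))
  }
  body <- x[is.na(xist_gene_id) | x$gene_id != xist_gene_id, , drop = FALSE]
  samples <- unique(x$sample_id)

  per_line <- do.call(rbind, lapply(samples, function(s) {
    bs <- body[body$sample_id == s & body$evaluable, , drop = FALSE]
    mono <- bs[bs$category == "monoallelic", , drop = FALSE]
    active <- NA_character_
    if (nrow(mono) > 0) {
      tab <- table(mono$direction)
      active <- names(tab)[which.max(tab)]
    }
    xist_rev <- NA
    if (!is.na(xist_gene_id)) {
      xr <- x[x$sample_id == s & x$gene_id == xist_gene_id &
                x$evaluable, , drop = FALSE]
      if (nrow(xr) == 1 && !is.na(active))
        xist_rev <- xr$category == "monoallelic" && xr$direction != active
    }
    data.frame(sample_id = s, active_x = active,
               n_evaluable = nrow(bs), n_monoallelic = nrow(mono),
               xist_reversed = xist_rev, stringsAsFactors = FALSE)
  }))
  if (all(is.na(per_line$active_x)))
    warning("x_chromosome_report: no monoallelic X genes; no consensus")

  # per-gene escape scan against each line's consensus
  consensus <- per_line$active_x[match(body$sample_id, per_line$sample_id)]
  nonconf <- body$evaluable & !is.na(consensus) &
    (body$category == "biallelic" |
       (body$category == "monoallelic" & body$direction != consensus))
  nc_by_gene <- rowsum(as.integer(nonconf), body$gene_id)
  escape <- rownames(nc_by_gene)[nc_by_gene[, 1] >= escape_min_lines]

  eval_by_gene <- rowsum(as.integer(x$evaluable), x$gene_id)[, 1]
  mono_by_gene <- rowsum(as.integer(x$evaluable &
                                      x$category == "monoallelic"),
                         x$gene_id)[, 1]
  list(
    per_line = per_line,
    escape_candidates = escape,
    n_evaluable_ge1 = sum(eval_by_gene >= 1),
    n_evaluable_ge2 = sum(eval_by_gene >= 2),
    n_monoallelic_ge1 = sum(eval_by_gene >= 1 & mono_by_gene >= 1)
  )
}
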