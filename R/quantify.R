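#' Reads per kilobase of exon model per million mapped reads
#'
#' The standard RPKM transcript-abundance unit:
#' \deqn{RPKM = 10^9 \, C / (N \, L)}
#' where \eqn{C} is the number of reads mapped to the gene, \eqn{L} the
#' summed exon-model length in bases, and \eqn{N} the total mapped reads
#' in the sample.
#'
#' @param gene_read_count Reads mapped to the gene (vector).
#' @param exon_model_length Summed exon length in bases; must be > 0.
#' @param total_mapped_reads Total mapped reads in the sample; must be > 0.
#' @return Numeric vector of RPKM values.
#' @examples
#' compute_rpkm(300, 1500, 2e7)   # 10
#' @export
compute_rpkm <- function(gene_read_count, exon_model_length, total_mapped_reads) {
  if (any(exon_model_length <= 0, na.rm = TRUE))
    stop("compute_rpkm: exon_model_length must be positive")
  if (any(total_mapped_reads <= 0, na.rm = TRUE))
    stop("compute_rpkm: total_mapped_reads must be positive")
  # double arithmetic: integer N * L overflows for real library sizes
  1e9 * as.numeric(gene_read_count) /
    (as.numeric(total_mapped_reads) * as.numeric(exon_model_length))
}

#' Filter per-SNP allele counts on total depth
#'
#' Retains SNP observations whose total depth (both alleles summed) lies
#' within `[min_depth, max_depth]`, bounds inclusive.  Extremely shallow
#' SNPs carry no allelic information; extremely deep ones are usually
#' mapping artifacts (paralogs, collapsed repeats).
#'
#' @param counts Data frame of per-SNP allele counts with columns
#'   `count_strain_A` and `count_strain_B`.
#' @param min_depth,max_depth Inclusive depth bounds (defaults 3 and 2000).
#' @return The filtered data frame (possibly zero rows).
#' @export
filter_snp_depths <- function(counts, min_depth = 3, max_depth = 2000) {
  counts <- validate_counts(counts)
  d <- counts$count_strain_A + counts$count_strain_B
  counts[d >= min_depth & d <= max_depth, , drop = FALSE]
}

#' Pool filtered SNP depths and flag evaluable gene-lines
#'
#' A gene is statistically evaluable in a cell line when it is expressed
#' (RPKM at or above `min_rpkm`) and carries enough allele-resolved reads
#' (pooled SNP depth at or above `min_pooled_depth`).  Pooled depth is the
#' sum of per-SNP total depths after the depth filter; genes present in
#' the expression table but with no surviving SNP get pooled depth 0.
#'
#' @param expression Data frame with columns `gene_id`, `sample_id`,
#'   `gene_read_count`, `exon_model_length`, `total_mapped_reads`.
#' @param counts Filtered per-SNP allele-count data frame (see
#'   [filter_snp_depths()]); every (gene, sample) in `counts` must have an
#'   expression row.
#' @param min_rpkm RPKM threshold for expressed genes (default 3).
#' @param min_pooled_depth Pooled SNP depth threshold (default 10).
#' @return Data frame with one row per (gene, sample) of `expression`:
#'   `gene_id`, `sample_id`, `k_strain_A`, `pooled_snp_depth`, `rpkm`,
#'   `evaluable`.
#' @export
evaluability <- function(expression, counts, min_rpkm = 3, min_pooled_depth = 10) {
  req <- c("gene_id", "sample_id", "gene_read_count", "exon_model_length",
           "total_mapped_reads")
  miss <- setdiff(req, names(expression))
  if (length(miss))
    stop("evaluability: expression table missing columns: ",
         paste(miss, collapse = ", "))
  counts <- validate_counts(counts)

  ekey <- paste(expression$gene_id, expression$sample_id, sep = "\r")
  if (anyDuplicated(ekey))
    stop("evaluability: duplicate (gene_id, sample_id) rows in expression")
  ckey <- paste(counts$gene_id, counts$sample_id, sep = "\r")
  orphan <- !(ckey %in% ekey)
  if (any(orphan)) {
    ex <- counts[which(orphan)[1L], ]
    stop(sprintf("evaluability: no expression row for gene '%s' sample '%s'",
                 ex$gene_id, ex$sample_id))
  }

  depth <- counts$count_strain_A + counts$count_strain_B
  pooled <- rowsum(cbind(depth, counts$count_strain_A), ckey)
  idx <- match(ekey, rownames(pooled))
  pooled_depth <- ifelse(is.na(idx), 0L, pooled[idx, 1L])
  k_a <- ifelse(is.na(idx), 0L, pooled[idx, 2L])

  rpkm <- compute_rpkm(expression$gene_read_count,
                       expression$exon_model_length,
                       expression$total_mapped_reads)
  data.frame(
    gene_id = expression$gene_id,
    sample_id = expression$sample_id,
    k_strain_A = as.integer(k_a),
    pooled_snp_depth = as.integer(pooled_depth),
    rpkm = rpkm,
    evaluable = rpkm >= min_rpkm & pooled_depth >= min_pooled_depth,
    stringsAsFactors = FALSE
  )
}

# shared column/NA/sign checks for per-SNP count tables
validate_counts <- function(counts) {
  req <- c("gene_id", "sample_id", "count_strain_A", "count_strain_B")
  miss <- setdiff(req, names(counts))
  if (length(miss))
    stop("allele-count table missing columns: ", paste(miss, collapse = ", "))
  if (any(counts$count_strain_A < 0, na.rm = TRUE) ||
      any(counts$count_strain_B < 0, na.rm = TRUE))
    stop("allele-count table contains negative counts")
  counts
}
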