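#' Read a per-SNP allele-count table
#'
#' Two dialects are supported.  `"tsv"` expects the package's counts
#' format: columns `gene_id`, `snp_id`, `chromosome`, `position`
#' (1-based), `sample_id`, `count_strain_A`, `count_strain_B`.  `"vcf"`
#' reads a VCF whose per-sample `AD` FORMAT field carries the
#' (strain-A, strain-B) depths of pre-phased strain alleles; the gene is
#' taken from a `GENE` INFO key and one row is emitted per SNP x sample.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return Validated counts data frame.
#' @export
read_allele_counts <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    x <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(position = "integer",
                                          chromosome = "character"))
    x <- validate_counts(x)
    req <- c("gene_id", "snp_id", "chromosome", "position", "sample_id")
    miss <- setdiff(req, names(x))
    if (length(miss))
      stop("read_allele_counts: missing columns: ",
           paste(miss, collapse = ", "))
    bad <- which(x$count_strain_A < 0 | x$count_strain_B < 0)
    if (length(bad))
      stop("read_allele_counts: negative count at data line ", bad[1L])
    key <- paste(x$snp_id, x$sample_id, sep = "\r")
    if (anyDuplicated(key))
      stop("read_allele_counts: duplicate (snp_id, sample_id) at data line ",
           which(duplicated(key))[1L])
    return(x)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  info <- vcfR::extract.info(vcf, element = "GENE")
  if (all(is.na(info)))
    stop("read_allele_counts: VCF lacks the GENE INFO key")
  snp_id <- fix[, "ID"]
  no_id <- is.na(snp_id) | snp_id == "."
  snp_id[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  out <- do.call(rbind, lapply(colnames(ad), function(s) {
    parts <- strsplit(ad[, s], ",", fixed = TRUE)
    a <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    b <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    data.frame(gene_id = info, snp_id = snp_id,
               chromosome = fix[, "CHROM"],
               position = as.integer(fix[, "POS"]),
               sample_id = s, count_strain_A = a, count_strain_B = b,
               stringsAsFactors = FALSE)
  }))
  out <- out[!is.na(out$count_strain_A) & !is.na(out$count_strain_B), ,
             drop = FALSE]
  rownames(out) <- NULL
  validate_counts(out)
}

#' Read an expression table
#'
#' TSV with columns `gene_id`, `sample_id`, `gene_read_count`,
#' `exon_model_length`, `total_mapped_reads`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_expression <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "sample_id", "gene_read_count", "exon_model_length",
           "total_mapped_reads")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("read_expression: missing columns: ", paste(miss, collapse = ", "))
  x
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `maternal_strain` ("A"/"B") and optional
#' `description`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_samples <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "maternal_strain") %in% names(x)))
    stop("read_samples: missing sample_id or maternal_strain")
  if (!all(x$maternal_strain %in% c("A", "B")))
    stop("read_samples: maternal_strain must be 'A' or 'B'")
  x
}

#' Write a pipeline table as TSV
#'
#' Plain tab-separated output with a header and no quoting or row names,
#' the format all `read_*` functions accept back unchanged.
#'
#' @param x Data frame.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write all tables of a generated cohort to a directory
#'
#' Writes `counts.tsv`, `expression.tsv`, `genes.tsv`, `samples.tsv` and
#' `truth.tsv` under `dir`.
#'
#' @param cohort List from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("counts", "expression", "genes", "samples", "truth"))
    write_tsv(cohort[[nm]], file.path(dir, paste0(nm, ".tsv")))
  invisible(dir)
}

#' Per-chromosome distribution of monoallelic genes
#'
#' Counts, per chromosome, the summarized genes monoallelic in at least
#' `min_lines` lines, together with the fraction of that chromosome's
#' summarized (evaluable) genes.
#'
#' @param patterns Gene-pattern table from [summarize_genes()].
#' @param min_lines Monoallelic-line threshold (default 1).
#' @return Data frame `chromosome`, `n_monoallelic`, `n_evaluable`,
#'   `fraction`.
#' @export
chromosome_distribution <- function(patterns, min_lines = 1) {
  if (nrow(patterns) == 0)
    return(data.frame(chromosome = character(0),
                      n_monoallelic = integer(0),
                      n_evaluable = integer(0), fraction = numeric(0)))
  chroms <- unique(patterns$chromosome)
  n_ev <- as.integer(table(factor(patterns$chromosome, levels = chroms)))
  mono <- patterns$chromosome[patterns$n_monoallelic >= min_lines]
  n_mono <- as.integer(table(factor(mono, levels = chroms)))
  data.frame(chromosome = chroms, n_monoallelic = n_mono,
             n_evaluable = n_ev, fraction = n_mono / n_ev,
             stringsAsFactors = FALSE)
}
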