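#' Configuration for a synthetic F1-hybrid cSNP-seq cohort
#'
#' Builds and validates the parameter set for [generate_cohort()].  The
#' generator emulates clonal F1-hybrid cell lines (strain A x strain B,
#' both reciprocal-cross directions) profiled by strain-resolved RNA-seq:
#' per-gene expression on a broad lognormal scale, a handful of cSNPs per
#' gene with negative-binomially dispersed depths, and planted allelic
#' classes whose per-line expressed-allele state drives both the allele
#' counts and (through `dosage_ratio`) the transcript level.
#'
#' @param n_lines Number of clonal cell lines.
#' @param maternal_strain Character vector, length `n_lines`, "A" or "B":
#'   the maternal strain of each line's founding cross.
#' @param n_genes_autosomal,n_genes_x Gene counts; autosomes are drawn
#'   uniformly from chromosomes 1-19, X genes sit on "X".
#' @param classes Data frame with columns `class`, `count`, `penetrance`
#'   planting autosomal allelic classes.  `class` is one of
#'   `mono_strain_A`, `mono_strain_B`, `mono_random`,
#'   `imprinted_maternal`, `imprinted_paternal`; `penetrance` is the
#'   per-line probability that the gene actually shows its monoallelic
#'   state in a given clone (allelic exclusion is stochastic).  Autosomal
#'   genes not covered by `classes` are biallelic.
#' @param dosage_ratio Transcript level of a monoallelic gene-line as a
#'   fraction of its biallelic level, in (0, 1].
#' @param log2_noise_sd Per-gene-line lognormal expression noise (log2
#'   scale standard deviation).
#' @param depth_mean,depth_size Negative-binomial model of the pooled SNP
#'   depth per gene-line (mean and dispersion size); each of a gene's
#'   SNPs receives an equal share so the pooled depth is exactly
#'   NB(`depth_size`, mean `depth_mean`).
#' @param snps_per_gene Integer vector from which each gene's cSNP count
#'   is drawn uniformly.
#' @param rpkm_meanlog2,rpkm_sdlog2 Location/spread of the per-gene base
#'   log2(RPKM).
#' @param contamination Fraction of reads from the silenced allele of a
#'   monoallelic gene-line (default 0.01; fully clean silencing is rare).
#' @param active_x Character vector, length `n_lines`, "A" or "B": the
#'   active X of each clone (clonal X-inactivation).  Required when
#'   `n_genes_x > 0`.
#' @param escape_gene_count Number of X genes escaping inactivation
#'   (biallelic in every line).
#' @param xist_like Plant one X gene transcribed from the inactive X
#'   (reverse direction of all other X genes).
#' @param total_mapped_reads Mapped reads per sample used to convert RPKM
#'   back to integer gene read counts.
#' @param seed Integer seed; all draws come from one stream so equal
#'   configs give byte-identical cohorts.
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_lines = 4,
                          maternal_strain = c("A", "A", "A", "B"),
                          n_genes_autosomal = 1000,
                          n_genes_x = 0,
                          classes = NULL,
                          dosage_ratio = 0.6417,
                          log2_noise_sd = 0.4,
                          depth_mean = 50,
                          depth_size = 2,
                          snps_per_gene = 1:5,
                          rpkm_meanlog2 = 4.5,
                          rpkm_sdlog2 = 2,
                          contamination = 0.01,
                          active_x = NULL,
                          escape_gene_count = 0,
                          xist_like = FALSE,
                          total_mapped_reads = 2e7,
                          seed = 1) {
  if (is.null(classes))
    classes <- data.frame(class = character(0), count = integer(0),
                          penetrance = numeric(0))
  cfg <- list(n_lines = as.integer(n_lines),
              maternal_strain = maternal_strain,
              n_genes_autosomal = as.integer(n_genes_autosomal),
              n_genes_x = as.integer(n_genes_x),
              classes = classes,
              dosage_ratio = dosage_ratio,
              log2_noise_sd = log2_noise_sd,
              depth_mean = depth_mean, depth_size = depth_size,
              snps_per_gene = as.integer(snps_per_gene),
              rpkm_meanlog2 = rpkm_meanlog2, rpkm_sdlog2 = rpkm_sdlog2,
              contamination = contamination,
              active_x = active_x,
              escape_gene_count = as.integer(escape_gene_count),
              xist_like = isTRUE(xist_like),
              total_mapped_reads = total_mapped_reads,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  known <- c("mono_strain_A", "mono_strain_B", "mono_random",
             "imprinted_maternal", "imprinted_paternal")
  cl <- cfg$classes
  if (!all(c("class", "count", "penetrance") %in% names(cl)))
    stop("cohort_config: 'classes' needs columns class, count, penetrance")
  if (!all(cl$class %in% known))
    stop("cohort_config: unknown class in 'classes': ",
         paste(setdiff(cl$class, known), collapse = ", "))
  if (any(cl$count < 0))
    stop("cohort_config: 'classes' counts must be non-negative")
  if (sum(cl$count) > cfg$n_genes_autosomal)
    stop("cohort_config: 'classes' counts sum (", sum(cl$count),
         ") exceeds n_genes_autosomal (", cfg$n_genes_autosomal, ")")
  if (any(cl$penetrance < 0 | cl$penetrance > 1))
    stop("cohort_config: 'classes' penetrance must lie in [0, 1]")
  if (cfg$dosage_ratio <= 0 || cfg$dosage_ratio > 1)
    stop("cohort_config: 'dosage_ratio' must lie in (0, 1]")
  if (cfg$log2_noise_sd < 0)
    stop("cohort_config: 'log2_noise_sd' must be non-negative")
  if (length(cfg$maternal_strain) != cfg$n_lines ||
      !all(cfg$maternal_strain %in% c("A", "B")))
    stop("cohort_config: 'maternal_strain' needs one of A/B per line")
  if (cfg$contamination < 0 || cfg$contamination >= 0.5)
    stop("cohort_config: 'contamination' must lie in [0, 0.5)")
  if (cfg$n_genes_x > 0) {
    if (is.null(cfg$active_x) || length(cfg$active_x) != cfg$n_lines ||
        !all(cfg$active_x %in% c("A", "B")))
      stop("cohort_config: 'active_x' needs one of A/B per line when ",
           "n_genes_x > 0")
    if (cfg$escape_gene_count + cfg$xist_like > cfg$n_genes_x)
      stop("cohort_config: 'escape_gene_count' plus the Xist-like gene ",
           "exceeds n_genes_x")
  }
  invisible(cfg)
}

other_strain <- function(s) ifelse(s == "A", "B", "A")

#' Generate a synthetic cSNP-seq cohort with known planted allelic classes
#'
#' Draws a complete cohort from a [cohort_config()]: per-SNP allele
#' counts, per-gene-line expression records, gene models, sample
#' metadata, and a ground-truth table recording each gene's planted
#' class and per-line expressed-allele state.
#'
#' Per gene-line, the expressed-allele state ("AB", "A" or "B") follows
#' the planted class (fair-coin allele choice per line for random
#' monoallelic genes, parent-of-origin for imprinted genes, the clone's
#' active X for X-linked genes).  Monoallelic states multiply the
#' transcript level by `dosage_ratio`.  Each SNP's depth takes an equal
#' negative-binomial share of the gene-line pooled depth, and strain-A
#' reads are binomial with success probability 0.5 (biallelic),
#' `1 - contamination` (A expressed) or `contamination` (B expressed).
#'
#' @param config A [cohort_config()].
#' @return List of data frames: `counts` (per-SNP allele depths),
#'   `expression` (read counts convertible to RPKM), `genes` (gene
#'   models: id, chromosome, exon length, SNP count), `samples` (line
#'   metadata), `truth` (planted class, per-line state, base log2 RPKM).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  nl <- config$n_lines
  samples <- data.frame(
    sample_id = paste0("line", seq_len(nl)),
    maternal_strain = config$maternal_strain,
    description = paste0("clonal F1 line, maternal strain ",
                         config$maternal_strain),
    stringsAsFactors = FALSE
  )

  na <- config$n_genes_autosomal
  nx <- config$n_genes_x
  ng <- na + nx
  gene_id <- c(sprintf("gA%05d", seq_len(na)),
               if (nx > 0) sprintf("gX%04d", seq_len(nx)))
  chromosome <- c(as.character(sample(1:19, na, replace = TRUE)),
                  rep("X", nx))

  planted <- rep("biallelic", ng)
  penetrance <- rep(1, ng)
  cl <- config$classes
  pos <- 1L
  for (i in seq_len(nrow(cl))) {
    if (cl$count[i] == 0) next
    idx <- pos:(pos + cl$count[i] - 1L)
    planted[idx] <- cl$class[i]
    penetrance[idx] <- cl$penetrance[i]
    pos <- pos + cl$count[i]
  }
  if (nx > 0) {
    xi <- na + seq_len(nx)
    planted[xi] <- "x_subject"
    if (config$escape_gene_count > 0)
      planted[na + seq_len(config$escape_gene_count)] <- "x_escape"
    if (config$xist_like) planted[na + nx] <- "xist_like"
  }

  # per-line expressed-allele state
  state <- matrix("AB", nrow = ng, ncol = nl)
  for (j in seq_len(nl)) {
    mat <- config$maternal_strain[j]
    mono <- stats::runif(ng) < penetrance
    coin <- ifelse(stats::runif(ng) < 0.5, "A", "B")
    state[, j] <- ifelse(
      planted == "mono_strain_A" & mono, "A",
      ifelse(planted == "mono_strain_B" & mono, "B",
      ifelse(planted == "mono_random" & mono, coin,
      ifelse(planted == "imprinted_maternal" & mono, mat,
      ifelse(planted == "imprinted_paternal" & mono, other_strain(mat),
      ifelse(planted == "x_subject", config$active_x[j] %||% "AB",
      ifelse(planted == "xist_like",
             other_strain(config$active_x[j] %||% "B"), "AB")))))))
  }

  base_l2 <- stats::rnorm(ng, config$rpkm_meanlog2, config$rpkm_sdlog2)
  # escape and Xist-like genes are constitutively, robustly expressed in
  # real cells; floor them at the cohort's median expression
  hi <- planted %in% c("x_escape", "xist_like")
  base_l2[hi] <- pmax(base_l2[hi], config$rpkm_meanlog2)
  snps <- sample(config$snps_per_gene, ng, replace = TRUE)
  exon_len <- sample(500:5000, ng, replace = TRUE)
  genes <- data.frame(gene_id = gene_id, chromosome = chromosome,
                      exon_model_length = exon_len, n_snps = snps,
                      stringsAsFactors = FALSE)

  # expression table: gene x line
  gl_gene <- rep(seq_len(ng), times = nl)
  gl_line <- rep(seq_len(nl), each = ng)
  st <- state[cbind(gl_gene, gl_line)]
  l2 <- base_l2[gl_gene] +
    stats::rnorm(ng * nl, 0, config$log2_noise_sd) +
    ifelse(st == "AB", 0, log2(config$dosage_ratio))
  rpkm <- 2^l2
  reads <- as.integer(round(rpkm * config$total_mapped_reads *
                              exon_len[gl_gene] / 1e9))
  expression <- data.frame(
    gene_id = gene_id[gl_gene],
    sample_id = samples$sample_id[gl_line],
    gene_read_count = reads,
    exon_model_length = exon_len[gl_gene],
    total_mapped_reads = config$total_mapped_reads,
    stringsAsFactors = FALSE
  )

  # counts table: gene x line x snp, equal NB share per SNP so the pooled
  # depth is NB(depth_size, mean depth_mean)
  snp_of_gene <- sequence(snps)
  row_gene <- rep(seq_len(ng), times = snps)
  snp_pos <- 1000L * row_gene + 10L * snp_of_gene  # synthetic coordinates
  cnt_gene <- rep(row_gene, times = nl)
  cnt_snp <- rep(snp_of_gene, times = nl)
  cnt_posn <- rep(snp_pos, times = nl)
  cnt_line <- rep(seq_len(nl), each = length(row_gene))
  share <- snps[cnt_gene]
  depth <- stats::rnbinom(length(cnt_gene),
                          size = config$depth_size / share,
                          mu = config$depth_mean / share)
  st2 <- state[cbind(cnt_gene, cnt_line)]
  p_a <- ifelse(st2 == "AB", 0.5,
                ifelse(st2 == "A", 1 - config$contamination,
                       config$contamination))
  a <- stats::rbinom(length(depth), depth, p_a)
  counts <- data.frame(
    gene_id = gene_id[cnt_gene],
    snp_id = paste0(gene_id[cnt_gene], "_s", cnt_snp),
    chromosome = chromosome[cnt_gene],
    position = cnt_posn,
    sample_id = samples$sample_id[cnt_line],
    count_strain_A = a,
    count_strain_B = depth - a,
    stringsAsFactors = FALSE
  )

  truth <- data.frame(gene_id = gene_id, chromosome = chromosome,
                      planted_class = planted,
                      true_log2_rpkm = base_l2,
                      stringsAsFactors = FALSE)
  for (j in seq_len(nl))
    truth[[paste0("state_", samples$sample_id[j])]] <- state[, j]

  list(counts = counts, expression = expression, genes = genes,
       samples = samples, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged cohort profiles
#'
#' Two frozen [cohort_config()]s reproducing the study design of a
#' four-clone F1-hybrid neural-stem-cell cohort (three lines of one cross
#' direction plus one reciprocal line):
#' \describe{
#'   \item{`"nsc-autosome"`}{~7,200 autosomal genes evaluable in at least
#'     2 lines, with planted strain-biased, random-monoallelic and
#'     imprinted classes whose expected downstream pattern counts match
#'     the reported cohort composition.}
#'   \item{`"nsc-x"`}{An X-chromosome cohort with clonal X-inactivation
#'     (one active X per line), a four-gene escape set and one Xist-like
#'     gene expressed from the inactive X.}
#' }
#'
#' @param name Profile name.
#' @param seed Integer seed stored in the returned config.
#' @return A [cohort_config()].
#' @export
cohort_profile <- function(name, seed = 1) {
  profiles <- c("nsc-autosome", "nsc-x")
  if (!name %in% profiles)
    stop("cohort_profile: unknown profile '", name, "'; available: ",
         paste(profiles, collapse = ", "))
  if (name == "nsc-autosome") {
    cohort_config(
      n_lines = 4,
      maternal_strain = c("A", "A", "A", "B"),
      n_genes_autosomal = 7750,
      classes = data.frame(
        class = c("mono_strain_A", "mono_strain_B", "mono_random",
                  "mono_strain_A", "mono_strain_B",
                  "imprinted_maternal", "imprinted_paternal"),
        count = c(91, 40, 34, 550, 550, 1, 2),
        penetrance = c(0.66, 0.88, 0.90, 0.10, 0.10, 1, 1)
      ),
      dosage_ratio = 0.6417,
      log2_noise_sd = 0.4,
      depth_mean = 50, depth_size = 2,
      snps_per_gene = 1:5,
      rpkm_meanlog2 = 4.5, rpkm_sdlog2 = 2,
      contamination = 0.01,
      seed = seed
    )
  } else {
    cohort_config(
      n_lines = 4,
      maternal_strain = c("A", "A", "A", "B"),
      n_genes_autosomal = 0,
      n_genes_x = 292,
      dosage_ratio = 0.6417,
      log2_noise_sd = 0.4,
      depth_mean = 50, depth_size = 2,
      snps_per_gene = 1:5,
      rpkm_meanlog2 = 4.5, rpkm_sdlog2 = 2,
      contamination = 0.01,
      active_x = c("B", "A", "B", "B"),
      escape_gene_count = 4,
      xist_like = TRUE,
      seed = seed
    )
  }
}

#' Simulate mixed-pattern genes for the paired expression analysis
#'
#' Generates a call-table of genes that are monoallelic in some cell
#' lines and biallelic in others ("mixed pattern").  Each gene draws a
#' base log2(RPKM); its monoallelic lines express
#' `dosage_ratio` times the biallelic level, and every gene-line adds
#' independent lognormal noise (`log2_noise_sd`).  The number of
#' monoallelic lines per gene is uniform on 1..(n_lines - 1).
#'
#' @param n_genes Number of mixed-pattern genes.
#' @param dosage_ratio Monoallelic/biallelic transcript ratio in (0, 1].
#' @param log2_noise_sd Per-gene-line log2-scale noise sd.
#' @param n_lines Number of cell lines (default 4).
#' @param rpkm_meanlog2,rpkm_sdlog2 Base expression distribution.
#' @param seed Integer seed.
#' @return A call-style data frame (`gene_id`, `sample_id`, `rpkm`,
#'   `evaluable`, `category`) consumable by [paired_mono_bi_analysis()].
#' @export
simulate_mixed_pattern <- function(n_genes, dosage_ratio,
                                   log2_noise_sd = 0.4, n_lines = 4,
                                   rpkm_meanlog2 = 4.5, rpkm_sdlog2 = 2,
                                   seed = 1) {
  if (dosage_ratio <= 0 || dosage_ratio > 1)
    stop("simulate_mixed_pattern: 'dosage_ratio' must lie in (0, 1]")
  set.seed(seed)
  base <- stats::rnorm(n_genes, rpkm_meanlog2, rpkm_sdlog2)
  n_mono <- sample(seq_len(n_lines - 1), n_genes, replace = TRUE)
  gl_gene <- rep(seq_len(n_genes), each = n_lines)
  gl_line <- rep(seq_len(n_lines), times = n_genes)
  is_mono <- gl_line <= n_mono[gl_gene]
  l2 <- base[gl_gene] + stats::rnorm(n_genes * n_lines, 0, log2_noise_sd) +
    ifelse(is_mono, log2(dosage_ratio), 0)
  data.frame(
    gene_id = sprintf("g%05d", gl_gene),
    sample_id = paste0("line", gl_line),
    rpkm = 2^l2,
    evaluable = TRUE,
    category = factor(ifelse(is_mono, "monoallelic", "biallelic"),
                      levels = ase_categories()),
    stringsAsFactors = FALSE
  )
}
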