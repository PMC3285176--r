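test_that("invalid configurations are rejected with the offending field", {
  expect_error(cohort_config(dosage_ratio = 0), "dosage_ratio")
  expect_error(cohort_config(dosage_ratio = 1.2), "dosage_ratio")
  expect_error(cohort_config(log2_noise_sd = -1), "log2_noise_sd")
  expect_error(cohort_config(maternal_strain = c("A", "A")), "maternal_strain")
  expect_error(cohort_config(
    n_genes_autosomal = 10,
    classes = data.frame(class = "mono_strain_A", count = 11,
                         penetrance = 1)), "exceeds n_genes_autosomal")
  expect_error(cohort_config(
    classes = data.frame(class = "mono_purple", count = 1,
                         penetrance = 1)), "unknown class")
  expect_error(cohort_config(n_genes_x = 5), "active_x")
})

test_that("the same config and seed give identical cohorts", {
  cfg <- cohort_config(n_genes_autosomal = 150, seed = 99,
                       classes = data.frame(class = "mono_random",
                                            count = 10, penetrance = 0.8))
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cohort_config(n_genes_autosomal = 150, seed = 100,
                        classes = cfg$classes)
  expect_false(identical(generate_cohort(cfg)$counts,
                         generate_cohort(cfg2)$counts))
})

test_that("planted strong monoallelic genes are fully recovered", {
  cfg <- cohort_config(
    n_genes_autosomal = 60, seed = 5,
    classes = data.frame(class = "mono_strain_A", count = 10,
                         penetrance = 1),
    depth_mean = 100, depth_size = 5, contamination = 0,
    rpkm_meanlog2 = 6, rpkm_sdlog2 = 1)
  co <- generate_cohort(cfg)
  fit <- ase_fit(co$counts, co$expression, co$samples)
  mono_ids <- co$truth$gene_id[co$truth$planted_class == "mono_strain_A"]
  calls <- fit$calls[fit$calls$gene_id %in% mono_ids & fit$calls$evaluable, ]
  expect_true(all(calls$category == "monoallelic"))
  expect_true(all(calls$direction == "A"))
  expect_equal(length(unique(calls$gene_id)), 10L)
})

test_that("downstream recovery of planted monoallelic states is >= 99%", {
  for (s in 1:5) {
    co <- generate_cohort(cohort_config(
      n_genes_autosomal = 300, seed = s,
      classes = data.frame(
        class = c("mono_strain_A", "mono_strain_B", "mono_random"),
        count = c(25, 25, 25), penetrance = 1),
      depth_mean = 50, contamination = 0.01))
    fit <- ase_fit(co$counts, co$expression, co$samples)
    state_cols <- paste0("state_", co$samples$sample_id)
    truth_long <- data.frame(
      gene_id = rep(co$truth$gene_id, length(state_cols)),
      sample_id = rep(co$samples$sample_id, each = nrow(co$truth)),
      state = unlist(co$truth[state_cols], use.names = FALSE),
      stringsAsFactors = FALSE
    )
    m <- merge(fit$calls, truth_long, by = c("gene_id", "sample_id"))
    planted <- m[m$state %in% c("A", "B") & m$evaluable, ]
    hit <- planted$category == "monoallelic" &
      planted$direction == planted$state
    expect_gte(mean(hit), 0.99)
  }
})

test_that("null monoallelic call rate matches the analytic probability", {
  co <- generate_cohort(cohort_config(n_genes_autosomal = 2000, seed = 2,
                                      depth_mean = 50))
  fit <- ase_fit(co$counts, co$expression, co$samples)
  ev <- fit$calls[fit$calls$evaluable, ]
  p_null <- null_call_probability(ev$n)
  expected <- sum(p_null)
  se <- sqrt(sum(p_null * (1 - p_null)))
  observed <- sum(ev$category == "monoallelic")
  expect_lt(abs(observed - expected), 3 * se + 1e-9)
})

test_that("dosage effect on expression is recovered from the truth table", {
  cfg <- cohort_config(
    n_genes_autosomal = 500, seed = 6,
    classes = data.frame(class = "mono_random", count = 200,
                         penetrance = 0.5),
    dosage_ratio = 0.6417)
  co <- generate_cohort(cfg)
  expr <- co$expression
  expr$rpkm <- compute_rpkm(expr$gene_read_count, expr$exon_model_length,
                            expr$total_mapped_reads)
  state_cols <- paste0("state_", co$samples$sample_id)
  st <- unlist(co$truth[state_cols], use.names = FALSE)
  key <- paste(rep(co$truth$gene_id, length(state_cols)),
               rep(co$samples$sample_id, each = nrow(co$truth)))
  expr$state <- st[match(paste(expr$gene_id, expr$sample_id), key)]
  mixed <- co$truth$gene_id[co$truth$planted_class == "mono_random"]
  e <- expr[expr$gene_id %in% mixed & expr$rpkm > 0, ]
  l2 <- log2(e$rpkm)
  mono_mean <- tapply(l2[e$state != "AB"], e$gene_id[e$state != "AB"], mean)
  bi_mean <- tapply(l2[e$state == "AB"], e$gene_id[e$state == "AB"], mean)
  genes <- intersect(names(mono_mean), names(bi_mean))
  d <- bi_mean[genes] - mono_mean[genes]
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - (-log2(0.6417))), 3 * se)
})

test_that("profiles are fully specified and unknown names error", {
  expect_error(cohort_profile("nope"), "available")
  auto <- cohort_profile("nsc-autosome")
  expect_s3_class(auto, "cohort_config")
  expect_equal(auto$n_lines, 4L)
  expect_equal(sum(auto$maternal_strain == "A"), 3L)
  expect_equal(sum(auto$maternal_strain == "B"), 1L)
  x <- cohort_profile("nsc-x")
  expect_equal(x$escape_gene_count, 4L)
  expect_true(x$xist_like)
  expect_equal(x$n_genes_autosomal, 0L)
})

test_that("X truth respects clonal inactivation and Xist reversal", {
  co <- generate_cohort(cohort_profile("nsc-x", seed = 8))
  tr <- co$truth
  subj <- tr[tr$planted_class == "x_subject", ]
  xist <- tr[tr$planted_class == "xist_like", ]
  expect_equal(nrow(xist), 1L)
  for (s in co$samples$sample_id) {
    col <- paste0("state_", s)
    expect_equal(length(unique(subj[[col]])), 1L)  # one active X per clone
    expect_false(xist[[col]] == unique(subj[[col]]))  # reversed
  }
  expect_true(all(tr[tr$planted_class == "x_escape",
                     paste0("state_", co$samples$sample_id)] == "AB"))
})
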