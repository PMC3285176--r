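test_that("summarize counts evaluable and monoallelic lines", {
  calls <- make_calls("g1",
                      category = c("monoallelic", "monoallelic",
                                   "biallelic", NA),
                      direction = c("A", "A", NA, NA))
  p <- summarize_genes(calls, meta31())
  expect_equal(p$n_evaluable, 3L)
  expect_equal(p$n_monoallelic, 2L)
  expect_equal(as.character(p$pattern), "strainA_or_biallelic")
})

test_that("genes below the evaluability floor are dropped", {
  calls <- make_calls("g1", category = c("monoallelic", NA, NA, NA),
                      direction = "A")
  expect_equal(nrow(summarize_genes(calls, meta31())), 0)
  expect_equal(nrow(summarize_genes(calls, meta31(), min_evaluable = 1)), 1)
})

test_that("trend and excluded count as evaluable but not monoallelic", {
  calls <- make_calls("g1", category = c("trend", "excluded",
                                         "biallelic", "biallelic"),
                      direction = c("A", NA, NA, NA))
  p <- summarize_genes(calls, meta31())
  expect_equal(p$n_evaluable, 4L)
  expect_equal(p$n_monoallelic, 0L)
  expect_equal(as.character(p$pattern), "biallelic_all")
  # trend direction votes only when opted in
  p2 <- summarize_genes(calls, meta31(), use_trend_direction = TRUE)
  expect_equal(as.character(p2$pattern), "strainA_or_biallelic")
})

test_that("opposite strains across lines give a haplotype-independent call", {
  calls <- make_calls("g1",
                      category = c("monoallelic", "monoallelic",
                                   "biallelic", "biallelic"),
                      direction = c("A", "B", NA, NA))
  p <- summarize_genes(calls, meta31())
  expect_equal(as.character(p$pattern), "both_alleles_observed")
})

test_that("imprinting needs origin consistency across both cross directions", {
  # B expressed in the A-maternal lines, A in the B-maternal line:
  # always the paternal allele
  pat <- make_calls("g1", category = "monoallelic",
                    direction = c("B", "B", "B", "A"))
  p <- summarize_genes(pat, meta31())
  expect_equal(as.character(p$pattern), "imprinted_paternal")
  # maternal mirror image
  mat <- make_calls("g2", category = "monoallelic",
                    direction = c("A", "A", "A", "B"))
  expect_equal(as.character(summarize_genes(mat, meta31())$pattern),
               "imprinted_maternal")
  # same strain in both directions: origins differ, not imprinted
  fix <- make_calls("g3", category = "monoallelic", direction = "B")
  expect_equal(as.character(summarize_genes(fix, meta31())$pattern),
               "strainB_only")
  # both strains within one cross direction: inconsistent origin
  one_dir <- make_calls("g4",
                        category = c("monoallelic", "monoallelic",
                                     "biallelic", NA),
                        direction = c("A", "B", NA, NA))
  expect_equal(as.character(summarize_genes(one_dir, meta31())$pattern),
               "both_alleles_observed")
})

test_that("imprinting calls are invariant under consistent strain relabeling", {
  calls <- make_calls("g1", category = "monoallelic",
                      direction = c("B", "B", "B", "A"))
  p1 <- summarize_genes(calls, meta31())
  swap <- function(x) chartr("AB", "BA", x)
  calls2 <- calls
  calls2$direction <- swap(calls2$direction)
  meta2 <- meta31()
  meta2$maternal_strain <- swap(meta2$maternal_strain)
  p2 <- summarize_genes(calls2, meta2)
  expect_equal(as.character(p1$pattern), as.character(p2$pattern))
})

test_that("duplicate gene-sample rows and missing metadata are errors", {
  calls <- rbind(make_calls("g1", "monoallelic", "A"),
                 make_calls("g1", "monoallelic", "A"))
  expect_error(summarize_genes(calls, meta31()), "duplicate")
  calls2 <- make_calls("g1", "monoallelic", "A")
  meta_na <- meta31()
  meta_na$maternal_strain[1] <- NA
  expect_error(summarize_genes(calls2, meta_na), "maternal_strain")
})

test_that("every summarized gene receives exactly one pattern", {
  co <- generate_cohort(cohort_config(
    n_genes_autosomal = 600, seed = 4,
    classes = data.frame(
      class = c("mono_strain_A", "mono_random", "imprinted_paternal"),
      count = c(30, 20, 5), penetrance = c(0.7, 0.7, 1))))
  fit <- ase_fit(co$counts, co$expression, co$samples)
  expect_false(anyNA(fit$patterns$pattern))
  expect_equal(sum(table(fit$patterns$pattern)), nrow(fit$patterns))
  expect_true(all(fit$patterns$n_monoallelic <= fit$patterns$n_evaluable))
})

test_that("planted imprinted genes are recovered and strain-biased never are", {
  for (s in 1:5) {
    co <- generate_cohort(cohort_config(
      n_genes_autosomal = 400, seed = s,
      classes = data.frame(
        class = c("imprinted_paternal", "imprinted_maternal",
                  "mono_strain_A", "mono_strain_B"),
        count = c(6, 2, 25, 25), penetrance = 1),
      depth_mean = 80, depth_size = 5, rpkm_meanlog2 = 6))
    fit <- ase_fit(co$counts, co$expression, co$samples)
    p <- fit$patterns
    p$planted <- co$truth$planted_class[match(p$gene_id, co$truth$gene_id)]
    imp_called <- grepl("imprinted", p$pattern)
    # no strain-biased gene is ever called imprinted
    expect_false(any(imp_called & grepl("mono_strain", p$planted)))
    # planted imprinted genes with monoallelic evidence from both cross
    # directions are all recovered with the right origin
    line4_mono <- p$cat_line4 == "monoallelic" & !is.na(p$cat_line4)
    recip <- grepl("imprinted", p$planted) & line4_mono &
      p$n_monoallelic >= 2
    expect_true(all(paste0("imprinted_",
                           sub("imprinted_", "", p$planted[recip])) ==
                      as.character(p$pattern[recip])))
    expect_gt(sum(recip), 0)
  }
})

test_that("X report finds consensus, reversal and escape candidates", {
  # 30 subject genes expressing B plus Xist-like expressing A, one line
  subj <- do.call(rbind, lapply(1:30, function(i)
    make_calls(sprintf("x%02d", i), "monoallelic", "B", chromosome = "X")))
  xist <- make_calls("xist", "monoallelic", "A", chromosome = "X")
  esc <- make_calls("esc1", "biallelic", NA, chromosome = "X")
  calls <- rbind(subj, xist, esc)
  rep <- x_chromosome_report(calls, xist_gene_id = "xist")
  expect_equal(rep$per_line$active_x, rep("B", 4))
  expect_true(all(rep$per_line$xist_reversed))
  expect_equal(rep$escape_candidates, "esc1")
  expect_equal(rep$n_evaluable_ge1, 32L)
  expect_equal(rep$n_monoallelic_ge1, 31L)
})

test_that("degenerate X inputs warn", {
  allbi <- make_calls("x1", "biallelic", NA, chromosome = "X")
  expect_warning(x_chromosome_report(rbind(
    allbi, make_calls("x2", "biallelic", NA, chromosome = "X"))),
    "no consensus")
  none <- make_calls("a1", "monoallelic", "A", chromosome = "1")
  expect_warning(x_chromosome_report(none), "no evaluable")
})
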