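# Hand-built call/sample tables for aggregate and compare tests.

# Standard 3+1 reciprocal-cross metadata: lines 1-3 A-maternal, line 4
# B-maternal.
meta31 <- function() {
  data.frame(sample_id = paste0("line", 1:4),
             maternal_strain = c("A", "A", "A", "B"),
             stringsAsFactors = FALSE)
}

# One gene's per-line call rows. `category` / `direction` vectors are
# recycled over lines; NA category means not_evaluable.
make_calls <- function(gene_id, category, direction = NA_character_,
                       rpkm = 10, sample_id = paste0("line", 1:4),
                       chromosome = "1") {
  category <- rep(category, length.out = length(sample_id))
  direction <- rep(direction, length.out = length(sample_id))
  rpkm <- rep(rpkm, length.out = length(sample_id))
  category[is.na(category)] <- "not_evaluable"
  data.frame(
    gene_id = gene_id, sample_id = sample_id, chromosome = chromosome,
    k_strain_A = NA_integer_, n = 50L, p_a = NA_real_, p_value = NA_real_,
    rpkm = rpkm, evaluable = category != "not_evaluable",
    category = factor(category, levels = asecall::ase_categories()),
    direction = direction, stringsAsFactors = FALSE
  )
}
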