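# Small in-code fixtures shared across test files.

# A one-gene model whose first pext tissue carries the exon value and the
# other 12 are zero (so brain_pext == the given value).
make_model <- function(gene_id = "G1", cds_length = 3000,
                       exon_bounds = list(c(1, 1500), c(1501, 3000)),
                       pext = c(0.8, 0.8)) {
  tissues <- lofburden:::pext_tissues
  purrr::imap_dfr(exon_bounds, function(b, i) {
    row <- tibble::tibble(gene_id = gene_id, cds_length = cds_length,
                          exon_index = i,
                          cds_start = b[1], cds_end = b[2])
    for (t in tissues) row[[paste0("pext_", t)]] <- 0
    row[[paste0("pext_", tissues[1])]] <- pext[i]
    row
  })
}

# One variant row that passes every stringency filter by default.
make_variant <- function(variant_id = "V1", gene_id = "G1",
                         individual_id = "I1", consequence = "LoF",
                         loftee_flag = "high_confidence",
                         loftee_other_flags = "",
                         ref_pop_af = 0, sample_af = 0.001,
                         allele_count = 1L, cds_position = 300L,
                         is_splice_site = FALSE,
                         splice_offset_bp = NA_integer_) {
  tibble::tibble(variant_id = variant_id, gene_id = gene_id,
                 individual_id = individual_id, consequence = consequence,
                 loftee_flag = loftee_flag,
                 loftee_other_flags = loftee_other_flags,
                 ref_pop_af = ref_pop_af, sample_af = sample_af,
                 allele_count = allele_count, cds_position = cds_position,
                 is_splice_site = is_splice_site,
                 splice_offset_bp = splice_offset_bp)
}

# Passing genotype metrics for every variant row.
make_calls <- function(variants, depth = 30L, genotype_quality = 50L,
                       allelic_fraction = 0.5, call_rate = 0.99,
                       autosomal = TRUE) {
  tibble::tibble(variant_id = variants$variant_id,
                 individual_id = variants$individual_id,
                 depth = depth, genotype_quality = genotype_quality,
                 allelic_fraction = allelic_fraction, call_rate = call_rate,
                 autosomal = autosomal)
}

# Minimal cohort for estimator tests: ids, status, sex.
make_cohort <- function(n_diagnosed, n_undiagnosed) {
  n <- n_diagnosed + n_undiagnosed
  tibble::tibble(
    individual_id = sprintf("I%05d", seq_len(n)),
    status = rep(c("diagnosed", "undiagnosed"),
                 c(n_diagnosed, n_undiagnosed)),
    role = rep(c("proband", "population"), c(n_diagnosed, n_undiagnosed)),
    sex = rep_len(c("male", "female"), n)
  )
}

# Carrier calls for one gene: given carrier ids, one unique variant each.
make_carriers <- function(ids, gene_id = "G1", prefix = "V") {
  tibble::tibble(gene_id = gene_id, individual_id = ids,
                 variant_id = paste0(prefix, seq_along(ids)))
}
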