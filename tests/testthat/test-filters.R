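test_that("genotype QC thresholds act exactly at their printed boundaries", {
  calls <- tibble::tibble(
    depth = c(21, 20, 30, 30, 30, 30, 30, 30, 30),
    genotype_quality = c(30, 30, 29, 30, 30, 30, 30, 30, 30),
    allelic_fraction = c(0.5, 0.5, 0.5, 0.25, 0.249, 0.75, 0.76, 0.8, 0.8),
    call_rate = c(0.95, 0.95, 0.95, 0.95, 0.95, 0.95, 0.95, 0.95, 0.95),
    autosomal = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  res <- qc_genotype(calls)
  expect_equal(res$qc_pass,
               c(TRUE,   # DP 21 passes (strict > 20)
                 FALSE,  # DP 20 fails
                 FALSE,  # GQ 29 fails (inclusive >= 30)
                 TRUE,   # AF 0.25 passes (inclusive)
                 FALSE,  # AF 0.249 fails
                 TRUE,   # AF 0.75 passes on autosome (inclusive <= 0.75)
                 FALSE,  # AF 0.76 fails on autosome
                 FALSE,  # AF 0.80 fails on autosome
                 TRUE))  # AF 0.80 passes off-autosome
  # call-rate boundary is strict and a missing metric fails with its reason
  cr <- qc_genotype(tibble::tibble(depth = 30, genotype_quality = 50,
                                   allelic_fraction = 0.5,
                                   call_rate = c(0.9, 0.901, NA),
                                   autosomal = TRUE))
  expect_equal(cr$qc_pass, c(FALSE, TRUE, FALSE))
  expect_equal(cr$qc_reason[3], "missing_metric")
})

test_that("frequency filter modes differ only on the reference population", {
  expect_true(frequency_filter(0, 0.001, "strict"))
  expect_true(frequency_filter(0, 0.001, "maf"))
  expect_false(frequency_filter(0.005, 0.001, "strict"))
  expect_true(frequency_filter(0.005, 0.001, "maf"))
  expect_false(frequency_filter(0, 0.015, "strict"))
  expect_false(frequency_filter(0.005, 0.015, "maf"))
})

test_that("recurrent-gene and annotation-confidence filters follow the rules", {
  expect_false(recurrent_gene_filter("TTN"))
  expect_true(recurrent_gene_filter("SCN2A"))
  expect_true(recurrent_gene_filter("TTN", blocklist = character(0)))
  expect_true(loftee_filter("high_confidence", ""))
  expect_false(loftee_filter("low_confidence", ""))
  expect_false(loftee_filter("high_confidence", "SINGLE_EXON"))
})

test_that("splice variants map within 3 bp inclusive and fail beyond", {
  model <- make_model(exon_bounds = list(c(1, 1500), c(1501, 3000)),
                      pext = c(0.8, 0.8))
  v <- dplyr::bind_rows(
    make_variant("V1", cds_position = 1501L, is_splice_site = TRUE,
                 splice_offset_bp = 2L),
    make_variant("V2", cds_position = 1501L, is_splice_site = TRUE,
                 splice_offset_bp = 3L),
    make_variant("V3", cds_position = 1501L, is_splice_site = TRUE,
                 splice_offset_bp = 4L)
  )
  mapped <- map_splice_to_exon(v, model, window = 3)
  expect_equal(mapped$effective_exon_index, c(2L, 2L, NA))
  expect_equal(mapped$effective_cds_position, c(1501L, 1501L, NA))
  expect_equal(mapped$splice_reason, c(NA, NA, "unmapped_splice"))
})

test_that("brain pext is the maximum over available tissues", {
  model <- make_model(exon_bounds = list(c(1, 3000)), pext = 0.2)
  model$pext_cortex <- 0.8
  model$pext_amygdala <- NA
  bp <- brain_pext(model)
  expect_equal(bp$brain_pext, 0.8)
  all_na <- make_model(exon_bounds = list(c(1, 3000)), pext = 0)
  all_na[grep("^pext_", names(all_na))] <- NA_real_
  expect_true(is.na(brain_pext(all_na)$brain_pext))
  all_zero <- make_model(exon_bounds = list(c(1, 3000)), pext = 0)
  expect_equal(brain_pext(all_zero)$brain_pext, 0)
})

test_that("truncated fraction is arithmetic with strict bounds", {
  expect_equal(truncated_fraction(300, 3000), 0.9)
  expect_equal(truncated_fraction(2701, 3000), 0.0996667, tolerance = 1e-6)
  expect_equal(truncated_fraction(3000, 3000), 0)
  expect_error(truncated_fraction(3001, 3000), "position_out_of_cds")
  expect_error(truncated_fraction(0, 3000), ">= 1")
})

test_that("classification requires every filter and is strict at thresholds", {
  model <- make_model(exon_bounds = list(c(1, 1500), c(1501, 3000)),
                      pext = c(0.5, 0.5))
  model_lowpext <- make_model(gene_id = "G2",
                              exon_bounds = list(c(1, 3000)), pext = 0.10)
  # pext 0.5 exon, truncation 0.9: qualifies
  v_pass <- make_variant("V1", cds_position = 300L)
  # exon with pext exactly 0.10 fails the strict rule
  v_pext <- make_variant("V2", gene_id = "G2", cds_position = 300L)
  # truncation exactly 0.10 fails; just above passes
  v_tr_eq <- make_variant("V3", cds_position = 2700L)
  v_tr_ok <- make_variant("V4", cds_position = 2699L)
  # synonymous with all shared filters passing
  v_syn <- make_variant("V5", consequence = "synonymous",
                        cds_position = 400L)
  cl <- classify_variants(dplyr::bind_rows(v_pass, v_pext, v_tr_eq, v_tr_ok,
                                           v_syn),
                          dplyr::bind_rows(model, model_lowpext))
  expect_equal(cl$class, c("S_LOF", "OTHER", "OTHER", "S_LOF", "S_SYN"))
  expect_match(cl$failed_filters[2], "pext")
  expect_match(cl$failed_filters[3], "truncation")
})

test_that("raising pext or truncation thresholds never adds S-LoFs", {
  co <- make_cohort(300, 700)
  genes <- simulate_gene_panel(n_autism = 6, n_constrained = 6, n_other = 3,
                               carrier_freq_diagnosed = 0.05,
                               carrier_freq_undiagnosed = 0.02,
                               low_pext_fraction = 0.4, seed = 12)
  sim <- simulate_variants(co, genes, seed = 13, decoys_per_gene = 3)
  models <- gene_models(genes)
  counts <- sapply(c(0.1, 0.3, 0.5, 0.7), function(thr) {
    sum(classify_variants(sim$variants, models,
                          config = classify_config(pext_threshold = thr))$class == "S_LOF")
  })
  expect_true(all(diff(counts) <= 0))
  counts_tr <- sapply(c(0.1, 0.3, 0.5, 0.7), function(thr) {
    sum(classify_variants(sim$variants, models,
                          config = classify_config(truncation_threshold = thr))$class == "S_LOF")
  })
  expect_true(all(diff(counts_tr) <= 0))
  # class subsets respect consequence
  cl <- classify_variants(sim$variants, models)
  expect_true(all(cl$consequence[cl$class == "S_LOF"] == "LoF"))
  expect_true(all(cl$consequence[cl$class == "S_SYN"] == "synonymous"))
})

test_that("a variant's classification does not depend on unrelated rows", {
  co <- make_cohort(100, 300)
  genes <- simulate_gene_panel(n_autism = 4, n_constrained = 4, n_other = 0,
                               carrier_freq_diagnosed = 0.1,
                               carrier_freq_undiagnosed = 0.05, seed = 14)
  sim <- simulate_variants(co, genes, seed = 15, decoys_per_gene = 2)
  models <- gene_models(genes)
  full <- classify_variants(sim$variants, models)
  set.seed(99)
  keep <- sample(nrow(sim$variants), ceiling(nrow(sim$variants) / 3))
  sub <- classify_variants(sim$variants[keep, ], models)
  merged <- dplyr::inner_join(
    full |> dplyr::select(variant_id, class_full = class),
    sub |> dplyr::select(variant_id, class_sub = class),
    by = "variant_id")
  expect_equal(merged$class_full, merged$class_sub)
})

test_that("in-phase MNVs in the vicinity window rescue the LoF call", {
  model <- make_model()
  v <- dplyr::bind_rows(
    make_variant("V1", cds_position = 300L),  # rescued by in-phase partner
    make_variant("V2", cds_position = 600L),  # isolated
    make_variant("V3", cds_position = 900L),  # partner outside the window
    make_variant("V4", cds_position = 1200L)  # unknown phase
  )
  pairs <- tibble::tibble(
    variant_id = c("V1", "V3", "V4"),
    partner_variant_id = c("P1", "P3", "P4"),
    phase = c("in_phase", "in_phase", "unknown"),
    distance_bp = c(1, 10, 1),
    joint_consequence = c("missense", "missense", "missense")
  )
  expect_warning(
    cl <- classify_variants(v, model, mnv_pairs = pairs),
    "unknown phase"
  )
  expect_equal(cl$class, c("OTHER", "S_LOF", "S_LOF", "S_LOF"))
  expect_match(cl$failed_filters[1], "mnv_phase")
})

test_that("carrier matrices are binary and conserve carrier counts", {
  model <- make_model()
  co <- make_cohort(2, 2)
  v <- dplyr::bind_rows(
    make_variant("V1", individual_id = "I00001", cds_position = 300L),
    make_variant("V2", individual_id = "I00001", cds_position = 500L),
    make_variant("V3", individual_id = "I00003", cds_position = 700L)
  )
  cl <- classify_variants(v, model)
  long <- carrier_matrix(cl, co, "S_LOF")
  # two qualifying variants in one gene count once
  expect_equal(nrow(long), 2)
  expect_equal(long$n_variants[long$individual_id == "I00001"], 2)
  wide <- carrier_matrix(cl, co, "S_LOF", format = "wide")
  expect_true(all(wide %in% 0:1))
  expect_equal(sum(wide), 2)
  # no qualifying variants: all-zero matrix
  none <- classify_variants(make_variant("V9", loftee_flag = "low_confidence"),
                            model)
  expect_equal(sum(carrier_matrix(none, co, "S_LOF", format = "wide")), 0)
})
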