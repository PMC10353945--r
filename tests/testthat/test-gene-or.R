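test_that("autism OR follows the cross-product formula with its edge cases", {
  expect_equal(autism_or(10, 990, 1, 999), 10 * 999 / 990)
  expect_equal(autism_or(5, 995, 0, 1000), Inf)
  expect_equal(autism_or(50, 950, 50, 950), 1)
  expect_true(is.na(autism_or(0, 1000, 5, 995)))
  expect_true(is.na(autism_or(0, 0, 0, 0)))
  expect_error(autism_or(-1, 10, 1, 9), "non-negative")
})

test_that("autism OR satisfies inverse symmetry on positive tables", {
  set.seed(41)
  for (i in 1:50) {
    k <- sample(1:50, 4)
    expect_equal(autism_or(k[1], k[2], k[3], k[4]) *
                   autism_or(k[3], k[4], k[1], k[2]), 1, tolerance = 1e-12)
  }
})

test_that("sub-sampling draws uniformly without replacement", {
  co <- make_cohort(50, 100)
  s1 <- subsample_undiagnosed(co, seed = 5)
  expect_length(s1, 50)
  expect_equal(anyDuplicated(s1), 0)
  expect_identical(s1, subsample_undiagnosed(co, seed = 5))
  expect_error(subsample_undiagnosed(make_cohort(10, 5)), "smaller")
  # selection frequency over 1,000 draws matches n_diag / n_undiag
  counts <- table(unlist(lapply(1:1000, function(i)
    subsample_undiagnosed(co, seed = i))))
  expect_equal(length(counts), 100)
  expect_true(all(abs(counts - 500) < 5 * sqrt(1000 * 0.25)))
})

test_that("singletons are determined within each group independently", {
  carriers <- tibble::tibble(
    gene_id = "G1",
    individual_id = c("A1", "B1", "B2"),
    variant_id = c("V1", "V2", "V2")
  )
  # V1 singleton in group {A1}; V2 doubleton in {B1, B2}, singleton in {B1}
  expect_equal(singleton_mask(carriers, "A1")$variant_id, "V1")
  expect_equal(nrow(singleton_mask(carriers, c("B1", "B2"))), 0)
  expect_equal(singleton_mask(carriers, c("A1", "B1"))$variant_id,
               c("V1", "V2"))
})

test_that("matched pool size makes the sub-sampled estimator exact", {
  co <- make_cohort(100, 100)
  ids <- co$individual_id
  carriers <- dplyr::bind_rows(
    make_carriers(ids[c(1, 5, 9)], "G1", "Va"),
    make_carriers(ids[c(2, 101, 150, 180)], "G2", "Vb")
  )
  for (mode in c("prefiltered_only", "per_group_singletons")) {
    est <- estimate_gene_or(carriers, co,
                            or_config(n_iterations = 100, seed = 3,
                                      singleton_mode = mode))
    # direct full-sample OR, computed by hand
    direct <- c(autism_or(3, 97, 0, 100), autism_or(1, 99, 3, 97))
    expect_equal(est$autism_or, direct)
    expect_equal(est$n_carriers_undiagnosed_mean, c(0, 3))
  }
})

test_that("equal carrier frequencies yield OR near one", {
  co <- make_cohort(3000, 9000)
  set.seed(17)
  carriers <- make_carriers(
    co$individual_id[runif(12000) < 0.05], "G1")
  est <- estimate_gene_or(carriers, co, or_config(n_iterations = 50, seed = 18))
  expect_lt(abs(log(est$autism_or)), 0.35)
})

test_that("estimation and bootstrap are deterministic given the config", {
  co <- make_cohort(200, 600)
  set.seed(31)
  carriers <- dplyr::bind_rows(
    make_carriers(sample(co$individual_id[1:200], 12), "G1", "Va"),
    make_carriers(sample(co$individual_id[201:800], 6), "G2", "Vb")
  )
  cfg <- or_config(n_iterations = 20, n_bootstraps = 200, seed = 7)
  expect_identical(estimate_gene_or(carriers, co, cfg),
                   estimate_gene_or(carriers, co, cfg))
  b1 <- bootstrap_null(carriers, co, cfg)
  b2 <- bootstrap_null(carriers, co, cfg)
  expect_identical(b1, b2)
  # G2 has no diagnosed carriers: its OR is undefined and so is its P
  expect_true(is.na(b1$autism_or[b1$gene_id == "G2"]))
  expect_true(is.na(b1$empirical_p[b1$gene_id == "G2"]))
  # bootstrap internals respect the empirical-P identities on defined genes
  ok <- b1[!is.na(b1$autism_or), ]
  expect_true(all(ok$M >= 0 & ok$M <= ok$n_bootstraps))
  expect_equal(ok$empirical_p, (ok$M + 1) / (ok$n_bootstraps + 1))
  expect_true(all(ok$p_ci_low <= ok$empirical_p &
                    ok$empirical_p <= ok$p_ci_high))
  # observed OR inside the bootstrap equals the exported estimator
  est <- estimate_gene_or(carriers, co, cfg)
  expect_identical(b1$autism_or, est$autism_or)
})

test_that("empirical P confidence interval follows the printed formula", {
  ci <- empirical_p_ci(0.5, 9999)
  expect_equal(ci$ci_low, 0.4902, tolerance = 1e-4)
  expect_equal(ci$ci_high, 0.5098, tolerance = 1e-4)
  exact_one <- empirical_p_ci(1, 9999)
  expect_equal(exact_one$ci_low, 1)
  expect_equal(exact_one$ci_high, 1)
  tiny <- empirical_p_ci(1 / 10001, 10000)
  expect_equal(tiny$ci_low, 0)  # clamped at zero
  expect_gt(tiny$ci_high, tiny$ci_low)
})

test_that("significance requires the CI upper bound strictly below 0.05", {
  expect_true(significance_flag(0.049))
  expect_false(significance_flag(0.05))
  expect_false(significance_flag(0.5))
  expect_false(significance_flag(NA))
})

test_that("infinite ORs are capped at the highest finite OR of the set", {
  expect_equal(cap_infinite_or(c(2, Inf, 5)), c(2, 5, 5))
  expect_equal(cap_infinite_or(c(2, 5)), c(2, 5))
  expect_error(cap_infinite_or(c(Inf, Inf)), "no_finite_reference")
  expect_equal(cap_infinite_or(c(NA, 3, Inf)), c(NA, 3, 3))
})

test_that("empirical P is calibrated when the pool exceeds the diagnosed group", {
  # with a 10x pool the averaged undiagnosed count smooths the OR support,
  # which is the regime the sub-sampling averaging is designed for
  co <- simulate_cohort(cohort_spec(400, 4000, family_fraction = 0, seed = 21))
  genes <- simulate_gene_panel(n_autism = 200, n_constrained = 0, n_other = 0,
                               carrier_freq_diagnosed = 0.02,
                               carrier_freq_undiagnosed = 0.02,
                               syn_freq = 0, seed = 21)
  sim <- simulate_variants(co, genes, seed = 22, decoys_per_gene = 0,
                           splice_fraction = 0)
  carriers <- dplyr::select(sim$variants, gene_id, individual_id, variant_id)
  boot <- bootstrap_null(carriers, co,
                         or_config(n_iterations = 20, n_bootstraps = 800,
                                   seed = 23))
  p <- boot$empirical_p[!is.na(boot$empirical_p)]
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gte(length(p), 190)
  expect_gt(ks$p.value, 0.01)
})
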