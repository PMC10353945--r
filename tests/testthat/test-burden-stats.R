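test_that("carrier proportion CIs reproduce cohort-scale reporting exactly", {
  # 523 / 13,091 diagnosed carriers -> 4.0% (3.66-4.33%)
  ci <- carrier_proportion_ci(523, 13091)
  expect_equal(round(100 * ci$p, 1), 4.0)
  expect_equal(round(100 * ci$ci_low, 2), 3.66)
  expect_equal(round(100 * ci$ci_high, 2), 4.33)
  # 1,090 / 188,856 population carriers -> 0.58% (0.54-0.61%)
  ci <- carrier_proportion_ci(1090, 188856)
  expect_equal(round(100 * ci$p, 2), 0.58)
  expect_equal(round(100 * ci$ci_low, 2), 0.54)
  expect_equal(round(100 * ci$ci_high, 2), 0.61)
  # 223 / 19,488 relatives -> computed 1.14% (CI 0.99-1.29)
  ci <- carrier_proportion_ci(223, 19488)
  expect_equal(round(100 * ci$p, 2), 1.14)
  expect_equal(round(100 * ci$ci_low, 2), 0.99)
  expect_equal(round(100 * ci$ci_high, 2), 1.29)
  # degenerate and invalid inputs
  zero <- carrier_proportion_ci(0, 100)
  expect_equal(c(zero$p, zero$ci_low, zero$ci_high), c(0, 0, 0))
  expect_error(carrier_proportion_ci(5, 0), "positive")
  expect_error(carrier_proportion_ci(11, 10), "0 <= k <= n")
})

test_that("Fisher exact p matches exhaustive enumeration", {
  expect_equal(fisher_exact_2x2(2, 0, 0, 2)$p_value, 1 / 3)
  expect_equal(fisher_exact_2x2(1, 1, 1, 1)$p_value, 1)
  # zero margin: p = 1, OR undefined
  degenerate <- fisher_exact_2x2(0, 0, 3, 4)
  expect_equal(degenerate$p_value, 1)
  expect_true(is.na(degenerate$odds_ratio))
  # property: all tables with margins <= 12 agree with the oracle
  set.seed(55)
  for (i in 1:80) {
    cells <- sample(0:6, 4, replace = TRUE)
    a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
    if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
    expect_equal(fisher_exact_2x2(a, b, cc, d)$p_value,
                 fisher_p_oracle(a, b, cc, d), tolerance = 1e-9)
  }
})

test_that("Bonferroni caps at one and never decreases a p value", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 5), 1)
  expect_equal(bonferroni(c(0.2, 0.7), 1), c(0.2, 0.7))
  set.seed(6)
  p <- runif(20)
  expect_true(all(bonferroni(p) >= p))
})

test_that("sex-ratio enrichment recovers generative odds ratios", {
  equal <- sex_ratio_test(tibble::tibble(
    group = "diagnosed", female_carriers = 10, female_total = 100,
    male_carriers = 10, male_total = 100))
  expect_equal(equal$odds_ratio, 1)
  doubled <- sex_ratio_test(tibble::tibble(
    group = "diagnosed", female_carriers = 200, female_total = 10000,
    male_carriers = 100, male_total = 10000))
  expect_equal(doubled$odds_ratio, 2, tolerance = 0.05)
  # p agrees with the enumeration oracle on small counts
  small <- sex_ratio_test(tibble::tibble(
    group = "g", female_carriers = 4, female_total = 9,
    male_carriers = 1, male_total = 8))
  expect_equal(small$p_value, fisher_p_oracle(4, 5, 1, 7), tolerance = 1e-9)
  # Bonferroni across groups
  two <- sex_ratio_test(tibble::tibble(
    group = c("a", "b"),
    female_carriers = c(3, 1), female_total = c(10, 10),
    male_carriers = c(1, 1), male_total = c(10, 10)))
  expect_equal(two$p_adjusted, pmin(1, two$p_value * 2))
})

test_that("Mann-Whitney p is exact for small tie-free samples", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(mann_whitney_u(c(1, 2, 7), c(1, 2, 7))$p_value, 1)
  # property: exact p equals enumeration for min sample size <= 8
  set.seed(77)
  for (i in 1:25) {
    nx <- sample(3:8, 1)
    ny <- sample(3:12, 1)
    vals <- sample(1:1000, nx + ny)
    x <- vals[1:nx]
    y <- vals[-(1:nx)]
    expect_equal(mann_whitney_u(x, y)$p_value, mw_p_oracle(x, y),
                 tolerance = 1e-9)
  }
  # the continuity-corrected normal approximation tracks enumeration at
  # n = 8; its worst-case deviation over the U support, computed by
  # enumeration, is 0.011
  set.seed(78)
  for (i in 1:10) {
    vals <- sample(1:1000, 16)
    x <- vals[1:8]
    y <- vals[9:16]
    exact <- mann_whitney_u(x, y)$p_value
    approx <- mann_whitney_u(x, y, exact_max = 0)$p_value
    expect_lt(abs(exact - approx), 0.011)
  }
})

make_or_table <- function(or_values) {
  tibble::tibble(gene_id = sprintf("G%03d", seq_along(or_values)),
                 n_carriers_diagnosed = 1,
                 autism_or = or_values,
                 capped_or = cap_infinite_or(or_values))
}

test_that("OR-expression correlation matches a pair-counting oracle", {
  ors <- c(2, 5, 1.2, 8, 3)
  expr_vals <- c(3, 9, 2, 20, 4)
  expr <- tibble::tibble(gene_id = sprintf("G%03d", 1:5), region = "R1",
                         period = "P1", expression = expr_vals)
  res <- or_expression_correlation(make_or_table(ors), expr)
  expect_equal(res$estimate, kendall_tau_oracle(ors, expr_vals),
               tolerance = 1e-9)
  # perfectly monotone pairing
  mono <- or_expression_correlation(
    make_or_table(c(1.5, 2, 4, 9)),
    tibble::tibble(gene_id = sprintf("G%03d", 1:4), region = "R1",
                   period = "P1", expression = c(2, 3, 5, 10)))
  expect_equal(mono$estimate, 1)
  # expression floor: values <= 1 are excluded before testing
  floor_tbl <- tibble::tibble(gene_id = sprintf("G%03d", 1:5), region = "R1",
                              period = "P1", expression = c(3, 9, 0.5, 20, 1))
  res_floor <- or_expression_correlation(make_or_table(ors), floor_tbl)
  expect_equal(res_floor$n_genes, 3)
  # constant vector flagged as degenerate
  const <- or_expression_correlation(
    make_or_table(c(2, 2, 2)),
    tibble::tibble(gene_id = sprintf("G%03d", 1:3), region = "R1",
                   period = "P1", expression = c(3, 6, 9)))
  expect_true(const$degenerate)
})

test_that("independent OR and expression give near-zero Kendall tau", {
  set.seed(91)
  inside <- 0
  for (r in 1:20) {
    ors <- rlnorm(130, 1, 1)
    expr <- tibble::tibble(gene_id = sprintf("G%03d", 1:130), region = "R1",
                           period = "P1", expression = rlnorm(130, 2, 1) + 1)
    tau <- or_expression_correlation(make_or_table(ors), expr)$estimate
    if (abs(tau) < 0.2) inside <- inside + 1
  }
  expect_gte(inside, 19)
})

test_that("module summaries order by mean OR and contrast neuron modules", {
  gene_or <- make_or_table(c(10, 20, 1, 2, 5, 7))
  modules <- tibble::tibble(
    gene_id = sprintf("G%03d", 1:6),
    module = c("A", "A", "B", "B", "C", "C"),
    cell_type = c("neuron", "neuron", "astrocyte", "astrocyte",
                  "interneuron", "astrocyte")
  )
  # gene 5 and 6 also share module assignments to make a mixed gene
  modules <- dplyr::bind_rows(modules, tibble::tibble(
    gene_id = "G005", module = "B", cell_type = "astrocyte"))
  res <- module_or_summary(gene_or, modules)
  expect_equal(res$modules$module[1], "A")
  expect_equal(res$modules$mean_or[res$modules$module == "A"], 15)
  expect_equal(res$modules$mean_or[res$modules$module == "B"], 8 / 3)
  expect_true(res$contrast$available)
  # a single module cannot be contrasted
  one <- module_or_summary(gene_or[1:2, ], modules[1:2, ])
  expect_false(one$contrast$available)
})

test_that("synthetic expression and module tables have the documented shape", {
  genes <- simulate_gene_panel(n_autism = 30, n_constrained = 0, n_other = 0,
                               seed = 3)
  expr <- simulate_expression(genes, seed = 4)
  expect_identical(expr, simulate_expression(genes, seed = 4))
  expect_true(all(expr$expression >= 0))
  # the early-fetal R4 combination is absent; all other 31 cells present
  expect_equal(nrow(expr), 30 * 31)
  expect_equal(nrow(dplyr::filter(expr, region == "R4", period == "P1")), 0)
  mods <- simulate_modules(genes, seed = 5)
  expect_true(all(genes$gene_id %in% mods$gene_id))
  expect_true(all(mods$cell_type %in% c("neuron", "interneuron", "astrocyte",
                                        "oligodendrocyte", "microglia")))
  # the full stack feeds the correlation and module summaries
  gene_or <- tibble::tibble(gene_id = genes$gene_id,
                            n_carriers_diagnosed = 1,
                            capped_or = exp(rnorm(30)))
  grid <- or_expression_correlation(gene_or, expr)
  expect_equal(nrow(grid), 31)
  summ <- module_or_summary(gene_or, mods)
  expect_true(nrow(summ$modules) >= 2)
})
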