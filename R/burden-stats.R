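#' Carrier proportion with normal-approximation confidence interval
#'
#' `p = k/n`, `se = sqrt(p(1-p)/n)`, 95% CI `p +/- 1.96 se` clamped to
#' \[0, 1\]. The normal approximation is used deliberately: it reproduces the
#' conventional reporting of carrier proportions at cohort scale exactly at
#' two-decimal rounding of the percentage.
#'
#' @param k Carrier counts (vector).
#' @param n Group sizes (vector, recycled).
#' @return Tibble: `k`, `n`, `p`, `se`, `ci_low`, `ci_high`.
#' @export
carrier_proportion_ci <- function(k, n) {
  if (any(n <= 0)) abort("`n` must be positive")
  if (any(k < 0 | k > n)) abort("`k` must satisfy 0 <= k <= n")
  p <- k / n
  se <- sqrt(p * (1 - p) / n)
  tibble(k = k, n = n, p = p, se = se,
         ci_low = clamp01(p - 1.96 * se),
         ci_high = clamp01(p + 1.96 * se))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' P value from the conditional hypergeometric distribution with the
#' probability-mass two-sided rule (the probabilities of all tables with the
#' observed margins that are no more likely than the observed one are
#' summed). The reported OR is the sample (cross-product) odds ratio, not the
#' conditional MLE. A zero margin gives p = 1 and an undefined OR.
#'
#' @param a,b,c,d Cell counts: carriers/non-carriers (columns) by group
#'   (rows), i.e. the table `rbind(c(a, b), c(c, d))`.
#' @return Tibble: `odds_ratio`, `p_value`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("cell counts must be non-negative integers")
  }
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(tibble(odds_ratio = NA_real_, p_value = 1))
  }
  p <- fisher.test(tab)$p.value
  or <- (as.numeric(a) * as.numeric(d)) / (as.numeric(b) * as.numeric(c))
  tibble(odds_ratio = or, p_value = p)
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)`. When the tests fall into families (e.g. one family per
#' variant type and gene set), pass the family sizes through `m` or use
#' [adjust_p_grouped()].
#'
#' @param p Raw p values.
#' @param m Number of tests in each p value's family (default
#'   `length(p)`).
#' @return Adjusted p values.
#' @export
bonferroni <- function(p, m = length(p)) {
  pmin(1, p * m)
}

#' Grouped multiple-testing adjustment
#'
#' Adjusts a p-value column within groups of rows (e.g. separately per
#' variant type and gene set), appending `p_adjusted`.
#'
#' @param data A data frame.
#' @param ... Grouping columns (tidy-select, unquoted).
#' @param p Name of the p-value column (unquoted; default `p_value`).
#' @param method `"bonferroni"` or `"BH"`.
#' @return `data` with `p_adjusted` appended.
#' @export
adjust_p_grouped <- function(data, ..., p = p_value,
                             method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  data |>
    group_by(...) |>
    mutate(p_adjusted = p.adjust({{ p }}, method = method)) |>
    ungroup()
}

#' Female-over-male carrier enrichment
#'
#' Per group (e.g. diagnosed, siblings, parents, population): the OR of
#' carrying a qualifying variant for female over male individuals,
#' `(female carriers x male non-carriers) / (male carriers x female
#' non-carriers)`, with a two-sided Fisher exact p value, Bonferroni-adjusted
#' across groups.
#'
#' @param counts Tibble with columns `group`, `female_carriers`,
#'   `female_total`, `male_carriers`, `male_total`.
#' @return Tibble: `group`, `odds_ratio`, `p_value`, `p_adjusted`.
#' @export
sex_ratio_test <- function(counts) {
  check_columns(counts, c("group", "female_carriers", "female_total",
                          "male_carriers", "male_total"), "sex ratio counts")
  res <- purrr::pmap_dfr(counts, function(group, female_carriers,
                                          female_total, male_carriers,
                                          male_total, ...) {
    ft <- fisher_exact_2x2(female_carriers, female_total - female_carriers,
                           male_carriers, male_total - male_carriers)
    tibble(group = group, odds_ratio = ft$odds_ratio, p_value = ft$p_value)
  })
  res |> mutate(p_adjusted = bonferroni(.data$p_value, nrow(res)))
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p value by enumeration when the smaller sample has at most
#' `exact_max` observations and there are no ties; a normal approximation
#' with tie correction (and continuity correction) otherwise. The statistic
#' is U for the first sample.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact_max Largest min-sample size for which the exact distribution
#'   is used.
#' @return Tibble: `statistic` (U), `p_value`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && min(length(x), length(y)) <= exact_max
  res <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Correlation between gene OR and brain expression
#'
#' Per brain region and developmental period, correlates the (capped) gene
#' odds ratio with expression among genes with at least one diagnosed
#' carrier. Expression values of at most `min_expression` are excluded before
#' the test. Two methods are exposed: tie-corrected Kendall tau-b on the raw
#' values (default) and Pearson in log10 space of both OR and expression.
#'
#' @param gene_or A gene OR table ([gene_autism_or()] output or any tibble
#'   with `gene_id`, `n_carriers_diagnosed`, `capped_or`).
#' @param expression Long expression table: `gene_id`, `region`, `period`,
#'   `expression`.
#' @param method `"kendall"` or `"pearson_log10"`.
#' @param min_expression Expression floor (strict; default 1).
#' @return Tibble: `region`, `period`, `n_genes`, `estimate`, `p_value`,
#'   `method`, `degenerate` (TRUE when a constant vector made the
#'   correlation undefined).
#' @export
or_expression_correlation <- function(gene_or, expression,
                                      method = c("kendall", "pearson_log10"),
                                      min_expression = 1) {
  method <- match.arg(method)
  check_columns(expression, c("gene_id", "region", "period", "expression"),
                "expression table")
  check_columns(gene_or, c("gene_id", "n_carriers_diagnosed", "capped_or"),
                "gene OR table")
  ors <- gene_or |>
    filter(.data$n_carriers_diagnosed > 0, !is.na(.data$capped_or),
           .data$capped_or > 0) |>
    select("gene_id", "capped_or")
  expression |>
    filter(.data$expression > min_expression) |>
    inner_join(ors, by = "gene_id") |>
    group_by(.data$region, .data$period) |>
    summarise(.groups = "drop", n_genes = dplyr::n(), res = list({
      o <- .data$capped_or
      e <- .data$expression
      if (length(o) < 3 || length(unique(o)) < 2 || length(unique(e)) < 2) {
        tibble(estimate = NA_real_, p_value = NA_real_, degenerate = TRUE)
      } else if (method == "kendall") {
        ct <- suppressWarnings(cor.test(o, e, method = "kendall"))
        tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
               degenerate = FALSE)
      } else {
        ct <- cor.test(log10(o), log10(e), method = "pearson")
        tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
               degenerate = FALSE)
      }
    })) |>
    tidyr::unnest("res") |>
    mutate(method = method)
}

#' Coexpression-module OR summary
#'
#' Mean (capped) gene OR per coexpression module, ordered by decreasing mean,
#' plus a Mann-Whitney contrast between genes found exclusively in modules
#' with neuron/interneuron cell types and genes also present in modules of
#' other cell types. With fewer than two modules, or an empty gene group, the
#' contrast is flagged as unavailable.
#'
#' @param gene_or Gene OR table (needs `gene_id`, `n_carriers_diagnosed`,
#'   `capped_or`).
#' @param modules Tibble: `gene_id`, `module`, `cell_type` (a gene may be
#'   assigned to several modules, one per row).
#' @param neuron_types Cell types counted as neuronal.
#' @return A list: `modules` (per-module `n_genes`, `mean_or`, descending),
#'   `contrast` (`p_value`, `n_neuron_only`, `n_mixed`, `available`).
#' @export
module_or_summary <- function(gene_or, modules,
                              neuron_types = c("neuron", "interneuron")) {
  check_columns(modules, c("gene_id", "module", "cell_type"), "module table")
  ors <- gene_or |>
    filter(.data$n_carriers_diagnosed > 0, !is.na(.data$capped_or)) |>
    select("gene_id", "capped_or")
  assigned <- modules |> inner_join(ors, by = "gene_id")
  mod_summary <- assigned |>
    group_by(.data$module, .data$cell_type) |>
    summarise(n_genes = dplyr::n_distinct(.data$gene_id),
              mean_or = mean(.data$capped_or), .groups = "drop") |>
    arrange(desc(.data$mean_or))

  gene_groups <- assigned |>
    group_by(.data$gene_id) |>
    summarise(capped_or = first(.data$capped_or),
              neuron_only = all(.data$cell_type %in% neuron_types),
              any_neuron = any(.data$cell_type %in% neuron_types),
              .groups = "drop") |>
    filter(.data$any_neuron)
  neuron_only <- gene_groups$capped_or[gene_groups$neuron_only]
  mixed <- gene_groups$capped_or[!gene_groups$neuron_only]
  contrast <- if (nrow(mod_summary) < 2 || length(neuron_only) == 0 ||
                  length(mixed) == 0) {
    tibble(p_value = NA_real_, n_neuron_only = length(neuron_only),
           n_mixed = length(mixed), available = FALSE)
  } else {
    mw <- mann_whitney_u(neuron_only, mixed)
    tibble(p_value = mw$p_value, n_neuron_only = length(neuron_only),
           n_mixed = length(mixed), available = TRUE)
  }
  list(modules = mod_summary, contrast = contrast)
}

#' Carrier proportions by cohort stratum
#'
#' Counts carriers of one variant class per stratum of the cohort (by
#' default the family role) and attaches the normal-approximation CI.
#'
#' @param carriers Long carrier calls (`gene_id`, `individual_id`, ...).
#' @param cohort Cohort table.
#' @param by Stratifying column of the cohort (default `role`).
#' @return Tibble: stratum, `k`, `n`, `p`, `se`, `ci_low`, `ci_high`.
#' @export
carrier_proportions <- function(carriers, cohort, by = "role") {
  check_columns(cohort, c("individual_id", by), "cohort")
  carrier_ids <- unique(carriers$individual_id)
  strata <- cohort |>
    mutate(is_carrier = .data$individual_id %in% carrier_ids) |>
    group_by(across(all_of(by))) |>
    summarise(k = sum(.data$is_carrier), n = dplyr::n(), .groups = "drop")
  bind_cols(strata[, by, drop = FALSE],
            carrier_proportion_ci(strata$k, strata$n))
}
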