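#' Configuration for gene-level odds-ratio estimation
#'
#' @param n_iterations Sub-sampling iterations used to average the
#'   undiagnosed carrier count (default 100).
#' @param n_bootstraps Relabeling bootstrap replicates for the empirical P
#'   value (default 10,000).
#' @param singleton_mode `"per_group_singletons"` re-applies the singleton
#'   (within-group allele count = 1) rule inside the diagnosed group and
#'   inside each undiagnosed sub-sample; `"prefiltered_only"` trusts the
#'   upstream rarity filter and counts every qualifying carrier.
#' @param boot_subsampling `"full"` reruns the `n_iterations` sub-sampling
#'   inside every bootstrap replicate; `"single_pass"` uses one sub-sample
#'   per replicate. When the undiagnosed pool has exactly the diagnosed size
#'   the sub-sample is the whole pool and both are exact.
#' @param seed Integer seed covering the sub-sampling and the bootstrap.
#' @return A list of class `or_config`.
#' @export
or_config <- function(n_iterations = 100,
                      n_bootstraps = 10000,
                      singleton_mode = c("per_group_singletons",
                                         "prefiltered_only"),
                      boot_subsampling = c("full", "single_pass"),
                      seed = 1L) {
  if (n_iterations < 1) abort("`n_iterations` must be >= 1")
  if (n_bootstraps < 1) abort("`n_bootstraps` must be >= 1")
  structure(list(
    n_iterations = as.integer(n_iterations),
    n_bootstraps = as.integer(n_bootstraps),
    singleton_mode = match.arg(singleton_mode),
    boot_subsampling = match.arg(boot_subsampling),
    seed = as.integer(seed)
  ), class = "or_config")
}

#' Gene-level autism odds ratio from contingency counts
#'
#' `OR = (carriers_diagnosed x noncarriers_undiagnosed) /
#' (carriers_undiagnosed x noncarriers_diagnosed)`. Undiagnosed counts may be
#' non-integer averages from the sub-sampling procedure. The OR is `+Inf`
#' when there are diagnosed carriers but no undiagnosed carriers, and
#' undefined (`NA`, excluded from downstream summaries) when there are no
#' diagnosed carriers.
#'
#' @param n_carriers_diagnosed,n_noncarriers_diagnosed,n_carriers_undiagnosed,n_noncarriers_undiagnosed
#'   Count vectors (recycled).
#' @return Numeric vector of odds ratios.
#' @export
autism_or <- function(n_carriers_diagnosed, n_noncarriers_diagnosed,
                      n_carriers_undiagnosed, n_noncarriers_undiagnosed) {
  if (any(c(n_carriers_diagnosed, n_noncarriers_diagnosed,
            n_carriers_undiagnosed, n_noncarriers_undiagnosed) < 0,
          na.rm = TRUE)) {
    abort("contingency counts must be non-negative")
  }
  ifelse(n_carriers_diagnosed == 0, NA_real_,
         (n_carriers_diagnosed * n_noncarriers_undiagnosed) /
           (n_carriers_undiagnosed * n_noncarriers_diagnosed))
}

#' Draw one undiagnosed sub-sample
#'
#' Uniform draw without replacement from the undiagnosed pool, of the
#' diagnosed group's size (the default) so that both groups are matched.
#'
#' @param cohort Cohort table with `individual_id`, `status`.
#' @param size Sub-sample size; defaults to the diagnosed count.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return Character vector of individual ids.
#' @export
subsample_undiagnosed <- function(cohort, size = NULL, seed = NULL) {
  pool <- cohort$individual_id[cohort$status == "undiagnosed"]
  size <- size %||% sum(cohort$status == "diagnosed")
  if (length(pool) < size) {
    abort("undiagnosed pool is smaller than the requested sub-sample size")
  }
  with_seed(seed, pool[sample.int(length(pool), size)])
}

#' Within-group singleton variants
#'
#' Restricts carrier calls to variants whose allele count within the stated
#' group of individuals equals one. Allele counts are computed within the
#' group only, so a variant may be a singleton among diagnosed individuals
#' while being a doubleton among undiagnosed individuals.
#'
#' @param carriers Long carrier calls (`gene_id`, `individual_id`,
#'   `variant_id`).
#' @param group_ids Individual ids defining the group.
#' @return The carrier rows of group members whose variant is a singleton
#'   within the group.
#' @export
singleton_mask <- function(carriers, group_ids) {
  in_group <- carriers |> filter(.data$individual_id %in% group_ids)
  counts <- in_group |> count(.data$variant_id, name = "group_ac")
  in_group |>
    inner_join(counts, by = "variant_id") |>
    filter(.data$group_ac == 1) |>
    select(-"group_ac")
}

# ---- fast integer-index core ------------------------------------------

carrier_index <- function(carriers, cohort) {
  check_columns(carriers, c("gene_id", "individual_id", "variant_id"),
                "carrier calls")
  genes <- sort(unique(carriers$gene_id))
  vars <- unique(carriers$variant_id)
  i <- match(carriers$individual_id, cohort$individual_id)
  if (anyNA(i)) abort("carrier individual(s) absent from cohort")
  list(g = match(carriers$gene_id, genes),
       v = match(carriers$variant_id, vars),
       i = i,
       genes = genes,
       n_gene = length(genes),
       n_var = length(vars),
       n_ind = nrow(cohort))
}

# Per-gene count of distinct carriers within a group (logical mask over the
# cohort), optionally keeping only variants that are singletons within it.
count_carriers_by_gene <- function(idx, in_group, singleton) {
  keep <- in_group[idx$i]
  g <- idx$g[keep]
  v <- idx$v[keep]
  i <- idx$i[keep]
  if (singleton && length(v) > 0) {
    vc <- tabulate(v, idx$n_var)
    s <- vc[v] == 1L
    g <- g[s]
    i <- i[s]
  }
  if (length(g) == 0) return(numeric(idx$n_gene))
  key <- (g - 1) * idx$n_ind + i
  dup <- duplicated(key)
  tabulate(g[!dup], idx$n_gene)
}

# Estimator core operating on a prebuilt index and the current RNG stream.
# diag_mask/undiag_mask are logical over cohort rows.
estimate_core <- function(idx, diag_mask, undiag_mask, config) {
  n_d <- sum(diag_mask)
  n_u <- sum(undiag_mask)
  if (n_u < n_d) abort("undiagnosed pool is smaller than the diagnosed group")
  singleton <- config$singleton_mode == "per_group_singletons"
  k_d <- count_carriers_by_gene(idx, diag_mask, singleton)
  if (n_u == n_d) {
    # the sub-sample is the whole pool: a single pass is exact
    k_u <- count_carriers_by_gene(idx, undiag_mask, singleton)
  } else {
    undiag_pos <- which(undiag_mask)
    acc <- numeric(idx$n_gene)
    sub_mask <- logical(idx$n_ind)
    for (it in seq_len(config$n_iterations)) {
      sub_mask[] <- FALSE
      sub_mask[undiag_pos[sample.int(n_u, n_d)]] <- TRUE
      acc <- acc + count_carriers_by_gene(idx, sub_mask, singleton)
    }
    k_u <- acc / config$n_iterations
  }
  list(k_d = k_d, k_u = k_u, n = n_d,
       or = autism_or(k_d, n_d - k_d, k_u, n_d - k_u))
}

#' Sub-sampled gene-level autism OR
#'
#' For every gene with at least one qualifying carrier: the diagnosed carrier
#' count is taken once on the full diagnosed group; the undiagnosed carrier
#' count is the average over `n_iterations` sub-samples of the undiagnosed
#' pool, each of the diagnosed group's size (the average is used unrounded).
#' In `per_group_singletons` mode the singleton rule is re-applied within the
#' diagnosed group and within each sub-sample. The OR uses matched group
#' sizes on both sides. When the undiagnosed pool already has the diagnosed
#' size, every sub-sample is the entire pool and the estimate equals the
#' direct full-sample OR exactly.
#'
#' @param carriers Long carrier calls (`gene_id`, `individual_id`,
#'   `variant_id`), e.g. from [qualifying_carriers()].
#' @param cohort Cohort table.
#' @param config An [or_config()].
#' @return Tibble: `gene_id`, `n_carriers_diagnosed`,
#'   `n_carriers_undiagnosed_mean`, `group_size`, `autism_or`.
#' @export
estimate_gene_or <- function(carriers, cohort, config = or_config()) {
  idx <- carrier_index(carriers, cohort)
  diag_mask <- cohort$status == "diagnosed"
  res <- with_seed(config$seed,
                   estimate_core(idx, diag_mask, !diag_mask, config))
  tibble(
    gene_id = idx$genes,
    n_carriers_diagnosed = res$k_d,
    n_carriers_undiagnosed_mean = res$k_u,
    group_size = res$n,
    autism_or = res$or
  )
}

#' Relabeling bootstrap for the empirical P value
#'
#' For each of `n_bootstraps` replicates, a pseudo-diagnosed set of the
#' diagnosed group's size is drawn without replacement from the pooled
#' cohort, the remainder is labelled undiagnosed, and the gene OR is
#' recomputed with the same sub-sampling algorithm. `M` counts replicates
#' whose OR is greater than or equal to the observed OR (`Inf >= Inf`
#' counts); the empirical P value is `(M + 1) / (N + 1)` with 95% CI
#' `P +/- 1.96 * sqrt(P(1-P)/(N+1))`, and a gene is flagged significant when
#' the CI's upper bound is below 0.05.
#'
#' @inheritParams estimate_gene_or
#' @return Tibble: `gene_id`, `autism_or` (observed), `M`, `n_bootstraps`,
#'   `empirical_p`, `p_ci_low`, `p_ci_high`, `significant`. Genes with no
#'   diagnosed carrier have `NA` throughout (their OR is undefined).
#' @export
bootstrap_null <- function(carriers, cohort, config = or_config()) {
  idx <- carrier_index(carriers, cohort)
  diag_mask <- cohort$status == "diagnosed"
  n_d <- sum(diag_mask)
  boot_config <- config
  if (config$boot_subsampling == "single_pass") boot_config$n_iterations <- 1L

  with_seed(config$seed, {
    observed <- estimate_core(idx, diag_mask, !diag_mask, config)$or
    m <- integer(idx$n_gene)
    pd_mask <- logical(idx$n_ind)
    for (b in seq_len(config$n_bootstraps)) {
      pd_mask[] <- FALSE
      pd_mask[sample.int(idx$n_ind, n_d)] <- TRUE
      or_b <- estimate_core(idx, pd_mask, !pd_mask, boot_config)$or
      m <- m + (!is.na(or_b) & or_b >= observed)
    }
    n_boot <- config$n_bootstraps
    p <- (m + 1) / (n_boot + 1)
    p[is.na(observed)] <- NA_real_
    ci <- empirical_p_ci(p, n_boot)
    tibble(
      gene_id = idx$genes,
      autism_or = observed,
      M = ifelse(is.na(observed), NA_integer_, m),
      n_bootstraps = n_boot,
      empirical_p = p,
      p_ci_low = ci$ci_low,
      p_ci_high = ci$ci_high,
      significant = significance_flag(ci$ci_high)
    )
  })
}

#' Confidence interval of a bootstrap empirical P value
#'
#' `P +/- 1.96 * sqrt(P(1-P)/(N+1))`, clamped to \[0, 1\].
#'
#' @param p Empirical P values in (0, 1\].
#' @param n_bootstraps Number of bootstrap replicates `N`.
#' @return Tibble with `ci_low`, `ci_high`.
#' @export
empirical_p_ci <- function(p, n_bootstraps) {
  half <- 1.96 * sqrt(p * (1 - p) / (n_bootstraps + 1))
  tibble(ci_low = clamp01(p - half), ci_high = clamp01(p + half))
}

#' Significance rule for bootstrap empirical P values
#'
#' A gene is significant when the upper bound of the 95% CI of its empirical
#' P value is strictly below 0.05.
#'
#' @param ci_high Upper CI bounds.
#' @return Logical vector.
#' @export
significance_flag <- function(ci_high) {
  !is.na(ci_high) & ci_high < 0.05
}

#' Replace infinite odds ratios by the highest finite OR of the set
#'
#' Genes with diagnosed carriers but no undiagnosed carriers have infinite
#' ORs; for rank- and correlation-based summaries these are replaced by the
#' highest measurable (finite) OR in the gene set. `NA` values (undefined
#' ORs) are left unchanged.
#'
#' @param or Numeric vector of odds ratios.
#' @return The vector with `+Inf` entries replaced.
#' @export
cap_infinite_or <- function(or) {
  inf <- is.infinite(or)
  if (!any(inf)) return(or)
  finite <- or[is.finite(or)]
  if (length(finite) == 0) {
    abort("no_finite_reference: all odds ratios are infinite")
  }
  or[inf] <- max(finite)
  or
}

#' Full gene-level OR analysis
#'
#' Convenience wrapper: sub-sampled OR estimate, relabeling bootstrap,
#' empirical P with CI and significance flag, and infinite-OR capping within
#' the supplied gene set.
#'
#' @inheritParams estimate_gene_or
#' @return A tibble of class `lof_gene_or` with the estimate and bootstrap
#'   columns plus `capped_or`.
#' @export
gene_autism_or <- function(carriers, cohort, config = or_config()) {
  est <- estimate_gene_or(carriers, cohort, config)
  boot <- bootstrap_null(carriers, cohort, config) |>
    select(-"autism_or")
  out <- est |> left_join(boot, by = "gene_id")
  out$capped_or <- tryCatch(cap_infinite_or(out$autism_or),
                            error = function(e) {
                              warn("all odds ratios infinite; capped_or set to NA")
                              rep(NA_real_, nrow(out))
                            })
  class(out) <- c("lof_gene_or", class(out))
  out
}
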