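#' Pipeline configuration
#'
#' Bundles every stage's parameters: the synthetic cohort and gene panel (or
#' paths to pre-existing tables), classification thresholds, OR estimation
#' settings, generative phenotype effects and the master seed. The
#' configuration hash is embedded in every output header.
#'
#' @param n_diagnosed,n_undiagnosed,family_fraction Cohort composition, see
#'   [cohort_spec()].
#' @param gene_panel Named list of arguments for [simulate_gene_panel()].
#' @param effects An [effect_spec()] for phenotype generation.
#' @param classify A [classify_config()].
#' @param or An [or_config()] (its seed is overridden by `seed`).
#' @param or_threshold OR threshold splitting the carrier indicators.
#' @param seed Master seed; all stage seeds derive from it.
#' @param output_dir Directory for stage outputs (`NULL` keeps everything in
#'   memory).
#' @param cohort_path,variants_path Optional paths to pre-existing cohort and
#'   variant tables; when given, simulation of that stage is skipped.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_diagnosed = 1000,
                            n_undiagnosed = 3000,
                            family_fraction = 0.5,
                            gene_panel = list(n_autism = 12,
                                              n_constrained = 12,
                                              n_other = 6),
                            effects = effect_spec(beta_lof_high = -0.3,
                                                  beta_lof_low = -0.1,
                                                  beta_pgs = 0.1,
                                                  participation_or_carrier = 0.8),
                            classify = classify_config(),
                            or = or_config(n_iterations = 100,
                                           n_bootstraps = 500),
                            or_threshold = 10,
                            seed = 1L,
                            output_dir = NULL,
                            cohort_path = NULL,
                            variants_path = NULL) {
  if (!is.null(cohort_path) && !file.exists(cohort_path)) {
    abort(sprintf("cohort_path does not exist: %s", cohort_path))
  }
  if (!is.null(variants_path) && !file.exists(variants_path)) {
    abort(sprintf("variants_path does not exist: %s", variants_path))
  }
  cfg <- list(
    n_diagnosed = n_diagnosed, n_undiagnosed = n_undiagnosed,
    family_fraction = family_fraction,
    gene_panel = gene_panel, effects = effects, classify = classify,
    or = or, or_threshold = or_threshold, seed = as.integer(seed),
    output_dir = output_dir,
    cohort_path = cohort_path, variants_path = variants_path
  )
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "output_dir")])
  structure(cfg, class = "pipeline_config")
}

#' Run the full burden-analysis pipeline
#'
#' Simulate (or load) the inputs, classify variants, build carrier calls,
#' estimate gene-level autism ORs with the relabeling bootstrap, compute
#' cohort burden statistics, fit the association models, and (optionally)
#' write every stage output with the seed and configuration hash in its
#' header.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `lof_pipeline` with elements `config`, `cohort`,
#'   `genes`, `variants`, `classified`, `carriers_slof`, `carriers_ssyn`,
#'   `gene_or`, `proportions`, `sex_ratio`, `phenotypes`, `regressions`,
#'   `participation`, and `filter_log` (per-filter variant counts).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config()")
  }
  seed <- config$seed

  # --- inputs ------------------------------------------------------------
  genes <- do.call(simulate_gene_panel,
                   c(config$gene_panel, list(seed = seed)))
  models <- gene_models(genes)
  cohort <- if (!is.null(config$cohort_path)) {
    read_stage_table(config$cohort_path)
  } else {
    simulate_cohort(cohort_spec(config$n_diagnosed, config$n_undiagnosed,
                                family_fraction = config$family_fraction,
                                seed = seed + 1L))
  }
  if (!is.null(config$variants_path)) {
    variants <- read_variant_input(config$variants_path)
    carrier_truth <- NULL
    calls <- simulate_genotype_metrics(variants, seed = seed + 3L)
  } else {
    sim <- simulate_variants(cohort, genes, seed = seed + 2L)
    variants <- sim$variants
    carrier_truth <- sim$carrier_truth
    calls <- simulate_genotype_metrics(variants, seed = seed + 3L)
  }
  phenotypes <- simulate_phenotypes(cohort, carrier_truth, genes,
                                    config$effects, seed = seed + 4L)

  # --- classification ----------------------------------------------------
  classified <- classify_variants(variants, models, calls,
                                  config = config$classify)
  filter_log <- classified |>
    tidyr::separate_rows("failed_filters", sep = ",") |>
    filter(.data$failed_filters != "") |>
    count(.data$failed_filters, name = "n_variants_failing")
  carriers_slof <- qualifying_carriers(classified, "S_LOF")
  carriers_ssyn <- qualifying_carriers(classified, "S_SYN")

  # --- gene-level OR -----------------------------------------------------
  or_cfg <- config$or
  or_cfg$seed <- seed + 5L
  gene_or <- gene_autism_or(carriers_slof, cohort, or_cfg)

  # --- burden statistics --------------------------------------------------
  proportions <- carrier_proportions(carriers_slof, cohort, by = "role")
  sex_counts <- cohort |>
    mutate(is_carrier = .data$individual_id %in%
             unique(carriers_slof$individual_id)) |>
    group_by(.data$status, .data$sex) |>
    summarise(carriers = sum(.data$is_carrier), total = dplyr::n(),
              .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sex",
                       values_from = c("carriers", "total")) |>
    rename(group = "status",
           female_carriers = "carriers_female",
           female_total = "total_female",
           male_carriers = "carriers_male",
           male_total = "total_male")
  sex_ratio <- sex_ratio_test(sex_counts)

  # --- association models -------------------------------------------------
  indicators <- split_lof_by_or(carriers_slof, gene_or, cohort,
                                threshold = config$or_threshold)
  model_data <- cohort |>
    left_join(indicators, by = "individual_id") |>
    left_join(phenotypes |> select(-"lof_low", -"lof_high"),
              by = "individual_id")
  fits <- list(
    diagnosis = fit_diagnosis_model(model_data),
    fluid_intelligence = fit_trait_linear(
      model_data,
      fluid_intelligence ~ lof_low + lof_high + pgs + sex + age +
        pc1 + pc2 + pc3 + pc4),
    townsend = fit_trait_linear(
      model_data |> mutate(townsend = reverse_townsend(.data$townsend)),
      townsend ~ lof_low + lof_high + pgs + sex + age +
        pc1 + pc2 + pc3 + pc4),
    income = fit_ordinal_model(
      model_data,
      income_band ~ lof_low + lof_high + pgs + sex + age +
        pc1 + pc2 + pc3 + pc4)
  )
  regressions <- purrr::imap_dfr(fits, function(fit, name) {
    tidy(fit) |> mutate(outcome = name, n = glance(fit)$n)
  }) |>
    fdr_adjust(.data$term)
  model_data$any_lof <- as.integer(model_data$lof_low | model_data$lof_high)
  participation <- participation_or(
    model_data |> filter(.data$status == "undiagnosed"),
    carrier = "any_lof",
    responses = c("responded_income", "responded_qualification",
                  "responded_fluid_intelligence", "responded_imaging"))

  bundle <- structure(list(
    config = config, cohort = cohort, genes = genes, variants = variants,
    calls = calls, carrier_truth = carrier_truth, phenotypes = phenotypes,
    classified = classified, filter_log = filter_log,
    carriers_slof = carriers_slof, carriers_ssyn = carriers_ssyn,
    gene_or = gene_or, proportions = proportions, sex_ratio = sex_ratio,
    regressions = regressions, participation = participation
  ), class = "lof_pipeline")

  if (!is.null(config$output_dir)) write_pipeline_outputs(bundle)
  bundle
}

pipeline_output_files <- c(
  cohort = "cohort.tsv", variants = "variants.tsv",
  classified = "classified.tsv", carriers_slof = "carriers_slof.tsv",
  gene_or = "gene_or.tsv", proportions = "proportions.tsv",
  sex_ratio = "sex_ratio.tsv", phenotypes = "phenotypes.tsv",
  regressions = "regressions.tsv", participation = "participation.tsv",
  filter_log = "filter_log.tsv"
)

write_pipeline_outputs <- function(bundle) {
  dir <- bundle$config$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seed <- bundle$config$seed
  hash <- bundle$config$hash
  doc <- character(0)
  for (name in names(pipeline_output_files)) {
    tab <- bundle[[name]]
    if (is.null(tab) || nrow(tab) == 0) next
    write_stage_table(tab, file.path(dir, pipeline_output_files[[name]]),
                      seed = seed, config_hash = hash)
    doc <- c(doc, sprintf("%s: %s", pipeline_output_files[[name]],
                          paste(names(tab), collapse = ", ")))
  }
  writeLines(doc, file.path(dir, "columns.txt"))
  invisible(dir)
}

#' Summarise a pipeline run
#'
#' Machine-readable summary of a pipeline result: every gene with at least
#' one diagnosed carrier together with its OR, empirical P and significance
#' flag; the carrier proportions; and the regression table. Accepts either an
#' in-memory result from [run_pipeline()] or the directory its outputs were
#' written to, so the report can be regenerated from saved stage outputs
#' without recomputation.
#'
#' @param x A `lof_pipeline` result or an output directory path.
#' @param path Optional path for a JSON copy of the summary.
#' @return A list of class `lof_report` with `genes`, `proportions`,
#'   `regressions`, `participation`, `seed` and `config_hash`.
#' @export
burden_report <- function(x, path = NULL) {
  if (inherits(x, "lof_pipeline")) {
    gene_or <- x$gene_or
    proportions <- x$proportions
    regressions <- x$regressions
    participation <- x$participation
    seed <- x$config$seed
    hash <- x$config$hash
  } else if (is.character(x) && dir.exists(x)) {
    gene_or <- read_stage_table(file.path(x, "gene_or.tsv"))
    proportions <- read_stage_table(file.path(x, "proportions.tsv"))
    regressions <- read_stage_table(file.path(x, "regressions.tsv"))
    participation <- read_stage_table(file.path(x, "participation.tsv"))
    first_line <- readLines(file.path(x, "gene_or.tsv"), n = 2)
    seed <- as.integer(sub("# seed=", "", first_line[1]))
    hash <- sub("# config_hash=", "", first_line[2])
  } else {
    abort("`x` must be a lof_pipeline result or an output directory")
  }
  report <- structure(list(
    genes = gene_or |>
      filter(.data$n_carriers_diagnosed > 0) |>
      arrange(desc(.data$autism_or)),
    proportions = proportions,
    regressions = regressions,
    participation = participation,
    seed = seed,
    config_hash = hash
  ), class = "lof_report")
  if (!is.null(path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.lof_report <- function(x, ...) {
  cat("Burden analysis report (seed", x$seed, ", config", x$config_hash, ")\n")
  cat(sprintf("  genes with >=1 diagnosed carrier: %d (%d significant)\n",
              nrow(x$genes), sum(x$genes$significant, na.rm = TRUE)))
  cat("  carrier proportions by role:\n")
  print(x$proportions)
  cat("  regression terms with adjusted p < 0.05:",
      sum(x$regressions$p_adjusted < 0.05, na.rm = TRUE), "\n")
  invisible(x)
}
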