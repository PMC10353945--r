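#' Simulate a developmental brain expression matrix
#'
#' Long-format expression values per gene across four brain regions (R1-R4)
#' and eight developmental periods (P1-P8), emulating the shape of a
#' region-by-period averaged developmental transcriptome. The early-fetal
#' cerebellum/thalamus combination (P1, R4) is absent, matching the missing
#' donor in the reference resource this layout mirrors. Expression is
#' log-normal and non-negative; an optional `signal` term adds a positive
#' association between a supplied per-gene score and early-period cortical
#' expression, for power checks of the OR-expression correlation.
#'
#' @param genes Gene panel or any tibble with `gene_id`.
#' @param signal Optional numeric per-gene score (length `nrow(genes)`);
#'   scaled into the log-mean of early-period (P1-P2) expression.
#' @param seed Integer seed.
#' @return Tibble: `gene_id`, `region` (R1-R4), `period` (P1-P8),
#'   `expression`.
#' @export
simulate_expression <- function(genes, signal = NULL, seed = 1L) {
  check_columns(genes, "gene_id", "gene panel")
  grid <- tidyr::expand_grid(
    gene_id = genes$gene_id,
    region = paste0("R", 1:4),
    period = paste0("P", 1:8)
  ) |>
    filter(!(.data$region == "R4" & .data$period == "P1"))
  if (!is.null(signal)) {
    if (length(signal) != nrow(genes)) {
      abort("`signal` must have one value per gene")
    }
    sig <- tibble(gene_id = genes$gene_id,
                  sig = as.numeric(scale(signal)))
  } else {
    sig <- tibble(gene_id = genes$gene_id, sig = 0)
  }
  with_seed(seed, {
    grid |>
      left_join(sig, by = "gene_id") |>
      mutate(
        meanlog = 1.5 +
          if_else(.data$period %in% c("P1", "P2"), 0.5 * .data$sig, 0),
        expression = exp(rnorm(dplyr::n(), mean = .data$meanlog, sd = 1))
      ) |>
      select("gene_id", "region", "period", "expression")
  })
}

#' Simulate coexpression-module assignments
#'
#' Assigns each gene to one coexpression module (a small fraction to two)
#' with a cell-type label, emulating module tables from differential
#' coexpression studies of autism and control brains.
#'
#' @param genes Gene panel or any tibble with `gene_id`.
#' @param n_modules Number of modules.
#' @param cell_types Cell-type labels sampled per module.
#' @param seed Integer seed.
#' @return Tibble: `gene_id`, `module`, `cell_type` (one row per
#'   assignment).
#' @export
simulate_modules <- function(genes, n_modules = 6,
                             cell_types = c("neuron", "interneuron",
                                            "astrocyte", "oligodendrocyte",
                                            "microglia"),
                             seed = 1L) {
  check_columns(genes, "gene_id", "gene panel")
  with_seed(seed, {
    modules <- tibble(
      module = sprintf("M%02d", seq_len(n_modules)),
      cell_type = sample(cell_types, n_modules, replace = TRUE)
    )
    primary <- tibble(
      gene_id = genes$gene_id,
      module = sample(modules$module, nrow(genes), replace = TRUE)
    )
    extra <- primary[runif(nrow(primary)) < 0.1, "gene_id", drop = FALSE]
    extra$module <- sample(modules$module, nrow(extra), replace = TRUE)
    bind_rows(primary, extra) |>
      distinct() |>
      left_join(modules, by = "module") |>
      arrange(.data$gene_id, .data$module)
  })
}
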