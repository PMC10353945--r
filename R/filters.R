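#' Default list of recurrently mutated genes excluded from burden analysis
#'
#' Genes recurrently found mutated across unrelated individuals in different
#' families, excluded from rare-variant burden analysis as likely alignment
#' or annotation artifacts.
#' @export
recurrent_gene_blocklist <- c("MUC4", "MUC12", "HLA-A", "HLA-B", "HYDIN",
                              "TTN", "PAX5", "OR2T10", "MYH4")

#' Genotype-call quality control
#'
#' A call passes iff call rate > 0.9, genotype quality >= 30, depth > 20 and
#' allelic fraction >= 0.25 (and <= 0.75 for autosomal variants). Thresholds
#' keep the printed strictness: depth and call rate strict, GQ and the lower
#' allelic-fraction bound inclusive. A missing metric fails with reason
#' `missing_metric`.
#'
#' @param calls A tibble with columns `depth`, `genotype_quality`,
#'   `allelic_fraction`, `call_rate`, `autosomal`.
#' @param min_gq,min_depth,min_af,max_af_autosomal,min_call_rate Thresholds.
#' @return The input with logical `qc_pass` and character `qc_reason`
#'   (`NA` when passing) columns appended.
#' @export
qc_genotype <- function(calls,
                        min_gq = 30, min_depth = 20, min_af = 0.25,
                        max_af_autosomal = 0.75, min_call_rate = 0.9) {
  check_columns(calls, c("depth", "genotype_quality", "allelic_fraction",
                         "call_rate", "autosomal"), "genotype calls")
  metrics <- calls[, c("depth", "genotype_quality", "allelic_fraction",
                       "call_rate", "autosomal")]
  missing <- !complete.cases(metrics)
  pass <- !missing &
    calls$call_rate > min_call_rate &
    calls$genotype_quality >= min_gq &
    calls$depth > min_depth &
    calls$allelic_fraction >= min_af &
    (!calls$autosomal | calls$allelic_fraction <= max_af_autosomal)
  reason <- rep(NA_character_, nrow(calls))
  reason[!pass] <- "qc_fail"
  reason[missing] <- "missing_metric"
  calls |> mutate(qc_pass = pass, qc_reason = reason)
}

#' Allele-frequency filter
#'
#' In `strict` mode (the default) a variant passes iff it is absent from the
#' reference population (`ref_pop_af == 0`) and has within-sample allele
#' frequency at most `max_sample_af`. In `maf` mode the reference-population
#' condition relaxes to `ref_pop_af <= max_ref_af`.
#'
#' @param ref_pop_af,sample_af Numeric vectors of allele frequencies.
#' @param mode `"strict"` or `"maf"`.
#' @param max_ref_af,max_sample_af Frequency ceilings (default 1%).
#' @return Logical vector.
#' @export
frequency_filter <- function(ref_pop_af, sample_af, mode = c("strict", "maf"),
                             max_ref_af = 0.01, max_sample_af = 0.01) {
  mode <- match.arg(mode)
  ref_ok <- if (mode == "strict") ref_pop_af == 0 else ref_pop_af <= max_ref_af
  ref_ok & sample_af <= max_sample_af
}

#' Recurrently mutated gene filter
#'
#' @param gene_id Character vector of gene symbols.
#' @param blocklist Genes to exclude; defaults to
#'   [recurrent_gene_blocklist].
#' @return Logical vector, `TRUE` when the gene is not blocklisted.
#' @export
recurrent_gene_filter <- function(gene_id,
                                  blocklist = recurrent_gene_blocklist) {
  !(gene_id %in% blocklist)
}

#' Annotation-confidence filter for LoF variants
#'
#' Passes only high-confidence LoF annotations carrying no auxiliary flag
#' (low-confidence calls, ancestral alleles and any flagged annotation are
#' rejected).
#'
#' @param loftee_flag Character vector (`high_confidence`, `low_confidence`,
#'   `flagged`, ...).
#' @param other_flags Character vector of auxiliary flags (`""` or `NA` =
#'   none).
#' @return Logical vector.
#' @export
loftee_filter <- function(loftee_flag, other_flags = "") {
  no_aux <- is.na(other_flags) | other_flags == ""
  !is.na(loftee_flag) & loftee_flag == "high_confidence" & no_aux
}
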