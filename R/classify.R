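#' Classification configuration
#'
#' Thresholds and modes for [classify_variants()]. Printed strictness is
#' kept: brain pext and truncated fraction must strictly exceed their
#' thresholds; the splice window is inclusive at 3 bp.
#'
#' @param pext_threshold Exon brain-pext must exceed this (strict).
#' @param truncation_threshold Truncated protein fraction must exceed this
#'   (strict).
#' @param frequency_mode `"strict"` (absent from the reference population) or
#'   `"maf"` (reference MAF at most `max_ref_af`).
#' @param max_ref_af,max_sample_af Frequency ceilings for `frequency_filter`.
#' @param splice_window Maximum intronic distance (bp, inclusive) for mapping
#'   a splice variant to its closest coding exon.
#' @param mnv_window Vicinity window (bp) for in-phase multi-nucleotide
#'   variant rescue; default 2 (same codon).
#' @param blocklist Recurrently mutated genes to exclude.
#' @param min_gq,min_depth,min_af,max_af_autosomal,min_call_rate Genotype QC
#'   thresholds, see [qc_genotype()].
#' @return A list of class `classify_config`.
#' @export
classify_config <- function(pext_threshold = 0.1,
                            truncation_threshold = 0.1,
                            frequency_mode = c("strict", "maf"),
                            max_ref_af = 0.01,
                            max_sample_af = 0.01,
                            splice_window = 3,
                            mnv_window = 2,
                            blocklist = recurrent_gene_blocklist,
                            min_gq = 30, min_depth = 20, min_af = 0.25,
                            max_af_autosomal = 0.75, min_call_rate = 0.9) {
  structure(list(
    pext_threshold = pext_threshold,
    truncation_threshold = truncation_threshold,
    frequency_mode = match.arg(frequency_mode),
    max_ref_af = max_ref_af,
    max_sample_af = max_sample_af,
    splice_window = splice_window,
    mnv_window = mnv_window,
    blocklist = blocklist,
    min_gq = min_gq, min_depth = min_depth, min_af = min_af,
    max_af_autosomal = max_af_autosomal, min_call_rate = min_call_rate
  ), class = "classify_config")
}

#' Maximum brain pext per exon
#'
#' Appends a `brain_pext` column to a gene-model table: the maximum of the 13
#' brain-tissue pext values per exon. Missing tissues are ignored (the
#' maximum is robust to missing components); an exon with all 13 missing gets
#' `NA` and downstream classification fails with reason `missing_pext`.
#'
#' @param models A gene-model table ([gene_models()]): one row per exon with
#'   `pext_<tissue>` columns.
#' @return `models` with `brain_pext` appended.
#' @export
brain_pext <- function(models) {
  pcols <- grep("^pext_", names(models), value = TRUE)
  if (length(pcols) == 0) abort("gene models carry no pext_* columns")
  vals <- suppressWarnings(
    do.call(pmax, c(unname(as.list(models[pcols])), list(na.rm = TRUE)))
  )
  vals[is.infinite(vals)] <- NA_real_
  models$brain_pext <- vals
  models
}

#' Truncated fraction of the encoded protein
#'
#' The fraction of the protein lost to a truncating variant at a given CDS
#' position: `1 - cds_position / cds_length`.
#'
#' @param cds_position 1-based CDS nucleotide position (vector).
#' @param cds_length CDS length in nucleotides (vector, recycled).
#' @return Numeric vector in \[0, 1\].
#' @export
truncated_fraction <- function(cds_position, cds_length) {
  if (any(cds_position > cds_length, na.rm = TRUE)) {
    abort("position_out_of_cds: cds_position exceeds cds_length")
  }
  if (any(cds_position < 1, na.rm = TRUE)) {
    abort("cds_position must be >= 1")
  }
  1 - cds_position / cds_length
}

#' Map splice-site variants to their closest coding exon
#'
#' A splice variant sits outside the CDS; its record carries the CDS
#' coordinate of the closest coding base (`cds_position`) and the intronic
#' distance to it (`splice_offset_bp`). When that distance is within the
#' window (inclusive, default +/- 3 bp) the variant maps to the exon
#' containing the boundary, with the boundary coordinate as effective
#' position; otherwise it is unmappable (reason `unmapped_splice`).
#'
#' @param variants Variant table with `gene_id`, `cds_position`,
#'   `is_splice_site`, `splice_offset_bp`.
#' @param models Gene-model table ([gene_models()]).
#' @param window Inclusive mapping window in bp.
#' @return `variants` with `effective_cds_position`, `effective_exon_index`
#'   and `splice_reason` (`NA` when mapped) appended.
#' @export
map_splice_to_exon <- function(variants, models, window = 3) {
  resolve_exon(variants, models, window)
}

# Resolve every variant (coding or splice) to an effective exon and CDS
# position. Coding variants resolve to the exon containing cds_position;
# splice variants additionally require splice_offset_bp <= window.
resolve_exon <- function(variants, models, window) {
  check_columns(variants, c("gene_id", "cds_position", "is_splice_site"),
                "variant table")
  check_columns(models, c("gene_id", "cds_length", "exon_index",
                          "cds_start", "cds_end"), "gene models")
  unknown <- setdiff(unique(variants$gene_id), unique(models$gene_id))
  if (length(unknown) > 0) {
    abort(sprintf("variants reference unknown gene(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  exons <- models |>
    select("gene_id", "exon_index", "cds_start", "cds_end")
  drop_cols <- intersect(c("exon_index", "cds_start", "cds_end"),
                         names(variants))
  v <- variants |>
    select(-all_of(drop_cols)) |>
    left_join(
      exons,
      by = dplyr::join_by(gene_id,
                          dplyr::between(cds_position, cds_start, cds_end))
    )
  offset <- if ("splice_offset_bp" %in% names(v)) v$splice_offset_bp else NA
  unmapped_splice <- v$is_splice_site &
    (is.na(offset) | abs(offset) > window)
  out_of_cds <- is.na(v$exon_index)
  v |>
    mutate(
      effective_exon_index = if_else(unmapped_splice, NA_integer_,
                                     .data$exon_index),
      effective_cds_position = if_else(unmapped_splice | out_of_cds,
                                       NA_integer_,
                                       as.integer(.data$cds_position)),
      splice_reason = dplyr::case_when(
        unmapped_splice ~ "unmapped_splice",
        out_of_cds ~ "position_out_of_cds",
        TRUE ~ NA_character_
      )
    ) |>
    select(-"exon_index", -"cds_start", -"cds_end")
}

#' Phase-aware multi-nucleotide variant (MNV) filter
#'
#' A stringent-LoF candidate is dropped iff an in-phase variant within the
#' vicinity window alters the joint consequence away from LoF (for example a
#' same-codon SNV turning a stop-gain into a missense codon). Out-of-phase or
#' distant partners never drop it; unknown phase retains the candidate with a
#' warning (conservative).
#'
#' @param variants Variant table with `variant_id`.
#' @param mnv_pairs `NULL`, or a tibble with `variant_id`,
#'   `partner_variant_id`, `phase` (`in_phase`/`out_of_phase`/`unknown`),
#'   `distance_bp`, `joint_consequence`.
#' @param window Vicinity window in bp (default 2, same codon).
#' @return Logical vector: `TRUE` when retained.
#' @export
mnv_phase_filter <- function(variants, mnv_pairs = NULL, window = 2) {
  if (is.null(mnv_pairs) || nrow(mnv_pairs) == 0) {
    return(rep(TRUE, nrow(variants)))
  }
  check_columns(mnv_pairs, c("variant_id", "phase", "distance_bp",
                             "joint_consequence"), "mnv pair table")
  near <- mnv_pairs |> filter(.data$distance_bp <= window)
  drop_ids <- near |>
    filter(.data$phase == "in_phase", .data$joint_consequence != "LoF") |>
    pull("variant_id")
  unknown <- near |>
    filter(.data$phase == "unknown", .data$joint_consequence != "LoF") |>
    pull("variant_id")
  unknown <- intersect(unknown, variants$variant_id)
  if (length(unknown) > 0) {
    warn(sprintf(
      "retaining %d variant(s) with unknown phase in MNV vicinity: %s",
      length(unknown), paste(utils::head(unknown, 5), collapse = ", ")))
  }
  !(variants$variant_id %in% drop_ids)
}

#' Classify variants into S-LoF / S-SYN / other
#'
#' Applies the full stringency cascade. A variant is `S_LOF` iff its
#' consequence is LoF and it passes genotype QC, the frequency filter, the
#' recurrent-gene filter, the annotation-confidence filter, the MNV phase
#' filter, maps to an exon with brain pext strictly above the threshold and
#' truncates strictly more than the threshold fraction of the protein.
#' `S_SYN` applies the same QC, frequency, recurrent-gene, exon-expression
#' and truncation-position filters to synonymous variants (the
#' negative-control class). Everything else is `OTHER`, with the list of
#' failed filters recorded.
#'
#' @param variants Variant table (`variant_id`, `gene_id`, `individual_id`,
#'   `consequence`, `loftee_flag`, `loftee_other_flags`, `ref_pop_af`,
#'   `sample_af`, `cds_position`, `is_splice_site`, `splice_offset_bp`).
#' @param models Gene-model table ([gene_models()]).
#' @param calls Optional genotype-call metrics (from
#'   [simulate_genotype_metrics()] or real QC output); when supplied, a
#'   variant call without passing metrics is rejected.
#' @param config A [classify_config()].
#' @param mnv_pairs Optional MNV phase table, see [mnv_phase_filter()].
#' @return A tibble: the variant keys plus `class`
#'   (`S_LOF`/`S_SYN`/`OTHER`), `failed_filters` (comma-separated, `""` when
#'   qualifying), `brain_pext`, `truncated_fraction`,
#'   `effective_cds_position`, `effective_exon_index`.
#' @export
classify_variants <- function(variants, models, calls = NULL,
                              config = classify_config(),
                              mnv_pairs = NULL) {
  check_columns(variants, c("variant_id", "gene_id", "individual_id",
                            "consequence", "ref_pop_af", "sample_af",
                            "cds_position", "is_splice_site"),
                "variant table")
  models <- brain_pext(models)
  v <- resolve_exon(variants, models, config$splice_window)

  # per-filter pass flags -----------------------------------------------
  if (!is.null(calls)) {
    qc <- qc_genotype(calls,
                      min_gq = config$min_gq, min_depth = config$min_depth,
                      min_af = config$min_af,
                      max_af_autosomal = config$max_af_autosomal,
                      min_call_rate = config$min_call_rate) |>
      select("variant_id", "individual_id", "qc_pass")
    v <- v |> left_join(qc, by = c("variant_id", "individual_id"))
    v$qc_pass[is.na(v$qc_pass)] <- FALSE
  } else {
    v$qc_pass <- TRUE
  }
  v$freq_pass <- frequency_filter(v$ref_pop_af, v$sample_af,
                                  mode = config$frequency_mode,
                                  max_ref_af = config$max_ref_af,
                                  max_sample_af = config$max_sample_af)
  v$recurrent_pass <- recurrent_gene_filter(v$gene_id, config$blocklist)
  other_flags <- if ("loftee_other_flags" %in% names(v)) {
    v$loftee_other_flags
  } else {
    ""
  }
  v$loftee_pass <- loftee_filter(v$loftee_flag, other_flags)

  pext_lookup <- models |>
    select("gene_id", "exon_index", "brain_pext") |>
    rename(effective_exon_index = "exon_index")
  v <- v |> left_join(pext_lookup, by = c("gene_id", "effective_exon_index"))
  v$pext_known <- !is.na(v$brain_pext) & is.na(v$splice_reason)
  v$pext_pass <- v$pext_known & v$brain_pext > config$pext_threshold

  len <- models |> distinct(.data$gene_id, .data$cds_length)
  v <- v |> left_join(len, by = "gene_id")
  tf <- rep(NA_real_, nrow(v))
  ok <- !is.na(v$effective_cds_position)
  tf[ok] <- truncated_fraction(v$effective_cds_position[ok],
                               v$cds_length[ok])
  v$truncated_fraction <- tf
  v$trunc_pass <- !is.na(tf) & tf > config$truncation_threshold

  v$mnv_pass <- mnv_phase_filter(v, mnv_pairs, window = config$mnv_window)

  # class assignment ----------------------------------------------------
  shared <- v$qc_pass & v$freq_pass & v$recurrent_pass &
    is.na(v$splice_reason) & v$pext_pass & v$trunc_pass
  is_slof <- v$consequence == "LoF" & shared & v$loftee_pass & v$mnv_pass
  is_ssyn <- v$consequence == "synonymous" & shared

  reasons <- character(nrow(v))
  fail <- function(flag, label) if_else(!flag, label, NA_character_)
  reason_mat <- cbind(
    fail(v$consequence %in% c("LoF", "synonymous"), "consequence"),
    fail(v$qc_pass, "genotype_qc"),
    fail(v$freq_pass, "frequency"),
    fail(v$recurrent_pass, "recurrent_gene"),
    if_else(v$consequence == "LoF" & !v$loftee_pass, "loftee", NA_character_),
    v$splice_reason,
    if_else(is.na(v$splice_reason) & !v$pext_known, "missing_pext",
            NA_character_),
    if_else(v$pext_known & !v$pext_pass, "pext", NA_character_),
    if_else(is.na(v$splice_reason) & !v$trunc_pass & !is.na(v$truncated_fraction),
            "truncation", NA_character_),
    if_else(v$consequence == "LoF" & !v$mnv_pass, "mnv_phase", NA_character_)
  )
  reasons <- apply(reason_mat, 1, function(r) {
    paste(stats::na.omit(r), collapse = ",")
  })

  v |>
    mutate(
      class = dplyr::case_when(is_slof ~ "S_LOF",
                               is_ssyn ~ "S_SYN",
                               TRUE ~ "OTHER"),
      failed_filters = if_else(.data$class == "OTHER", reasons, "")
    ) |>
    select("variant_id", "gene_id", "individual_id", "consequence", "class",
           "failed_filters", "brain_pext", "truncated_fraction",
           "effective_cds_position", "effective_exon_index")
}

#' Long-form carrier calls for one variant class
#'
#' @param classified Output of [classify_variants()].
#' @param class `"S_LOF"` or `"S_SYN"`.
#' @return Tibble with `gene_id`, `individual_id`, `variant_id` (one row per
#'   qualifying variant call; an individual may appear more than once per
#'   gene).
#' @export
qualifying_carriers <- function(classified, class = "S_LOF") {
  classified |>
    filter(.data$class == !!class) |>
    select("gene_id", "individual_id", "variant_id")
}

#' Gene-by-individual carrier matrix
#'
#' Binary carrier indicators per gene and individual for one variant class.
#' An individual with several qualifying variants in a gene counts once.
#'
#' @param classified Output of [classify_variants()].
#' @param cohort Cohort table (defines the full individual set).
#' @param class Variant class.
#' @param format `"long"` (tibble of carriers: `gene_id`, `individual_id`,
#'   `class`, `n_variants`) or `"wide"` (base 0/1 matrix, genes in rows).
#' @export
carrier_matrix <- function(classified, cohort, class = "S_LOF",
                           format = c("long", "wide")) {
  format <- match.arg(format)
  carriers <- qualifying_carriers(classified, class) |>
    count(.data$gene_id, .data$individual_id, name = "n_variants") |>
    mutate(class = !!class)
  bad <- setdiff(carriers$individual_id, cohort$individual_id)
  if (length(bad) > 0) {
    abort(sprintf("carrier(s) not present in cohort: %s",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (format == "long") return(carriers)
  genes <- sort(unique(classified$gene_id))
  m <- matrix(0L, nrow = length(genes), ncol = nrow(cohort),
              dimnames = list(genes, cohort$individual_id))
  if (nrow(carriers) > 0) {
    m[cbind(match(carriers$gene_id, genes),
            match(carriers$individual_id, cohort$individual_id))] <- 1L
  }
  m
}
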