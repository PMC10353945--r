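#' Write a stage output table with a seed-stamped header
#'
#' Tab-delimited text with leading `#` comment lines recording the seed and
#' (optionally) the pipeline configuration hash, so every output is
#' self-describing and reproducible.
#'
#' @param data A data frame.
#' @param path Output path.
#' @param seed Seed to record (optional).
#' @param config_hash Configuration hash to record (optional).
#' @export
write_stage_table <- function(data, path, seed = NULL, config_hash = NULL) {
  header <- c(
    if (!is.null(seed)) sprintf("# seed=%s", seed),
    if (!is.null(config_hash)) sprintf("# config_hash=%s", config_hash)
  )
  if (length(header) > 0) {
    writeLines(header, path)
    readr::write_tsv(data, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(data, path)
  }
  invisible(path)
}

#' Read a stage output table
#'
#' @param path Path written by [write_stage_table()].
#' @return A tibble (header comments skipped).
#' @export
read_stage_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

variant_required_cols <- c("variant_id", "gene_id", "individual_id",
                           "consequence", "loftee_flag", "ref_pop_af",
                           "sample_af", "cds_position", "is_splice_site")

#' Read an annotated variant table
#'
#' Accepts the tab-delimited layout written by the simulator/pipeline or a
#' VCF 4.2 file carrying the annotation fields in INFO and per-sample
#' metrics in FORMAT (see [write_variant_vcf()]). Missing required columns
#' raise an error naming them.
#'
#' @param path Input path.
#' @param format `"tabular"` or `"vcf"`.
#' @return For tabular input, the variant tibble; for VCF, a list with
#'   `variants` and `calls` (genotype metrics).
#' @export
read_variant_input <- function(path, format = c("tabular", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") return(read_variant_vcf(path))
  variants <- read_stage_table(path)
  check_columns(variants, variant_required_cols, sprintf("'%s'", path))
  if ("loftee_other_flags" %in% names(variants)) {
    # empty strings (no auxiliary flag) round-trip as NA in delimited text
    variants$loftee_other_flags[is.na(variants$loftee_other_flags)] <- ""
  }
  variants
}

#' Write variants (and genotype metrics) as VCF 4.2
#'
#' Emits one record per variant with annotation in INFO (`GENE`,
#' `CSQ_CLASS`, `LOFTEE`, `LOFTEE_FLAGS`, `CDS_POS`, `EXON`, `REF_AF`, `AC`,
#' `SAMPLE_AF`, `SPLICE_OFFSET`) and per-sample `GT:DP:GQ:AF:CR` FORMAT
#' fields for the carrier of each variant. Positions are synthetic
#' bookkeeping coordinates (one locus per record); the file exists to
#' round-trip the annotation, not to describe a genome.
#'
#' @param variants Variant table.
#' @param calls Genotype metrics ([simulate_genotype_metrics()] output).
#' @param path Output path (plain text `.vcf`).
#' @export
write_variant_vcf <- function(variants, calls, path) {
  check_columns(variants, variant_required_cols, "variant table")
  samples <- sort(unique(variants$individual_id))
  calls_key <- paste(calls$variant_id, calls$individual_id)

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=lofburden",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=LOFTEE,Number=1,Type=String,Description="LoF confidence">',
    '##INFO=<ID=LOFTEE_FLAGS,Number=1,Type=String,Description="Auxiliary LoF flags">',
    '##INFO=<ID=CDS_POS,Number=1,Type=Integer,Description="1-based CDS position">',
    '##INFO=<ID=EXON,Number=1,Type=Integer,Description="Exon index">',
    '##INFO=<ID=REF_AF,Number=1,Type=Float,Description="Reference population allele frequency">',
    '##INFO=<ID=AC,Number=1,Type=Integer,Description="Within-sample allele count">',
    '##INFO=<ID=SAMPLE_AF,Number=1,Type=Float,Description="Within-sample allele frequency">',
    '##INFO=<ID=SPLICE_OFFSET,Number=1,Type=Integer,Description="Distance (bp) from splice variant to closest coding base">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=AF,Number=1,Type=Float,Description="Allelic fraction">',
    '##FORMAT=<ID=CR,Number=1,Type=Float,Description="Variant call rate">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )

  exon <- if ("exon_index" %in% names(variants)) variants$exon_index else NA
  offset <- if ("splice_offset_bp" %in% names(variants)) {
    variants$splice_offset_bp
  } else {
    NA
  }
  flags <- if ("loftee_other_flags" %in% names(variants)) {
    variants$loftee_other_flags
  } else {
    ""
  }
  ac <- if ("allele_count" %in% names(variants)) variants$allele_count else 1L

  info <- sprintf(
    "GENE=%s;CSQ_CLASS=%s;LOFTEE=%s;LOFTEE_FLAGS=%s;CDS_POS=%d;EXON=%s;REF_AF=%g;AC=%d;SAMPLE_AF=%g%s",
    variants$gene_id, variants$consequence, variants$loftee_flag,
    if_else(is.na(flags) | flags == "", ".", flags),
    as.integer(variants$cds_position),
    if_else(is.na(exon), ".", as.character(exon)),
    variants$ref_pop_af, as.integer(ac), variants$sample_af,
    if_else(variants$is_splice_site & !is.na(offset),
            sprintf(";SPLICE_OFFSET=%d", as.integer(offset)), "")
  )

  records <- character(nrow(variants))
  for (r in seq_len(nrow(variants))) {
    geno <- rep("./.:.:.:.:.", length(samples))
    j <- match(paste(variants$variant_id[r], variants$individual_id[r]),
               calls_key)
    s <- match(variants$individual_id[r], samples)
    if (!is.na(j)) {
      geno[s] <- sprintf("0/1:%d:%d:%.4f:%.4f", calls$depth[j],
                         calls$genotype_quality[j],
                         calls$allelic_fraction[j], calls$call_rate[j])
    } else {
      geno[s] <- "0/1:.:.:.:."
    }
    records[r] <- paste(c("1", r, variants$variant_id[r], "A", "T", ".",
                          "PASS", info[r], "GT:DP:GQ:AF:CR", geno),
                        collapse = "\t")
  }
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read a VCF written by [write_variant_vcf()]
#'
#' @param path Path to the VCF.
#' @return List with `variants` and `calls` tibbles matching the tabular
#'   layout.
#' @export
read_variant_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info_get <- function(key, numeric = FALSE) {
    vals <- vcfR::extract.info(vcf, element = key)
    if (numeric) suppressWarnings(as.numeric(vals)) else vals
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  carrier_idx <- apply(gt, 1, function(row) {
    which(!is.na(row) & row %in% c("0/1", "1/0", "1/1", "0|1", "1|0"))[1]
  })
  if (anyNA(carrier_idx)) abort("VCF record without a carrier genotype")
  samples <- colnames(gt)
  offset <- info_get("SPLICE_OFFSET", numeric = TRUE)
  flags <- info_get("LOFTEE_FLAGS")
  variants <- tibble(
    variant_id = fix$ID,
    gene_id = info_get("GENE"),
    individual_id = samples[carrier_idx],
    consequence = info_get("CSQ_CLASS"),
    loftee_flag = info_get("LOFTEE"),
    loftee_other_flags = if_else(is.na(flags) | flags == ".", "", flags),
    ref_pop_af = info_get("REF_AF", numeric = TRUE),
    allele_count = as.integer(info_get("AC", numeric = TRUE)),
    sample_af = info_get("SAMPLE_AF", numeric = TRUE),
    cds_position = as.integer(info_get("CDS_POS", numeric = TRUE)),
    exon_index = as.integer(info_get("EXON", numeric = TRUE)),
    is_splice_site = !is.na(offset),
    splice_offset_bp = as.integer(offset)
  )
  fmt_num <- function(key) {
    m <- vcfR::extract.gt(vcf, element = key)
    suppressWarnings(as.numeric(m[cbind(seq_len(nrow(m)), carrier_idx)]))
  }
  calls <- tibble(
    variant_id = variants$variant_id,
    individual_id = variants$individual_id,
    depth = as.integer(fmt_num("DP")),
    genotype_quality = as.integer(fmt_num("GQ")),
    allelic_fraction = fmt_num("AF"),
    call_rate = fmt_num("CR"),
    autosomal = TRUE
  )
  list(variants = variants, calls = calls)
}
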