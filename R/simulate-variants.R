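#' Simulate annotated variants and ground-truth carrier status
#'
#' Draws, for every gene in the panel, qualifying loss-of-function carriers
#' (Bernoulli per individual at `carrier_freq_diagnosed` /
#' `carrier_freq_undiagnosed`) and qualifying synonymous carriers (at
#' `syn_freq` in both groups), and emits one annotated variant record per
#' carrier per gene. Variants carried by ground-truth carriers are generated
#' to pass every stringency filter: reference-population allele frequency 0,
#' high-confidence annotation without flags, CDS position in a brain-expressed
#' exon (pext > 0.1) truncating more than 10% of the protein, and -- for the
#' `splice_fraction` of truth LoF variants placed at splice sites -- an
#' intronic offset of at most 3 bp from the closest coding base.
#'
#' In addition, `decoys_per_gene` decoy variants per gene are assigned to
#' random individuals, each violating exactly one filter (common reference
#' allele, low-confidence or flagged annotation, skipped exon, truncation of
#' at most 10%, splice offset beyond 3 bp, or a non-LoF/non-synonymous
#' consequence). Decoys are the material the classifier must reject; the
#' `carrier_truth` table never includes them.
#'
#' @param cohort A cohort table from [simulate_cohort()].
#' @param genes A gene panel from [simulate_gene_panel()].
#' @param seed Integer seed.
#' @param splice_fraction Fraction of truth LoF variants modelled as
#'   essential splice variants.
#' @param decoys_per_gene Number of filter-violating decoy variants per gene.
#' @param multi_variant If `TRUE`, a small fraction of truth carriers receive
#'   a second qualifying variant in the same gene (carrier status downstream
#'   is binary either way).
#' @return A list with `variants` (one row per variant record) and
#'   `carrier_truth` (columns `gene_id`, `individual_id`, `class` in
#'   `S_LOF`/`S_SYN`).
#' @export
simulate_variants <- function(cohort, genes, seed = 1L,
                              splice_fraction = 0.1,
                              decoys_per_gene = 1,
                              multi_variant = FALSE) {
  check_columns(cohort, c("individual_id", "status"), "cohort")
  check_columns(genes, c("gene_id", "gene_set", "carrier_freq_diagnosed",
                         "carrier_freq_undiagnosed", "syn_freq",
                         "cds_length", "exons"), "gene panel")
  if (nrow(genes) == 0) abort("gene panel is empty")

  diag_ids <- cohort$individual_id[cohort$status == "diagnosed"]
  undiag_ids <- cohort$individual_id[cohort$status == "undiagnosed"]
  n_alleles <- 2L * nrow(cohort)

  with_seed(seed, {
    rows <- vector("list", nrow(genes))
    truth <- vector("list", nrow(genes))
    for (gi in seq_len(nrow(genes))) {
      g <- genes[gi, ]
      exons <- g$exons[[1]]
      site <- qualifying_sites(exons, g$cds_length)

      lof_carriers <- c(
        diag_ids[runif(length(diag_ids)) < g$carrier_freq_diagnosed],
        undiag_ids[runif(length(undiag_ids)) < g$carrier_freq_undiagnosed]
      )
      syn_carriers <- cohort$individual_id[runif(nrow(cohort)) < g$syn_freq]

      if (multi_variant && length(lof_carriers) > 0) {
        dup <- lof_carriers[runif(length(lof_carriers)) < 0.1]
        lof_carriers <- c(lof_carriers, dup)
      }

      lof <- truth_variant_rows(g$gene_id, lof_carriers, "LoF", site,
                                splice_fraction)
      syn <- truth_variant_rows(g$gene_id, syn_carriers, "synonymous", site,
                                splice_fraction = 0)
      dec <- decoy_variant_rows(g$gene_id, decoys_per_gene,
                                cohort$individual_id, exons, g$cds_length,
                                site)
      rows[[gi]] <- bind_rows(lof, syn, dec)
      truth[[gi]] <- bind_rows(
        if (length(lof_carriers) > 0) {
          tibble(gene_id = g$gene_id,
                 individual_id = unique(lof_carriers), class = "S_LOF")
        },
        if (length(syn_carriers) > 0) {
          tibble(gene_id = g$gene_id,
                 individual_id = unique(syn_carriers), class = "S_SYN")
        }
      )
    }
    variants <- bind_rows(rows)
    if (nrow(variants) > 0) {
      variants <- variants |>
        mutate(
          variant_id = sprintf("V%06d", row_number()),
          allele_count = 1L,
          sample_af = 1 / n_alleles
        ) |>
        select("variant_id", dplyr::everything())
    }
    list(variants = variants, carrier_truth = bind_rows(truth))
  })
}

# Uniform integer draw from [a, b]; sample(x, 1) on a length-one numeric
# would sample 1:x instead.
sample_int_range <- function(a, b) {
  if (a == b) return(a)
  sample(seq(a, b), 1)
}

# Positions that satisfy both stringency rules: inside an exon whose maximum
# brain pext exceeds 0.1, and truncating strictly more than 10% of the
# protein (cds_position < 0.9 * cds_length).
qualifying_sites <- function(exons, cds_length) {
  p_max <- floor(0.9 * cds_length)
  if (p_max >= 0.9 * cds_length) p_max <- p_max - 1L
  pext_max <- apply(as.matrix(exons[, paste0("pext_", pext_tissues)]), 1, max)
  ok <- exons[pext_max > 0.1 & exons$cds_start <= p_max, , drop = FALSE]
  ok$cds_end <- pmin(ok$cds_end, p_max)
  low <- exons[pext_max <= 0.1, , drop = FALSE]
  list(pass = ok, low_pext = low, p_max = as.integer(p_max),
       cds_length = cds_length)
}

sample_pass_position <- function(site, n) {
  widths <- site$pass$cds_end - site$pass$cds_start + 1L
  ex <- site$pass$exon_index[sample.int(nrow(site$pass), n,
                                        replace = TRUE, prob = widths)]
  pos <- integer(n)
  for (k in seq_len(n)) {
    row <- site$pass[site$pass$exon_index == ex[k], ]
    pos[k] <- sample_int_range(row$cds_start, row$cds_end)
  }
  list(exon_index = ex, cds_position = pos)
}

truth_variant_rows <- function(gene_id, carriers, consequence, site,
                               splice_fraction) {
  n <- length(carriers)
  if (n == 0) return(NULL)
  loc <- sample_pass_position(site, n)
  is_splice <- consequence == "LoF" & runif(n) < splice_fraction
  offset <- rep(NA_integer_, n)
  if (any(is_splice)) {
    # splice variants sit 1-3 bp outside an exon boundary; their
    # cds_position is the boundary's CDS coordinate
    for (k in which(is_splice)) {
      row <- site$pass[sample.int(nrow(site$pass), 1), ]
      loc$cds_position[k] <- row$cds_start
      loc$exon_index[k] <- row$exon_index
      offset[k] <- sample(1:3, 1)
    }
  }
  tibble(
    gene_id = gene_id,
    individual_id = carriers,
    consequence = consequence,
    loftee_flag = "high_confidence",
    loftee_other_flags = "",
    ref_pop_af = 0,
    cds_position = as.integer(loc$cds_position),
    exon_index = as.integer(loc$exon_index),
    is_splice_site = is_splice,
    splice_offset_bp = offset
  )
}

decoy_failure_modes <- c("common_ref_af", "low_confidence", "flagged",
                         "low_pext_exon", "late_truncation", "far_splice",
                         "other_consequence")

decoy_variant_rows <- function(gene_id, n_decoys, all_ids, exons, cds_length,
                               site) {
  if (n_decoys <= 0) return(NULL)
  modes <- sample(decoy_failure_modes, n_decoys, replace = TRUE)
  out <- vector("list", n_decoys)
  for (k in seq_len(n_decoys)) {
    mode <- modes[k]
    # genes without a skippable exon cannot host a low-pext decoy
    if (mode == "low_pext_exon" && nrow(site$low_pext) == 0) {
      mode <- "late_truncation"
    }
    loc <- sample_pass_position(site, 1)
    row <- tibble(
      gene_id = gene_id,
      individual_id = sample(all_ids, 1),
      consequence = "LoF",
      loftee_flag = "high_confidence",
      loftee_other_flags = "",
      ref_pop_af = 0,
      cds_position = as.integer(loc$cds_position),
      exon_index = as.integer(loc$exon_index),
      is_splice_site = FALSE,
      splice_offset_bp = NA_integer_
    )
    if (mode == "common_ref_af") {
      row$ref_pop_af <- 0.02
    } else if (mode == "low_confidence") {
      row$loftee_flag <- "low_confidence"
    } else if (mode == "flagged") {
      row$loftee_other_flags <- "SINGLE_EXON"
    } else if (mode == "low_pext_exon" && nrow(site$low_pext) > 0) {
      e <- site$low_pext[sample.int(nrow(site$low_pext), 1), ]
      row$exon_index <- e$exon_index
      row$cds_position <- as.integer(sample_int_range(e$cds_start, e$cds_end))
    } else if (mode == "late_truncation" && site$p_max < cds_length) {
      row$cds_position <- as.integer(sample_int_range(site$p_max + 1L, cds_length))
      ex <- exons[exons$cds_start <= row$cds_position &
                    exons$cds_end >= row$cds_position, ]
      row$exon_index <- ex$exon_index[1]
    } else if (mode == "far_splice") {
      row$is_splice_site <- TRUE
      row$splice_offset_bp <- as.integer(sample(4:8, 1))
    } else if (mode == "other_consequence") {
      row$consequence <- "other"
    }
    out[[k]] <- row
  }
  bind_rows(out)
}

#' Simulate per-call genotype quality-control metrics
#'
#' Attaches sequencing metrics to each variant call: read depth, genotype
#' quality, allelic fraction and per-variant call rate. By default all calls
#' pass the downstream QC thresholds (depth > 20, GQ >= 30, allelic fraction
#' in \[0.25, 0.75\] on autosomes, call rate > 0.9); a configurable fraction
#' of calls is made to violate each threshold independently.
#'
#' @param variants A variant table (needs `variant_id`, `individual_id`).
#' @param fail_depth,fail_gq,fail_af,fail_call_rate Fraction of calls made to
#'   fail the corresponding threshold.
#' @param seed Integer seed.
#' @return A tibble with `variant_id`, `individual_id`, `depth`,
#'   `genotype_quality`, `allelic_fraction`, `call_rate`, `autosomal`.
#' @export
simulate_genotype_metrics <- function(variants,
                                      fail_depth = 0, fail_gq = 0,
                                      fail_af = 0, fail_call_rate = 0,
                                      seed = 1L) {
  check_columns(variants, c("variant_id", "individual_id"), "variant table")
  if (nrow(variants) == 0) abort("variant table is empty")
  n <- nrow(variants)
  with_seed(seed, {
    calls <- tibble(
      variant_id = variants$variant_id,
      individual_id = variants$individual_id,
      depth = 21L + rpois(n, 40),
      genotype_quality = pmin(99L, 30L + rpois(n, 40)),
      allelic_fraction = 0.25 + 0.5 * rbeta(n, 5, 5),
      call_rate = runif(n, 0.95, 1),
      autosomal = TRUE
    )
    bad_depth <- runif(n) < fail_depth
    bad_gq <- runif(n) < fail_gq
    bad_af <- runif(n) < fail_af
    bad_cr <- runif(n) < fail_call_rate
    calls$depth[bad_depth] <- sample(1:20, sum(bad_depth), replace = TRUE)
    calls$genotype_quality[bad_gq] <- sample(0:29, sum(bad_gq), replace = TRUE)
    if (any(bad_af)) {
      hi <- runif(sum(bad_af)) < 0.5
      af <- numeric(sum(bad_af))
      af[hi] <- runif(sum(hi), 0.76, 1)
      af[!hi] <- runif(sum(!hi), 0, 0.249)
      calls$allelic_fraction[bad_af] <- af
    }
    calls$call_rate[bad_cr] <- runif(sum(bad_cr), 0.5, 0.9)
    calls
  })
}
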