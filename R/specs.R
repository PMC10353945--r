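#' Specify a synthetic cohort
#'
#' Describes a case-control cohort with the structure a family-based autism
#' study assumes: diagnosed probands (a fraction of them embedded in
#' trio/quad families whose parents are always undiagnosed), undiagnosed
#' siblings and parents, and unselected population individuals. The same
#' spec and seed always reproduce the same cohort byte for byte.
#'
#' @param n_diagnosed Number of diagnosed individuals (> 0).
#' @param n_undiagnosed Number of undiagnosed individuals (> 0); family
#'   members of diagnosed probands are drawn from this budget, the remainder
#'   are labelled `population`.
#' @param family_fraction Fraction of diagnosed individuals embedded in a
#'   family (mother + father, plus an undiagnosed sibling with probability
#'   `sibling_prob`).
#' @param sex_ratio_diagnosed Male:female odds among diagnosed individuals.
#'   The default 4 reflects the roughly 4:1 ratio reported in autism cohorts.
#' @param sibling_prob Probability a family contributes an undiagnosed
#'   sibling.
#' @param pgs_shift_diagnosed Mean shift (in SD units) of the standardized
#'   polygenic score among diagnosed individuals. Default 0.2 SD; this is a
#'   free parameter of the generator, not an estimate.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(n_diagnosed,
                        n_undiagnosed,
                        family_fraction = 0.5,
                        sex_ratio_diagnosed = 4,
                        sibling_prob = 0.5,
                        pgs_shift_diagnosed = 0.2,
                        seed = 1L) {
  spec <- list(
    n_diagnosed = check_count(n_diagnosed, "n_diagnosed"),
    n_undiagnosed = check_count(n_undiagnosed, "n_undiagnosed"),
    family_fraction = check_proportion(family_fraction, "family_fraction"),
    sex_ratio_diagnosed = sex_ratio_diagnosed,
    sibling_prob = check_proportion(sibling_prob, "sibling_prob"),
    pgs_shift_diagnosed = as.numeric(pgs_shift_diagnosed),
    seed = as.integer(seed)
  )
  if (!is.numeric(sex_ratio_diagnosed) || sex_ratio_diagnosed <= 0) {
    abort("`sex_ratio_diagnosed` must be positive male:female odds")
  }
  structure(spec, class = "cohort_spec")
}

#' Specify per-trait generative effects for synthetic phenotypes
#'
#' Holds the standardized effect sizes entering the linear predictor
#' `beta_lof_high * LoF_high + beta_lof_low * LoF_low + beta_pgs * PGS +
#' beta_sex * sex` used for every generated trait, the residual scale for
#' continuous traits, the cut points used to discretize latent scores into
#' ordinal bands, and the participation odds multiplier for carriers.
#'
#' @param beta_lof_high,beta_lof_low Effects of carrying an S-LoF in a
#'   high-OR (> 10) / low-OR (<= 10) gene.
#' @param beta_pgs Effect per SD of polygenic score.
#' @param beta_sex Effect of sex, coded 0 = male, 1 = female (the coding used
#'   throughout the package).
#' @param noise_sd Residual SD for continuous traits (> 0).
#' @param band_thresholds Strictly increasing cut points (on the latent
#'   logistic scale) for 5-band ordinal traits (income, qualification).
#' @param iq_thresholds Strictly increasing cut points (latent Gaussian
#'   scale) for the 10 IQ score bins.
#' @param participation_or_carrier Odds multiplier for questionnaire
#'   response when carrying any S-LoF.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(beta_lof_high = 0,
                        beta_lof_low = 0,
                        beta_pgs = 0,
                        beta_sex = 0,
                        noise_sd = 1,
                        band_thresholds = qlogis(c(0.2, 0.4, 0.6, 0.8)),
                        iq_thresholds = qnorm(seq(0.1, 0.9, by = 0.1)),
                        participation_or_carrier = 1) {
  if (!is.numeric(noise_sd) || noise_sd <= 0) abort("`noise_sd` must be > 0")
  if (is.unsorted(band_thresholds, strictly = TRUE)) {
    abort("`band_thresholds` must be strictly increasing")
  }
  if (is.unsorted(iq_thresholds, strictly = TRUE)) {
    abort("`iq_thresholds` must be strictly increasing")
  }
  if (participation_or_carrier <= 0) {
    abort("`participation_or_carrier` must be positive")
  }
  structure(
    list(
      beta_lof_high = beta_lof_high,
      beta_lof_low = beta_lof_low,
      beta_pgs = beta_pgs,
      beta_sex = beta_sex,
      noise_sd = noise_sd,
      band_thresholds = band_thresholds,
      iq_thresholds = iq_thresholds,
      participation_or_carrier = participation_or_carrier
    ),
    class = "effect_spec"
  )
}

#' Build a synthetic gene panel
#'
#' Generates a tibble of gene specifications: gene set membership
#' (`autism_associated`, `constrained`, `other`), carrier frequencies of
#' qualifying LoF variants in the diagnosed and undiagnosed groups, a
#' synonymous-variant frequency shared by both groups, a CDS length and an
#' exon model. Each gene's exons tile `[1, cds_length]` without overlap and
#' carry per-exon pext values for 13 brain tissues (high for most exons, low
#' for `low_pext_fraction` of them so that the exon-expression filter has
#' something to reject).
#'
#' @param n_autism,n_constrained,n_other Number of genes per set.
#' @param carrier_freq_diagnosed,carrier_freq_undiagnosed Default qualifying
#'   LoF carrier frequencies; recycled across genes (vectors allowed).
#' @param syn_freq Synonymous qualifying-variant carrier frequency, equal in
#'   both groups (the negative-control class).
#' @param cds_length_range CDS length range (nt), drawn uniformly and rounded
#'   to a multiple of 3.
#' @param n_exons_range Range of exon counts per gene.
#' @param low_pext_fraction Fraction of exons given brain pext values below
#'   0.1 (skippable exons).
#' @param seed Integer seed.
#' @return A tibble with one row per gene: `gene_id`, `gene_set`,
#'   `carrier_freq_diagnosed`, `carrier_freq_undiagnosed`, `syn_freq`,
#'   `cds_length`, and a nested `exons` list-column (tibbles with
#'   `exon_index`, `cds_start`, `cds_end` and 13 `pext_*` tissue columns).
#' @export
simulate_gene_panel <- function(n_autism = 20,
                                n_constrained = 30,
                                n_other = 10,
                                carrier_freq_diagnosed = 0.004,
                                carrier_freq_undiagnosed = 0.0005,
                                syn_freq = 0.001,
                                cds_length_range = c(900, 6000),
                                n_exons_range = c(3, 12),
                                low_pext_fraction = 0.2,
                                seed = 1L) {
  n_total <- n_autism + n_constrained + n_other
  if (n_total < 1) abort("gene panel must contain at least one gene")
  with_seed(seed, {
    gene_set <- rep(c("autism_associated", "constrained", "other"),
                    times = c(n_autism, n_constrained, n_other))
    cds_length <- round(runif(n_total, cds_length_range[1], cds_length_range[2]) / 3) * 3
    panel <- tibble(
      gene_id = sprintf("G%04d", seq_len(n_total)),
      gene_set = gene_set,
      carrier_freq_diagnosed = rep_len(carrier_freq_diagnosed, n_total),
      carrier_freq_undiagnosed = rep_len(carrier_freq_undiagnosed, n_total),
      syn_freq = rep_len(syn_freq, n_total),
      cds_length = as.integer(cds_length)
    )
    panel$exons <- purrr::map2(panel$gene_id, panel$cds_length, function(g, len) {
      n_exons <- sample(seq(n_exons_range[1], n_exons_range[2]), 1)
      simulate_exon_model(len, n_exons, low_pext_fraction)
    })
    panel
  })
}

# The 13 brain tissues over which the exon-level pext maximum is taken.
pext_tissues <- c(
  "amygdala", "acc_ba24", "caudate", "cerebellar_hemisphere", "cerebellum",
  "cortex", "frontal_ba9", "hippocampus", "hypothalamus",
  "nucleus_accumbens", "putamen", "spinal_cord", "substantia_nigra"
)

simulate_exon_model <- function(cds_length, n_exons, low_pext_fraction) {
  n_exons <- max(1L, min(n_exons, cds_length))
  # random exon boundaries tiling [1, cds_length]
  cuts <- sort(sample(seq_len(cds_length - 1), n_exons - 1))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, cds_length)
  low <- runif(n_exons) < low_pext_fraction
  low[1] <- FALSE  # guarantee >=1 brain-expressed exon at the CDS start
  # high-pext exons: one dominant tissue value > 0.3, others anywhere below it;
  # low-pext exons: all 13 tissues below 0.1 so brain_pext() rejects them.
  pext <- matrix(0, nrow = n_exons, ncol = 13)
  for (e in seq_len(n_exons)) {
    if (low[e]) {
      pext[e, ] <- runif(13, 0, 0.09)
    } else {
      vals <- runif(13, 0, 1)
      vals[which.max(vals)] <- runif(1, 0.3, 1)
      pext[e, ] <- vals
    }
  }
  colnames(pext) <- paste0("pext_", pext_tissues)
  dplyr::bind_cols(
    tibble(exon_index = seq_len(n_exons),
           cds_start = as.integer(starts),
           cds_end = as.integer(ends)),
    as_tibble(pext)
  )
}

#' Flatten a gene panel into a gene-model table
#'
#' Unnests the per-gene exon models into the long, file-friendly form used by
#' the classification functions: one row per exon with its CDS interval and
#' 13 brain-tissue pext values.
#'
#' @param genes A gene panel from [simulate_gene_panel()] (or a tibble with
#'   `gene_id`, `cds_length`, `exons`).
#' @return A tibble with columns `gene_id`, `cds_length`, `exon_index`,
#'   `cds_start`, `cds_end`, `pext_<tissue>` (13 columns).
#' @export
gene_models <- function(genes) {
  check_columns(genes, c("gene_id", "cds_length", "exons"), "gene panel")
  genes |>
    select("gene_id", "cds_length", "exons") |>
    tidyr::unnest("exons")
}
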