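#' Simulate phenotypes with known generative effects
#'
#' Generates the phenotype battery the association models consume, from a
#' shared linear predictor
#' `lp = beta_lof_high * LoF_high + beta_lof_low * LoF_low + beta_pgs * PGS +
#' beta_sex * sex` (sex coded 0 = male, 1 = female). Carrier indicators come
#' from the ground-truth S-LoF carriers, split into high/low strata by the
#' analytic odds ratio implied by each gene's generative carrier frequencies
#' (threshold 10, infinite counts as high).
#'
#' Trait families:
#' * continuous (SCQ t-score analog, factors F1-F6, fluid intelligence):
#'   `lp + N(0, noise_sd)`;
#' * developmental milestones (months, >= 0): affine transforms of the same
#'   standardized score;
#' * Townsend deprivation index: `-lp + N(0, noise_sd)`, oriented so larger =
#'   more deprived (so that after [reverse_townsend()] a fitted coefficient
#'   recovers the generative beta with its sign);
#' * ordinal bands (income, qualification; 5 bands): latent `lp + logistic`
#'   cut at `band_thresholds` -- logistic errors so a proportional-odds fit
#'   recovers the latent beta on its own scale;
#' * IQ score bins (10 bins, analyzed as continuous): latent `lp + N(0, 1)`
#'   cut at `iq_thresholds`;
#' * questionnaire-response indicators: Bernoulli with
#'   `logit(p) = logit(base rate) + log(participation_or_carrier) * carrier`.
#'
#' @param cohort A cohort table from [simulate_cohort()].
#' @param carrier_truth Ground-truth carriers from [simulate_variants()].
#' @param genes The gene panel (used to stratify genes by implied OR).
#' @param effects An [effect_spec()].
#' @param seed Integer seed.
#' @return A tibble keyed by `individual_id` with the carrier indicators
#'   (`lof_low`, `lof_high`), all traits and the four response indicators.
#' @export
simulate_phenotypes <- function(cohort, carrier_truth, genes, effects,
                                seed = 1L) {
  if (!inherits(effects, "effect_spec")) abort("`effects` must be an effect_spec()")
  check_columns(cohort, c("individual_id", "sex", "pgs"), "cohort")

  or_class <- gene_or_class(genes)
  ind <- carrier_indicators(cohort, carrier_truth, or_class)

  n <- nrow(cohort)
  with_seed(seed, {
    sex_code <- as.integer(cohort$sex == "female")
    lp <- effects$beta_lof_high * ind$lof_high +
      effects$beta_lof_low * ind$lof_low +
      effects$beta_pgs * cohort$pgs +
      effects$beta_sex * sex_code
    carrier <- as.integer(ind$lof_high | ind$lof_low)

    noise <- function() rnorm(n, sd = effects$noise_sd)
    cut_bands <- function(latent, thresholds) {
      as.integer(cut(latent, c(-Inf, thresholds, Inf)))
    }
    respond <- function(base_rate) {
      p <- plogis(qlogis(base_rate) +
                    log(effects$participation_or_carrier) * carrier)
      as.integer(runif(n) < p)
    }

    tibble(
      individual_id = cohort$individual_id,
      lof_low = ind$lof_low,
      lof_high = ind$lof_high,
      scq_t = lp + noise(),
      f1 = lp + noise(), f2 = lp + noise(), f3 = lp + noise(),
      f4 = lp + noise(), f5 = lp + noise(), f6 = lp + noise(),
      iq_bin = cut_bands(lp + rnorm(n), effects$iq_thresholds),
      age_first_words_months = pmax(0, round(18 + 6 * (lp + noise()))),
      age_walking_months = pmax(0, round(13 + 3 * (lp + noise()))),
      fluid_intelligence = lp + noise(),
      income_band = cut_bands(lp + rlogis(n), effects$band_thresholds),
      qualification_band = cut_bands(lp + rlogis(n), effects$band_thresholds),
      townsend = -lp + noise(),
      responded_income = respond(0.86),
      responded_qualification = respond(0.83),
      responded_fluid_intelligence = respond(0.60),
      responded_imaging = respond(0.11)
    )
  })
}

# Classify panel genes as high/low autism-OR strata from their generative
# carrier frequencies (analytic OR; infinite when the undiagnosed frequency
# is zero, which counts as high).
gene_or_class <- function(genes) {
  fd <- genes$carrier_freq_diagnosed
  fu <- genes$carrier_freq_undiagnosed
  analytic_or <- ifelse(fd == 0, NA_real_,
                        ifelse(fu == 0, Inf,
                               (fd * (1 - fu)) / (fu * (1 - fd))))
  tibble(gene_id = genes$gene_id,
         or_class = if_else(!is.na(analytic_or) & analytic_or > 10,
                            "high", "low"))
}

carrier_indicators <- function(cohort, carrier_truth, or_class) {
  lof_low <- integer(nrow(cohort))
  lof_high <- integer(nrow(cohort))
  if (!is.null(carrier_truth) && nrow(carrier_truth) > 0) {
    slof <- carrier_truth |>
      filter(.data$class == "S_LOF") |>
      inner_join(or_class, by = "gene_id")
    low_ids <- unique(slof$individual_id[slof$or_class == "low"])
    high_ids <- unique(slof$individual_id[slof$or_class == "high"])
    lof_low <- as.integer(cohort$individual_id %in% low_ids)
    lof_high <- as.integer(cohort$individual_id %in% high_ids)
  }
  list(lof_low = lof_low, lof_high = lof_high)
}
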