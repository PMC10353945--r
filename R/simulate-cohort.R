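#' Generate a synthetic cohort table
#'
#' Builds one row per individual: diagnosis status, family role, family id,
#' sex, age, cohort label, a standardized polygenic score (PGS) and four
#' ancestry principal components. A `family_fraction` of diagnosed
#' individuals are probands embedded in families; their mother and father are
#' always undiagnosed (families are ascertained through an undiagnosed-parent
#' design) and a sibling is added with probability `sibling_prob`, all drawn
#' from the undiagnosed budget. Remaining undiagnosed individuals are
#' unselected `population` members.
#'
#' Sex among diagnosed individuals is male with odds
#' `sex_ratio_diagnosed : 1`; siblings and population members are 1:1. The
#' PGS is standard normal with a `pgs_shift_diagnosed` mean shift in the
#' diagnosed group; PC1-PC4 are standard normal.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `individual_id`, `status`
#'   (`diagnosed`/`undiagnosed`), `role` (`proband`, `sibling`, `mother`,
#'   `father`, `population`), `family_id` (NA outside families), `sex`
#'   (`male`/`female`), `age` (years), `cohort` (`familial`/`population`),
#'   `pgs`, `pc1`-`pc4`.
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec()")
  with_seed(spec$seed, {
    n_d <- spec$n_diagnosed
    n_u <- spec$n_undiagnosed

    n_fam <- round(spec$family_fraction * n_d)
    sibs <- if (n_fam > 0) rbinom(n_fam, 1, spec$sibling_prob) else integer(0)
    fam_undiag <- 2L * n_fam + sum(sibs)
    while (fam_undiag > n_u && n_fam > 0) {
      # shrink the family block until its undiagnosed members fit the budget
      n_fam <- n_fam - 1L
      sibs <- sibs[seq_len(n_fam)]
      fam_undiag <- 2L * n_fam + sum(sibs)
    }

    p_male_diag <- spec$sex_ratio_diagnosed / (spec$sex_ratio_diagnosed + 1)

    diag <- tibble(
      status = "diagnosed",
      role = "proband",
      family_id = c(if (n_fam > 0) sprintf("F%05d", seq_len(n_fam)),
                    rep(NA_character_, n_d - n_fam)),
      sex = if_else(runif(n_d) < p_male_diag, "male", "female"),
      age = round(runif(n_d, 4, 18)),
      cohort = "familial"
    )

    fam_rows <- list()
    if (n_fam > 0) {
      fam_ids <- sprintf("F%05d", seq_len(n_fam))
      parents <- tibble(
        status = "undiagnosed",
        role = rep(c("mother", "father"), each = n_fam),
        family_id = rep(fam_ids, times = 2),
        sex = rep(c("female", "male"), each = n_fam),
        age = round(runif(2L * n_fam, 30, 60)),
        cohort = "familial"
      )
      fam_rows <- list(parents)
      if (sum(sibs) > 0) {
        sib_ids <- fam_ids[sibs == 1]
        fam_rows <- c(fam_rows, list(tibble(
          status = "undiagnosed",
          role = "sibling",
          family_id = sib_ids,
          sex = if_else(runif(length(sib_ids)) < 0.5, "male", "female"),
          age = round(runif(length(sib_ids), 4, 18)),
          cohort = "familial"
        )))
      }
    }

    n_pop <- n_u - fam_undiag
    pop <- tibble(
      status = "undiagnosed",
      role = "population",
      family_id = NA_character_,
      sex = if_else(runif(n_pop) < 0.5, "male", "female"),
      age = round(runif(n_pop, 40, 70)),
      cohort = "population"
    )

    cohort <- bind_rows(c(list(diag), fam_rows, list(pop)))
    n_total <- nrow(cohort)
    cohort |>
      mutate(
        individual_id = sprintf("I%06d", row_number()),
        pgs = rnorm(n_total) +
          if_else(.data$status == "diagnosed", spec$pgs_shift_diagnosed, 0),
        pc1 = rnorm(n_total), pc2 = rnorm(n_total),
        pc3 = rnorm(n_total), pc4 = rnorm(n_total)
      ) |>
      select("individual_id", "status", "role", "family_id", "sex", "age",
             "cohort", "pgs", "pc1", "pc2", "pc3", "pc4")
  })
}
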