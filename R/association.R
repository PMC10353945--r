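#' Split carrier status by gene-level autism OR
#'
#' Produces the two binary carrier indicators used throughout the regression
#' models: carrying an S-LoF in a gene with autism OR at most `threshold`
#' (`lof_low`) and in a gene with OR above it (`lof_high`; infinite ORs count
#' as high). An individual carrying variants on both sides is 1 in both.
#' Genes with an undefined OR (no diagnosed carrier) cannot be stratified and
#' are excluded.
#'
#' @param carriers Long carrier calls (`gene_id`, `individual_id`).
#' @param gene_or Gene OR table (`gene_id`, `autism_or`).
#' @param cohort Cohort table (defines the individual set).
#' @param threshold OR threshold (default 10; a gene at exactly 10 falls in
#'   the low stratum).
#' @return Tibble: `individual_id`, `lof_low`, `lof_high` (0/1), one row per
#'   cohort individual.
#' @export
split_lof_by_or <- function(carriers, gene_or, cohort, threshold = 10) {
  check_columns(gene_or, c("gene_id", "autism_or"), "gene OR table")
  strat <- gene_or |>
    filter(!is.na(.data$autism_or)) |>
    mutate(stratum = if_else(.data$autism_or > threshold, "high", "low")) |>
    select("gene_id", "stratum")
  tagged <- carriers |> inner_join(strat, by = "gene_id")
  low_ids <- unique(tagged$individual_id[tagged$stratum == "low"])
  high_ids <- unique(tagged$individual_id[tagged$stratum == "high"])
  tibble(
    individual_id = cohort$individual_id,
    lof_low = as.integer(cohort$individual_id %in% low_ids),
    lof_high = as.integer(cohort$individual_id %in% high_ids)
  )
}

#' Reverse the Townsend deprivation index
#'
#' The raw index is oriented so that larger values indicate more material
#' deprivation; modelling uses the reversed index so that deprivation is
#' indicated by a negative sign. Fitted coefficients flip sign exactly.
#'
#' @param x Townsend index values.
#' @return `-x`.
#' @export
reverse_townsend <- function(x) -x

# ---- model fitting ------------------------------------------------------

# z-score continuous model-frame columns; binary 0/1 indicators and factors
# stay untouched so carrier effects read per carrier.
standardize_columns <- function(data, vars) {
  for (v in vars) {
    col <- data[[v]]
    if (is.numeric(col) && length(unique(col[!is.na(col)])) > 2) {
      data[[v]] <- as.numeric(scale(col))
    }
  }
  data
}

# Recode a character/factor sex column as 0 = male, 1 = female.
code_sex <- function(data) {
  if ("sex" %in% names(data) && !is.numeric(data$sex)) {
    data$sex <- as.integer(data$sex == "female")
  }
  data
}

new_lof_fit <- function(fit, family, outcome, n, separation = FALSE) {
  structure(list(fit = fit, family = family, outcome = outcome, n = n,
                 separation = separation),
            class = "lof_fit")
}

#' Logistic model of diagnosis on rare-variant burden and polygenic score
#'
#' Fits a maximum-likelihood logistic regression of diagnosis status on the
#' carrier indicators, polygenic score, sex, the LoF x PGS interactions and
#' ancestry principal components. LoF coefficients exponentiate to odds
#' ratios. Complete or quasi-complete separation is detected and flagged
#' (see [glance()]), not silently corrected.
#'
#' @param data Cohort joined with carrier indicators; needs a `status` column
#'   (or a 0/1 `diagnosed` column) plus the model terms.
#' @param formula Model formula; the default mirrors the standard
#'   burden-plus-PGS specification.
#' @param standardize Z-score continuous predictors (default `TRUE`).
#' @return A `lof_fit` object; use [tidy()]/[glance()].
#' @export
fit_diagnosis_model <- function(data,
                                formula = diagnosed ~ lof_low + lof_high +
                                  pgs + sex + lof_low:pgs + lof_high:pgs +
                                  pc1 + pc2 + pc3 + pc4,
                                standardize = TRUE) {
  data <- code_sex(data)
  if (!"diagnosed" %in% names(data)) {
    check_columns(data, "status", "model data")
    data$diagnosed <- as.integer(data$status == "diagnosed")
  }
  vars <- setdiff(all.vars(formula), "diagnosed")
  check_columns(data, vars, "model data")
  if (standardize) data <- standardize_columns(data, setdiff(vars, "sex"))
  fit <- glm(formula, data = data, family = binomial())
  probs <- fit$fitted.values
  separation <- any(probs > 1 - 1e-8 | probs < 1e-8) ||
    any(abs(coef(fit)) > 15, na.rm = TRUE)
  if (separation) warn("possible separation in logistic fit; estimates flagged")
  new_lof_fit(fit, "binary_logistic", "diagnosed", nrow(fit$model),
              separation)
}

#' Linear model of a continuous trait
#'
#' Ordinary least squares with continuous predictors and the outcome z-scored
#' (standardized beta coefficients); binary carrier indicators are left
#' unstandardized so their coefficients read per carrier.
#'
#' @param data Phenotype table joined with covariates.
#' @param formula Model formula, e.g.
#'   `fluid_intelligence ~ lof_low + lof_high + pgs + sex + age + pc1 + pc2 +
#'   pc3 + pc4`.
#' @param standardize Z-score the outcome and continuous predictors.
#' @return A `lof_fit` object.
#' @export
fit_trait_linear <- function(data, formula, standardize = TRUE) {
  data <- code_sex(data)
  vars <- all.vars(formula)
  check_columns(data, vars, "model data")
  if (standardize) {
    outcome <- vars[1]
    data[[outcome]] <- as.numeric(scale(data[[outcome]]))
    data <- standardize_columns(data, setdiff(vars[-1], "sex"))
  }
  fit <- lm(formula, data = data)
  new_lof_fit(fit, "linear", all.vars(formula)[1], nrow(fit$model))
}

#' Proportional-odds model of an ordinal outcome
#'
#' Ordinal logistic (proportional odds) regression for banded outcomes such
#' as income or qualification level. Coefficients exponentiate to
#' cumulative odds ratios: the latent-scale effect of each term.
#'
#' @param data Phenotype table joined with covariates.
#' @param formula Model formula with an ordered (or integer-banded) outcome.
#' @param standardize Z-score continuous predictors.
#' @return A `lof_fit` object.
#' @export
fit_ordinal_model <- function(data, formula, standardize = TRUE) {
  data <- code_sex(data)
  vars <- all.vars(formula)
  check_columns(data, vars, "model data")
  outcome <- vars[1]
  y <- data[[outcome]]
  if (!is.ordered(y)) y <- factor(y, ordered = TRUE)
  if (nlevels(y) < 3) abort("ordinal outcome needs at least 3 levels")
  if (any(table(y) == 0)) abort("empty outcome level; collapse bands first")
  data[[outcome]] <- y
  if (standardize) data <- standardize_columns(data, setdiff(vars[-1], "sex"))
  fit <- MASS::polr(formula, data = data, Hess = TRUE)
  new_lof_fit(fit, "ordinal_logistic", outcome, nrow(fit$model))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted burden model
#'
#' One row per model term with the estimate on its reported scale
#' (standardized beta for linear fits, odds ratio for logistic and ordinal
#' fits), Wald 95% confidence bounds and two-sided p value. Ordinal
#' intercept cutpoints are omitted.
#'
#' @param x A `lof_fit`.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `estimate_type`, `conf.low`,
#'   `conf.high`, `p.value`.
#' @export
tidy.lof_fit <- function(x, conf.level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  if (x$family == "ordinal_logistic") {
    est <- coef(x$fit)  # excludes the zeta cutpoints
    se <- sqrt(diag(vcov(x$fit)))[seq_along(est)]
  } else {
    sm <- summary(x$fit)$coefficients
    est <- sm[, 1]
    se <- sm[, 2]
  }
  terms <- names(est)
  est <- unname(est)
  se <- unname(se)
  stat <- est / se
  p <- 2 * pnorm(-abs(stat))
  lo <- est - z * se
  hi <- est + z * se
  if (x$family %in% c("binary_logistic", "ordinal_logistic")) {
    out <- tibble(term = terms, estimate = exp(est),
                  estimate_type = "OR",
                  conf.low = exp(lo), conf.high = exp(hi), p.value = p)
    if (x$family == "binary_logistic") {
      out <- out |> filter(.data$term != "(Intercept)")
    }
    out
  } else {
    tibble(term = terms, estimate = est, estimate_type = "beta",
           conf.low = lo, conf.high = hi, p.value = p)
  }
}

#' Model-level summary of a fitted burden model
#'
#' @param x A `lof_fit`.
#' @param ... Unused.
#' @return One-row tibble: `outcome`, `family`, `n`, `separation`.
#' @export
glance.lof_fit <- function(x, ...) {
  tibble(outcome = x$outcome, family = x$family, n = x$n,
         separation = isTRUE(x$separation))
}

#' @export
print.lof_fit <- function(x, ...) {
  cat(sprintf("<lof_fit> %s model of %s (n = %d)\n",
              x$family, x$outcome, x$n))
  print(tidy(x))
  invisible(x)
}

#' Benjamini-Hochberg adjustment within result groups
#'
#' Applies the BH step-up FDR adjustment to a column of p values within
#' groups of rows -- conventionally one group per covariate and outcome
#' family (diagnosis/trait models, developmental milestones, socioeconomic
#' features).
#'
#' @param results A results tibble (e.g. row-bound [tidy()] outputs).
#' @param ... Grouping columns (unquoted).
#' @param p P-value column (unquoted; default `p.value`).
#' @return `results` with `p_adjusted` appended; within each group the
#'   adjusted values are a monotone step-up transform of the raw ones.
#' @export
fdr_adjust <- function(results, ..., p = p.value) {
  results |>
    group_by(...) |>
    mutate(p_adjusted = p.adjust({{ p }}, method = "BH")) |>
    ungroup()
}

#' Participation odds ratios for questionnaire response
#'
#' For each response indicator: the 2x2 sample odds ratio of responding when
#' carrying a qualifying variant, with a Woolf (log-OR) 95% CI and two-sided
#' z-test p value, BH-adjusted across the questionnaires. When any cell is
#' zero the point OR is reported from the raw table (0 when no carrier
#' responded) and CI/p use the Haldane-Anscombe 0.5 correction.
#'
#' @param data Table with one row per individual.
#' @param carrier Unquoted 0/1 carrier column.
#' @param responses Character vector of 0/1 response-indicator columns.
#' @param haldane Apply the 0.5 correction to zero-cell tables (default
#'   `TRUE`; otherwise zero-cell CIs are `NA`).
#' @return Tibble: `questionnaire`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `p_adjusted`, `n`.
#' @export
participation_or <- function(data, carrier, responses, haldane = TRUE) {
  carrier_vec <- dplyr::pull(data, {{ carrier }})
  rows <- purrr::map_dfr(responses, function(col) {
    resp <- data[[col]]
    ok <- !is.na(resp) & !is.na(carrier_vec)
    a <- as.numeric(sum(carrier_vec[ok] == 1 & resp[ok] == 1))
    b <- as.numeric(sum(carrier_vec[ok] == 0 & resp[ok] == 1))
    cc <- as.numeric(sum(carrier_vec[ok] == 1 & resp[ok] == 0))
    d <- as.numeric(sum(carrier_vec[ok] == 0 & resp[ok] == 0))
    or <- (a * d) / (b * cc)
    zero <- any(c(a, b, cc, d) == 0)
    if (zero && !haldane) {
      return(tibble(questionnaire = col, odds_ratio = or,
                    ci_low = NA_real_, ci_high = NA_real_,
                    p_value = NA_real_, n = sum(ok)))
    }
    h <- if (zero) 0.5 else 0
    log_or <- log(((a + h) * (d + h)) / ((b + h) * (cc + h)))
    se <- sqrt(1 / (a + h) + 1 / (b + h) + 1 / (cc + h) + 1 / (d + h))
    tibble(questionnaire = col,
           odds_ratio = if (zero) or else exp(log_or),
           ci_low = exp(log_or - 1.96 * se),
           ci_high = exp(log_or + 1.96 * se),
           p_value = 2 * pnorm(-abs(log_or / se)),
           n = sum(ok))
  })
  rows |> mutate(p_adjusted = p.adjust(.data$p_value, method = "BH"))
}
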