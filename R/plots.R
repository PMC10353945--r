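#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_errorbar
#'   geom_hline geom_vline scale_y_log10 scale_colour_manual labs
#'   position_dodge theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Diagnosed carrier count versus gene autism OR
#'
#' Scatter of the number of diagnosed S-LoF carriers against the (capped)
#' gene autism OR, with genes whose bootstrap empirical P is significant
#' highlighted.
#'
#' @param object A `lof_gene_or` table from [gene_autism_or()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lof_gene_or <- function(object, ...) {
  df <- object |> filter(.data$n_carriers_diagnosed > 0)
  ggplot(df, aes(x = .data$n_carriers_diagnosed, y = .data$capped_or,
                 colour = .data$significant)) +
    geom_point(alpha = 0.8) +
    scale_y_log10() +
    scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick"),
                        na.value = "grey80") +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    labs(x = "Diagnosed S-LoF carriers", y = "Autism OR (capped)",
         colour = "Significant") +
    theme_minimal()
}

#' Forest plot of a fitted burden model
#'
#' Term-level estimates with 95% confidence intervals; the reference line is
#' 1 for odds ratios and 0 for betas.
#'
#' @param object A `lof_fit`.
#' @param ... Passed to [tidy()].
#' @return A ggplot.
#' @export
autoplot.lof_fit <- function(object, ...) {
  df <- tidy(object, ...)
  ref <- if (df$estimate_type[1] == "OR") 1 else 0
  ggplot(df, aes(x = .data$estimate, y = .data$term)) +
    geom_point() +
    geom_errorbar(aes(xmin = .data$conf.low, xmax = .data$conf.high),
                  width = 0.2) +
    geom_vline(xintercept = ref, linetype = "dashed", colour = "grey40") +
    labs(x = df$estimate_type[1], y = NULL) +
    theme_minimal()
}

#' Carrier proportions by cohort stratum
#'
#' Bar chart of per-stratum carrier proportions with normal-approximation
#' 95% error bars.
#'
#' @param proportions Output of [carrier_proportions()].
#' @param by Stratum column name.
#' @return A ggplot.
#' @export
plot_carrier_proportions <- function(proportions, by = "role") {
  ggplot(proportions,
         aes(x = .data[[by]], y = .data$p)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                  width = 0.2) +
    labs(x = NULL, y = "Carrier proportion") +
    theme_minimal()
}
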