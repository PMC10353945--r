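#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows bind_cols n distinct across
#'   all_of count
#'   if_else row_number pull rename desc first
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif rbinom rpois rlogis rbeta qlogis plogis qnorm
#'   pnorm lm glm binomial coef vcov fisher.test wilcox.test cor.test p.adjust
#'   ks.test sd median quantile as.formula setNames complete.cases
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# funnel through this so that (spec, seed) pins outputs exactly.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x != round(x)) {
    abort(sprintf("`%s` must be a single positive integer, got %s",
                  name, deparse(substitute(x))))
  }
  as.integer(x)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1]", name))
  }
  as.numeric(x)
}

check_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

# Half-away-from-zero rounding; base round() is banker's and disagrees with
# how proportions are conventionally reported at two decimals.
round_half_up <- function(x, digits = 0) {
  mult <- 10^digits
  sign(x) * floor(abs(x) * mult + 0.5) / mult
}
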