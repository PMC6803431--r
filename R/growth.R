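#' Specific growth rate
#'
#' `SGR = 100 * (ln(final) - ln(initial)) / days`, in percent per day.
#'
#' @param initial_g,final_g Weights in grams (> 0).
#' @param days Trial length in days (> 0).
#' @return Percent per day; vectorized.
#' @examples
#' sgr(25, 399.31, 120)  # ~2.31 %/day
#' @export
sgr <- function(initial_g, final_g, days) {
  if (any(initial_g <= 0) || any(final_g <= 0)) {
    stop("weights must be positive", call. = FALSE)
  }
  if (any(days <= 0)) stop("days must be positive", call. = FALSE)
  100 * (log(final_g) - log(initial_g)) / days
}

#' Percentage weight gain
#'
#' `100 * (final - initial) / initial`, in percent of the initial weight.
#' Provided alongside [sgr()] because "growth rate" percentages in trial
#' reports are usually this quantity, not the SGR.
#'
#' @param initial_g,final_g Weights in grams (> 0).
#' @return Percent; vectorized.
#' @examples
#' weight_gain_rate(25.84, 399.31)  # ~1445 %
#' @export
weight_gain_rate <- function(initial_g, final_g) {
  if (any(initial_g <= 0) || any(final_g <= 0)) {
    stop("weights must be positive", call. = FALSE)
  }
  100 * (final_g - initial_g) / initial_g
}

#' Per-fish growth metrics
#'
#' @param records Data frame with columns `individual`, `group`,
#'   `initial_g`, `final_g`, `days`.
#' @return The input with `sgr_pct_per_day` and `weight_gain_pct` appended.
#' @export
growth_metrics <- function(records) {
  needed <- c("individual", "group", "initial_g", "final_g", "days")
  if (!all(needed %in% names(records))) {
    stop("growth table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  records$sgr_pct_per_day <- sgr(records$initial_g, records$final_g,
                                 records$days)
  records$weight_gain_pct <- weight_gain_rate(records$initial_g,
                                              records$final_g)
  records
}

#' Compare growth between cohorts
#'
#' Tests final weights and SGR across groups: Welch t for two groups,
#' one-way ANOVA with Tukey HSD (and the variance-homogeneity gate) for
#' three or more.
#'
#' @param records Growth table as in [growth_metrics()].
#' @param alpha Significance level.
#' @return List with per-metric results (`final_weight`, `sgr`), each either
#'   a two-group test (`p`, `significant`) or an [anova_tukey()] result,
#'   plus a `summary` data frame of group means.
#' @export
compare_growth <- function(records, alpha = 0.05) {
  records <- growth_metrics(records)
  groups <- droplevels(as.factor(records$group))
  if (nlevels(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2L)) {
    stop("every group needs at least two fish", call. = FALSE)
  }
  test_metric <- function(values) {
    if (nlevels(groups) == 2L) {
      sp <- split(values, groups)
      p <- two_sample_p(sp[[1]], sp[[2]])
      list(p = p, significant = p < alpha)
    } else {
      anova_tukey(values, groups, alpha = alpha)
    }
  }
  summary <- aggregate(cbind(initial_g, final_g, sgr_pct_per_day,
                             weight_gain_pct) ~ group,
                       data = records, FUN = mean)
  list(final_weight = test_metric(records$final_g),
       sgr = test_metric(records$sgr_pct_per_day),
       summary = summary)
}
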