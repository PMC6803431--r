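#' Maternal allelic fraction
#'
#' @param mat_count,pat_count Read counts (>= 0, total > 0); vectorized.
#' @return `mat_count / (mat_count + pat_count)`.
#' @export
maternal_fraction <- function(mat_count, pat_count) {
  if (any(mat_count < 0) || any(pat_count < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  total <- mat_count + pat_count
  if (any(total <= 0)) stop("total read count must be positive", call. = FALSE)
  mat_count / total
}

#' Exact binomial test of allelic imbalance
#'
#' Per-individual two-sided exact binomial test of the maternal read count
#' against a balanced (or other) null proportion.  The two-sided p-value
#' sums the probabilities of all outcomes no more likely than the observed
#' one (the standard exact two-sided rule).  Direction is assigned only for
#' significant individuals; otherwise the call is `balanced`.
#'
#' @param mat_count,pat_count Read counts; vectorized over individuals.
#' @param null_p Null maternal proportion (default 0.5).
#' @param alpha Significance level for the direction call.
#' @param adjust P-value adjustment across individuals: `"none"` (default)
#'   or `"BH"` (Benjamini-Hochberg).
#' @return Data frame with `mat_count`, `pat_count`, `fraction`, `p`
#'   (adjusted if requested) and `direction` (`maternal_biased`,
#'   `paternal_biased`, `balanced`).
#' @examples
#' binomial_imbalance_test(9, 1)$p  # 0.021484375
#' @export
binomial_imbalance_test <- function(mat_count, pat_count, null_p = 0.5,
                                    alpha = 0.05,
                                    adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  fraction <- maternal_fraction(mat_count, pat_count)
  p <- vapply(seq_along(mat_count), function(i) {
    binom.test(mat_count[i], mat_count[i] + pat_count[i],
               p = null_p)$p.value
  }, numeric(1))
  if (adjust == "BH") p <- p.adjust(p, method = "BH")
  direction <- ifelse(p >= alpha, "balanced",
                      ifelse(fraction > null_p, "maternal_biased",
                             "paternal_biased"))
  data.frame(mat_count = mat_count, pat_count = pat_count,
             fraction = fraction, p = p, direction = direction,
             stringsAsFactors = FALSE)
}

#' Per-individual allelic-imbalance calls for a count table
#'
#' @param counts Data frame with columns `individual`, `sex`, `condition`,
#'   `mat_count`, `pat_count` (as written by [simulate_allele_counts()]).
#' @inheritParams binomial_imbalance_test
#' @return The input columns with `fraction`, `p` and `direction` appended.
#' @export
ase_calls <- function(counts, null_p = 0.5, alpha = 0.05,
                      adjust = c("none", "BH")) {
  needed <- c("individual", "mat_count", "pat_count")
  if (!all(needed %in% names(counts))) {
    stop("counts table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  res <- binomial_imbalance_test(counts$mat_count, counts$pat_count,
                                 null_p = null_p, alpha = alpha,
                                 adjust = adjust)
  cbind(counts, res[, c("fraction", "p", "direction")])
}

#' Cohort-level allelic-bias test
#'
#' One-sample t test of the per-individual maternal percentages against the
#' balanced expectation of 50% (equivalent to a paired t of maternal versus
#' paternal percentages, since the two sum to 100).  A zero-variance cohort
#' cannot be tested; it is reported with `degenerate = TRUE` and, when its
#' mean equals the null, as `balanced`.
#'
#' @param fractions Per-individual maternal fractions in `[0, 1]` (n >= 2).
#' @param label Cohort label carried into the result.
#' @param null_pct Null maternal percentage (default 50).
#' @param alpha Significance level.
#' @return An object of class `cohort_bias`: list with `label`, `n`,
#'   `mean_pct`, `sd_pct`, `p`, `direction`, `degenerate`.
#' @export
cohort_bias_test <- function(fractions, label = NA_character_,
                             null_pct = 50, alpha = 0.05) {
  if (length(fractions) < 2L) {
    stop("cohort bias test needs at least two individuals", call. = FALSE)
  }
  if (any(fractions < 0 | fractions > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  pct <- 100 * fractions
  m <- mean(pct)
  s <- sd(pct)
  if (s == 0) {
    direction <- if (m == null_pct) "balanced" else {
      if (m > null_pct) "maternal_biased" else "paternal_biased"
    }
    res <- list(label = label, n = length(pct), mean_pct = m, sd_pct = s,
                p = NA_real_, direction = direction, degenerate = TRUE)
  } else {
    p <- t.test(pct, mu = null_pct)$p.value
    direction <- if (p >= alpha) "balanced" else {
      if (m > null_pct) "maternal_biased" else "paternal_biased"
    }
    res <- list(label = label, n = length(pct), mean_pct = m, sd_pct = s,
                p = p, direction = direction, degenerate = FALSE)
  }
  structure(res, class = "cohort_bias")
}

#' @export
print.cohort_bias <- function(x, ...) {
  cat(sprintf("<cohort_bias> %s: maternal %.2f%% +/- %.2f (n = %d), %s%s\n",
              ifelse(is.na(x$label), "cohort", x$label),
              x$mean_pct, x$sd_pct, x$n, x$direction,
              if (x$degenerate) " [degenerate]" else
                sprintf(" (p = %.3g)", x$p)))
  invisible(x)
}

#' Compare allelic bias between two conditions
#'
#' Welch two-sample t test on maternal percentages between two cohorts
#' (e.g. fed versus fasted), answering whether the allelic imbalance shifts
#' with condition.
#'
#' @param fractions_a,fractions_b Maternal fractions per individual
#'   (each n >= 2).
#' @param alpha Significance level.
#' @param labels Length-2 character vector naming the conditions.
#' @return List with `labels`, `mean_pct` (length 2), `p`, `effect`
#'   (logical) and `decision` ("condition effect" / "no condition effect").
#' @export
condition_comparison <- function(fractions_a, fractions_b, alpha = 0.05,
                                 labels = c("A", "B")) {
  if (length(fractions_a) < 2L || length(fractions_b) < 2L) {
    stop("both condition groups need at least two individuals",
         call. = FALSE)
  }
  pa <- 100 * fractions_a
  pb <- 100 * fractions_b
  p <- t.test(pa, pb)$p.value
  effect <- p < alpha
  list(labels = labels, mean_pct = c(mean(pa), mean(pb)), p = p,
       effect = effect,
       decision = if (effect) "condition effect" else "no condition effect")
}
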