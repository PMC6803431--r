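#' Parental expression divergence (A)
#'
#' `A = log2(mean_NN / mean_BB)`: the log2 ratio of the maternal-line to
#' paternal-line cohort expression means.
#'
#' @param mean_nn,mean_bb Positive cohort means (e.g. mean RQ).
#' @return A, in log2 units.
#' @export
parental_divergence <- function(mean_nn, mean_bb) {
  if (any(mean_nn <= 0) || any(mean_bb <= 0)) {
    stop("expression means must be positive", call. = FALSE)
  }
  log2(mean_nn / mean_bb)
}

#' Cis effect (B) from hybrid allelic expression
#'
#' `B = log2(maternal allele / paternal allele)` within the hybrid.  Since
#' only the ratio matters, the inputs may be counts, percentages or
#' fractions.
#'
#' @param maternal,paternal Positive allelic quantities.
#' @return B, in log2 units.
#' @examples
#' cis_effect(87.10, 12.90)  # ~2.76
#' @export
cis_effect <- function(maternal, paternal) {
  if (any(maternal <= 0) || any(paternal <= 0)) {
    stop("allelic quantities must be positive", call. = FALSE)
  }
  log2(maternal / paternal)
}

#' Classify a cis/trans decomposition
#'
#' Given the parental divergence `A` and the cis component `B`, the trans
#' component is `A - B` exactly.  Sign-rule categories:
#'
#' * `enhancing` — B and A-B share a sign (cis and trans act in the same
#'   direction);
#' * `compensating` — B and A-B have opposite signs;
#' * `cis_only`, `trans_only`, `conserved` — extended categories for the
#'   degenerate boundaries where one or both components fall inside the
#'   dead-zone `epsilon` (the two sign rules alone are undefined at B = 0 or
#'   A - B = 0).
#'
#' @param A,B Finite log2 divergences.
#' @param epsilon Dead-zone half-width in log2 units (>= 0; default 0.1).
#' @return An object of class `cistrans_result`: list with `A`, `B`,
#'   `trans` (= A - B), `epsilon`, `category` and `extended` (TRUE when the
#'   category is one of the dead-zone extensions).
#' @examples
#' classify_cis_trans(0.5, 1.0)$category  # "compensating"
#' @export
classify_cis_trans <- function(A, B, epsilon = 0.1) {
  if (!is.finite(A) || !is.finite(B)) {
    stop("A and B must be finite", call. = FALSE)
  }
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  trans <- A - B
  small_b <- abs(B) <= epsilon
  small_t <- abs(trans) <= epsilon
  category <- if (small_b && small_t) {
    "conserved"
  } else if (small_t) {
    "cis_only"
  } else if (small_b) {
    "trans_only"
  } else if (sign(B) == sign(trans)) {
    "enhancing"
  } else {
    "compensating"
  }
  structure(
    list(A = A, B = B, trans = trans, epsilon = epsilon,
         category = category,
         extended = category %in% c("conserved", "cis_only", "trans_only")),
    class = "cistrans_result"
  )
}

#' @export
print.cistrans_result <- function(x, ...) {
  cat(sprintf("<cistrans_result> %s%s: A = %.4g, B = %.4g, A-B = %.4g (eps %.3g)\n",
              x$category, if (x$extended) " [extended]" else "",
              x$A, x$B, x$trans, x$epsilon))
  invisible(x)
}

#' Cis/trans decomposition from expression summaries and cohort ASE
#'
#' Chains [parental_divergence()] on the parental cohort RQ means,
#' [cis_effect()] on the hybrid's cohort-mean maternal percentage, and
#' [classify_cis_trans()].  When a `sex` column is present in the summary,
#' the decomposition is restricted to the requested sex.
#'
#' @param expr_summary A [group_expression_summary()] data frame containing
#'   NN and BB rows.
#' @param mean_maternal_pct Cohort-mean maternal allelic percentage from the
#'   hybrid (e.g. `cohort_bias_test(...)$mean_pct`), in (0, 100).
#' @param sex Optional sex to filter `expr_summary` by.
#' @param epsilon Dead-zone for [classify_cis_trans()].
#' @return A `cistrans_result` (with the `sex` attached when given).
#' @export
decompose_cis_trans <- function(expr_summary, mean_maternal_pct, sex = NULL,
                                epsilon = 0.1) {
  if (!is.null(sex)) {
    if (!"sex" %in% names(expr_summary)) {
      stop("expr_summary has no sex column to filter by", call. = FALSE)
    }
    expr_summary <- expr_summary[expr_summary$sex == sex, , drop = FALSE]
  }
  mean_for <- function(grp) {
    v <- expr_summary$mean_rq[expr_summary$group == grp]
    if (length(v) != 1L) {
      stop(sprintf("expression summary must contain exactly one %s row%s",
                   grp, if (is.null(sex)) "" else paste0(" for sex ", sex)),
           call. = FALSE)
    }
    v
  }
  if (mean_maternal_pct <= 0 || mean_maternal_pct >= 100) {
    stop("mean_maternal_pct must lie in (0, 100)", call. = FALSE)
  }
  A <- parental_divergence(mean_for("NN"), mean_for("BB"))
  B <- cis_effect(mean_maternal_pct, 100 - mean_maternal_pct)
  res <- classify_cis_trans(A, B, epsilon)
  res$sex <- sex
  res
}
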