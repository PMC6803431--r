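#' Relative quantification by the delta-delta-Ct method
#'
#' Computes, per biological sample, dCt = mean Ct(target) - mean Ct(reference)
#' over technical replicates, then ddCt = dCt(sample) - mean dCt of the
#' calibrator group, and RQ = 2^-ddCt.  With a single calibrator sample its
#' RQ is exactly 1; with a calibrator group, the group's geometric-mean RQ
#' is 1.  No amplification-efficiency correction is applied (100% efficiency
#' assumed).
#'
#' @param ct Data frame with columns `sample`, `group`, `gene`, `ct` (and
#'   optionally `sex`, carried through).
#' @param target,reference Gene labels in `ct$gene`.
#' @param calibrator_group Group whose mean dCt anchors RQ = 1; by default
#'   the lowest-expressing parental line ("BB").
#' @return Data frame with one row per sample: `sample`, `group` (and `sex`
#'   if present), `dct`, `ddct`, `rq`.
#' @examples
#' ct <- data.frame(sample = c("s1", "s1", "s2", "s2"),
#'                  group = c("NB", "NB", "BB", "BB"),
#'                  gene = c("GH", "actb", "GH", "actb"),
#'                  ct = c(20, 15, 22, 15))
#' delta_delta_ct(ct, calibrator_group = "BB")$rq  # 4, 1
#' @export
delta_delta_ct <- function(ct, target = "GH", reference = "actb",
                           calibrator_group = "BB") {
  needed <- c("sample", "group", "gene", "ct")
  if (!all(needed %in% names(ct))) {
    stop("ct table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(ct$ct <= 0 | ct$ct >= 45)) {
    stop("Ct values must lie in (0, 45) cycles", call. = FALSE)
  }
  mean_ct <- aggregate(ct ~ sample + group + gene, data = ct, FUN = mean)
  samples <- unique(mean_ct[, c("sample", "group")])
  dct <- vapply(seq_len(nrow(samples)), function(i) {
    s <- samples$sample[i]
    tgt <- mean_ct$ct[mean_ct$sample == s & mean_ct$gene == target]
    ref <- mean_ct$ct[mean_ct$sample == s & mean_ct$gene == reference]
    if (length(tgt) != 1L || length(ref) != 1L) {
      stop(sprintf("sample '%s' must have exactly one %s and one %s mean Ct",
                   s, target, reference), call. = FALSE)
    }
    tgt - ref
  }, numeric(1))
  cal <- dct[samples$group == calibrator_group]
  if (!length(cal)) {
    stop(sprintf("no samples in calibrator group '%s'", calibrator_group),
         call. = FALSE)
  }
  ddct <- dct - mean(cal)
  out <- data.frame(sample = samples$sample, group = samples$group,
                    dct = dct, ddct = ddct, rq = 2^(-ddct),
                    stringsAsFactors = FALSE)
  if ("sex" %in% names(ct)) {
    sex_map <- unique(ct[, c("sample", "sex")])
    out$sex <- sex_map$sex[match(out$sample, sex_map$sample)]
    out <- out[, c("sample", "group", "sex", "dct", "ddct", "rq")]
  }
  out
}

#' Summarize relative expression by group
#'
#' @param rq A [delta_delta_ct()] result.
#' @return Data frame with `group` (and `sex` if present), `n`, `mean_rq`,
#'   `sd_rq`, `sem_rq`.
#' @export
group_expression_summary <- function(rq) {
  by_cols <- intersect(c("group", "sex"), names(rq))
  agg <- aggregate(rq$rq, by = rq[by_cols], FUN = function(x) {
    c(n = length(x), mean = mean(x), sd = sd(x))
  })
  out <- data.frame(agg[by_cols],
                    n = agg$x[, "n"],
                    mean_rq = agg$x[, "mean"],
                    sd_rq = agg$x[, "sd"],
                    stringsAsFactors = FALSE)
  out$sem_rq <- out$sd_rq / sqrt(out$n)
  out
}

#' Midparent value
#'
#' The additive expectation for the hybrid: the arithmetic mean of the two
#' parental cohort means.
#'
#' @param mean_nn,mean_bb Parental means (> 0).
#' @return `(mean_nn + mean_bb) / 2`.
#' @export
midparent_value <- function(mean_nn, mean_bb) {
  if (mean_nn <= 0 || mean_bb <= 0) {
    stop("parental means must be positive", call. = FALSE)
  }
  (mean_nn + mean_bb) / 2
}

#' Variance-homogeneity gate with log10 fallback
#'
#' Assesses homogeneity of variances across groups with the median-centred
#' Levene test; when rejected at `alpha`, returns log10-transformed values
#' (all values must then be positive) and sets the transform flag, otherwise
#' returns the data unchanged.  This mirrors the common practice of
#' log-transforming expression values before ANOVA when variances are
#' heteroscedastic.
#'
#' @param values Numeric response.
#' @param groups Grouping factor (>= 2 groups, each with >= 2 values).
#' @param alpha Significance level for the Levene test.
#' @return List with `values`, `groups`, `log10_applied`, `levene_p`.
#' @export
check_homogeneity_and_transform <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  if (any(table(droplevels(groups)) < 2L)) {
    stop("every group needs at least two values", call. = FALSE)
  }
  lev <- car::leveneTest(values, droplevels(groups))
  p <- lev[["Pr(>F)"]][1]
  applied <- is.finite(p) && p < alpha
  if (applied) {
    if (any(values <= 0)) {
      stop("log10 transform requested for nonpositive values", call. = FALSE)
    }
    values <- log10(values)
  }
  list(values = values, groups = groups, log10_applied = applied,
       levene_p = p)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Standard one-way ANOVA omnibus F test followed by Tukey's honest
#' significant difference on all group pairs.  When `homogeneity_gate` is
#' set, values are first passed through [check_homogeneity_and_transform()].
#'
#' @param values Numeric response.
#' @param groups Grouping factor with >= 3 groups.
#' @param alpha Significance level for pairwise decisions.
#' @param homogeneity_gate Apply the Levene/log10 gate first?
#' @return List with `omnibus_p`, `pairwise` (data frame: `comparison`,
#'   `diff`, `p_adj`, `significant`), `log10_applied`, `levene_p`.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05,
                        homogeneity_gate = TRUE) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 3L) {
    stop("one-way ANOVA with Tukey needs at least three groups",
         call. = FALSE)
  }
  levene_p <- NA_real_
  applied <- FALSE
  if (homogeneity_gate) {
    gate <- check_homogeneity_and_transform(values, groups, alpha)
    values <- gate$values
    levene_p <- gate$levene_p
    applied <- gate$log10_applied
  }
  fit <- aov(values ~ groups, data = data.frame(values = values,
                                                groups = groups))
  omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$groups
  pairwise <- data.frame(comparison = rownames(tk),
                         diff = tk[, "diff"],
                         p_adj = tk[, "p adj"],
                         significant = tk[, "p adj"] < alpha,
                         row.names = NULL, stringsAsFactors = FALSE)
  list(omnibus_p = omnibus_p, pairwise = pairwise,
       log10_applied = applied, levene_p = levene_p)
}

# Two-sample comparison used throughout: Welch by default (independent fish
# cohorts); a paired option is exposed for genuinely paired designs.
two_sample_p <- function(x, y, paired = FALSE) {
  t.test(x, y, paired = paired)$p.value
}

#' Classify the inheritance mode of hybrid expression
#'
#' Compares hybrid relative-expression values against the midparent value
#' (MPV) and against each parental cohort, and assigns one primary category:
#'
#' * `additive` — hybrid not significantly different from the MPV;
#' * `overdominant` / `underdominant` — nonadditive and significantly
#'   above/below *both* parents;
#' * `maternal_dominant` / `paternal_dominant` — nonadditive, statistically
#'   indistinguishable from one parent, different from the other, with the
#'   parents themselves differing;
#' * `above_mpv` / `below_mpv` — nonadditive with the given direction but no
#'   parent-level refinement ("predominant" expression when above).
#'
#' The MPV test is a one-sample t of the hybrid values against the MPV point
#' estimate; sampling error of the parental means is ignored (a documented
#' approximation that slightly inflates the nonadditive call rate).  Parent
#' comparisons use Welch two-sample t tests (or paired t when `paired`).
#'
#' @param hybrid,maternal,paternal Numeric RQ vectors, each of length >= 2
#'   and with nonzero variance.
#' @param alpha Significance level.
#' @param paired Use paired t tests for the parent comparisons.
#' @return An object of class `inheritance_call`: list with `category`,
#'   `nonadditive`, `direction` ("above"/"below"/"none"), `mpv`, and the
#'   p-values used (`p_vs_mpv`, `p_vs_maternal`, `p_vs_paternal`,
#'   `p_parents`).
#' @export
classify_inheritance <- function(hybrid, maternal, paternal, alpha = 0.05,
                                 paired = FALSE) {
  cohorts <- list(hybrid = hybrid, maternal = maternal, paternal = paternal)
  for (nm in names(cohorts)) {
    x <- cohorts[[nm]]
    if (length(x) < 2L) {
      stop(sprintf("%s cohort needs at least two values", nm), call. = FALSE)
    }
    if (sd(x) == 0) {
      stop(sprintf("degenerate input: %s cohort has zero variance", nm),
           call. = FALSE)
    }
  }
  mpv <- midparent_value(mean(maternal), mean(paternal))
  p_mpv <- t.test(hybrid, mu = mpv)$p.value
  p_m <- two_sample_p(hybrid, maternal, paired)
  p_p <- two_sample_p(hybrid, paternal, paired)
  p_par <- two_sample_p(maternal, paternal, paired)

  if (p_mpv >= alpha) {
    category <- "additive"
    direction <- "none"
  } else {
    direction <- if (mean(hybrid) > mpv) "above" else "below"
    beyond_both <- p_m < alpha && p_p < alpha &&
      ((mean(hybrid) > mean(maternal) && mean(hybrid) > mean(paternal)) ||
       (mean(hybrid) < mean(maternal) && mean(hybrid) < mean(paternal)))
    if (beyond_both) {
      category <- if (mean(hybrid) > mpv) "overdominant" else "underdominant"
    } else if (p_m >= alpha && p_p < alpha && p_par < alpha) {
      category <- "maternal_dominant"
    } else if (p_p >= alpha && p_m < alpha && p_par < alpha) {
      category <- "paternal_dominant"
    } else {
      category <- if (direction == "above") "above_mpv" else "below_mpv"
    }
  }
  structure(
    list(category = category, nonadditive = category != "additive",
         direction = direction, mpv = mpv,
         p_vs_mpv = p_mpv, p_vs_maternal = p_m, p_vs_paternal = p_p,
         p_parents = p_par, alpha = alpha),
    class = "inheritance_call"
  )
}

#' @export
print.inheritance_call <- function(x, ...) {
  cat(sprintf("<inheritance_call> %s (%s MPV %.4g; p vs MPV = %.3g)\n",
              x$category,
              switch(x$direction, above = "above", below = "below", "at"),
              x$mpv, x$p_vs_mpv))
  invisible(x)
}
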