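#' Pipeline run configuration
#'
#' @param outdir Output directory for all stage artifacts.
#' @param seed Master seed (drives the synthetic generator).
#' @param alpha Significance level used by every statistical stage.
#' @param epsilon Dead-zone for the cis/trans classification (log2 units).
#' @param calibrator_group Calibrator group for ddCt (default "BB").
#' @param scenario A [scenario_config()]; defaults to the packaged study
#'   design under `seed`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1L, alpha = 0.05, epsilon = 0.1,
                       calibrator_group = "BB",
                       scenario = scenario_config(seed = seed)) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  stopifnot(inherits(scenario, "scenario_config"))
  structure(
    list(outdir = outdir, seed = as.integer(seed), alpha = alpha,
         epsilon = epsilon, calibrator_group = calibrator_group,
         scenario = scenario),
    class = "run_config"
  )
}

stage_log <- function(stage, seed, msg, ...) {
  message(sprintf("[%s seed=%s] %s", stage, seed, sprintf(msg, ...)))
}

read_stage_file <- function(path, stage) {
  if (!file.exists(path)) {
    stop(sprintf("stage '%s': input file not found: %s", stage, path),
         call. = FALSE)
  }
  read.delim(path, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> SNP calling -> expression -> growth -> ASE ->
#' cis/trans on one seeded synthetic study, writing every intermediate as
#' plain TSV/JSON under `config$outdir` and aggregating the stage results
#' into a combined `report.json`.  Deterministic given the seed.
#'
#' @param config A [run_config()].
#' @return The report, invisibly (a nested list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  alpha <- config$alpha
  seed <- config$seed

  # --- simulate -------------------------------------------------------
  bundle <- generate_fixture_bundle(config$scenario,
                                    file.path(outdir, "inputs"))
  stage_log("simulate", seed, "wrote fixture bundle (fasta md5 %s)",
            unname(md5sum(bundle$parental_fasta)))

  # --- snps -----------------------------------------------------------
  seqs <- Biostrings::readDNAStringSet(bundle$parental_fasta)
  if (length(seqs) != 2L) {
    stop("stage 'snps': parental FASTA must contain exactly two sequences",
         call. = FALSE)
  }
  aln <- align_pair(as.character(seqs[[1]]), as.character(seqs[[2]]))
  fd <- call_fixed_differences(aln, utr5_len = config$scenario$utr5_len)
  write.table(fd$snps, file.path(outdir, "snps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  primers <- gh_primer_set()
  assay_site <- if (501 %in% fd$snps$position) {
    site_in_amplicon(501, primers[["pyr-GH"]])
  } else {
    list(inside = FALSE, offset = NA_integer_)
  }
  stage_log("snps", seed, "%d fixed difference(s) at %s", nrow(fd$snps),
            paste(fd$snps$position, collapse = ","))

  # --- expression -----------------------------------------------------
  ct <- read_stage_file(bundle$ct_table, "expression")
  expression <- list()
  summaries <- list()
  for (sx in unique(ct$sex)) {
    rq <- delta_delta_ct(ct[ct$sex == sx, ],
                         calibrator_group = config$calibrator_group)
    summ <- group_expression_summary(rq)
    omnibus <- anova_tukey(rq$rq, rq$group, alpha = alpha)
    call <- classify_inheritance(rq$rq[rq$group == "NB"],
                                 rq$rq[rq$group == "NN"],
                                 rq$rq[rq$group == "BB"], alpha = alpha)
    write.table(rq, file.path(outdir, sprintf("rq_%s.tsv", sx)), sep = "\t",
                quote = FALSE, row.names = FALSE)
    expression[[sx]] <- list(
      summary = summ, omnibus_p = omnibus$omnibus_p,
      pairwise = omnibus$pairwise,
      inheritance = unclass(call))
    summaries[[sx]] <- summ
    stage_log("expression", seed, "%s: %s (p vs MPV = %.3g)", sx,
              call$category, call$p_vs_mpv)
  }

  # --- growth ---------------------------------------------------------
  growth_tab <- read_stage_file(bundle$growth_table, "growth")
  growth_cmp <- compare_growth(growth_tab, alpha = alpha)
  write.table(growth_metrics(growth_tab),
              file.path(outdir, "growth_metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stage_log("growth", seed, "final-weight omnibus p = %.3g",
            growth_cmp$final_weight$omnibus_p)

  # --- ase ------------------------------------------------------------
  counts <- read_stage_file(bundle$allele_counts, "ase")
  calls <- ase_calls(counts, alpha = alpha)
  write.table(calls, file.path(outdir, "ase_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  adults <- calls[calls$condition == "adult", ]
  cohorts <- lapply(split(adults, adults$sex), function(d) {
    unclass(cohort_bias_test(d$fraction, label = d$sex[1], alpha = alpha))
  })
  fed <- calls$fraction[calls$condition == "fed"]
  fasted <- calls$fraction[calls$condition == "fasted"]
  condition <- condition_comparison(fed, fasted, alpha = alpha,
                                    labels = c("fed", "fasted"))
  stage_log("ase", seed, "adult maternal %% male %.2f / female %.2f; %s",
            cohorts$male$mean_pct, cohorts$female$mean_pct,
            condition$decision)

  # --- cistrans -------------------------------------------------------
  cistrans <- lapply(names(summaries), function(sx) {
    unclass(decompose_cis_trans(summaries[[sx]], cohorts[[sx]]$mean_pct,
                                sex = sx, epsilon = config$epsilon))
  })
  names(cistrans) <- names(summaries)
  for (sx in names(cistrans)) {
    stage_log("cistrans", seed, "%s: %s (A=%.3f B=%.3f)", sx,
              cistrans[[sx]]$category, cistrans[[sx]]$A, cistrans[[sx]]$B)
  }

  report <- list(
    seed = seed, alpha = alpha, epsilon = config$epsilon,
    snps = fd$snps,
    assay_covers_diagnostic_site = assay_site,
    expression = expression,
    growth = growth_cmp,
    ase = list(per_individual = calls, cohorts = cohorts,
               condition = condition),
    cistrans = cistrans
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(report)
}
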