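#' Synthetic study-design generator
#'
#' The functions in this file generate seeded synthetic inputs with the
#' statistical structure the downstream analysis stages assume: two parental
#' cDNAs differing at a fixed set of coding positions, group-level qPCR Ct
#' tables, per-individual pyrosequencing allele counts with beta-binomial
#' overdispersion, and lognormal growth-trial weights.  The default
#' configuration encodes the study conditions of a Nile tilapia (maternal,
#' "NN") x blue tilapia (paternal, "BB") hybridization design with an F1
#' hybrid cohort ("NB").
#'
#' @name synthetic-data
NULL

# Derive a deterministic per-table substream seed from the master seed, so
# adding a new table to a bundle never perturbs existing ones.  Kept below
# 2^31 (R integers are 32-bit); arithmetic is exact in doubles (< 2^53).
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629 + 1)
}

#' Default per-individual allelic-fraction presets
#'
#' True maternal-allele fractions for the four simulated cohorts.  The two
#' adult presets are calibrated so that the cohort means equal the observed
#' maternal percentages (87.10 for males, 82.33 for females) and so that
#' exactly five individuals per sex are maternal-biased and one
#' paternal-biased; the juvenile feeding/fasting presets reproduce a strong
#' maternal bias unaffected by nutritional condition.  These are fixture
#' conventions: only the cohort means are constrained by data.
#'
#' @return Named list of presets, each with `fractions`, `sex`, `condition`.
#' @export
default_ase_presets <- function() {
  list(
    male_adult = list(
      fractions = c(0.980, 0.978, 0.975, 0.972, 0.971, 0.350),
      sex = "male", condition = "adult"),
    female_adult = list(
      fractions = c(0.940, 0.930, 0.920, 0.910, 0.890, 0.3498),
      sex = "female", condition = "adult"),
    fed_juvenile = list(
      fractions = c(0.950, 0.930, 0.900, 0.850, 0.500),
      sex = "male", condition = "fed"),
    fasted_juvenile = list(
      fractions = c(0.950, 0.930, 0.910, 0.880, 0.850),
      sex = "male", condition = "fasted")
  )
}

#' Default group-level qPCR Ct means
#'
#' Mean Ct (cycles) for each group x sex x gene cell.  The reference gene is
#' flat across groups; target-gene means are chosen so that, after ddCt
#' quantification, males show hybrid > both parents (overdominant), females
#' show hybrid ~ maternal parent > paternal parent (maternal dominance), and
#' both sexes sit above the midparent value, with parental divergence small
#' enough in males (and large enough in females) to produce compensating and
#' enhancing cis/trans categories respectively.
#'
#' @return Data frame with columns `group`, `sex`, `gene`, `mean_ct`.
#' @export
default_ct_means <- function() {
  gh <- data.frame(
    group = rep(c("NN", "BB", "NB"), 2),
    sex = rep(c("male", "female"), each = 3),
    gene = "GH",
    mean_ct = c(22.0, 24.0, 20.8,
                21.5, 24.3, 21.5),
    stringsAsFactors = FALSE
  )
  ref <- gh
  ref$gene <- "actb"
  ref$mean_ct <- 15.0
  rbind(gh, ref)
}

#' Default growth-trial parameters
#'
#' Group-level lognormal weight parameters for a 120-day trial of 20 males
#' per group.  Final-weight means are the observed cohort means (399.31 g
#' hybrid, 378.95 g maternal line, 305.25 g paternal line); initial-weight
#' means are back-calculated from the observed percentage weight gains; the
#' lognormal sigma (0.11) reproduces the observed cohort SEM of ~10 g at
#' n = 20.
#'
#' @return Data frame with columns `group`, `initial_mean_g`, `final_mean_g`,
#'   `sdlog`, `days`, `n`.
#' @export
default_growth_params <- function() {
  data.frame(
    group = c("NB", "NN", "BB"),
    initial_mean_g = c(25.84, 25.82, 26.15),
    final_mean_g = c(399.31, 378.95, 305.25),
    sdlog = 0.11,
    days = 120L,
    n = 20L,
    stringsAsFactors = FALSE
  )
}

#' Scenario configuration for the synthetic generator
#'
#' Collects every tunable of the synthetic study in one validated object.
#' The defaults are the package's emulation of the two-line tilapia
#' hybridization design; see the individual `default_*()` helpers for what
#' each block encodes.
#'
#' @param seed Master seed; all per-table substreams derive from it.
#' @param n_per_group Biological replicates per group x sex for qPCR.
#' @param ct_sd Ct standard deviation in cycles (technical + biological).
#' @param group_means_ct Data frame as [default_ct_means()].
#' @param ase_presets Named list as [default_ase_presets()].
#' @param overdispersion_rho Beta-binomial intra-individual correlation in
#'   `[0, 1)`; 0 degenerates to binomial sampling.
#' @param read_depth Pyrosequencing read depth per individual.
#' @param growth Data frame as [default_growth_params()].
#' @param utr5_len Leader bases 5' of the coding start in the cDNA fixture.
#' @param cds_length Length of the coding/3' portion of the cDNA fixture.
#' @param snp_positions Signed coding positions of the parental fixed
#'   differences.
#' @param snp_alleles List of `c(maternal, paternal)` base pairs, one per
#'   position.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_per_group = 5L,
                            ct_sd = 0.15,
                            group_means_ct = default_ct_means(),
                            ase_presets = default_ase_presets(),
                            overdispersion_rho = 0.02,
                            read_depth = 2000L,
                            growth = default_growth_params(),
                            utr5_len = 26L,
                            cds_length = 780L,
                            snp_positions = c(53L, 327L, 501L, 603L),
                            snp_alleles = list(c("T", "C"), c("A", "G"),
                                               c("C", "G"), c("T", "A"))) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (ct_sd < 0) stop("ct_sd must be >= 0", call. = FALSE)
  if (n_per_group < 1L) stop("n_per_group must be >= 1", call. = FALSE)
  if (read_depth < 1L) stop("read_depth must be >= 1", call. = FALSE)
  if (overdispersion_rho < 0 || overdispersion_rho >= 1) {
    stop("overdispersion_rho must lie in [0, 1)", call. = FALSE)
  }
  for (p in ase_presets) {
    if (any(p$fractions < 0 | p$fractions > 1)) {
      stop("preset fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  if (any(growth$initial_mean_g <= 0) || any(growth$final_mean_g <= 0) ||
      any(growth$sdlog < 0)) {
    stop("growth weight parameters must be positive (sdlog >= 0)",
         call. = FALSE)
  }
  if (any(growth$days <= 0)) stop("trial days must be > 0", call. = FALSE)
  structure(
    list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
         ct_sd = ct_sd, group_means_ct = group_means_ct,
         ase_presets = ase_presets,
         overdispersion_rho = overdispersion_rho,
         read_depth = as.integer(read_depth), growth = growth,
         utr5_len = as.integer(utr5_len),
         cds_length = as.integer(cds_length),
         snp_positions = as.integer(snp_positions),
         snp_alleles = snp_alleles),
    class = "scenario_config"
  )
}

#' Generate a pair of parental cDNA sequences
#'
#' Draws one random cDNA (a 5' leader of `utr5_len` bases followed by
#' `cds_length` coding-frame bases) and derives the two parental sequences
#' by writing the maternal/paternal allele at each requested signed position.
#' The two outputs are identical everywhere except at exactly those
#' positions.
#'
#' @param seed RNG seed.
#' @param cds_length,utr5_len Sequence dimensions (bases).
#' @param snp_positions Distinct nonzero signed positions within
#'   `[-utr5_len, cds_length]`.
#' @param allele_pairs List of `c(maternal_base, paternal_base)` per
#'   position; the bases in a pair must differ.
#' @return An object of class `parental_cds`: list with `nile`, `blue`
#'   (character sequences), `snps` (data frame), `utr5_len`, `cds_length`.
#' @export
generate_parental_cds <- function(seed = 101L,
                                  cds_length = 780L,
                                  utr5_len = 26L,
                                  snp_positions = c(53L, 327L, 501L, 603L),
                                  snp_alleles = list(c("T", "C"), c("A", "G"),
                                                     c("C", "G"), c("T", "A"))) {
  if (length(snp_positions) != length(snp_alleles)) {
    stop("snp_positions and snp_alleles must have equal length", call. = FALSE)
  }
  if (anyDuplicated(snp_positions)) {
    stop("snp_positions must be distinct", call. = FALSE)
  }
  snp_positions <- vapply(snp_positions, assert_signed_coord, integer(1),
                          arg = "snp_positions")
  if (any(snp_positions < -utr5_len) || any(snp_positions > cds_length)) {
    stop(sprintf("snp_positions must lie within [-%d, %d]", utr5_len,
                 cds_length), call. = FALSE)
  }
  set.seed(seed)
  base_seq <- sample(c("A", "C", "G", "T"), utr5_len + cds_length,
                     replace = TRUE)
  nile <- base_seq
  blue <- base_seq
  for (k in seq_along(snp_positions)) {
    pair <- toupper(snp_alleles[[k]])
    if (length(pair) != 2L || pair[1] == pair[2] ||
        !all(pair %in% c("A", "C", "G", "T"))) {
      stop("each allele pair must be two distinct A/C/G/T bases",
           call. = FALSE)
    }
    idx <- signed_to_index(snp_positions[k], utr5_len)
    nile[idx] <- pair[1]
    blue[idx] <- pair[2]
  }
  snps <- data.frame(
    position = snp_positions,
    nile_allele = vapply(snp_alleles, function(p) toupper(p[1]), ""),
    blue_allele = vapply(snp_alleles, function(p) toupper(p[2]), ""),
    stringsAsFactors = FALSE
  )
  snps <- snps[order(snps$position), , drop = FALSE]
  rownames(snps) <- NULL
  structure(
    list(nile = paste(nile, collapse = ""),
         blue = paste(blue, collapse = ""),
         snps = snps, utr5_len = as.integer(utr5_len),
         cds_length = as.integer(cds_length)),
    class = "parental_cds"
  )
}

#' Write parental cDNAs to FASTA
#'
#' @param cds A [generate_parental_cds()] result.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_parental_fasta <- function(cds, path) {
  stopifnot(inherits(cds, "parental_cds"))
  seqs <- Biostrings::DNAStringSet(c(NN_GH_cdna = cds$nile,
                                     BB_GH_cdna = cds$blue))
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

# Draw beta-binomial maternal counts: individual i's realized maternal
# probability is Beta with mean p_i and intra-class correlation rho; rho = 0
# degenerates to plain binomial sampling, as do the boundary fractions 0/1.
rbetabinom_counts <- function(fractions, depth, rho) {
  p <- fractions
  if (rho > 0) {
    mid <- p > 0 & p < 1
    a <- p[mid] * (1 - rho) / rho
    b <- (1 - p[mid]) * (1 - rho) / rho
    p[mid] <- rbeta(sum(mid), a, b)
  }
  rbinom(length(p), depth, p)
}

#' Simulate pyrosequencing allele counts for a cohort preset
#'
#' For each individual in the preset, draws the maternal-allele read count
#' from a beta-binomial with the individual's true fraction as mean, read
#' depth `depth`, and intra-individual correlation `rho` (0 gives binomial
#' sampling).  Sex and condition labels are taken from the preset.
#'
#' @param preset Preset name (see [default_ase_presets()]).
#' @param depth Read depth per individual (>= 1).
#' @param rho Overdispersion in `[0, 1)`.
#' @param seed RNG seed.
#' @param presets Preset list; defaults to the packaged presets.
#' @return Data frame with columns `individual`, `sex`, `condition`,
#'   `mat_count`, `pat_count`.
#' @export
simulate_allele_counts <- function(preset = "male_adult", depth = 2000L,
                                   rho = 0.02, seed = 1L,
                                   presets = default_ase_presets()) {
  if (!preset %in% names(presets)) {
    stop(sprintf("unknown preset '%s' (available: %s)", preset,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  }
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  p <- presets[[preset]]
  set.seed(seed)
  mat <- rbetabinom_counts(p$fractions, depth, rho)
  data.frame(
    individual = sprintf("%s_%d", preset, seq_along(p$fractions)),
    sex = p$sex,
    condition = p$condition,
    mat_count = as.integer(mat),
    pat_count = as.integer(depth - mat),
    stringsAsFactors = FALSE
  )
}

#' Simulate a qPCR Ct table
#'
#' Draws triplicate technical-replicate Ct values for `n_per_group`
#' biological samples in every group x sex cell, for both the target and the
#' reference gene, as Normal(group mean, `ct_sd`).
#'
#' @param config A [scenario_config()].
#' @param seed RNG seed (defaults to the config's master seed).
#' @param n_technical Technical replicates per sample per gene.
#' @return Data frame with columns `sample`, `group`, `sex`, `gene`,
#'   `replicate`, `ct`.
#' @export
simulate_ct_table <- function(config = scenario_config(),
                              seed = config$seed, n_technical = 3L) {
  stopifnot(inherits(config, "scenario_config"))
  means <- config$group_means_ct
  cells <- unique(means[, c("group", "sex")])
  genes <- unique(means$gene)
  if (length(genes) < 2L) {
    stop("group_means_ct must cover a target and a reference gene",
         call. = FALSE)
  }
  set.seed(seed)
  out <- list()
  for (r in seq_len(nrow(cells))) {
    grp <- cells$group[r]
    sx <- cells$sex[r]
    for (i in seq_len(config$n_per_group)) {
      sample_id <- sprintf("%s_%s_%d", grp, sx, i)
      for (g in genes) {
        mu <- means$mean_ct[means$group == grp & means$sex == sx &
                              means$gene == g]
        if (length(mu) != 1L) {
          stop(sprintf("missing mean Ct for %s/%s/%s", grp, sx, g),
               call. = FALSE)
        }
        ct <- rnorm(n_technical, mu, config$ct_sd)
        out[[length(out) + 1L]] <- data.frame(
          sample = sample_id, group = grp, sex = sx, gene = g,
          replicate = seq_len(n_technical), ct = ct,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Simulate a growth-trial table
#'
#' Draws per-fish initial and final weights from lognormal distributions
#' whose arithmetic means equal the configured group means (meanlog is
#' offset by `-sdlog^2/2`), for the configured number of fish per group.
#'
#' @param config A [scenario_config()].
#' @param seed RNG seed (defaults to the config's master seed).
#' @return Data frame with columns `individual`, `group`, `initial_g`,
#'   `final_g`, `days`.
#' @export
simulate_growth <- function(config = scenario_config(), seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  gp <- config$growth
  set.seed(seed)
  out <- list()
  for (r in seq_len(nrow(gp))) {
    n <- gp$n[r]
    sdl <- gp$sdlog[r]
    ini <- rlnorm(n, log(gp$initial_mean_g[r]) - sdl^2 / 2, sdl)
    fin <- rlnorm(n, log(gp$final_mean_g[r]) - sdl^2 / 2, sdl)
    out[[r]] <- data.frame(
      individual = sprintf("%s_%d", gp$group[r], seq_len(n)),
      group = gp$group[r], initial_g = ini, final_g = fin,
      days = gp$days[r], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate the full synthetic fixture bundle
#'
#' Writes every input the pipeline consumes — parental FASTA, Ct TSV,
#' allele-count TSV (all presets), growth TSV — plus a structured JSON
#' "truth" sidecar recording the exact parameters used, so recovery tests
#' can compare estimates against the generating truth without re-reading
#' the config.  Each table uses its own substream of the master seed.
#'
#' @param config A [scenario_config()].
#' @param outdir Output directory (created if needed).
#' @return An object of class `fixture_bundle`: list of file paths plus the
#'   `truth` list.
#' @export
generate_fixture_bundle <- function(config = scenario_config(), outdir) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  cds <- generate_parental_cds(seed = sub_seed(config$seed, "sequence"),
                               cds_length = config$cds_length,
                               utr5_len = config$utr5_len,
                               snp_positions = config$snp_positions,
                               snp_alleles = config$snp_alleles)
  fasta_path <- file.path(outdir, "parental_cdna.fasta")
  write_parental_fasta(cds, fasta_path)

  ct <- simulate_ct_table(config, seed = sub_seed(config$seed, "ct"))
  ct_path <- file.path(outdir, "ct_values.tsv")
  write.table(ct, ct_path, sep = "\t", quote = FALSE, row.names = FALSE)

  counts <- do.call(rbind, lapply(names(config$ase_presets), function(pn) {
    simulate_allele_counts(pn, depth = config$read_depth,
                           rho = config$overdispersion_rho,
                           seed = sub_seed(config$seed, paste0("ase_", pn)),
                           presets = config$ase_presets)
  }))
  counts_path <- file.path(outdir, "allele_counts.tsv")
  write.table(counts, counts_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  growth <- simulate_growth(config, seed = sub_seed(config$seed, "growth"))
  growth_path <- file.path(outdir, "growth.tsv")
  write.table(growth, growth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  truth <- list(
    seed = config$seed,
    utr5_len = config$utr5_len,
    snps = cds$snps,
    group_means_ct = config$group_means_ct,
    ct_sd = config$ct_sd,
    n_per_group = config$n_per_group,
    ase_presets = lapply(config$ase_presets, function(p) {
      list(fractions = p$fractions, mean_pct = 100 * mean(p$fractions),
           sex = p$sex, condition = p$condition)
    }),
    overdispersion_rho = config$overdispersion_rho,
    read_depth = config$read_depth,
    growth = config$growth
  )
  truth_path <- file.path(outdir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)

  structure(
    list(parental_fasta = fasta_path, ct_table = ct_path,
         allele_counts = counts_path, growth_table = growth_path,
         truth_sidecar = truth_path, truth = truth),
    class = "fixture_bundle"
  )
}
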