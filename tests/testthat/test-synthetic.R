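test_that("parental cDNAs differ at exactly the requested positions", {
  cds <- generate_parental_cds()
  expect_identical(nchar(cds$nile), nchar(cds$blue))
  scan <- scan_fixed_differences(cds$nile, cds$blue, cds$utr5_len)
  expect_identical(scan$position, c(53L, 327L, 501L, 603L))
  expect_identical(cds$snps$nile_allele[cds$snps$position == 501], "C")
  expect_identical(cds$snps$blue_allele[cds$snps$position == 501], "G")

  # empty SNP list -> identical sequences
  none <- generate_parental_cds(snp_positions = integer(0),
                                snp_alleles = list())
  expect_identical(none$nile, none$blue)
  expect_identical(nrow(none$snps), 0L)

  # positions in the 5' leader are honoured too
  lead <- generate_parental_cds(snp_positions = c(-10L, 40L),
                                snp_alleles = list(c("A", "G"), c("C", "T")))
  expect_identical(
    scan_fixed_differences(lead$nile, lead$blue, lead$utr5_len)$position,
    c(-10L, 40L))
})

test_that("generator rejects invalid SNP specifications", {
  expect_error(generate_parental_cds(snp_positions = 0L,
                                     snp_alleles = list(c("C", "G"))),
               "position 0")
  expect_error(generate_parental_cds(snp_positions = c(53L, 53L),
                                     snp_alleles = list(c("C", "G"),
                                                        c("A", "T"))),
               "distinct")
  expect_error(generate_parental_cds(snp_positions = 9999L,
                                     snp_alleles = list(c("C", "G"))),
               "within")
  expect_error(generate_parental_cds(snp_positions = 53L,
                                     snp_alleles = list(c("C", "C"))),
               "distinct")
})

test_that("allele-count simulation honours degenerate settings", {
  pres <- list(all_mat = list(fractions = rep(1, 4), sex = "male",
                              condition = "adult"))
  cc <- simulate_allele_counts("all_mat", depth = 100, rho = 0,
                               seed = 1, presets = pres)
  expect_true(all(cc$mat_count == 100L))
  expect_true(all(cc$pat_count == 0L))
  expect_error(simulate_allele_counts("nope"), "unknown preset")
  expect_error(simulate_allele_counts("male_adult", rho = 1), "rho")
  expect_error(simulate_allele_counts("male_adult", depth = 0), "depth")
})

test_that("simulated fractions recover the preset mean (Monte Carlo)", {
  means <- vapply(1:200, function(s) {
    cc <- simulate_allele_counts("male_adult", depth = 2000, rho = 0.02,
                                 seed = s)
    mean(maternal_fraction(cc$mat_count, cc$pat_count))
  }, numeric(1))
  preset_mean <- mean(default_ase_presets()$male_adult$fractions)
  expect_lt(abs(mean(means) - preset_mean), 0.01)
})

test_that("overdispersion strictly inflates the variance of fractions", {
  pres <- list(p7 = list(fractions = 0.7, sex = "male", condition = "adult"))
  draw <- function(rho) vapply(1:500, function(s) {
    cc <- simulate_allele_counts("p7", depth = 200, rho = rho, seed = s,
                                 presets = pres)
    maternal_fraction(cc$mat_count, cc$pat_count)
  }, numeric(1))
  expect_gt(var(draw(0.9)), var(draw(0)))
})

test_that("beta-binomial empirical mean matches p within 3 MC errors", {
  n <- 10000
  p <- 0.87
  pres <- list(big = list(fractions = rep(p, n), sex = "male",
                          condition = "adult"))
  cc <- simulate_allele_counts("big", depth = 100, rho = 0.02, seed = 99,
                               presets = pres)
  fr <- maternal_fraction(cc$mat_count, cc$pat_count)
  se <- sd(fr) / sqrt(n)
  expect_lt(abs(mean(fr) - p), 3 * se)
})

test_that("Ct simulation has the configured bookkeeping and means", {
  cfg <- scenario_config(seed = 3, ct_sd = 0)
  ct <- simulate_ct_table(cfg)
  # 3 groups x 2 sexes x 5 samples x 2 genes x 3 replicates
  expect_identical(nrow(ct), 3L * 2L * 5L * 2L * 3L)
  # sd = 0 -> every replicate equals the configured mean
  m <- merge(ct, cfg$group_means_ct)
  expect_equal(m$ct, m$mean_ct)
  # missing group x gene mean -> config error
  bad <- cfg
  bad$group_means_ct <- cfg$group_means_ct[-1, ]
  expect_error(simulate_ct_table(bad), "missing mean Ct")
})

test_that("growth simulation honours degenerate sd and positivity checks", {
  gp <- default_growth_params()
  gp$sdlog <- 0
  cfg <- scenario_config(seed = 5, growth = gp)
  g <- simulate_growth(cfg)
  expect_equal(g$final_g[g$group == "NB"], rep(399.31, 20))
  expect_error(scenario_config(growth = transform(gp, final_mean_g = -1)),
               "positive")
})

test_that("simulated growth recovers group means within 2 standard errors", {
  cfg <- scenario_config(seed = 8)
  g <- simulate_growth(cfg)
  for (grp in c("NB", "NN", "BB")) {
    fin <- g$final_g[g$group == grp]
    want <- cfg$growth$final_mean_g[cfg$growth$group == grp]
    expect_lt(abs(mean(fin) - want), 2 * sd(fin) / sqrt(length(fin)))
  }
})

test_that("fixture bundles are byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- generate_fixture_bundle(scenario_config(seed = 17), d1)
  b2 <- generate_fixture_bundle(scenario_config(seed = 17), d2)
  files <- c("parental_fasta", "ct_table", "allele_counts", "growth_table",
             "truth_sidecar")
  for (f in files) {
    expect_identical(unname(tools::md5sum(b1[[f]])),
                     unname(tools::md5sum(b2[[f]])),
                     info = f)
  }
  b3 <- generate_fixture_bundle(scenario_config(seed = 18), d2)
  expect_false(identical(unname(tools::md5sum(b1$ct_table)),
                         unname(tools::md5sum(b3$ct_table))))
})

test_that("the truth sidecar round-trips the generating parameters", {
  d <- withr::local_tempdir()
  b <- generate_fixture_bundle(scenario_config(seed = 21), d)
  truth <- jsonlite::read_json(b$truth_sidecar, simplifyVector = TRUE)
  expect_equal(truth$seed, 21)
  expect_equal(truth$snps$position, c(53, 327, 501, 603))
  expect_equal(truth$ase_presets$male_adult$mean_pct, 87.10,
               tolerance = 1e-10)
  expect_equal(truth$ase_presets$female_adult$mean_pct, 82.33,
               tolerance = 1e-3)
  expect_equal(truth$growth$final_mean_g, c(399.31, 378.95, 305.25))
})
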