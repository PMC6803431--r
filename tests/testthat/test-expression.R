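make_ct <- function(samples) {
  # samples: list of list(sample, group, gh, actb) with scalar mean Cts
  do.call(rbind, lapply(samples, function(s) {
    data.frame(sample = s$sample, group = s$group,
               gene = c("GH", "actb"), ct = c(s$gh, s$actb),
               stringsAsFactors = FALSE)
  }))
}

test_that("ddCt closed forms: shifted target and self-calibration", {
  ct <- make_ct(list(list(sample = "s", group = "NB", gh = 20, actb = 15),
                     list(sample = "c", group = "BB", gh = 22, actb = 15)))
  rq <- delta_delta_ct(ct, calibrator_group = "BB")
  expect_equal(rq$rq[rq$sample == "s"], 4)
  expect_equal(rq$rq[rq$sample == "c"], 1)

  same <- make_ct(list(list(sample = "c", group = "BB", gh = 21, actb = 16),
                       list(sample = "c2", group = "BB", gh = 21, actb = 16)))
  expect_equal(delta_delta_ct(same, calibrator_group = "BB")$rq, c(1, 1))
})

test_that("ddCt averages technical replicates before differencing", {
  ct <- rbind(
    data.frame(sample = "s", group = "NB", gene = "GH",
               ct = c(20.1, 19.9, 20.0)),
    data.frame(sample = "s", group = "NB", gene = "actb", ct = 15),
    data.frame(sample = "c", group = "BB", gene = "GH", ct = 22),
    data.frame(sample = "c", group = "BB", gene = "actb", ct = 15)
  )
  rq <- delta_delta_ct(ct, calibrator_group = "BB")
  expect_equal(rq$rq[rq$sample == "s"], 2^-((20.0 - 15) - (22 - 15)))
})

test_that("ddCt rejects samples missing the reference gene", {
  ct <- data.frame(sample = c("s", "c", "c"), group = c("NB", "BB", "BB"),
                   gene = c("GH", "GH", "actb"), ct = c(20, 22, 15))
  expect_error(delta_delta_ct(ct, calibrator_group = "BB"),
               "exactly one")
  complete <- make_ct(list(list(sample = "s", group = "NB", gh = 20,
                                actb = 15)))
  expect_error(delta_delta_ct(complete, calibrator_group = "XX"),
               "calibrator")
})

test_that("RQ is invariant to a constant shift of one sample's Cts", {
  set.seed(31)
  for (rep in 1:20) {
    base <- make_ct(list(
      list(sample = "s", group = "NB", gh = runif(1, 18, 26),
           actb = runif(1, 13, 17)),
      list(sample = "c", group = "BB", gh = runif(1, 18, 26),
           actb = runif(1, 13, 17))))
    shifted <- base
    k <- runif(1, -3, 3)
    shifted$ct[shifted$sample == "s"] <- shifted$ct[shifted$sample == "s"] + k
    expect_equal(delta_delta_ct(base, calibrator_group = "BB")$rq,
                 delta_delta_ct(shifted, calibrator_group = "BB")$rq)
  }
})

test_that("midparent value is the arithmetic parental mean", {
  expect_equal(midparent_value(1, 1), 1)
  expect_equal(midparent_value(378.95, 305.25), 342.10)
  expect_equal(midparent_value(2, 0.5), 1.25)
  expect_error(midparent_value(-1, 2), "positive")
})

test_that("homogeneity gate leaves equal-variance data untouched (MC)", {
  set.seed(51)
  flags <- replicate(400, {
    v <- rnorm(30, 10, 1)
    g <- rep(letters[1:3], each = 10)
    check_homogeneity_and_transform(v, g)$log10_applied
  })
  expect_gte(mean(!flags), 0.90)
})

test_that("homogeneity gate log-transforms heteroscedastic data", {
  set.seed(52)
  hits <- replicate(50, {
    v <- c(rlnorm(10, 1, 0.2), rlnorm(10, 1, 0.2) * 100)  # one group x100
    g <- rep(c("a", "b"), each = 10)
    check_homogeneity_and_transform(v, g)$log10_applied
  })
  expect_gte(mean(hits), 0.9)
  # identical groups cannot reject homogeneity
  v <- rep(c(1, 2, 3, 4), 2)
  g <- rep(c("a", "b"), each = 4)
  expect_false(check_homogeneity_and_transform(v, g)$log10_applied)
})

test_that("anova_tukey flags only the truly divergent group", {
  set.seed(61)
  hit_third <- replicate(50, {
    v <- c(rnorm(10, 0), rnorm(10, 0), rnorm(10, 5))
    g <- rep(c("a", "b", "c"), each = 10)
    res <- anova_tukey(v, g, homogeneity_gate = FALSE)
    third <- grepl("c", res$pairwise$comparison)
    res$omnibus_p < 0.001 && all(res$pairwise$significant[third])
  })
  expect_gte(mean(hit_third), 0.95)

  v <- rep(c(1.0, 1.1, 0.9, 1.05, 0.95), 3)
  g <- rep(c("a", "b", "c"), each = 5)
  res <- anova_tukey(v, g, homogeneity_gate = FALSE)
  expect_gt(res$omnibus_p, 0.9)
  expect_false(any(res$pairwise$significant))

  expect_error(anova_tukey(rnorm(10), rep(c("a", "b"), 5)),
               "three groups")
})

test_that("ANOVA omnibus p matches a permutation p within MC error", {
  set.seed(71)
  v <- c(rnorm(6, 0), rnorm(6, 0.8), rnorm(6, 1.6))
  g <- factor(rep(c("a", "b", "c"), each = 6))
  fstat <- function(vals) {
    summary(aov(vals ~ g))[[1]][["F value"]][1]
  }
  obs <- fstat(v)
  perm <- replicate(2000, fstat(sample(v)))
  p_perm <- mean(perm >= obs)
  p_anova <- anova_tukey(v, g, homogeneity_gate = FALSE)$omnibus_p
  expect_lt(abs(p_perm - p_anova), 3 * sqrt(p_anova * (1 - p_anova) / 2000) + 0.01)
})

test_that("large-effect cohorts are classified over- and maternal-dominant", {
  set.seed(81)
  h <- rnorm(8, 20, 1); m <- rnorm(8, 8, 1); p <- rnorm(8, 2, 1)
  expect_identical(classify_inheritance(h, m, p)$category, "overdominant")

  h2 <- rnorm(8, 8, 1)
  cl <- classify_inheritance(h2, m, p)
  expect_identical(cl$category, "maternal_dominant")
  expect_true(cl$nonadditive)
  expect_identical(cl$direction, "above")
})

test_that("swapping parents swaps dominant labels, keeps overdominance", {
  set.seed(82)
  h <- rnorm(8, 8, 1); m <- rnorm(8, 8, 1); p <- rnorm(8, 2, 1)
  a <- classify_inheritance(h, m, p)
  b <- classify_inheritance(h, p, m)
  swap <- c(maternal_dominant = "paternal_dominant",
            paternal_dominant = "maternal_dominant")
  if (a$category %in% names(swap)) {
    expect_identical(b$category, unname(swap[a$category]))
  } else {
    expect_identical(b$category, a$category)
  }
  expect_equal(a$mpv, b$mpv)

  set.seed(83)
  ho <- rnorm(8, 20, 1)
  expect_identical(classify_inheritance(ho, m, p)$category,
                   classify_inheritance(ho, p, m)$category)
})

test_that("null cohorts are called additive at close to the nominal rate", {
  set.seed(91)
  nonadd <- replicate(1000, {
    h <- rnorm(5, 10, 2); m <- rnorm(5, 10, 2); p <- rnorm(5, 10, 2)
    classify_inheritance(h, m, p)$category != "additive"
  })
  expect_lte(mean(nonadd), 0.10)
})

test_that("degenerate zero-variance cohorts raise an explicit error", {
  expect_error(classify_inheritance(rep(1, 5), rnorm(5), rnorm(5)),
               "degenerate")
  expect_error(classify_inheritance(rnorm(5), rnorm(5), 3), "two values")
})
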