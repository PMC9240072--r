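# Severity discretization, contingency statistics, bootstrap, correlations.

# the study's printed severity count tables (interventions x classes)
ccl4_table <- matrix(c(8, 12, 0, 49, 54, 3, 9, 69, 13), nrow = 3, byrow = TRUE,
                     dimnames = list(c("bsl", "pre", "post"),
                                     c("mild", "moderate", "severe")))
oil_table <- matrix(c(11, 7, 0, 93, 41, 2, 63, 59, 5), nrow = 3, byrow = TRUE,
                    dimnames = list(c("bsl", "pre", "post"),
                                    c("mild", "moderate", "severe")))

test_that("severity classification follows the 3/6 thresholds with closed boundaries", {
  expect_equal(as.character(classify_severity(c(0, 2.99, 3, 4.5, 6, 6.01, 16))),
               c("mild", "mild", "moderate", "moderate", "moderate",
                 "severe", "severe"))
  expect_error(classify_severity(-0.1), "non-negative")
})

test_that("severity counts conserve records across the table", {
  ds <- emulate_study(seed = 12)
  counts <- severity_counts(ds)
  expect_equal(sum(counts), nrow(ds))
  for (trt in c("Oil", "CCl4")) {
    for (iv in c("bsl", "pre", "post")) {
      cell <- sum(ds$treatment == trt & ds$intervention == iv)
      expect_equal(sum(counts[trt, iv, ]), cell)
    }
  }
  empty <- severity_counts(make_dataset(data.frame(
    animal_id = character(), treatment = character(), week = integer(),
    day = integer(), intervention = character(), ot_score = numeric(),
    nb_score = numeric(), cb_score = numeric(), ep_score = numeric(),
    wc_score = numeric(), avg_picture_score = numeric())))
  expect_equal(sum(empty), 0L)
})

test_that("the chi-squared test matches the direct definition and edge cases", {
  for (s in 1:20) {
    set.seed(400 + s)
    tab <- matrix(rpois(12, 20) + 1, 3, 4)
    res <- chi_square(tab)
    expect_equal(res$statistic, direct_chisq(tab), tolerance = 1e-9)
    expect_equal(res$df, 6)
  }
  prop <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 2, byrow = TRUE)
  expect_equal(chi_square(prop)$statistic, 0, tolerance = 1e-12)
  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "row 1")
  expect_error(chi_square(cbind(c(0, 0), c(1, 2))), "column 1")
})

test_that("printed study tables reproduce the reported statistics", {
  r_ccl4 <- chi_square(ccl4_table)
  expect_equal(r_ccl4$statistic, 37.15, tolerance = 0.005)
  expect_equal(r_ccl4$df, 4)
  r_oil <- chi_square(oil_table)
  expect_equal(r_oil$statistic, 10.579, tolerance = 0.0005)
  expect_equal(r_oil$df, 4)
})

test_that("pairwise post-hocs reproduce the printed control-arm values", {
  ph_oil <- posthoc_pairwise(oil_table, adjust = "fdr")
  expect_equal(ph_oil$p_adj[ph_oil$pair == "mild/moderate"], 0.044,
               tolerance = 0.0005 / 0.044)
  expect_equal(ph_oil$p_adj[ph_oil$pair == "mild/severe"], 0.285,
               tolerance = 0.0005 / 0.285)
  expect_equal(ph_oil$p_adj[ph_oil$pair == "moderate/severe"], 0.627,
               tolerance = 0.0005 / 0.627)
  ph_ccl4 <- posthoc_pairwise(ccl4_table, adjust = "fdr")
  expect_lte(ph_ccl4$p_adj[ph_ccl4$pair == "mild/moderate"], 0.001)
  expect_lte(ph_ccl4$p_adj[ph_ccl4$pair == "mild/severe"], 0.001)
})

test_that("pairwise post-hocs adjust monotonically and handle degenerate profiles", {
  ph <- posthoc_pairwise(ccl4_table)
  expect_equal(nrow(ph), 3L)
  for (m in c("fdr", "holm", "bonferroni")) {
    phm <- posthoc_pairwise(ccl4_table, adjust = m)
    expect_true(all(phm$p_adj >= phm$p_raw - 1e-12))
  }
  flat <- matrix(c(5, 10, 15, 5, 10, 15), nrow = 3,
                 dimnames = list(c("bsl", "pre", "post"), c("mild", "moderate")))
  expect_equal(posthoc_pairwise(flat)$p_adj, 1)
  # low expected counts are flagged; Fisher only on request
  tiny <- matrix(c(1, 2, 1, 30, 2, 40), nrow = 3,
                 dimnames = list(c("bsl", "pre", "post"), c("a", "b")))
  expect_true(posthoc_pairwise(tiny)$low_expected)
  expect_equal(posthoc_pairwise(tiny)$method, "chisq")
  expect_equal(posthoc_pairwise(tiny, fisher = TRUE)$method, "fisher")
})

test_that("severity report assembles counts, tests and post-hocs per arm", {
  ds <- emulate_study(seed = 14)
  rep <- severity_report(ds)
  expect_s3_class(rep, "severity_report")
  expect_equal(sum(rep$counts), nrow(ds))
  for (trt in c("Oil", "CCl4")) {
    p <- rep$per_treatment[[trt]]
    expect_equal(p$chi2$df, 4)
    expect_equal(nrow(p$posthoc), 3L)
  }
})

test_that("Mann-Whitney contrasts select records and record provenance", {
  ds <- emulate_study(seed = 15)
  es <- mann_whitney_contrast(ds,
    group_a = list(treatment = "CCl4", week = 0),
    group_b = list(treatment = "CCl4", week = 1, intervention = "post"))
  expect_s3_class(es, "effect_size")
  expect_equal(attr(es, "selectors")$group_a$week, 0)
  same <- mann_whitney_contrast(ds, list(treatment = "Oil"), list(treatment = "Oil"))
  expect_equal(same$r, 0)
  expect_error(mann_whitney_contrast(ds, list(treatment = "Oil", week = 9),
                                     list(treatment = "Oil")), "group_a")
  expect_error(mann_whitney_contrast(ds, list(bogus = 1), list(treatment = "Oil")),
               "unknown column")
})

test_that("the bootstrap median is seeded, ordered and degenerate-safe", {
  b <- bootstrap_median(rep(4.2, 10), n_boot = 500, seed = 1)
  expect_equal(b$median, 4.2)
  expect_equal(c(b$ci_low, b$ci_high), c(4.2, 4.2))
  set.seed(77)
  x <- rgamma(40, 2)
  b1 <- bootstrap_median(x, n_boot = 2000, seed = 3)
  b2 <- bootstrap_median(x, n_boot = 2000, seed = 3)
  expect_identical(b1, b2)
  expect_true(b1$ci_low <= b1$median && b1$median <= b1$ci_high)
  expect_error(bootstrap_median(numeric(0)), "non-empty")
})

test_that("bootstrap CI width shrinks with sample size on Gaussian data", {
  width <- function(n) {
    w <- numeric(50)
    for (i in 1:50) {
      set.seed(9000 + i)
      x <- rnorm(n)
      b <- bootstrap_median(x, n_boot = 400, seed = i)
      w[i] <- b$ci_high - b$ci_low
    }
    median(w)
  }
  expect_lt(width(80), width(20))
})

test_that("correlation matrices are symmetric with unit diagonal and NA-safe", {
  ds <- emulate_study(seed = 16)
  cc <- correlation_matrix(ds, "CCl4")
  expect_equal(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, 5))
  # duplicated criterion: perfect correlation
  ds2 <- ds
  ds2$nb_score <- ds2$ot_score
  cc2 <- correlation_matrix(ds2, "CCl4")
  expect_equal(unname(cc2["ot", "nb"]), 1)
  # constant criterion: NA row/column plus warning
  ds3 <- ds
  ds3$wc_score <- 2
  expect_warning(cc3 <- correlation_matrix(ds3, "CCl4"), "constant")
  expect_true(all(is.na(cc3["wc", ])))
  expect_false(anyNA(cc3[1:4, 1:4]))
  expect_error(correlation_matrix(ds[0, ], "Oil"), "at least 3")
  # spearman option
  cs <- correlation_matrix(ds, "Oil", method = "spearman")
  expect_equal(cs, t(cs))
})

test_that("normality checks flag discreteness and reject degenerate input", {
  set.seed(8)
  gaussian <- rnorm(200)
  nc <- normality_check(gaussian)
  expect_gt(nc$shapiro_p, 0.001)
  expect_equal(nrow(nc$qq), 200)
  ordinal <- rep(0:2, c(120, 60, 20))
  expect_lt(normality_check(ordinal)$shapiro_p, 1e-4)
  expect_error(normality_check(rep(1, 10)), "constant")
  expect_error(normality_check(c(1, 2)), "sample size")
})
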