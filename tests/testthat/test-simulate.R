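# Synthetic generator: determinism, design invariants, calibration shape.

test_that("simulation is deterministic under a seed and distinct across seeds", {
  a <- simulate_mgs(mgs_sim_config(seed = 42))
  b <- simulate_mgs(mgs_sim_config(seed = 42))
  expect_identical(a$images, b$images)
  c <- simulate_mgs(mgs_sim_config(seed = 43))
  expect_false(identical(a$images, c$images))

  # per-animal substreams: adding animals leaves existing ones untouched
  big <- simulate_mgs(mgs_sim_config(seed = 42, n_animals_per_group = 13))
  oil_ids <- sprintf("oil_%02d", 1:12)
  expect_identical(a$images[a$images$animal_id %in% oil_ids, ],
                   big$images[big$images$animal_id %in% oil_ids, ])
})

test_that("simulated scores respect the study design invariants", {
  sim <- simulate_mgs(mgs_sim_config(seed = 7))
  img <- sim$images
  expect_silent(validate_image_scores(img))
  expect_equal(length(unique(img$animal_id)), 24L)
  expect_true(all((img$week == 0) == (img$intervention == "bsl")))
  for (f in fau_labels()) expect_true(all(img[[f]] %in% c(-1L, 0L, 1L, 2L)))
})

test_that("marginal score distributions cover all three categories", {
  sim <- simulate_mgs(mgs_sim_config(seed = 1, n_animals_per_group = 40))
  expect_gt(nrow(sim$images), 1000)
  for (f in fau_labels()) {
    v <- sim$images[[f]]
    expect_setequal(sort(unique(v[v >= 0])), 0:2)
  }
})

test_that("null configuration shows no treatment difference", {
  cfg <- mgs_sim_config(seed = 9, fau_sensitivity = stats::setNames(rep(0, 5), fau_labels()),
                        fau_threshold_shift = stats::setNames(rep(0, 5), fau_labels()),
                        treatment_effect = 0, intervention_effect = 0,
                        ccl4_intervention_effect = 0, week_trend = 0)
  sim <- simulate_mgs(cfg)
  img <- sim$images
  ot <- ifelse(img$ot < 0, NA, img$ot)
  diff <- mean(ot[img$treatment == "CCl4"], na.rm = TRUE) -
    mean(ot[img$treatment == "Oil"], na.rm = TRUE)
  expect_lt(abs(diff), 0.05)
})

test_that("a fully degenerate configuration is refused", {
  expect_error(mgs_sim_config(
    fau_sensitivity = stats::setNames(rep(0, 5), fau_labels()),
    latent_corr = 0, animal_sd = 0, residual_sd = 0), "degenerate")
})

test_that("increasing the intervention effect never decreases the post-pre contrast", {
  diffs <- vapply(c(0.1, 0.3, 0.5), function(eff) {
    ds <- emulate_study(seed = 21, ccl4_intervention_effect = eff)
    sub <- as.data.frame(ds)[ds$treatment == "CCl4" & ds$week >= 1, ]
    mean(sub$ot_score[sub$intervention == "post"]) -
      mean(sub$ot_score[sub$intervention == "pre"])
  }, numeric(1))
  expect_true(all(diff(diffs) >= 0))
})

test_that("inter-criterion frame correlations are positive for pain-loaded pairs", {
  sim <- simulate_mgs(mgs_sim_config(seed = 13, n_animals_per_group = 30))
  img <- sim$images[, fau_labels()]
  img[img < 0] <- NA
  cc <- cor(img, use = "pairwise.complete.obs")
  off <- cc[lower.tri(cc)]
  expect_true(all(off > 0))
  # the strongly loaded pair correlates well above the weakly loaded one
  expect_gt(cc["ot", "ep"], cc["nb", "wc"])
})

test_that("the study preset matches the target design shape", {
  ds <- emulate_study(seed = 2)
  s <- summarize_dataset(ds)
  expect_equal(s$n_animals, 24L)
  expect_lt(abs(s$n_records - 498) / 498, 0.10)
  sim <- attr(ds, "simulation")
  rej_rate <- sum(sim$truth$rejection_counts) / (sim$truth$n_images * 5)
  expect_lt(abs(rej_rate - 749 / 4944), 0.03)
  # byte-identical CSV under a fixed seed
  t1 <- withr::local_tempfile(fileext = ".csv")
  t2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(emulate_study(seed = 4), t1)
  write_dataset(emulate_study(seed = 4), t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("ground truth bookkeeping is consistent", {
  sim <- simulate_mgs(mgs_sim_config(seed = 3))
  expect_equal(sim$truth$importance_ranking,
               names(sort(sim$config$fau_sensitivity, decreasing = TRUE)))
  expect_equal(sim$truth$n_scheduled_videos,
               24 * (3 + 4 * 3 * 2))
  expect_equal(nrow(sim$truth$latent) + sim$truth$n_missing_videos,
               sim$truth$n_scheduled_videos)
  expect_equal(nrow(sim$images), nrow(sim$truth$latent) * 8)
})
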