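# Coalition importance: Shapley axioms, the measure M, the full ranking.

test_that("Shapley attribution satisfies the axioms on canonical games", {
  players <- fau_labels()
  # additive game: phi equals the individual weights
  w <- c(ot = 3, nb = 1, cb = 2, ep = 5, wc = 0.5)
  keys <- names(random_game(players, 1))
  v_add <- vapply(keys, function(k) {
    if (k == "{}") 0 else sum(w[strsplit(k, "+", fixed = TRUE)[[1]]])
  }, numeric(1))
  expect_equal(shapley_attribution(v_add), w[players])

  # dummy-dominated game: only membership of ot matters
  v_ot <- vapply(keys, function(k) {
    6 * ("ot" %in% strsplit(k, "+", fixed = TRUE)[[1]])
  }, numeric(1))
  phi <- shapley_attribution(v_ot)
  expect_equal(phi, brute_shapley(v_ot, players))
  expect_equal(unname(phi["ot"]), 6)
  expect_equal(unname(phi[c("nb", "cb", "ep", "wc")]), rep(0, 4))

  # fully symmetric game: equal shares of v(N)
  v_sym <- vapply(keys, function(k) {
    if (k == "{}") 0 else length(strsplit(k, "+", fixed = TRUE)[[1]])^2
  }, numeric(1))
  expect_equal(unname(shapley_attribution(v_sym)), rep(25 / 5, 5))
})

test_that("Shapley matches the brute-force permutation oracle on random games", {
  players <- fau_labels()
  for (s in 1:25) {
    v <- random_game(players, s)
    phi <- shapley_attribution(v)
    expect_equal(phi, brute_shapley(v, players), tolerance = 1e-12)
    # efficiency
    expect_equal(sum(phi), unname(v[subset_key(players)]), tolerance = 1e-12)
  }
})

test_that("missing subset values are reported by name", {
  v <- random_game(fau_labels(), 2)
  expect_error(shapley_attribution(v[-5]), "missing subset")
})

test_that("the coalition measure is null, permutation- and scale-invariant as required", {
  set.seed(31)
  n <- 40
  df <- data.frame(
    animal_id = rep(sprintf("c%02d", 1:10), 4),
    treatment = "CCl4", week = rep(1:2, each = 20), day = 1,
    intervention = rep(c("pre", "post"), 20),
    ot_score = runif(n, 0, 10), nb_score = runif(n, 0, 10),
    cb_score = runif(n, 0, 10), ep_score = runif(n, 0, 10),
    wc_score = 4, stringsAsFactors = FALSE)
  ds <- make_dataset(df)
  # identical values across groups: no effect
  expect_equal(coalition_measure(ds, "wc"), 0)
  # permutation invariance
  ds_shuf <- make_dataset(df[sample(n), ])
  expect_equal(coalition_measure(ds, c("ot", "nb")),
               coalition_measure(ds_shuf, c("ot", "nb")))
  # scale invariance of the rank-based measure
  df2 <- df
  for (f in fau_labels()) df2[[paste0(f, "_score")]] <- df2[[paste0(f, "_score")]] * 7.3
  expect_equal(coalition_measure(ds, c("ot", "ep", "wc")),
               coalition_measure(make_dataset(df2), c("ot", "ep", "wc")))
  # errors
  expect_error(coalition_measure(ds, character(0)), "non-empty")
  expect_error(coalition_measure(ds, "xx"), "unknown FAU")
  expect_error(coalition_measure(ds, "ot", mobps_contrast("Oil")), "empty")
})

test_that("the full ranking covers all 31 subsets with coherent normalization", {
  ds <- emulate_study(seed = 6)
  rk <- rank_combinations(ds)
  expect_equal(nrow(rk), 31L)
  expect_equal(max(rk$M_rel), 1)
  expect_equal(rk$M_rel[1], 1)
  expect_true(all(rk$M_rel >= 0 & rk$M_rel <= 1))
  expect_true(!is.unsorted(rev(rk$M_rel)))
  # member weights sum to one within each subset
  wcols <- as.matrix(rk[, paste0("w_", fau_labels())])
  expect_equal(unname(rowSums(wcols, na.rm = TRUE)), rep(1, 31), tolerance = 1e-9)
  # full-game Shapley efficiency against the measure of the full coalition
  phi <- attr(rk, "shapley")
  expect_equal(sum(phi), rk$M[rk$subset == subset_key(fau_labels())],
               tolerance = 1e-12)
  # cliffs_delta route works and stays in [0, 1] after normalization
  rk2 <- rank_combinations(ds, kind = "cliffs_delta")
  expect_equal(nrow(rk2), 31L)
  expect_true(all(rk2$M >= 0))
})

test_that("single-criterion ranking recovers the planted ordering on the preset", {
  ds <- emulate_study(seed = 1)
  sf <- single_fau_ranking(rank_combinations(ds))
  expect_equal(sf$subset[1], "ot")
  expect_equal(sf$subset[5], "wc")
  planted <- attr(ds, "simulation")$truth$importance_ranking
  expect_gte(kendall_rank(sf$subset, planted), 0.8 - 1e-9)
})
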