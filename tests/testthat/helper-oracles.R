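# Independent oracles and small fixture builders shared across tests.

# O(n1*n2) Mann-Whitney statistic by explicit pair enumeration
# (first-sample convention: #{x > y} + 0.5 * #{x == y}).
brute_w <- function(x, y) {
  gt <- 0; eq <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) gt <- gt + 1 else if (xi == yj) eq <- eq + 1
  }
  gt + eq / 2
}

# Shapley values by brute-force averaging of marginal contributions over all
# |players|! orderings; v is a named vector keyed by subset_key().
brute_shapley <- function(v, players) {
  n <- length(players)
  perms <- gtools_permutations(players)
  phi <- stats::setNames(numeric(n), players)
  key <- function(s) if (length(s) == 0) "{}" else paste(sort(s), collapse = "+")
  for (p in perms) {
    before <- character(0)
    for (pl in p) {
      phi[pl] <- phi[pl] + v[[key(c(before, pl))]] - v[[key(before)]]
      before <- c(before, pl)
    }
  }
  phi / length(perms)
}

# all permutations of a character vector (recursion; n <= 5 here)
gtools_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in gtools_permutations(x[-i]))
      out[[length(out) + 1]] <- c(x[i], rest)
  out
}

# random coalition game on the given players (v(empty) = 0)
random_game <- function(players, seed) {
  set.seed(seed)
  n <- length(players)
  keys <- vapply(1:(2^n - 1), function(m) {
    s <- players[bitwAnd(m, 2^(seq_len(n) - 1)) > 0]
    paste(sort(s), collapse = "+")
  }, character(1))
  c(stats::setNames(0, "{}"), stats::setNames(stats::rnorm(length(keys)), keys))
}

# Pearson chi-squared by the direct sum((O - E)^2 / E) definition
direct_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# exact Kendall tau between an observed ranking and a planted order
kendall_rank <- function(observed, planted) {
  perm <- match(observed, planted)
  n <- length(perm)
  inv <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) if (perm[i] > perm[j]) inv <- inv + 1
  1 - 4 * inv / (n * (n - 1))
}

# a tiny deterministic image-score table: one animal/video per call unless
# overridden; scores recycled across `n` frames
make_images <- function(n = 8, animal_id = "a1", treatment = "Oil", week = 1,
                        day = 1, intervention = "pre",
                        ot = 1, nb = 0, cb = 0, ep = 0, wc = 0) {
  data.frame(animal_id = animal_id, treatment = treatment, week = week,
             day = day, intervention = intervention,
             ot = rep_len(ot, n), nb = rep_len(nb, n), cb = rep_len(cb, n),
             ep = rep_len(ep, n), wc = rep_len(wc, n),
             stringsAsFactors = FALSE)
}

# a small synthetic video-level dataset built directly (no generator):
# scores supplied per record via a data.frame of score columns
make_dataset <- function(df) {
  stopifnot(all(c("animal_id", "treatment", "week", "day", "intervention",
                  paste0(fau_labels(), "_score")) %in% names(df)))
  if (!"avg_picture_score" %in% names(df))
    df$avg_picture_score <- pmin(10, rowSums(df[, paste0(fau_labels(), "_score")]) / 8)
  for (f in fau_labels()) df[[paste0(f, "_n")]] <- rep(8L, nrow(df))
  df$n_images <- rep(8L, nrow(df))
  structure(df, class = c("mgs_dataset", "data.frame"),
            aggregation = list(mode = "scaled_sum", nominal_images = 8L,
                               dropped_videos = 0L))
}

# direct linear-mixed-model simulator on the video-record layout (model II
# structure: CCl4 arm, weeks 1-4, pre/post)
sim_lmm_ds <- function(seed, b0 = 3.3, b_int = 1.7, tau = 0.35, sigma2 = 1.4,
                       n_animals = 12, treatment = "CCl4") {
  set.seed(seed)
  grid <- expand.grid(animal_id = sprintf("m%02d", seq_len(n_animals)),
                      week = 1:4, day = 1:3, intervention = c("pre", "post"),
                      stringsAsFactors = FALSE)
  b <- rnorm(n_animals, 0, sqrt(tau))
  names(b) <- sprintf("m%02d", seq_len(n_animals))
  y <- b0 + b_int * (grid$intervention == "post") + b[grid$animal_id] +
    rnorm(nrow(grid), 0, sqrt(sigma2))
  df <- data.frame(grid, treatment = treatment,
                   ot_score = pmax(0, y), nb_score = 0, cb_score = 0,
                   ep_score = 0, wc_score = 0, stringsAsFactors = FALSE)
  df$ot_score <- y   # keep the exact linear response for recovery checks
  make_dataset(df)
}

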