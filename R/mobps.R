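# Coalition importance of the five grimace criteria: an effect-size measure M
# for every non-empty criterion subset, normalized to its maximum, with each
# member's contribution attributed by an exact Shapley value.

#' Canonical key for a criterion subset
#' @param members Character vector of FAU labels (possibly empty).
#' @return A single string, members sorted and joined by `+`; the empty set
#'   is the sentinel `"{}"` (R cannot index by an empty name).
#' @keywords internal
subset_key <- function(members) {
  if (length(members) == 0L) return("{}")
  paste(sort(members), collapse = "+")
}

#' Define the pre/post contrast for the coalition measure
#'
#' The coalition measure compares composite scores between pre- and
#' post-injection videos; by default within the CCl4 arm over weeks 1-4,
#' where the intervention effect is expected. Pooling both arms is available
#' because either choice is defensible for an injection-pain contrast.
#'
#' @param treatment `"CCl4"`, `"Oil"` or `"both"`.
#' @param weeks Weeks to include (baseline week 0 has no pre/post videos).
#' @return A list of class `mgs_contrast`.
#' @export
mobps_contrast <- function(treatment = c("CCl4", "Oil", "both"), weeks = 1:4) {
  treatment <- match.arg(treatment)
  structure(list(treatment = treatment, weeks = as.integer(weeks)),
            class = "mgs_contrast")
}

# Split a dataset into the two contrast groups (pre vs post composite rows).
.contrast_rows <- function(ds, contrast) {
  keep <- ds$week %in% contrast$weeks
  if (contrast$treatment != "both") keep <- keep & ds$treatment == contrast$treatment
  sub <- ds[keep, , drop = FALSE]
  g1 <- sub[sub$intervention == "pre", , drop = FALSE]
  g2 <- sub[sub$intervention == "post", , drop = FALSE]
  if (nrow(g1) == 0L) stop("contrast group 'pre' is empty (treatment = ",
                           contrast$treatment, ", weeks = ",
                           paste(contrast$weeks, collapse = ","), ")")
  if (nrow(g2) == 0L) stop("contrast group 'post' is empty (treatment = ",
                           contrast$treatment, ", weeks = ",
                           paste(contrast$weeks, collapse = ","), ")")
  list(pre = g1, post = g2)
}

#' Coalition effect-size measure M for one criterion subset
#'
#' The composite score of a record is the sum of the subset's aggregated
#' criterion scores; M is the rank-based effect size (r by default, or
#' |Cliff's delta|) of the pre/post contrast on that composite. Being
#' rank-based, M is invariant to positive rescaling of the scores.
#'
#' @param ds A `mgs_dataset`.
#' @param subset Non-empty character vector of FAU labels.
#' @param contrast A [mobps_contrast()].
#' @param kind Effect size to use, `"r"` (default) or `"cliffs_delta"`.
#' @return A single non-negative number.
#' @export
coalition_measure <- function(ds, subset, contrast = mobps_contrast(),
                              kind = c("r", "cliffs_delta")) {
  kind <- match.arg(kind)
  subset <- unique(subset)
  if (length(subset) == 0L) stop("subset must be non-empty")
  bad <- setdiff(subset, fau_labels())
  if (length(bad) > 0L) stop("unknown FAU label(s): ", paste(bad, collapse = ", "))
  g <- .contrast_rows(ds, contrast)
  cols <- paste0(subset, "_score")
  comp <- function(d) rowSums(as.matrix(d[, cols, drop = FALSE]))
  .effect_value(effect_size(comp(g$pre), comp(g$post), kind = kind))
}

#' Exact Shapley attribution for a 5-criterion coalition game
#'
#' Given the value v(S) of every subset S of the players (v(empty) = 0), the
#' Shapley value of player i is the average of its marginal contributions
#' v(S + i) - v(S) over all orderings, computed by exact subset enumeration:
#' phi_i = sum over S not containing i of |S|! (n-|S|-1)! / n! * (v(S+i) - v(S)).
#'
#' @param v Named numeric vector with one entry per subset, names built by
#'   [subset_key()] (sorted labels joined by `+`; the empty set has key
#'   `"{}"` and may be omitted, in which case v(empty) = 0).
#' @param players Character vector of player labels (default the five FAUs).
#' @return Named numeric vector phi over players; satisfies efficiency:
#'   sum(phi) = v(all players).
#' @export
shapley_attribution <- function(v, players = fau_labels()) {
  n <- length(players)
  if (!("{}" %in% names(v))) v <- c(stats::setNames(0, "{}"), v)
  masks <- 0:(2^n - 1)
  key_of_mask <- vapply(masks, function(m) {
    subset_key(players[bitwAnd(m, 2^(seq_len(n) - 1)) > 0])
  }, character(1))
  missing <- setdiff(key_of_mask, names(v))
  if (length(missing) > 0L)
    stop("v is missing subset value(s): ",
         paste(sprintf("'%s'", utils::head(missing, 5L)), collapse = ", "))
  vv <- as.numeric(v[key_of_mask])   # indexed by mask + 1
  fact <- factorial(0:n)
  phi <- stats::setNames(numeric(n), players)
  for (i in seq_len(n)) {
    bit <- 2^(i - 1)
    without <- masks[bitwAnd(masks, bit) == 0]
    s <- vapply(without, function(m) sum(bitwAnd(m, 2^(seq_len(n) - 1)) > 0), numeric(1))
    w <- fact[s + 1] * fact[n - s] / fact[n + 1]
    phi[i] <- sum(w * (vv[without + bit + 1] - vv[without + 1]))
  }
  phi
}

#' Rank all criterion combinations by coalition importance
#'
#' Scores every non-empty subset of the five criteria with
#' [coalition_measure()], normalizes to the maximum (M_rel = M / M_max) and
#' sorts descending. Each subset's member weights are the Shapley values of
#' the sub-game restricted to that subset, normalized to sum to one (equal
#' shares when the subset's value is zero).
#'
#' @inheritParams coalition_measure
#' @return An object of class `mobps_ranking`: a data.frame with columns
#'   `subset`, `size`, `M`, `M_rel` and one weight column `w_<fau>` per
#'   criterion (NA when the criterion is not a member), ordered by decreasing
#'   `M_rel`. The full-game Shapley values are attached as attribute
#'   `"shapley"`, the contrast as `"contrast"`.
#' @export
rank_combinations <- function(ds, contrast = mobps_contrast(),
                              kind = c("r", "cliffs_delta")) {
  kind <- match.arg(kind)
  faus <- fau_labels()
  n <- length(faus)
  masks <- 1:(2^n - 1)
  subsets <- lapply(masks, function(m) faus[bitwAnd(m, 2^(seq_len(n) - 1)) > 0])
  M <- vapply(subsets, function(s)
    coalition_measure(ds, s, contrast = contrast, kind = kind), numeric(1))
  names(M) <- vapply(subsets, subset_key, character(1))
  v <- c(stats::setNames(0, "{}"), M)
  M_max <- max(M)
  if (M_max <= 0) stop("all coalition measures are zero; nothing to rank")
  wt <- matrix(NA_real_, length(subsets), n, dimnames = list(NULL, paste0("w_", faus)))
  for (j in seq_along(subsets)) {
    s <- subsets[[j]]
    phi <- shapley_attribution(v[vapply(
      seq_len(2^length(s)) - 1,
      function(m) subset_key(s[bitwAnd(m, 2^(seq_along(s) - 1)) > 0]),
      character(1))], players = s)
    tot <- sum(phi)
    wt[j, paste0("w_", s)] <- if (abs(tot) < .Machine$double.eps^0.5)
      rep(1 / length(s), length(s)) else phi / tot
  }
  out <- data.frame(subset = names(M),
                    size = vapply(subsets, length, integer(1)),
                    M = M, M_rel = M / M_max, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(wt))
  ord <- order(-out$M_rel, out$size, out$subset)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("mobps_ranking", "data.frame"),
            shapley = shapley_attribution(v, players = faus),
            contrast = contrast, kind = kind)
}

#' @export
print.mobps_ranking <- function(x, n = 10L, ...) {
  ct <- attr(x, "contrast")
  cat("Coalition importance ranking (", nrow(x), " subsets, effect size ",
      attr(x, "kind"), ", pre vs post, treatment ", ct$treatment, ")\n", sep = "")
  df <- as.data.frame(x)
  df$M <- round(df$M, 3); df$M_rel <- round(df$M_rel, 3)
  for (cn in grep("^w_", names(df), value = TRUE)) df[[cn]] <- round(df[[cn]], 3)
  print(utils::head(df, n), ...)
  if (nrow(df) > n) cat("... and ", nrow(df) - n, " more subsets\n", sep = "")
  cat("Full-game Shapley attribution:\n")
  print(round(attr(x, "shapley"), 4))
  invisible(x)
}

#' @export
plot.mobps_ranking <- function(x, ...) {
  op <- graphics::par(mar = c(4, 8, 2, 1))
  on.exit(graphics::par(op))
  df <- as.data.frame(x)[nrow(x):1, ]
  graphics::barplot(df$M_rel, names.arg = df$subset, horiz = TRUE, las = 1,
                    xlab = "relative importance M / M_max",
                    main = "Criterion combination importance",
                    cex.names = 0.55, ...)
  invisible(x)
}

#' Single-criterion importance ranking
#'
#' Convenience accessor: the rows of a [rank_combinations()] result with
#' subset size one, i.e. the per-criterion importance ordering.
#'
#' @param ranking A `mobps_ranking`.
#' @return Data.frame of the five singleton rows, ordered by decreasing M_rel.
#' @export
single_fau_ranking <- function(ranking) {
  stopifnot(inherits(ranking, "mobps_ranking"))
  out <- as.data.frame(ranking)[ranking$size == 1L,
                                c("subset", "M", "M_rel"), drop = FALSE]
  rownames(out) <- NULL
  out
}
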