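# Rank-based two-sample effect sizes: Mann-Whitney W with tie-corrected
# normal approximation, the r = |z|/sqrt(N) effect size, and Cliff's delta.

#' Rank-based two-sample effect size
#'
#' Computes the Mann-Whitney statistic in the first-sample convention
#' (W = #\{x_i > y_j\} + half the number of tied pairs, identical to the `W`
#' printed by [stats::wilcox.test()]), the tie-corrected normal-approximation
#' z (no continuity correction), the effect size r = |z| / sqrt(n1 + n2),
#' and Cliff's delta. r is comparable across groups of different sizes and
#' distributions, which is what the coalition importance measure requires.
#'
#' @param x,y Numeric samples (first and second group).
#' @param kind Which effect size [coalition_measure()] should read from the
#'   result; recorded on the object.
#' @return An object of class `effect_size`: list with `statistic_w`, `z`,
#'   `r`, `cliffs_delta`, `p` (two-sided normal approximation), `n1`, `n2`,
#'   `kind`.
#' @examples
#' effect_size(c(1, 2), c(3, 4, 5))   # W = 0, Cliff's delta = -1
#' @export
effect_size <- function(x, y, kind = c("r", "cliffs_delta")) {
  kind <- match.arg(kind)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  rk <- rank(c(x, y))
  W <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tt <- table(c(x, y))
  tie_term <- sum(tt^3 - tt)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  z <- if (sigma2 <= 0) 0 else (W - n1 * n2 / 2) / sqrt(sigma2)
  r <- abs(z) / sqrt(N)
  # tied cross-pairs: sum over shared values of count_x * count_y
  tx <- table(x); ty <- table(y)
  shared <- intersect(names(tx), names(ty))
  ties <- sum(as.numeric(tx[shared]) * as.numeric(ty[shared]))
  gt <- W - ties / 2
  lt <- n1 * n2 - gt - ties
  structure(list(
    statistic_w = W, z = z, r = r,
    cliffs_delta = (gt - lt) / (n1 * n2),
    p = 2 * stats::pnorm(-abs(z)),
    n1 = n1, n2 = n2, kind = kind), class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("W = %.4g, z = %.3f, r = %.3f, Cliff's delta = %.3f (n1 = %d, n2 = %d, p = %.4g)\n",
              x$statistic_w, x$z, x$r, x$cliffs_delta, x$n1, x$n2, x$p))
  invisible(x)
}

# numeric value the coalition measure uses
.effect_value <- function(es) {
  switch(es$kind, r = es$r, cliffs_delta = abs(es$cliffs_delta))
}
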