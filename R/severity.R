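# Severity discretization and the surrounding statistics: class count tables
# with chi-squared tests and pairwise post-hocs, Mann-Whitney contrasts,
# bootstrap median confidence intervals, inter-criterion correlations and
# normality checks.

.severity_levels <- c("mild", "moderate", "severe")

#' Discretize an aggregated score into a severity class
#'
#' mild: score < 3; moderate: 3 <= score <= 6; severe: score > 6 (the
#' boundaries 3 and 6 are moderate). The thresholds presume the multi-frame
#' aggregated score scale (0-16 for `scaled_sum` over 8 frames).
#'
#' @param score Non-negative numeric vector.
#' @return Factor with levels mild, moderate, severe.
#' @examples
#' classify_severity(c(2.99, 3, 6, 6.01))
#' @export
classify_severity <- function(score) {
  if (any(!is.finite(score)) || any(score < 0))
    stop("scores must be finite and non-negative")
  cls <- ifelse(score < 3, "mild", ifelse(score <= 6, "moderate", "severe"))
  factor(cls, levels = .severity_levels)
}

#' Severity class counts by treatment and intervention
#'
#' Counts video records per (treatment, intervention, severity class) using
#' the orbital tightening score. The grand total equals the record count.
#'
#' @param ds A `mgs_dataset`.
#' @param score_col Column to classify (default `"ot_score"`).
#' @return A 3-dimensional table `treatment x intervention x class`.
#' @export
severity_counts <- function(ds, score_col = "ot_score") {
  if (nrow(ds) == 0L)
    return(table(treatment = factor(character(), .treatment_levels),
                 intervention = factor(character(), .intervention_levels),
                 class = factor(character(), .severity_levels)))
  table(treatment = factor(ds$treatment, .treatment_levels),
        intervention = factor(ds$intervention, .intervention_levels),
        class = classify_severity(ds[[score_col]]))
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson chi-squared without continuity correction (the correction would
#' only apply to 2x2 tables and is not used anywhere in this analysis);
#' df = (rows - 1)(cols - 1).
#'
#' @param tab Integer matrix of counts.
#' @return List with `statistic`, `df`, `p`, `expected`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  zr <- which(rowSums(tab) == 0)
  if (length(zr) > 0L)
    stop("zero marginal in row ", paste(zr, collapse = ", "))
  zc <- which(colSums(tab) == 0)
  if (length(zc) > 0L)
    stop("zero marginal in column ", paste(zc, collapse = ", "))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, expected = ht$expected)
}

#' Pairwise severity-class post-hoc tests
#'
#' For each pair of severity classes, tests whether the intervention profile
#' (bsl/pre/post counts) differs between the two classes: a Pearson
#' chi-squared test (no continuity correction) on the interventions x
#' 2-classes sub-table, with p-values adjusted for the three comparisons
#' (default FDR). Pairs where some expected count falls below 5 are flagged
#' in `low_expected`; `fisher = TRUE` switches those pairs to Fisher's exact
#' test instead.
#'
#' @param tab Matrix of counts, interventions in rows, severity classes in
#'   columns (one treatment arm; see [severity_report()]).
#' @param adjust Multiplicity adjustment: `"fdr"`, `"holm"` or `"bonferroni"`.
#' @param fisher Use Fisher's exact test for pairs with low expected counts.
#' @return Data.frame: `pair`, `statistic` (NA under Fisher), `p_raw`,
#'   `p_adj`, `low_expected`, `method`.
#' @export
posthoc_pairwise <- function(tab, adjust = c("fdr", "holm", "bonferroni"),
                             fisher = FALSE) {
  adjust <- match.arg(adjust)
  tab <- as.matrix(tab)
  if (ncol(tab) < 2L) stop("need at least two severity classes")
  prs <- utils::combn(colnames(tab), 2L, simplify = FALSE)
  rows <- lapply(prs, function(pr) {
    sub <- tab[, pr, drop = FALSE]
    keep <- rowSums(sub) > 0
    sub <- sub[keep, , drop = FALSE]
    ht0 <- suppressWarnings(stats::chisq.test(sub, correct = FALSE))
    low <- any(ht0$expected < 5)
    if (fisher && low) {
      ht <- stats::fisher.test(sub, workspace = 2e6)
      data.frame(pair = paste(pr, collapse = "/"),
                 statistic = NA_real_, p_raw = ht$p.value,
                 low_expected = low, method = "fisher",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(pair = paste(pr, collapse = "/"),
                 statistic = unname(ht0$statistic), p_raw = ht0$p.value,
                 low_expected = low, method = "chisq",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = adjust)
  out[, c("pair", "statistic", "p_raw", "p_adj", "low_expected", "method")]
}

#' Severity report for a dataset
#'
#' Builds the full severity analysis: the treatment x intervention x class
#' count table, a per-treatment chi-squared test of the intervention x class
#' sub-table, and the pairwise class post-hocs.
#'
#' @param ds A `mgs_dataset`.
#' @param adjust Post-hoc adjustment method (see [posthoc_pairwise()]).
#' @param score_col Score column to classify (default `"ot_score"`).
#' @return Object of class `severity_report`: `counts` (3-d table),
#'   `per_treatment` (list per arm with `table`, `chi2`, `posthoc`),
#'   `adjust`.
#' @export
severity_report <- function(ds, adjust = "fdr", score_col = "ot_score") {
  counts <- severity_counts(ds, score_col = score_col)
  per <- lapply(.treatment_levels, function(trt) {
    tab <- counts[trt, , ]
    list(table = tab,
         chi2 = chi_square(tab),
         posthoc = posthoc_pairwise(tab, adjust = adjust))
  })
  names(per) <- .treatment_levels
  structure(list(counts = counts, per_treatment = per, adjust = adjust,
                 score_col = score_col), class = "severity_report")
}

#' @export
print.severity_report <- function(x, ...) {
  cat("Severity classification (", x$score_col, "; thresholds 3 and 6)\n", sep = "")
  for (trt in names(x$per_treatment)) {
    p <- x$per_treatment[[trt]]
    cat("\n", trt, ":\n", sep = "")
    print(p$table)
    cat(sprintf("  chi2 = %.4g, df = %d, p = %.4g\n",
                p$chi2$statistic, p$chi2$df, p$chi2$p))
    ph <- p$posthoc
    ph$p_raw <- signif(ph$p_raw, 3); ph$p_adj <- signif(ph$p_adj, 3)
    ph$statistic <- round(ph$statistic, 3)
    cat("  pairwise post-hoc (", x$adjust, "):\n", sep = "")
    print(ph, row.names = FALSE)
  }
  invisible(x)
}

#' Mann-Whitney contrast between two record selections
#'
#' Selects two groups of records by named filters (e.g.
#' `list(treatment = "CCl4", week = 0)`), extracts a score column and runs
#' the rank-based [effect_size()] (two-sided). The selector definitions are
#' recorded on the result for provenance.
#'
#' @param ds A `mgs_dataset`.
#' @param group_a,group_b Named lists of column = value(s) filters.
#' @param score_col Score column (default `"ot_score"`).
#' @return An `effect_size` object with attribute `"selectors"`.
#' @export
mann_whitney_contrast <- function(ds, group_a, group_b, score_col = "ot_score") {
  sel <- function(flt, label) {
    keep <- rep(TRUE, nrow(ds))
    for (nm in names(flt)) {
      if (!nm %in% names(ds)) stop("selector ", label, ": unknown column '", nm, "'")
      keep <- keep & ds[[nm]] %in% flt[[nm]]
    }
    v <- ds[[score_col]][keep]
    if (length(v) == 0L)
      stop("selector ", label, " matches no records: ",
           paste(sprintf("%s=%s", names(flt),
                         vapply(flt, function(z) paste(z, collapse = "|"),
                                character(1))), collapse = ", "))
    v
  }
  es <- effect_size(sel(group_a, "group_a"), sel(group_b, "group_b"))
  attr(es, "selectors") <- list(group_a = group_a, group_b = group_b,
                                score_col = score_col)
  es
}

#' Bootstrap median with percentile confidence interval
#'
#' Resamples with replacement (same size), takes the median of each
#' resample, and reports the median of the bootstrap distribution with the
#' percentile 2.5/97.5 interval. Seeded and deterministic.
#'
#' @param x Non-empty numeric sample.
#' @param n_boot Number of resamples (default 10000).
#' @param seed Seed.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `boot_median`: `median`, `ci_low`, `ci_high`,
#'   `n`, `n_boot`, `seed`.
#' @export
bootstrap_median <- function(x, n_boot = 10000L, seed = 1L, conf = 0.95) {
  x <- as.numeric(x)
  if (length(x) == 0L) stop("sample must be non-empty")
  if (anyNA(x)) stop("sample must not contain NA")
  set.seed(seed)
  n <- length(x)
  meds <- apply(matrix(sample(x, n * n_boot, replace = TRUE), nrow = n),
                2, stats::median)
  a <- (1 - conf) / 2
  qs <- unname(stats::quantile(meds, c(a, 1 - a), type = 7))
  structure(list(median = unname(stats::median(meds)),
                 ci_low = qs[1], ci_high = qs[2],
                 n = n, n_boot = as.integer(n_boot), seed = seed, conf = conf),
            class = "boot_median")
}

#' @export
print.boot_median <- function(x, ...) {
  cat(sprintf("bootstrap median = %.3f, %g%% CI [%.3f, %.3f] (n = %d, %d resamples)\n",
              x$median, 100 * x$conf, x$ci_low, x$ci_high, x$n, x$n_boot))
  invisible(x)
}

#' Inter-criterion correlation matrix
#'
#' Pairwise correlations of the five aggregated criterion scores within one
#' treatment arm, pooled over weeks and interventions.
#'
#' @param ds A `mgs_dataset`.
#' @param treatment `"Oil"` or `"CCl4"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Symmetric 5x5 matrix with unit diagonal (rows/columns of constant
#'   criteria are NA, with a warning).
#' @export
correlation_matrix <- function(ds, treatment = c("CCl4", "Oil"),
                               method = c("pearson", "spearman")) {
  treatment <- match.arg(treatment)
  method <- match.arg(method)
  sub <- ds[ds$treatment == treatment, , drop = FALSE]
  if (nrow(sub) < 3L) stop("need at least 3 records for treatment ", treatment)
  m <- as.matrix(sub[, paste0(fau_labels(), "_score")])
  colnames(m) <- rownames(m) <- NULL
  const <- apply(m, 2, stats::sd) == 0
  cc <- suppressWarnings(stats::cor(m, method = method))
  dimnames(cc) <- list(fau_labels(), fau_labels())
  if (any(const)) {
    warning("constant criterion column(s): ",
            paste(fau_labels()[const], collapse = ", "),
            "; correlations reported as NA")
    cc[const, ] <- NA_real_
    cc[, const] <- NA_real_
  }
  diag(cc)[!const] <- 1
  cc
}

#' Normality check: Shapiro-Wilk and quantile-quantile pairs
#'
#' @param x Numeric sample, 3 <= n <= 5000, not constant.
#' @return List with `shapiro_p`, `statistic` and `qq` (data.frame of
#'   theoretical and sample quantiles for plotting).
#' @export
normality_check <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L || n > 5000L) stop("sample size must be in [3, 5000], got ", n)
  if (stats::sd(x) == 0) stop("sample is constant; normality is undefined")
  sw <- stats::shapiro.test(x)
  qq <- stats::qqnorm(x, plot.it = FALSE)
  list(shapiro_p = sw$p.value, statistic = unname(sw$statistic),
       qq = data.frame(theoretical = sort(qq$x), sample = sort(qq$y)))
}
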