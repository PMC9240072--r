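# Random-intercept linear mixed-effects models of the orbital tightening
# score: a between-treatments model over the full design and within-treatment
# models per arm over weeks 1-4, with REML estimation, variance
# decomposition and ICC.

.model_specs <- list(
  I = list(
    label = "between-treatments",
    formula = ot_score ~ treatment * intervention + day * treatment +
      day * intervention + (1 | animal_id) + (1 | week / day),
    filter = function(ds) ds),
  II = list(
    label = "within-treatment CCl4",
    formula = ot_score ~ week * intervention + (1 | animal_id),
    filter = function(ds) ds[ds$treatment == "CCl4" & ds$week >= 1L, , drop = FALSE]),
  III = list(
    label = "within-treatment Oil",
    formula = ot_score ~ week * intervention + (1 | animal_id),
    filter = function(ds) ds[ds$treatment == "Oil" & ds$week >= 1L, , drop = FALSE])
)

#' Fit a random-intercept mixed model of orbital tightening
#'
#' Three model layouts are available:
#' \describe{
#'   \item{`"I"`}{between-treatments over the full dataset (weeks 0-4):
#'     fixed effects treatment, intervention, day and their pairwise
#'     interactions; random intercepts for animal and for day nested in week.
#'     Reference levels: Oil, pre, day 1.}
#'   \item{`"II"`}{within the CCl4 arm, weeks 1-4 (week 0 excluded: the
#'     intervention variable is constant there): fixed effects week
#'     (categorical, reference week 1), intervention and their interaction;
#'     random intercept for animal.}
#'   \item{`"III"`}{as `"II"` for the Oil arm.}
#' }
#' Estimation is REML via \pkg{lme4}/\pkg{lmerTest}. Confidence intervals and
#' p-values use Satterthwaite degrees of freedom by default (a
#' small-sample approximation in the same family as Kenward-Roger; point
#' estimates are unaffected by the choice), or a normal approximation.
#' Singular fits (a variance component estimated at zero) are returned with
#' a boundary flag, not errored.
#'
#' @param ds A `mgs_dataset` aggregated with the orbital tightening score.
#' @param model `"I"`, `"II"` or `"III"`.
#' @param df_method `"satterthwaite"` (default) or `"normal"`.
#' @return Object of class `mgs_mixed`: `model`, `label`, `coefficients`
#'   (data.frame: term, estimate, se, df, ci_low, ci_high, p),
#'   `variance_components` (named tau vector), `sigma2`, `icc`,
#'   `variance_shares` (percent, residual included), `boundary` (logical),
#'   `n_obs`, `fit` (the underlying `lmerModLmerTest`).
#' @export
fit_ot_model <- function(ds, model = c("I", "II", "III"),
                         df_method = c("satterthwaite", "normal")) {
  model <- match.arg(model)
  df_method <- match.arg(df_method)
  spec <- .model_specs[[model]]
  dat <- spec$filter(as.data.frame(ds))
  if (nrow(dat) == 0L) stop("model ", model, ": filtered data are empty")
  dat$treatment <- factor(dat$treatment, levels = c("Oil", "CCl4"))
  dat$intervention <- if (model == "I")
    factor(dat$intervention, levels = c("pre", "post", "bsl"))
  else factor(dat$intervention, levels = c("pre", "post"))
  dat$day <- factor(dat$day)
  dat$week <- factor(dat$week)
  dat$animal_id <- factor(dat$animal_id)

  fit <- suppressMessages(lmerTest::lmer(spec$formula, data = dat, REML = TRUE))
  boundary <- lme4::isSingular(fit, tol = 1e-5)

  sm <- summary(fit, ddf = if (df_method == "satterthwaite") "Satterthwaite"
                           else "lme4")
  ct <- as.data.frame(sm$coefficients)
  est <- ct[, "Estimate"]
  se <- ct[, "Std. Error"]
  if (df_method == "satterthwaite") {
    dfree <- ct[, "df"]
    p <- ct[, "Pr(>|t|)"]
    q <- stats::qt(0.975, dfree)
  } else {
    dfree <- rep(Inf, nrow(ct))
    z <- est / se
    p <- 2 * stats::pnorm(-abs(z))
    q <- rep(stats::qnorm(0.975), nrow(ct))
  }
  coefs <- data.frame(term = rownames(ct), estimate = est, se = se,
                      df = dfree, ci_low = est - q * se, ci_high = est + q * se,
                      p = p, row.names = NULL, stringsAsFactors = FALSE)

  vc <- as.data.frame(lme4::VarCorr(fit))
  res_row <- vc$grp == "Residual"
  tau <- stats::setNames(vc$vcov[!res_row], vc$grp[!res_row])
  sigma2 <- vc$vcov[res_row]
  total <- sum(tau) + sigma2
  shares <- c(tau, Residual = sigma2) / total * 100

  structure(list(
    model = model, label = spec$label, df_method = df_method,
    coefficients = coefs,
    variance_components = tau, sigma2 = sigma2,
    icc = sum(tau) / total,
    variance_shares = shares,
    boundary = boundary, n_obs = nrow(dat),
    n_animals = length(unique(dat$animal_id)),
    fit = fit), class = "mgs_mixed")
}

#' @export
print.mgs_mixed <- function(x, ...) {
  cat("Mixed-effects model ", x$model, " (", x$label, "), REML, ",
      x$n_obs, " records / ", x$n_animals, " animals",
      if (x$boundary) " [boundary fit: some variance component at 0]",
      "\n", sep = "")
  cf <- x$coefficients
  cf[, -1] <- round(cf[, -1], 3)
  print(cf, row.names = FALSE)
  cat(sprintf("Variance components: %s; sigma2 = %.3f; ICC = %.3f\n",
              paste(sprintf("tau_%s = %.3f", names(x$variance_components),
                            x$variance_components), collapse = ", "),
              x$sigma2, x$icc))
  invisible(x)
}

#' @export
coef.mgs_mixed <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
summary.mgs_mixed <- function(object, ...) {
  list(model = object$model, coefficients = object$coefficients,
       variance = variance_decomposition(object), boundary = object$boundary)
}

#' Variance decomposition of a mixed-model fit
#'
#' Expresses each random-effect variance tau and the residual variance as a
#' percentage of the total, and the intra-class correlation
#' ICC = sum(tau) / (sum(tau) + sigma2). Accepts either a fitted `mgs_mixed`
#' or raw `tau` / `sigma2` values.
#'
#' @param fit A `mgs_mixed`, or a numeric vector of tau values.
#' @param sigma2 Residual variance (required when `fit` is a numeric vector).
#' @return List with `tau`, `sigma2`, `shares` (percent, named, residual
#'   last) and `icc`.
#' @export
variance_decomposition <- function(fit, sigma2 = NULL) {
  if (inherits(fit, "mgs_mixed")) {
    tau <- fit$variance_components
    sigma2 <- fit$sigma2
  } else {
    tau <- fit
    if (is.null(sigma2)) stop("sigma2 is required with raw tau values")
  }
  if (any(tau < 0) || sigma2 <= 0) stop("tau must be >= 0 and sigma2 > 0")
  total <- sum(tau) + sigma2
  shares <- c(tau, Residual = sigma2) / total * 100
  list(tau = tau, sigma2 = sigma2, shares = shares, icc = sum(tau) / total)
}

#' Ordered coefficient table for reporting
#'
#' Deterministic presentation order — intercept, then main effects, then
#' interactions (by interaction order, then alphabetically) — with a sign
#' annotation and significance marker, as used for coefficient plots.
#'
#' @param fit A `mgs_mixed`.
#' @param alpha Significance threshold for the marker (default 0.05).
#' @return Data.frame: `term`, `estimate`, `ci_low`, `ci_high`, `p`, `sign`
#'   (`"+"`/`"-"`), `significant` (logical).
#' @export
coefficient_table <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "mgs_mixed"))
  cf <- fit$coefficients
  if (nrow(cf) == 0L) stop("empty fit: no coefficients")
  order_key <- function(term) {
    if (term == "(Intercept)") return(0L)
    1L + lengths(regmatches(term, gregexpr(":", term, fixed = TRUE)))
  }
  k <- vapply(cf$term, order_key, integer(1))
  cf <- cf[order(k, cf$term), , drop = FALSE]
  data.frame(term = cf$term, estimate = cf$estimate,
             ci_low = cf$ci_low, ci_high = cf$ci_high, p = cf$p,
             sign = ifelse(cf$estimate >= 0, "+", "-"),
             significant = cf$p < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
plot.mgs_mixed <- function(x, ...) {
  tb <- coefficient_table(x)
  n <- nrow(tb)
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  idx <- rev(seq_len(n))
  graphics::plot(tb$estimate, idx, xlim = range(tb$ci_low, tb$ci_high),
                 yaxt = "n", ylab = "", xlab = "estimate (95% CI)",
                 pch = 19, col = ifelse(tb$estimate >= 0, "steelblue", "firebrick"),
                 main = paste("Model", x$model, "coefficients"), ...)
  graphics::segments(tb$ci_low, idx, tb$ci_high, idx)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = idx, labels = tb$term, las = 1, cex.axis = 0.7)
  invisible(x)
}
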