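# L1-penalized ranking of the grimace criteria: the average picture score is
# regressed on the five (strongly collinear) criterion scores and their
# interactions with week and pre/post intervention; coefficients at the
# one-standard-error penalty are ranked by magnitude, per treatment arm.

#' Build the penalized-regression design for one treatment arm
#'
#' Response: the average picture score. Predictors: the five criterion scores
#' plus their interactions with week (numeric 1-4 by default, or categorical
#' contrasts) and with the post-intervention indicator. Baseline week 0 is
#' excluded (the intervention variable is constant there, making the design
#' rank deficient). All predictor columns are standardized to zero mean and
#' unit variance so coefficient magnitudes are comparable; columns constant
#' after filtering are dropped with a warning.
#'
#' @param ds A `mgs_dataset`.
#' @param treatment `"Oil"` or `"CCl4"`.
#' @param week_numeric Treat week as numeric 1-4 in the interactions
#'   (default); otherwise one interaction column per week level > 1.
#' @return List with `y` (response), `x` (standardized predictor matrix),
#'   `names` (colnames of `x`), `scaling` (data.frame of the centers/scales),
#'   `dropped` (names of dropped constant columns).
#' @export
build_design <- function(ds, treatment = c("CCl4", "Oil"), week_numeric = TRUE) {
  treatment <- match.arg(treatment)
  sub <- ds[ds$treatment == treatment & ds$week >= 1L, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no week 1-4 records for treatment ", treatment)
  faus <- fau_labels()
  post <- as.numeric(sub$intervention == "post")
  base <- as.matrix(sub[, paste0(faus, "_score")])
  colnames(base) <- faus
  if (week_numeric) {
    wk <- as.numeric(sub$week)
    x <- cbind(base, base * wk, base * post)
    colnames(x) <- c(faus, paste0(faus, ":week"), paste0(faus, ":post"))
  } else {
    wk_f <- factor(sub$week)
    wcols <- stats::model.matrix(~ wk_f)[, -1, drop = FALSE]
    colnames(wcols) <- paste0("week", levels(wk_f)[-1])
    inter <- do.call(cbind, lapply(seq_len(ncol(wcols)), function(j) {
      m <- base * wcols[, j]
      colnames(m) <- paste0(faus, ":", colnames(wcols)[j])
      m
    }))
    x <- cbind(base, inter, base * post)
    colnames(x) <- c(faus, colnames(inter), paste0(faus, ":post"))
  }
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0 | !is.finite(sds)]
  if (length(dropped) > 0L) {
    warning("dropping constant predictor column(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, !(colnames(x) %in% dropped), drop = FALSE]
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  x <- scale(x, center = ctr, scale = scl)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  list(y = sub$avg_picture_score, x = x, names = colnames(x),
       scaling = data.frame(name = colnames(x), center = ctr, scale = scl,
                            row.names = NULL),
       dropped = dropped)
}

#' LASSO with seeded 10-fold cross-validation and the one-SE rule
#'
#' Fits the L1 path (alpha = 1) over a 100-point log-spaced penalty grid from
#' the smallest penalty zeroing all coefficients down by a factor 1e-4,
#' cross-validates the mean squared error with a seeded fold assignment, and
#' selects `lambda_1se`, the largest penalty whose CV error is within one
#' standard error of the minimum — the most parsimonious near-optimal model.
#' The path itself is computed by \pkg{glmnet}; design construction, scaling,
#' fold assignment, CV aggregation and the one-SE rule are owned here.
#'
#' @param y Response vector.
#' @param x Predictor matrix (already standardized; see [build_design()]).
#' @param folds Number of CV folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param lambda Optional penalty grid (descending); default as described.
#' @return Object of class `mgs_lasso`: `lambda` (grid), `cv_mean`, `cv_se`,
#'   `lambda_min`, `lambda_1se`, `coefficients` (named vector at
#'   `lambda_1se`, intercept included as `(Intercept)`), `coefficients_min`,
#'   `folds`, `seed`, and the underlying `glmnet` path fit as `path`.
#' @export
fit_lasso_cv <- function(y, x, folds = 10L, seed = 1L, lambda = NULL) {
  n <- length(y)
  if (n < 2L * folds) stop("need at least ", 2L * folds, " observations for ",
                           folds, "-fold cross-validation")
  if (nrow(x) != n) stop("x and y dimensions disagree")
  if (is.null(lambda)) {
    # smallest penalty with all coefficients zero: max |x' (y - mean y)| / n
    lmax <- max(abs(crossprod(x, y - mean(y)))) / n
    lambda <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 100L))
  }
  path <- glmnet::glmnet(x, y, alpha = 1, lambda = lambda,
                         standardize = FALSE, thresh = 1e-10)
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = n))
  mse <- matrix(NA_real_, folds, length(lambda))
  for (f in seq_len(folds)) {
    tr <- foldid != f
    fit_f <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], alpha = 1,
                            lambda = lambda, standardize = FALSE, thresh = 1e-10)
    pred <- stats::predict(fit_f, newx = x[!tr, , drop = FALSE], s = lambda)
    mse[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  nfold <- tabulate(foldid, folds)
  cv_mean <- as.numeric(colSums(mse * nfold) / n)
  cv_se <- apply(mse, 2, stats::sd) / sqrt(folds)
  i_min <- which.min(cv_mean)
  lambda_min <- lambda[i_min]
  ok <- cv_mean <= cv_mean[i_min] + cv_se[i_min]
  lambda_1se <- max(lambda[ok])
  coef_at <- function(s) {
    b <- suppressWarnings(
      as.matrix(stats::coef(path, s = s, exact = TRUE, x = x, y = y)))
    stats::setNames(as.numeric(b), rownames(b))
  }
  structure(list(
    lambda = lambda, cv_mean = cv_mean, cv_se = cv_se,
    lambda_min = lambda_min, lambda_1se = lambda_1se,
    coefficients = coef_at(lambda_1se),
    coefficients_min = coef_at(lambda_min),
    folds = folds, seed = seed, n = n, path = path), class = "mgs_lasso")
}

#' Fit the criterion-importance LASSO for one treatment arm
#'
#' Convenience wrapper: [build_design()] then [fit_lasso_cv()].
#'
#' @inheritParams build_design
#' @inheritParams fit_lasso_cv
#' @return A `mgs_lasso` with the treatment recorded.
#' @export
mgs_lasso <- function(ds, treatment = c("CCl4", "Oil"), folds = 10L,
                      seed = 1L, week_numeric = TRUE) {
  treatment <- match.arg(treatment)
  d <- build_design(ds, treatment, week_numeric = week_numeric)
  fit <- fit_lasso_cv(d$y, d$x, folds = folds, seed = seed)
  fit$treatment <- treatment
  fit$design_names <- d$names
  fit$dropped <- d$dropped
  fit
}

#' @export
print.mgs_lasso <- function(x, ...) {
  cat("L1-penalized criterion regression",
      if (!is.null(x$treatment)) paste0(" (", x$treatment, ")"), "\n", sep = "")
  cat(sprintf("  n = %d, %d-fold CV (seed %d): lambda_min = %.4g, lambda_1se = %.4g\n",
              x$n, x$folds, x$seed, x$lambda_min, x$lambda_1se))
  rk <- rank_coefficients(x)
  if (nrow(rk) == 0L) {
    cat("  all coefficients zero at lambda_1se\n")
  } else {
    cat("  nonzero coefficients at lambda_1se (|beta| descending):\n")
    print(transform(rk, beta = round(beta, 4)), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.mgs_lasso <- function(object, which = c("1se", "min"), ...) {
  which <- match.arg(which)
  if (which == "1se") object$coefficients else object$coefficients_min
}

#' Rank nonzero LASSO coefficients by magnitude
#'
#' Orders the (intercept-free) coefficients at `lambda_1se` by decreasing
#' absolute value; ties broken alphabetically by predictor name. On an
#' all-zero fit the ranking is empty.
#'
#' @param fit A `mgs_lasso`.
#' @return Data.frame with columns `name`, `beta`.
#' @export
rank_coefficients <- function(fit) {
  stopifnot(inherits(fit, "mgs_lasso"))
  b <- fit$coefficients
  b <- b[names(b) != "(Intercept)"]
  b <- b[b != 0]
  if (length(b) == 0L)
    return(data.frame(name = character(), beta = numeric()))
  ord <- order(-abs(b), names(b))
  data.frame(name = names(b)[ord], beta = as.numeric(b[ord]),
             stringsAsFactors = FALSE)
}
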