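# End-to-end orchestration: ingest or simulate, aggregate, rank criterion
# importance two ways, fit the mixed models, run the severity statistics, and
# assemble one reproducible report.

.stage <- function(name, expr, log) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  log(sprintf("stage %-12s done in %.2fs", name, proc.time()[["elapsed"]] - t0))
  res
}

# small deterministic fingerprint of the analysis input
.fingerprint <- function(ds) {
  sprintf("records=%d animals=%d ot_sum=%.6f", nrow(ds),
          length(unique(ds$animal_id)), sum(ds$ot_score))
}

#' Run the full grimace-scale analysis pipeline
#'
#' Executes all stages in order — ingest (or simulate), aggregate, dataset
#' summary, coalition importance ranking, per-arm LASSO coefficient ranking,
#' the three mixed models, severity classification with post-hocs, baseline
#' and week-1 Mann-Whitney contrasts, per-stratum bootstrap medians and
#' inter-criterion correlations — and collects the results in one report.
#' Identical inputs and seeds give an identical report.
#'
#' @param images Data.frame of per-image scores (see [read_image_scores()]),
#'   or `NULL` to simulate the calibrated study preset.
#' @param input Path to a raw per-image CSV, used when `images` is `NULL`
#'   and not simulating.
#' @param sim_seed Seed for the synthetic preset (used when no input given).
#' @param aggregate Aggregation mode for [aggregate_videos()].
#' @param contrast Coalition contrast, see [mobps_contrast()].
#' @param effect_kind Effect size for the coalition measure.
#' @param cv_seed Seed for LASSO fold assignment.
#' @param boot_seed Seed for bootstrap resampling.
#' @param n_boot Bootstrap resamples per stratum (default 10000).
#' @param adjust Post-hoc adjustment method.
#' @param df_method Mixed-model degrees-of-freedom method.
#' @param quiet Suppress per-stage log lines.
#' @return Object of class `mgs_report` (a named list; see
#'   [write_report()] for serialisation).
#' @export
run_mgs_pipeline <- function(images = NULL, input = NULL, sim_seed = 1L,
                             aggregate = "scaled_sum",
                             contrast = mobps_contrast(),
                             effect_kind = "r",
                             cv_seed = 1L, boot_seed = 1L, n_boot = 10000L,
                             adjust = "fdr",
                             df_method = "satterthwaite",
                             quiet = FALSE) {
  log <- if (quiet) function(...) invisible() else function(msg) message(msg)
  source_desc <- if (!is.null(images)) "supplied images"
    else if (!is.null(input)) input
    else sprintf("synthetic preset (seed %d)", sim_seed)

  images <- .stage("ingest", {
    if (!is.null(images)) validate_image_scores(images)
    else if (!is.null(input)) read_image_scores(input)
    else simulate_mgs(mgs_sim_config(seed = sim_seed))$images
  }, log)

  ds <- .stage("aggregate", suppressWarnings(
    aggregate_videos(images, mode = aggregate)), log)
  log(sprintf("input fingerprint: %s", .fingerprint(ds)))

  summary_ds <- .stage("summary", summarize_dataset(ds), log)

  mobps <- .stage("mobps", rank_combinations(ds, contrast = contrast,
                                             kind = effect_kind), log)

  lasso <- .stage("lasso", lapply(
    stats::setNames(.treatment_levels, .treatment_levels),
    function(trt) mgs_lasso(ds, trt, seed = cv_seed)), log)

  models <- .stage("mixed", lapply(
    stats::setNames(c("I", "II", "III"), c("I", "II", "III")),
    function(m) fit_ot_model(ds, m, df_method = df_method)), log)

  severity <- .stage("severity", severity_report(ds, adjust = adjust), log)

  contrasts <- .stage("contrasts", list(
    bsl_vs_post_week1 = lapply(
      stats::setNames(.treatment_levels, .treatment_levels),
      function(trt) mann_whitney_contrast(
        ds,
        group_a = list(treatment = trt, week = 0L, intervention = "bsl"),
        group_b = list(treatment = trt, week = 1L, intervention = "post"))),
    baseline_between_treatments = mann_whitney_contrast(
      ds,
      group_a = list(treatment = "Oil", week = 0L),
      group_b = list(treatment = "CCl4", week = 0L))), log)

  boots <- .stage("bootstrap", {
    strata <- unique(ds[, c("treatment", "week", "intervention")])
    strata <- strata[order(strata$treatment, strata$week, strata$intervention), ]
    res <- lapply(seq_len(nrow(strata)), function(i) {
      s <- strata[i, ]
      v <- ds$ot_score[ds$treatment == s$treatment & ds$week == s$week &
                         ds$intervention == s$intervention]
      b <- bootstrap_median(v, n_boot = n_boot,
                            seed = boot_seed + 13L * i)
      cbind(s, median = b$median, ci_low = b$ci_low, ci_high = b$ci_high,
            n = b$n)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  }, log)

  correlations <- .stage("correlations", lapply(
    stats::setNames(.treatment_levels, .treatment_levels),
    function(trt) correlation_matrix(ds, trt)), log)

  structure(list(
    schema_version = "1",
    meta = list(source = source_desc, aggregation = aggregate,
                effect_kind = effect_kind,
                contrast = unclass(contrast),
                seeds = list(simulation = if (is.null(input)) sim_seed else NULL,
                             cv = cv_seed, bootstrap = boot_seed),
                n_boot = n_boot, adjust = adjust, df_method = df_method,
                fingerprint = .fingerprint(ds)),
    dataset = ds,
    summary = summary_ds,
    importance_mobps = mobps,
    importance_lasso = lasso,
    mixed_models = models,
    severity = severity,
    contrasts = contrasts,
    bootstrap_medians = boots,
    correlations = correlations), class = "mgs_report")
}

#' @export
print.mgs_report <- function(x, ...) {
  cat("MGS analysis report (schema ", x$schema_version, ")\n", sep = "")
  cat("  source: ", x$meta$source, "; aggregation: ", x$meta$aggregation,
      "\n", sep = "")
  cat("  ", x$summary$n_records, " records, ", x$summary$n_animals,
      " animals\n", sep = "")
  top <- single_fau_ranking(x$importance_mobps)
  cat("  coalition single-criterion ranking: ",
      paste(top$subset, collapse = " > "), "\n", sep = "")
  for (trt in names(x$importance_lasso)) {
    rk <- rank_coefficients(x$importance_lasso[[trt]])
    cat("  LASSO top coefficient (", trt, "): ",
        if (nrow(rk) > 0) sprintf("%s (%.3f)", rk$name[1], rk$beta[1])
        else "none nonzero", "\n", sep = "")
  }
  for (m in names(x$mixed_models))
    cat(sprintf("  model %s: ICC = %.3f\n", m, x$mixed_models[[m]]$icc))
  invisible(x)
}

# JSON-friendly view of a report (everything numeric the stages computed;
# no wall times, so identical inputs serialize identically).
.report_payload <- function(report) {
  es_list <- function(es) list(W = es$statistic_w, z = es$z, r = es$r,
                               cliffs_delta = es$cliffs_delta, p = es$p,
                               n1 = es$n1, n2 = es$n2)
  lasso_list <- function(f) list(
    treatment = f$treatment, lambda_min = f$lambda_min,
    lambda_1se = f$lambda_1se, folds = f$folds, seed = f$seed,
    ranking = rank_coefficients(f))
  model_list <- function(m) list(
    model = m$model, label = m$label, df_method = m$df_method,
    coefficients = m$coefficients,
    tau = as.list(m$variance_components), sigma2 = m$sigma2,
    icc = m$icc, variance_shares = as.list(m$variance_shares),
    boundary = m$boundary, n_obs = m$n_obs)
  sev <- report$severity
  list(
    schema_version = report$schema_version,
    meta = report$meta,
    summary = list(
      n_records = report$summary$n_records,
      n_animals = report$summary$n_animals,
      by_treatment_intervention = as.data.frame(report$summary$by_treatment_intervention),
      dropped_videos = report$summary$dropped_videos),
    importance_mobps = as.data.frame(report$importance_mobps),
    shapley_full_game = as.list(attr(report$importance_mobps, "shapley")),
    importance_lasso = lapply(report$importance_lasso, lasso_list),
    mixed_models = lapply(report$mixed_models, model_list),
    severity = list(
      counts = as.data.frame(sev$counts),
      per_treatment = lapply(sev$per_treatment, function(p) list(
        chi2 = p$chi2[c("statistic", "df", "p")], posthoc = p$posthoc)),
      adjust = sev$adjust),
    contrasts = list(
      bsl_vs_post_week1 = lapply(report$contrasts$bsl_vs_post_week1, es_list),
      baseline_between_treatments =
        es_list(report$contrasts$baseline_between_treatments)),
    bootstrap_medians = report$bootstrap_medians,
    correlations = lapply(report$correlations, function(m)
      as.data.frame(as.table(m))))
}

#' Write a pipeline report to disk
#'
#' Serialises the report to `report.json` (full numeric payload; identical
#' configuration and seeds give byte-identical files) and writes the main
#' tables as CSVs (`dataset.csv`, `mobps_ranking.csv`,
#' `lasso_<treatment>.csv`, `severity_counts.csv`, `bootstrap_medians.csv`).
#'
#' @param report A `mgs_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mgs_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(.report_payload(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  write_dataset(report$dataset, file.path(dir, "dataset.csv"))
  utils::write.csv(as.data.frame(report$importance_mobps),
                   file.path(dir, "mobps_ranking.csv"), row.names = FALSE)
  for (trt in names(report$importance_lasso))
    utils::write.csv(rank_coefficients(report$importance_lasso[[trt]]),
                     file.path(dir, paste0("lasso_", tolower(trt), ".csv")),
                     row.names = FALSE)
  utils::write.csv(as.data.frame(report$severity$counts),
                   file.path(dir, "severity_counts.csv"), row.names = FALSE)
  utils::write.csv(report$bootstrap_medians,
                   file.path(dir, "bootstrap_medians.csv"), row.names = FALSE)
  invisible(dir)
}
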