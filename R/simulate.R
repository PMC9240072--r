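# Synthetic per-image grimace-score generator emulating a two-group
# repeated-injection study with a planted criterion-importance structure.

#' Configuration for the synthetic grimace-score generator
#'
#' The generator draws a latent per-video pain level (animal random intercept
#' + treatment shift + injection effect + weekly trend + video noise) and
#' turns it into five ordinal 0/1/2 frame scores through a thresholded
#' Gaussian copula. Each criterion loads on the latent pain with its own
#' sensitivity, which plants a ground-truth importance ordering: by default
#' orbital tightening is the most pain-sensitive criterion and whisker change
#' the least. Frames are rejected (-1) independently per criterion, most
#' often for whisker change; whole videos can be missing, emulating
#' unusable recordings.
#'
#' @param n_animals_per_group Animals per treatment arm (default 12).
#' @param weeks Week indices; week 0 is the uninjected baseline week.
#' @param days_per_week Filming days per week (default 3).
#' @param images_per_video Frames scored per video (default 8).
#' @param fau_sensitivity Named non-negative loadings of the five criteria on
#'   the latent pain level; the descending order is the planted importance
#'   ranking.
#' @param latent_corr Share of the frame-level copula noise that is common
#'   to all five criteria within a frame, in \[0, 1); together with the
#'   latent-pain loadings it drives the strong positive inter-criterion
#'   correlations seen in real scorings.
#' @param frame_noise_sd Standard deviation of the total frame-level copula
#'   noise relative to the latent-pain scale. Values below 1 mean a scorer
#'   rates the 8 frames of one video consistently, which keeps the per-video
#'   residual variance near what trained raters achieve.
#' @param animal_sd,residual_sd Standard deviations of the animal random
#'   intercept and of the per-video noise on the latent scale.
#' @param treatment_effect Latent shift of the hepatotoxic (CCl4) arm,
#'   present in all weeks (groups may differ already at baseline).
#' @param intervention_effect Latent shift of a post-injection video relative
#'   to pre, common to both arms (the injection itself is painful).
#' @param ccl4_intervention_effect Additional post-injection shift specific
#'   to the CCl4 arm (the substance is the main pain driver).
#' @param week_trend Latent shift per week (weeks 1-4).
#' @param thresholds Two increasing cutpoints turning the latent frame value
#'   into scores 0/1/2; calibrated so baseline videos are mostly mild
#'   (total score < 3 on the 0-16 scale) with occasional moderate.
#' @param fau_threshold_shift Named per-criterion expressiveness shift:
#'   added in full to the first cutpoint and at 30% to the second. Negative
#'   values make a criterion more expressive (scored nonzero more often,
#'   like orbital tightening), positive values stiffer (like whisker
#'   change); a stiff criterion mainly resists first activation, while
#'   graduation from moderate to severe stays comparable, so every category
#'   remains reachable. Ordered consistently with `fau_sensitivity` so
#'   expressiveness reinforces the planted ranking.
#' @param reject_prob Named per-criterion frame rejection probabilities.
#' @param video_missing_prob Probability that a scheduled video is missing
#'   entirely (not recorded or unusable).
#' @param seed Master seed; per-animal substreams are derived by fixed
#'   offsets so adding animals does not perturb existing ones.
#' @return A list of class `mgs_sim_config`.
#' @export
mgs_sim_config <- function(n_animals_per_group = 12L,
                           weeks = 0:4,
                           days_per_week = 3L,
                           images_per_video = 8L,
                           fau_sensitivity = c(ot = 1.6, nb = 0.42, cb = 0.52,
                                               ep = 0.6, wc = 0.03),
                           latent_corr = 0.45,
                           frame_noise_sd = 0.6,
                           animal_sd = 0.25,
                           residual_sd = 0.1,
                           treatment_effect = 0.11,
                           intervention_effect = 0.06,
                           ccl4_intervention_effect = 0.28,
                           week_trend = 0.012,
                           thresholds = c(0.45, 1.7),
                           fau_threshold_shift = c(ot = -0.12, nb = 0.42,
                                                   cb = 0.28, ep = 0.1,
                                                   wc = 0.9),
                           reject_prob = c(ot = 0.10, nb = 0.15, cb = 0.15,
                                           ep = 0.14, wc = 0.22),
                           video_missing_prob = 0.232,
                           seed = 1L) {
  faus <- fau_labels()
  stopifnot(n_animals_per_group >= 1L, days_per_week >= 1L,
            images_per_video >= 1L)
  fau_sensitivity <- fau_sensitivity[faus]
  reject_prob <- reject_prob[faus]
  if (anyNA(fau_sensitivity) || any(fau_sensitivity < 0))
    stop("fau_sensitivity must be named non-negative values for all of: ",
         paste(faus, collapse = ", "))
  if (anyNA(reject_prob) || any(reject_prob < 0 | reject_prob > 1))
    stop("reject_prob must be named probabilities for all of: ",
         paste(faus, collapse = ", "))
  if (latent_corr < 0 || latent_corr >= 1) stop("latent_corr must be in [0, 1)")
  if (frame_noise_sd <= 0) stop("frame_noise_sd must be positive")
  if (video_missing_prob < 0 || video_missing_prob > 1)
    stop("video_missing_prob must be a probability")
  if (length(thresholds) != 2L || diff(thresholds) <= 0)
    stop("thresholds must be two increasing cutpoints")
  fau_threshold_shift <- fau_threshold_shift[faus]
  if (anyNA(fau_threshold_shift))
    stop("fau_threshold_shift must be named values for all of: ",
         paste(faus, collapse = ", "))
  if (animal_sd == 0 && residual_sd == 0 && latent_corr == 0 &&
      all(fau_sensitivity == 0))
    stop("degenerate configuration: no source of variation anywhere")
  structure(list(
    n_animals_per_group = as.integer(n_animals_per_group),
    weeks = as.integer(weeks), days_per_week = as.integer(days_per_week),
    images_per_video = as.integer(images_per_video),
    fau_sensitivity = fau_sensitivity, latent_corr = latent_corr,
    frame_noise_sd = frame_noise_sd,
    animal_sd = animal_sd, residual_sd = residual_sd,
    treatment_effect = treatment_effect,
    intervention_effect = intervention_effect,
    ccl4_intervention_effect = ccl4_intervention_effect,
    week_trend = week_trend, thresholds = thresholds,
    fau_threshold_shift = fau_threshold_shift,
    reject_prob = reject_prob, video_missing_prob = video_missing_prob,
    seed = as.integer(seed)), class = "mgs_sim_config")
}

# Per-animal video schedule: week 0 -> bsl once per day; weeks >= 1 -> pre and
# post per day.
.video_schedule <- function(cfg) {
  rows <- list()
  for (w in cfg$weeks) {
    for (d in seq_len(cfg$days_per_week)) {
      ivs <- if (w == 0L) "bsl" else c("pre", "post")
      for (iv in ivs) rows[[length(rows) + 1L]] <- list(week = w, day = d,
                                                        intervention = iv)
    }
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Simulate per-image grimace scores
#'
#' Draws the full study design defined by `cfg` and returns the raw per-image
#' score table together with the generator's ground truth (latent values,
#' planted importance ranking, realized rejection counts).
#'
#' @param cfg A [mgs_sim_config()].
#' @return A list of class `mgs_simulation` with elements `images` (data.frame
#'   of per-image scores, same layout as [read_image_scores()]) and `truth`
#'   (list: `latent` per-video data.frame, `importance_ranking`,
#'   `rejection_counts`, `n_scheduled_videos`, `n_missing_videos`).
#' @export
simulate_mgs <- function(cfg = mgs_sim_config()) {
  stopifnot(inherits(cfg, "mgs_sim_config"))
  faus <- fau_labels()
  sched <- .video_schedule(cfg)
  n_an <- 2L * cfg$n_animals_per_group
  ids <- c(sprintf("oil_%02d", seq_len(cfg$n_animals_per_group)),
           sprintf("ccl4_%02d", seq_len(cfg$n_animals_per_group)))
  trts <- rep(c("Oil", "CCl4"), each = cfg$n_animals_per_group)

  img_list <- vector("list", n_an)
  lat_list <- vector("list", n_an)
  rej <- stats::setNames(integer(length(faus)), faus)
  n_missing <- 0L

  for (ai in seq_len(n_an)) {
    # fixed-offset substream per animal
    set.seed((cfg$seed %% 1000000L) * 2048L + 7919L + ai)
    a_i <- stats::rnorm(1L, 0, cfg$animal_sd)
    is_ccl4 <- trts[ai] == "CCl4"
    present <- stats::runif(nrow(sched)) >= cfg$video_missing_prob
    n_missing <- n_missing + sum(!present)
    vids <- sched[present, , drop = FALSE]
    if (nrow(vids) == 0L) next
    post <- vids$intervention == "post"
    L <- a_i +
      cfg$treatment_effect * is_ccl4 +
      (cfg$intervention_effect + cfg$ccl4_intervention_effect * is_ccl4) * post +
      cfg$week_trend * vids$week +
      stats::rnorm(nrow(vids), 0, cfg$residual_sd)
    m <- cfg$images_per_video
    nimg <- nrow(vids) * m
    G <- stats::rnorm(nimg)                     # shared frame factor
    E <- matrix(stats::rnorm(nimg * length(faus)), nimg, length(faus))
    X <- outer(rep(L, each = m), cfg$fau_sensitivity) +
      cfg$frame_noise_sd * (sqrt(cfg$latent_corr) * G +
                            sqrt(1 - cfg$latent_corr) * E)
    S <- matrix(0L, nimg, length(faus))
    T1 <- matrix(cfg$thresholds[1] + cfg$fau_threshold_shift, nimg,
                 length(faus), byrow = TRUE)
    T2 <- matrix(cfg$thresholds[2] + 0.3 * cfg$fau_threshold_shift, nimg,
                 length(faus), byrow = TRUE)
    S[X > T1] <- 1L
    S[X > T2] <- 2L
    R <- matrix(stats::runif(nimg * length(faus)), nimg, length(faus)) <
      matrix(cfg$reject_prob, nimg, length(faus), byrow = TRUE)
    S[R] <- -1L
    rej <- rej + colSums(R)
    colnames(S) <- faus
    img <- data.frame(
      animal_id = ids[ai], treatment = trts[ai],
      week = rep(vids$week, each = m), day = rep(vids$day, each = m),
      intervention = rep(vids$intervention, each = m),
      stringsAsFactors = FALSE)
    img <- cbind(img, as.data.frame(S))
    img_list[[ai]] <- img
    lat_list[[ai]] <- data.frame(
      animal_id = ids[ai], treatment = trts[ai], week = vids$week,
      day = vids$day, intervention = vids$intervention, latent = L,
      stringsAsFactors = FALSE)
  }
  images <- do.call(rbind, img_list)
  rownames(images) <- NULL
  latent <- do.call(rbind, lat_list)
  rownames(latent) <- NULL
  structure(list(
    images = images,
    truth = list(
      latent = latent,
      importance_ranking = names(sort(cfg$fau_sensitivity, decreasing = TRUE)),
      rejection_counts = rej,
      n_images = nrow(images),
      n_scheduled_videos = nrow(sched) * n_an,
      n_missing_videos = n_missing),
    config = cfg), class = "mgs_simulation")
}

#' @export
print.mgs_simulation <- function(x, ...) {
  cat("Synthetic MGS simulation: ", nrow(x$images), " images, ",
      length(unique(x$images$animal_id)), " animals\n", sep = "")
  cat("Planted importance ranking: ",
      paste(x$truth$importance_ranking, collapse = " > "), "\n", sep = "")
  cat("Rejected frame values: ", sum(x$truth$rejection_counts), " (",
      sprintf("%.1f%%", 100 * sum(x$truth$rejection_counts) /
                (x$truth$n_images * 5L)), " of values)\n", sep = "")
  invisible(x)
}

#' Generate the calibrated study-design preset
#'
#' Runs the generator at its default calibration (24 animals in 2 arms, weeks
#' 0-4, 3 days/week, pre/post videos, 8 frames/video, ~15% frame rejection,
#' ~23% missing videos) and aggregates to the video level, yielding a dataset
#' of roughly 500 records comparable in shape and scale to a real four-week
#' injection study.
#'
#' @param seed Master seed.
#' @param mode Aggregation mode passed to [aggregate_videos()].
#' @param ... Overrides forwarded to [mgs_sim_config()].
#' @return A `mgs_dataset`; the simulation object (with ground truth) is
#'   attached as attribute `"simulation"`.
#' @export
emulate_study <- function(seed = 1L, mode = "scaled_sum", ...) {
  sim <- simulate_mgs(mgs_sim_config(seed = seed, ...))
  ds <- suppressWarnings(aggregate_videos(sim$images, mode = mode,
                                          nominal_images = sim$config$images_per_video))
  attr(ds, "simulation") <- sim
  ds
}
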