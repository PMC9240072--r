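# Ingestion, validation and per-video aggregation of raw per-image grimace scores.

#' Facial action unit labels
#'
#' The five Mouse Grimace Scale criteria, in canonical column order:
#' orbital tightening (`ot`), nose bulge (`nb`), cheek bulge (`cb`),
#' ear position (`ep`) and whisker change (`wc`).
#'
#' @return Character vector of length five.
#' @export
fau_labels <- function() c("ot", "nb", "cb", "ep", "wc")

.key_cols <- c("animal_id", "treatment", "week", "day", "intervention")
.treatment_levels <- c("Oil", "CCl4")
.intervention_levels <- c("bsl", "pre", "post")

#' Read per-image grimace scores from CSV
#'
#' Each row is one scored video frame: identifiers (animal, treatment, week,
#' day, intervention) and the five ordinal facial action unit scores. Scores
#' take values 0 (no deviation), 1 (moderate) or 2 (severe deviation); -1
#' marks a frame rejected as unscorable for that criterion.
#'
#' @param path Path to a CSV file.
#' @param column_map Optional named character vector mapping the expected
#'   column names (`animal_id`, `treatment`, `week`, `day`, `intervention`,
#'   `ot`, `nb`, `cb`, `ep`, `wc`) to the headers actually present in the
#'   file, e.g. `c(animal_id = "ID", ot = "OT")`. Unmapped names are assumed
#'   to match directly (case-insensitively).
#' @return A data.frame of image scores with validated columns.
#' @export
read_image_scores <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  wanted <- c(.key_cols, fau_labels())
  map <- stats::setNames(wanted, wanted)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), wanted)
    if (length(bad) > 0L)
      stop("column_map names not recognised: ", paste(bad, collapse = ", "))
    map[names(column_map)] <- column_map
  }
  # case-insensitive fallback for unmapped columns
  for (w in wanted) {
    if (!map[[w]] %in% names(raw)) {
      hit <- which(tolower(names(raw)) == tolower(map[[w]]))
      if (length(hit) == 1L) map[[w]] <- names(raw)[hit]
    }
  }
  missing <- wanted[!map[wanted] %in% names(raw)]
  if (length(missing) > 0L)
    stop("missing column(s) in ", path, ": ",
         paste(sprintf("%s (mapped to '%s')", missing, map[missing]), collapse = ", "))
  df <- raw[, map[wanted]]
  names(df) <- wanted
  validate_image_scores(df)
}

#' Validate a table of per-image grimace scores
#'
#' Checks domain constraints: treatment and intervention levels, week in 0-4,
#' day in 1-3, every FAU value in \{-1, 0, 1, 2\}, and the design invariant
#' that week 0 carries only baseline (`bsl`) videos while weeks 1-4 carry
#' only `pre`/`post` videos. Violations raise errors naming the offending
#' rows.
#'
#' @param df A data.frame with the image-score columns.
#' @return The validated data.frame (factors normalised, scores integer).
#' @export
validate_image_scores <- function(df) {
  wanted <- c(.key_cols, fau_labels())
  missing <- setdiff(wanted, names(df))
  if (length(missing) > 0L)
    stop("missing column(s): ", paste(missing, collapse = ", "))
  df$animal_id <- as.character(df$animal_id)
  df$treatment <- as.character(df$treatment)
  df$intervention <- as.character(df$intervention)

  bad <- which(!df$treatment %in% .treatment_levels)
  if (length(bad) > 0L)
    stop("invalid treatment at row(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         " (expected one of ", paste(.treatment_levels, collapse = ", "), ")")
  bad <- which(!df$intervention %in% .intervention_levels)
  if (length(bad) > 0L)
    stop("invalid intervention at row(s) ", paste(utils::head(bad, 5L), collapse = ", "))

  for (col in c("week", "day", fau_labels())) {
    v <- df[[col]]
    nonint <- which(!is.finite(v) | v != round(v))
    if (length(nonint) > 0L)
      stop("non-integer value in column '", col, "' at row(s) ",
           paste(utils::head(nonint, 5L), collapse = ", "))
    df[[col]] <- as.integer(round(v))
  }
  if (any(df$week < 0L | df$week > 4L))
    stop("week out of range 0-4 at row(s) ",
         paste(utils::head(which(df$week < 0L | df$week > 4L), 5L), collapse = ", "))
  if (any(df$day < 1L | df$day > 3L))
    stop("day out of range 1-3 at row(s) ",
         paste(utils::head(which(df$day < 1L | df$day > 3L), 5L), collapse = ", "))
  for (col in fau_labels()) {
    bad <- which(!df[[col]] %in% c(-1L, 0L, 1L, 2L))
    if (length(bad) > 0L)
      stop("score outside {-1,0,1,2} in column '", col, "' at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }
  bad <- which((df$week == 0L) != (df$intervention == "bsl"))
  if (length(bad) > 0L)
    stop("week/intervention mismatch (week 0 <=> bsl) at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Aggregate per-image scores into per-video records
#'
#' Collapses all frames sharing an (animal, week, day, intervention) key into
#' one video-level record. Rejected values (-1) are excluded per criterion
#' before aggregating; a video in which some criterion has no accepted frame
#' at all, or in which no frame has all five criteria scored, is dropped with
#' a warning and counted.
#'
#' Aggregation modes for the per-video criterion score:
#' \describe{
#'   \item{`mean`}{mean over accepted frames (scale 0-2);}
#'   \item{`sum`}{sum over accepted frames (scale depends on frame count);}
#'   \item{`scaled_sum`}{mean over accepted frames times the nominal frame
#'     count (default 8), i.e. a rejection-unbiased multi-frame total on the
#'     0-16 scale. This is the default analysis scale: severity thresholds
#'     at 3 and 6 presume a multi-frame total.}
#' }
#' The average picture score is always the mean, over frames with all five
#' criteria accepted, of the per-frame sum of the five scores (range 0-10).
#'
#' @param images Data.frame of image scores (see [read_image_scores()]).
#' @param mode Aggregation mode, see Details.
#' @param nominal_images Nominal frames per video used by `scaled_sum`.
#' @return A `mgs_dataset`: data.frame of video records with columns
#'   `animal_id`, `treatment`, `week`, `day`, `intervention`,
#'   `<fau>_score` and `<fau>_n` for each criterion, `n_images`,
#'   `avg_picture_score`. Attributes record the aggregation settings and
#'   the number of dropped videos.
#' @export
aggregate_videos <- function(images, mode = c("scaled_sum", "mean", "sum"),
                             nominal_images = 8L) {
  mode <- match.arg(mode)
  images <- validate_image_scores(images)
  if (nrow(images) == 0L) stop("no image scores to aggregate")
  key <- interaction(images$animal_id, images$treatment, images$week,
                     images$day, images$intervention, drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(images)), key)
  faus <- fau_labels()
  recs <- lapply(idx, function(i) {
    sub <- images[i, , drop = FALSE]
    scores <- numeric(length(faus))
    ns <- integer(length(faus))
    for (k in seq_along(faus)) {
      v <- sub[[faus[k]]]
      acc <- v[v >= 0L]
      ns[k] <- length(acc)
      if (ns[k] == 0L) return(NULL)
      scores[k] <- switch(mode,
        mean = mean(acc),
        sum = sum(acc),
        scaled_sum = mean(acc) * nominal_images)
    }
    full <- rowSums(as.matrix(sub[, faus]) >= 0L) == length(faus)
    if (!any(full)) return(NULL)
    aps <- mean(rowSums(as.matrix(sub[full, faus, drop = FALSE])))
    out <- sub[1L, .key_cols]
    for (k in seq_along(faus)) {
      out[[paste0(faus[k], "_score")]] <- scores[k]
      out[[paste0(faus[k], "_n")]] <- ns[k]
    }
    out$n_images <- nrow(sub)
    out$avg_picture_score <- aps
    out
  })
  dropped <- sum(vapply(recs, is.null, logical(1)))
  if (dropped > 0L)
    warning(dropped, " video(s) dropped: no accepted frame for some criterion ",
            "or no fully scored frame")
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L) stop("all videos dropped during aggregation")
  ds <- do.call(rbind, recs)
  rownames(ds) <- NULL
  ord <- order(ds$treatment, ds$animal_id, ds$week, ds$day,
               match(ds$intervention, .intervention_levels))
  ds <- ds[ord, , drop = FALSE]
  rownames(ds) <- NULL
  structure(ds,
            class = c("mgs_dataset", "data.frame"),
            aggregation = list(mode = mode, nominal_images = nominal_images,
                               dropped_videos = dropped))
}

#' @export
print.mgs_dataset <- function(x, ...) {
  agg <- attr(x, "aggregation")
  cat("MGS video-level dataset: ", nrow(x), " records, ",
      length(unique(x$animal_id)), " animals",
      if (!is.null(agg)) paste0(" (aggregation: ", agg$mode, ")"), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("... and ", nrow(x) - 6L, " more records\n", sep = "")
  invisible(x)
}

#' Summarize a video-level dataset
#'
#' Record counts by treatment, intervention and week, animal count and (when
#' available from aggregation) the number of dropped videos.
#'
#' @param ds A `mgs_dataset`.
#' @return A list with elements `n_records`, `n_animals`,
#'   `by_treatment_intervention` (table), `by_week` (table),
#'   `dropped_videos`.
#' @export
summarize_dataset <- function(ds) {
  stopifnot(is.data.frame(ds))
  if (nrow(ds) == 0L) {
    return(list(n_records = 0L, n_animals = 0L,
                by_treatment_intervention = table(character(), character()),
                by_week = table(integer()), dropped_videos = 0L))
  }
  agg <- attr(ds, "aggregation")
  list(
    n_records = nrow(ds),
    n_animals = length(unique(ds$animal_id)),
    by_treatment_intervention = table(
      treatment = factor(ds$treatment, .treatment_levels),
      intervention = factor(ds$intervention, .intervention_levels)),
    by_week = table(week = ds$week),
    dropped_videos = if (is.null(agg)) 0L else agg$dropped_videos
  )
}

#' Write / read a video-level dataset as CSV
#'
#' Plain-text round trip: `write_dataset()` stores the record table;
#' `read_dataset()` restores it (with the `mgs_dataset` class; aggregation
#' provenance is stored in a header comment).
#'
#' @param ds A `mgs_dataset`.
#' @param path Output/input CSV path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   the `mgs_dataset`.
#' @export
write_dataset <- function(ds, path) {
  agg <- attr(ds, "aggregation")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(agg))
    writeLines(sprintf("# aggregation: mode=%s nominal_images=%d dropped=%d",
                       agg$mode, agg$nominal_images, agg$dropped_videos), con)
  utils::write.csv(as.data.frame(ds), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  first <- readLines(path, n = 1L)
  agg <- NULL
  if (startsWith(first, "# aggregation:")) {
    m <- regmatches(first, regexec(
      "mode=(\\S+) nominal_images=(\\d+) dropped=(\\d+)", first))[[1]]
    agg <- list(mode = m[2], nominal_images = as.integer(m[3]),
                dropped_videos = as.integer(m[4]))
  }
  ds <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("week", "day", "n_images", paste0(fau_labels(), "_n")))
    if (col %in% names(ds)) ds[[col]] <- as.integer(ds[[col]])
  structure(ds, class = c("mgs_dataset", "data.frame"), aggregation = agg)
}
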