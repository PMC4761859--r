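# End-to-end trial and cohort processing: read, segment, measure, report.

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Process one trial end to end
#'
#' Reads a trial log, segments it into events and phases, computes the
#' spatio-temporal metrics, and (when frames are supplied) extracts and
#' segments the grasp posture at each key instant. Writes `events.json`,
#' `metrics.csv`, per-event panorama/mask PNGs and a `report.png` with the
#' resultant acceleration and sagittal angle annotated A-E. Every output
#' carries the configuration hash and seed. Stage failures name the stage;
#' outputs produced before the failure are kept.
#'
#' @param trial Path to a trial text log, or an [imu_trace()].
#' @param frames Optional frames tibble for [posture_at_events()] (needs
#'   `config$mirror`).
#' @param config A [run_config()].
#' @param out_dir Output directory (created); `NULL` to skip writing.
#' @return List with `segmentation`, `metrics`, `postures` (or `NULL`),
#'   `outputs` (paths written), `config_hash`.
#' @export
run_trial_pipeline <- function(trial, frames = NULL, config = run_config(),
                               out_dir = NULL) {
  outputs <- character(0)
  hash <- config_hash(config)
  stage <- "read"
  trace <- tryCatch({
    if (inherits(trial, "imu_trace")) trial
    else read_imu_text(trial, dialect = config$dialect)
  }, graspkin_error = function(e) {
    abort_format(paste0("stage 'read': ", conditionMessage(e)))
  }, error = function(e) {
    abort_format(paste0("stage 'read': cannot parse trial file: ", conditionMessage(e)))
  })

  seg <- segment_trial(trace, config$segmentation)
  metrics <- trial_metrics(seg, unit_threshold = config$unit_threshold,
                           speed_channel = config$speed_channel)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ev <- as.list(seg$events)
    ev$params <- unclass_rec(config$segmentation)
    ev$config_hash <- hash
    ev$seed <- config$seed
    p <- file.path(out_dir, "events.json")
    write_json_out(ev, p); outputs <- c(outputs, p)
    p <- file.path(out_dir, "metrics.csv")
    m <- metrics
    m$config_hash <- hash
    readr::write_csv(m, p, progress = FALSE); outputs <- c(outputs, p)
  }

  postures <- NULL
  if (!is.null(frames)) {
    if (is.null(config$mirror)) {
      abort_capability("frames supplied but config$mirror is NULL")
    }
    postures <- posture_at_events(frames, seg$events, config$mirror,
                                  out_w = config$pano_w, out_h = config$pano_h,
                                  seed = config$seed,
                                  restarts = config$kmeans_restarts,
                                  reference_skin_ab = config$reference_skin_ab)
    if (!is.null(out_dir) && nrow(postures) > 0) {
      for (i in seq_len(nrow(postures))) {
        px <- postures$pano[[i]]$pixels
        px[is.na(px)] <- 0
        p <- file.path(out_dir, sprintf("pano_%s.png", postures$event[i]))
        png::writePNG(px, p); outputs <- c(outputs, p)
        mk <- postures$seg[[i]]$mask * 1
        mk[is.na(mk)] <- 0
        p <- file.path(out_dir, sprintf("mask_%s.png", postures$event[i]))
        png::writePNG(mk, p); outputs <- c(outputs, p)
      }
      side <- list(config_hash = hash, seed = config$seed,
                   mm_per_px_x = postures$pano[[1]]$mm_per_px_x,
                   mm_per_px_y = postures$pano[[1]]$mm_per_px_y,
                   events = as.list(seg$events),
                   grasp_area_mm2 = stats::setNames(
                     as.list(postures$grasp_area_mm2), postures$event),
                   centroids = lapply(postures$seg, function(s) s$centroids))
      p <- file.path(out_dir, "postures.json")
      write_json_out(side, p); outputs <- c(outputs, p)
    }
  }

  if (!is.null(out_dir)) {
    p <- file.path(out_dir, "report.png")
    ok <- tryCatch({
      grDevices::png(p, width = 900, height = 600)
      print(ggplot2::autoplot(seg))
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      try(grDevices::dev.off(), silent = TRUE)
      FALSE
    })
    if (ok) outputs <- c(outputs, p)
  }

  list(segmentation = seg, metrics = metrics, postures = postures,
       outputs = outputs, config_hash = hash)
}

#' Summarize a cohort of trials
#'
#' Accepts either a tibble of trials (columns `trace` — list of
#' [imu_trace()] — plus grouping labels such as `age`, `gender`; the shape
#' [synth_cohort()] returns) or a directory whose subdirectories are groups
#' of trial CSVs. Each trial runs through segmentation and metrics; groups
#' whose trials all fail are reported and skipped.
#'
#' @param trials Tibble or directory path.
#' @param config A [run_config()].
#' @param by Grouping columns (default `"age"`; directories group by
#'   subdirectory name under a `group` column).
#' @param out_dir Optional directory for `cohort_metrics.csv` and
#'   `cohort_summary.csv`.
#' @return List with `metrics` (per-trial tibble) and `summary`
#'   (mean/SD table from [summarize_groups()]).
#' @export
run_cohort <- function(trials, config = run_config(), by = "age",
                       out_dir = NULL) {
  if (is.character(trials)) {
    groups <- list.dirs(trials, recursive = FALSE)
    if (length(groups) == 0) abort_parameter("no group subdirectories found")
    rows <- purrr::map(groups, function(g) {
      files <- list.files(g, pattern = "\\.(csv|txt|tsv)$", full.names = TRUE)
      if (length(files) == 0) {
        rlang::warn(paste0("group '", basename(g), "' has no trial files; skipped"))
        return(NULL)
      }
      tibble::tibble(group = basename(g), path = files)
    })
    trials <- dplyr::bind_rows(rows)
    trials$trace <- purrr::map(trials$path, read_imu_text, dialect = config$dialect)
    by <- "group"
  }
  per_trial <- purrr::map(seq_len(nrow(trials)), function(i) {
    m <- tryCatch(
      trial_metrics(trials$trace[[i]], unit_threshold = config$unit_threshold,
                    speed_channel = config$speed_channel,
                    params = config$segmentation),
      graspkin_error = function(e) {
        rlang::warn(sprintf("trial %d failed: %s", i, conditionMessage(e)))
        NULL
      })
    if (is.null(m)) return(NULL)
    dplyr::bind_cols(trials[i, intersect(by, names(trials)), drop = FALSE], m)
  })
  metrics <- dplyr::bind_rows(per_trial)
  if (nrow(metrics) == 0) abort_event("no trial segmented successfully")
  summary <- summarize_groups(metrics, by = by)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hash <- config_hash(config)
    m <- metrics; m$config_hash <- hash
    readr::write_csv(m, file.path(out_dir, "cohort_metrics.csv"), progress = FALSE)
    s <- summary; s$config_hash <- hash
    readr::write_csv(s, file.path(out_dir, "cohort_summary.csv"), progress = FALSE)
  }
  list(metrics = metrics, summary = summary)
}
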