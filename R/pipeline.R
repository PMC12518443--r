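#' Run the full tracking-classification-summary pipeline
#'
#' Orchestrates track -> classify -> summarize/windows (and, when interval
#' annotations are supplied, a phase-stratified summary with per-phase
#' table-interaction, movement and annotated patient-interaction
#' fractions). All outputs are CSV; given identical inputs the outputs
#' are byte-identical across runs. On error, partially written outputs
#' are removed.
#'
#' @param poses A [pose_stream] or path to a pose JSON file.
#' @param regions A [region_set()] or path to a region JSON file.
#' @param out_dir Output directory (created if needed); receives
#'   `class.csv`, `summary.csv`, `windows.csv` and, with annotations,
#'   `phase_summary.csv`.
#' @param params [interaction_params()].
#' @param tparams [tracker_params()].
#' @param wspec [window_spec()].
#' @param activities Optional activity interval data.frame (or CSV path)
#'   with `person_id`, `start_frame`, `end_frame`, `label`.
#' @param label_mapping Named character vector label -> category for
#'   [category_map()]; required when `activities` lack a `category`
#'   column.
#' @param phases Optional phase interval data.frame (or CSV path) with
#'   `phase`, `start_frame`, `end_frame`.
#' @param dialect Pose file dialect when `poses` is a path.
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list with `records`, `summary`, `windows`, and
#'   (if available) `phase_summary`, plus the output file paths.
#' @export
run_pipeline <- function(poses, regions, out_dir,
                         params = interaction_params(),
                         tparams = tracker_params(),
                         wspec = window_spec(),
                         activities = NULL, label_mapping = NULL,
                         phases = NULL, dialect = "coco_result",
                         quiet = FALSE) {
  log_ <- function(...) if (!quiet) message("[tableside] ", sprintf(...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  stage <- "setup"
  tryCatch({
    stage <- "read"
    if (is.character(poses)) poses <- read_pose_stream(poses, dialect)
    if (is.character(regions)) regions <- read_regions(regions)
    if (is.character(activities)) activities <- read_intervals(activities)
    if (is.character(phases)) phases <- read_intervals(phases)
    log_("input: %d detections over %d frames", nrow(poses$poses),
         poses$n_frames)

    stage <- "track"
    if (nrow(poses$poses) > 0 && anyNA(poses$poses$track_id)) {
      poses <- build_tracklets(poses, tparams)
      log_("tracked: %d detections in %d tracklets", nrow(poses$poses),
           length(unique(poses$poses$track_id)))
    }

    stage <- "classify"
    records <- classify_interaction(poses, regions, params)
    f_class <- file.path(out_dir, "class.csv")
    write_classifications(records, f_class)
    written <- c(written, f_class)
    log_("classified: %d records", nrow(records))

    stage <- "summarize"
    summary <- summarize_classifications(records)
    f_sum <- file.path(out_dir, "summary.csv")
    utils::write.csv(summary, f_sum, row.names = FALSE, quote = FALSE)
    written <- c(written, f_sum)
    log_("table interaction F = %d/%d = %.4f; movement F = %.4f",
         sum(records$interacting), nrow(records),
         summary$table_interaction, summary$movement)

    stage <- "windows"
    windows <- windowed_fraction(records, poses$n_frames, wspec)
    f_win <- file.path(out_dir, "windows.csv")
    utils::write.csv(windows, f_win, row.names = FALSE, quote = FALSE)
    written <- c(written, f_win)
    log_("windows: %d (length %d, step %d)", nrow(windows),
         wspec$length, wspec$step)

    out <- list(records = records, summary = summary, windows = windows,
                files = written)
    if (!is.null(phases)) {
      stage <- "phase_summary"
      if (!is.null(activities) && is.null(activities$category)) {
        if (is.null(label_mapping)) {
          stop("activities lack a category column and no label_mapping given",
               call. = FALSE)
        }
        activities$category <- category_map(activities$label, label_mapping)
      }
      ph <- phase_intervals(phases$phase, phases$start_frame,
                            phases$end_frame)
      psum <- phase_summary(records, ph, activities)
      f_ph <- file.path(out_dir, "phase_summary.csv")
      utils::write.csv(psum, f_ph, row.names = FALSE, quote = FALSE)
      written <- c(written, f_ph)
      out$phase_summary <- psum
      out$files <- written
    }
    invisible(out)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Render colour-coded pose overlays
#'
#' Draws each pose's skeleton and keypoints coloured by its three-way
#' classification — interacting, positioned-but-moving (right position
#' but moving too fast to interact), wrong position — together with the
#' track id and detection score. Keypoints below the drawing confidence
#' threshold are omitted (the id is still printed). One PNG per frame.
#'
#' @param stream A tracked [pose_stream].
#' @param records Classification data.frame aligned with `stream` (as
#'   returned by [classify_interaction()] on it).
#' @param regions A [region_set()] (drawn as outlines).
#' @param out_dir Output directory for `frame_<n>.png` files.
#' @param frames Frames to render (default: all frames with detections).
#' @param frame_size `c(width, height)` in pixels.
#' @param draw_confidence_min Keypoints below this confidence are not
#'   drawn (default 0.2).
#' @param colors Named vector of colours for the three categories.
#' @return Character vector of written file paths.
#' @export
render_overlay <- function(stream, records, regions, out_dir,
                           frames = NULL, frame_size = c(1280, 720),
                           draw_confidence_min = 0.2,
                           colors = c(interacting = "#2ca02c",
                                      positioned_but_moving = "#ff7f0e",
                                      wrong_position = "#d62728")) {
  p <- stream$poses
  if (nrow(p) != nrow(records) || !all(p$frame == records$frame) ||
      !all(p$track_id == records$track_id)) {
    stop("records do not align with the stream's detections", call. = FALSE)
  }
  if (is.null(frames)) frames <- sort(unique(p$frame))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- character()
  for (f in frames) {
    path <- file.path(out_dir, sprintf("frame_%06d.png", f))
    grDevices::png(path, width = frame_size[1], height = frame_size[2])
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot(NA, xlim = c(0, frame_size[1]),
                   ylim = c(frame_size[2], 0),  # image convention: y down
                   xaxs = "i", yaxs = "i", axes = FALSE, xlab = "", ylab = "")
    for (nm in names(regions)) {
      graphics::polygon(regions[[nm]][, 1], regions[[nm]][, 2],
                        border = "grey60", lty = 2)
      graphics::text(mean(regions[[nm]][, 1]), min(regions[[nm]][, 2]),
                     nm, col = "grey60", cex = 0.8, pos = 3)
    }
    rows <- which(p$frame == f)
    for (i in rows) {
      col <- colors[[records$category[i]]]
      kp <- get_pose(stream, p$det_id[i])
      vis <- kp$detected & kp$confidence >= draw_confidence_min
      for (e in seq_len(nrow(.coco_skeleton))) {
        a <- match(.coco_skeleton[e, 1], kp$keypoint)
        b <- match(.coco_skeleton[e, 2], kp$keypoint)
        if (vis[a] && vis[b]) {
          graphics::segments(kp$x[a], kp$y[a], kp$x[b], kp$y[b],
                             col = col, lwd = 2)
        }
      }
      if (any(vis)) {
        graphics::points(kp$x[vis], kp$y[vis], pch = 16, col = col)
      }
      # id + score label near the pose (topmost visible keypoint, or the
      # pose's last known centroid when nothing is drawable)
      lx <- if (any(vis)) kp$x[vis][which.min(kp$y[vis])] else
        mean(kp$x[kp$detected], na.rm = TRUE)
      ly <- if (any(vis)) min(kp$y[vis]) - 12 else
        mean(kp$y[kp$detected], na.rm = TRUE)
      graphics::text(lx, ly, sprintf("#%d %.2f", p$track_id[i],
                                     p$score[i]), col = col, cex = 0.9)
    }
    grDevices::dev.off()
    out <- c(out, path)
  }
  invisible(out)
}
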