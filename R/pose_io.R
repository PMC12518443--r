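#' Construct a pose stream
#'
#' A pose stream is the package's container for per-frame 2D pose
#' detections: a `poses` table (one row per detected person per frame) and a
#' `keypoints` table (one row per keypoint per detection, 17 per pose in
#' the COCO layout). Both tables are kept sorted by frame, then track id,
#' then detection id.
#'
#' @param poses data.frame with columns `det_id` (integer, unique),
#'   `frame` (non-negative integer), `track_id` (integer or `NA` when
#'   untracked) and `score` (pose-level detection confidence in \[0, 1\]).
#' @param keypoints data.frame with columns `det_id`, `keypoint` (COCO
#'   name), `x`, `y` (pixels), `confidence` (in \[0, 1\]) and `detected`
#'   (logical; `FALSE` marks a keypoint absent from the input, whose
#'   coordinates are `NA`).
#' @param n_frames Total recording length in frames; every `frame` must be
#'   `< n_frames`.
#' @param fps_nominal Nominal framerate, metadata only (room cameras in
#'   practice vary between roughly 6 and 26 fps with lighting).
#' @return An object of class `pose_stream`.
#' @export
pose_stream <- function(poses, keypoints, n_frames, fps_nominal = 25) {
  stopifnot(is.data.frame(poses), is.data.frame(keypoints))
  need_p <- c("det_id", "frame", "track_id", "score")
  need_k <- c("det_id", "keypoint", "x", "y", "confidence", "detected")
  if (!all(need_p %in% names(poses))) {
    stop("poses must have columns ", paste(need_p, collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_k %in% names(keypoints))) {
    stop("keypoints must have columns ", paste(need_k, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(poses) > 0) {
    if (any(poses$frame < 0)) stop("frame indices must be non-negative",
                                   call. = FALSE)
    if (any(poses$frame >= n_frames)) {
      stop("every detection frame must be < n_frames", call. = FALSE)
    }
    counts <- table(keypoints$det_id)
    if (any(counts != 17L) || !setequal(names(counts), poses$det_id)) {
      stop("each pose needs exactly 17 keypoints", call. = FALSE)
    }
    .assert_keypoint_names(unique(keypoints$keypoint))
  }
  out <- structure(
    list(poses = poses, keypoints = keypoints,
         n_frames = as.integer(n_frames), fps_nominal = fps_nominal),
    class = "pose_stream")
  .sort_stream(out)
}

# canonical ordering + det_id renumbering so that equal streams compare equal
.sort_stream <- function(stream) {
  p <- stream$poses
  if (nrow(p) == 0) {
    stream$poses <- p[, c("det_id", "frame", "track_id", "score")]
    stream$keypoints <- stream$keypoints[
      , c("det_id", "keypoint", "x", "y", "confidence", "detected")]
    rownames(stream$poses) <- rownames(stream$keypoints) <- NULL
    return(stream)
  }
  ord <- order(p$frame, p$track_id, p$det_id, na.last = TRUE)
  p <- p[ord, , drop = FALSE]
  new_id <- seq_len(nrow(p))
  k <- stream$keypoints
  k$new_id <- new_id[match(k$det_id, p$det_id)]
  k <- k[order(k$new_id, match(k$keypoint, coco_keypoints())), , drop = FALSE]
  k$det_id <- k$new_id
  p$det_id <- new_id
  stream$poses <- p[, c("det_id", "frame", "track_id", "score")]
  stream$keypoints <- k[, c("det_id", "keypoint", "x", "y", "confidence",
                            "detected")]
  rownames(stream$poses) <- rownames(stream$keypoints) <- NULL
  stream
}

#' @export
print.pose_stream <- function(x, ...) {
  tracked <- sum(!is.na(x$poses$track_id))
  cat(sprintf(
    "<pose_stream> %d detections over %d frames (%s fps nominal), %d tracked\n",
    nrow(x$poses), x$n_frames, format(x$fps_nominal), tracked))
  invisible(x)
}

#' Read a pose stream from COCO-style keypoint JSON
#'
#' Reads pose-estimation results: a JSON array of records each carrying a
#' frame index (`frame` or `image_id`), a 51-value keypoint array of
#' `(x, y, confidence)` triplets in COCO order, and a pose-level `score`.
#' The `tracked` dialect additionally requires an integer `track_id` per
#' record. Keypoints whose confidence is exactly 0 or whose coordinates are
#' absent/null are marked undetected. Records are sorted by frame on read,
#' so record order in the file does not matter.
#'
#' @param path Path to the JSON file.
#' @param dialect `"coco_result"` (untracked) or `"tracked"`.
#' @param n_frames Recording length in frames. Defaults to the file's
#'   top-level `n_frames` if the file is an object, else `max(frame) + 1`.
#' @param fps_nominal Nominal framerate metadata (default 25).
#' @return A [pose_stream].
#' @export
read_pose_stream <- function(path, dialect = c("coco_result", "tracked"),
                             n_frames = NULL, fps_nominal = 25) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("malformed JSON in ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  records <- raw
  if (!is.null(names(raw))) {  # wrapped object {n_frames, fps, records}
    records <- raw$records %||% list()
    if (is.null(n_frames) && !is.null(raw$n_frames)) n_frames <- raw$n_frames
    if (!is.null(raw$fps_nominal)) fps_nominal <- raw$fps_nominal
  }
  n <- length(records)
  kp_names <- coco_keypoints()
  poses <- vector("list", n)
  kps <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- records[[i]]
    frame <- rec$frame %||% rec$image_id
    if (is.null(frame)) {
      stop(sprintf("record %d: missing frame/image_id", i), call. = FALSE)
    }
    arr <- unlist(lapply(rec$keypoints, function(v) {
      if (is.null(v)) NA_real_ else as.numeric(v)
    }))
    if (length(arr) != 51L) {
      stop(sprintf("record %d: keypoint array has %d values, expected 51",
                   i, length(arr)), call. = FALSE)
    }
    xs <- arr[seq(1, 51, by = 3)]
    ys <- arr[seq(2, 51, by = 3)]
    cs <- arr[seq(3, 51, by = 3)]
    cs[is.na(cs)] <- 0
    det <- cs > 0 & !is.na(xs) & !is.na(ys)
    xs[!det] <- NA_real_
    ys[!det] <- NA_real_
    tid <- NA_integer_
    if (dialect == "tracked") {
      if (is.null(rec$track_id)) {
        stop(sprintf("record %d: tracked dialect requires track_id", i),
             call. = FALSE)
      }
      tid <- as.integer(rec$track_id)
    } else if (!is.null(rec$track_id)) {
      tid <- as.integer(rec$track_id)
    }
    poses[[i]] <- data.frame(det_id = i, frame = as.integer(frame),
                             track_id = tid,
                             score = as.numeric(rec$score %||% 1))
    kps[[i]] <- data.frame(det_id = i, keypoint = kp_names, x = xs, y = ys,
                           confidence = ifelse(det, cs, 0),
                           detected = det)
  }
  if (n == 0) {
    poses_df <- data.frame(det_id = integer(), frame = integer(),
                           track_id = integer(), score = numeric())
    kps_df <- data.frame(det_id = integer(), keypoint = character(),
                         x = numeric(), y = numeric(),
                         confidence = numeric(), detected = logical())
  } else {
    poses_df <- do.call(rbind, poses)
    kps_df <- do.call(rbind, kps)
  }
  if (is.null(n_frames)) {
    n_frames <- if (n == 0) 0L else max(poses_df$frame) + 1L
  }
  pose_stream(poses_df, kps_df, n_frames = n_frames,
              fps_nominal = fps_nominal)
}

#' Write a pose stream as keypoint JSON
#'
#' Writes the wrapped-object form `{n_frames, fps_nominal, records}` with
#' one record per detection; undetected keypoints are written as
#' `(0, 0, 0)` triplets. Tracked detections carry `track_id`.
#'
#' @param stream A [pose_stream].
#' @param path Output path.
#' @export
write_pose_stream <- function(stream, path) {
  stopifnot(inherits(stream, "pose_stream"))
  p <- stream$poses
  k <- stream$keypoints
  records <- lapply(seq_len(nrow(p)), function(i) {
    ki <- k[k$det_id == p$det_id[i], ]
    ki <- ki[match(coco_keypoints(), ki$keypoint), ]
    trip <- rbind(ifelse(ki$detected, ki$x, 0),
                  ifelse(ki$detected, ki$y, 0),
                  ifelse(ki$detected, ki$confidence, 0))
    rec <- list(frame = p$frame[i], keypoints = as.numeric(trip),
                score = p$score[i])
    if (!is.na(p$track_id[i])) rec$track_id <- p$track_id[i]
    rec
  })
  jsonlite::write_json(
    list(n_frames = stream$n_frames, fps_nominal = stream$fps_nominal,
         records = records),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a region annotation file
#'
#' Room regions are annotated once per camera view as three polygons in
#' image pixel coordinates: where the wrists, the shoulders and the head of
#' a person standing at the operating table should be. The file is a JSON
#' object `{"wrists": [[x,y],...], "shoulders": [...], "head": [...]}`.
#' Polygons are implicitly closed. Self-intersecting polygons are accepted
#' with a warning (containment stays well defined under the even-odd rule).
#'
#' @param path Path to the JSON region file.
#' @return A `region_set`: named list of two-column vertex matrices.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  region_set(lapply(raw, function(m) matrix(unlist(m), ncol = 2,
                                            byrow = !is.matrix(m))))
}

#' Construct a region set
#'
#' @param regions Named list with elements `wrists`, `shoulders` and
#'   `head`, each a two-column matrix (or list of `(x, y)` pairs) of at
#'   least 3 polygon vertices in pixels.
#' @return An object of class `region_set`.
#' @export
region_set <- function(regions) {
  needed <- c("wrists", "shoulders", "head")
  missing <- setdiff(needed, names(regions))
  if (length(missing) > 0) {
    stop("region file missing region(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  regions <- lapply(regions[needed], function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (nrow(m) < 3) stop("each region polygon needs >= 3 vertices",
                          call. = FALSE)
    colnames(m) <- c("x", "y")
    m
  })
  for (nm in needed) {
    if (.polygon_self_intersects(regions[[nm]])) {
      warning(sprintf("region '%s' is self-intersecting; using even-odd containment",
                      nm), call. = FALSE)
    }
  }
  structure(regions, class = "region_set")
}

#' Write a region set to JSON
#' @param regions A `region_set`.
#' @param path Output path.
#' @export
write_regions <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  jsonlite::write_json(
    lapply(unclass(regions), function(m) {
      lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
    }),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# segment-intersection scan over non-adjacent edge pairs
.polygon_self_intersects <- function(m) {
  n <- nrow(m)
  nxt <- c(seq_len(n)[-1], 1L)
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      # skip adjacent edges (share a vertex)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (seg_int(m[i, ], m[nxt[i], ], m[j, ], m[nxt[j], ])) return(TRUE)
    }
  }
  FALSE
}

#' Write classification records to CSV
#'
#' One row per classified pose detection with the header columns
#' `frame,track_id,still,by_table,interacting,category` followed by one
#' boolean column per subpose verdict (`still_*` for movement subposes,
#' `pos_*` for position subposes). Reading the file back with
#' [read_classifications()] reproduces the records exactly.
#'
#' @param records Classification data.frame from [classify_interaction()].
#' @param path Output CSV path.
#' @export
write_classifications <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read classification records from CSV
#' @param path CSV path written by [write_classifications()].
#' @return Classification data.frame.
#' @export
read_classifications <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  logi <- setdiff(names(df), c("frame", "track_id", "category"))
  for (nm in logi) df[[nm]] <- as.logical(df[[nm]])
  df
}

#' Read interval annotations from CSV
#'
#' Interval annotations describe per-person activities (columns
#' `person_id,start_frame,end_frame,label`) or workflow phases (columns
#' `phase,start_frame,end_frame`). Intervals are half-open
#' `[start_frame, end_frame)`.
#'
#' @param path CSV path.
#' @return data.frame of intervals.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (any(df$start_frame >= df$end_frame)) {
    stop("intervals must satisfy start_frame < end_frame", call. = FALSE)
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
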