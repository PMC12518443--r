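#' OKS parameters
#'
#' Per-keypoint falloff constants for object keypoint similarity. The
#' defaults are twice the standard COCO evaluation sigmas (the COCO
#' convention `k_i = 2 * sigma_i`); the object scale `s^2` is taken as the
#' area of the pose's detected-keypoint bounding box.
#'
#' @param per_keypoint_constant Named numeric vector mapping each COCO
#'   keypoint name to its `k_i > 0`.
#' @param scale_mode Currently only `"bbox_area"`.
#' @return An `oks_params` object.
#' @export
oks_params <- function(per_keypoint_constant = 2 * .coco_sigmas,
                       scale_mode = "bbox_area") {
  stopifnot(scale_mode == "bbox_area",
            all(coco_keypoints() %in% names(per_keypoint_constant)),
            all(per_keypoint_constant > 0))
  structure(list(per_keypoint_constant = per_keypoint_constant,
                 scale_mode = scale_mode),
            class = "oks_params")
}

#' Tracker parameters
#'
#' Confidence-prioritised two-stage association in the BYTE style:
#' detections at or above `high_conf_threshold` are matched first, the
#' remainder at or above `low_conf_threshold` second; matches require OKS
#' at or above `oks_match_threshold`; tracklets present on fewer than
#' `min_consecutive_frames` consecutive frames are discarded.
#'
#' @param high_conf_threshold,low_conf_threshold Pose score thresholds in
#'   \[0, 1\], `low <= high`.
#' @param oks_match_threshold Minimum OKS for an association, in \[0, 1\].
#' @param min_consecutive_frames Minimum tracklet length (>= 2).
#' @return A `tracker_params` object.
#' @export
tracker_params <- function(high_conf_threshold = 0.6,
                           low_conf_threshold = 0.1,
                           oks_match_threshold = 0.3,
                           min_consecutive_frames = 2L) {
  stopifnot(low_conf_threshold <= high_conf_threshold,
            min_consecutive_frames >= 2)
  structure(list(high_conf_threshold = high_conf_threshold,
                 low_conf_threshold = low_conf_threshold,
                 oks_match_threshold = oks_match_threshold,
                 min_consecutive_frames = as.integer(min_consecutive_frames)),
            class = "tracker_params")
}

#' Extract one pose's keypoint table from a stream
#' @param stream A [pose_stream].
#' @param det_id Detection id.
#' @return 17-row keypoint data.frame in canonical COCO order.
#' @export
get_pose <- function(stream, det_id) {
  k <- stream$keypoints[stream$keypoints$det_id == det_id, ]
  k[match(coco_keypoints(), k$keypoint), ]
}

#' Object keypoint similarity between two poses
#'
#' Mean Gaussian-falloff term `exp(-d_i^2 / (2 s^2 k_i^2))` over the
#' keypoints detected in both poses, where `d_i` is the pixel distance
#' between the keypoint in `a` and in `b`, `s^2` is the area of `a`'s
#' detected-keypoint bounding box (floored at 1 px^2 for degenerate
#' poses), and `k_i` the per-keypoint falloff constant. If no keypoint is
#' detected in both poses, the similarity is 0.
#'
#' @param a,b 17-row keypoint data.frames (see [get_pose()]) in canonical
#'   order, with `x`, `y`, `detected` columns.
#' @param params An [oks_params()].
#' @return Similarity in \[0, 1\].
#' @export
oks <- function(a, b, params = oks_params()) {
  da <- a$detected
  if (!any(da)) {
    stop("OKS undefined: pose 'a' has no detected keypoints", call. = FALSE)
  }
  shared <- da & b$detected
  if (!any(shared)) return(0)
  s2 <- max((max(a$x[da]) - min(a$x[da])) * (max(a$y[da]) - min(a$y[da])), 1)
  ki <- params$per_keypoint_constant[a$keypoint[shared]]
  d2 <- (a$x[shared] - b$x[shared])^2 + (a$y[shared] - b$y[shared])^2
  mean(exp(-d2 / (2 * s2 * ki^2)))
}

#' Associate one frame's detections with active tracks
#'
#' Two-stage greedy matching on OKS. Stage 1 considers detections with
#' score at or above the high-confidence threshold, pairing them with
#' tracks in descending OKS order and accepting pairs whose OKS meets the
#' match threshold. Stage 2 matches the remaining detections with score at
#' or above the low-confidence threshold to the remaining tracks. Each
#' track and each detection is matched at most once. Unmatched
#' high-confidence detections become new tracks; unmatched low-confidence
#' detections are dropped. Ties in OKS are broken by lower track id, then
#' lower detection index.
#'
#' @param tracks Named list mapping track id (as names) to the track's
#'   last keypoint data.frame.
#' @param detections List of `list(keypoints = <17-row df>, score = s)`.
#' @param tparams A [tracker_params()].
#' @param oparams An [oks_params()].
#' @return List with `matches` (data.frame `det_index`, `track_id`,
#'   `oks`) and `new_tracks` (integer vector of detection indices).
#' @export
associate_frame <- function(tracks, detections,
                            tparams = tracker_params(),
                            oparams = oks_params()) {
  nt <- length(tracks)
  nd <- length(detections)
  track_ids <- as.integer(names(tracks))
  matches <- data.frame(det_index = integer(), track_id = integer(),
                        oks = numeric())
  if (nd == 0) return(list(matches = matches, new_tracks = integer()))
  scores <- vapply(detections, function(d) d$score, numeric(1))

  sim <- matrix(0, nrow = nt, ncol = nd)
  if (nt > 0) {
    for (i in seq_len(nt)) {
      for (j in seq_len(nd)) {
        sim[i, j] <- tryCatch(
          oks(tracks[[i]], detections[[j]]$keypoints, oparams),
          error = function(e) 0)
      }
    }
  }

  free_track <- rep(TRUE, nt)
  free_det <- rep(TRUE, nd)
  greedy_stage <- function(det_pool) {
    repeat {
      cand_t <- which(free_track)
      cand_d <- intersect(which(free_det), det_pool)
      if (length(cand_t) == 0 || length(cand_d) == 0) break
      sub <- sim[cand_t, cand_d, drop = FALSE]
      best <- max(sub)
      if (best < tparams$oks_match_threshold) break
      hits <- which(sub == best, arr.ind = TRUE)
      # ties: lower track id, then lower detection index
      ord <- order(track_ids[cand_t[hits[, 1]]], cand_d[hits[, 2]])
      ti <- cand_t[hits[ord[1], 1]]
      di <- cand_d[hits[ord[1], 2]]
      matches <<- rbind(matches, data.frame(
        det_index = di, track_id = track_ids[ti], oks = sim[ti, di]))
      free_track[ti] <<- FALSE
      free_det[di] <<- FALSE
    }
  }
  high <- which(scores >= tparams$high_conf_threshold)
  greedy_stage(high)
  low <- which(scores >= tparams$low_conf_threshold)
  greedy_stage(low)

  new_tracks <- intersect(which(free_det), high)
  list(matches = matches[order(matches$det_index), , drop = FALSE],
       new_tracks = new_tracks)
}

#' Build tracklets for a pose stream
#'
#' Frame-by-frame confidence-prioritised greedy association on OKS. The
#' tracker is purely geometric: no appearance features and no motion
#' model. A track not matched on the next frame terminates (no re-birth
#' after a gap). Tracklets present on fewer than `min_consecutive_frames`
#' consecutive frames are removed from the output, as are detections that
#' never joined a surviving tracklet. Surviving tracks are renumbered from
#' 1 in order of first appearance.
#'
#' @param stream A [pose_stream]; existing track ids are overwritten.
#' @param tparams A [tracker_params()].
#' @param oparams An [oks_params()].
#' @return A tracked [pose_stream].
#' @export
build_tracklets <- function(stream, tparams = tracker_params(),
                            oparams = oks_params()) {
  stopifnot(inherits(stream, "pose_stream"))
  p <- stream$poses
  if (nrow(p) == 0) return(stream)
  k <- stream$keypoints
  assigned <- rep(NA_integer_, nrow(p))
  next_id <- 1L
  active <- list()       # track_id (as name) -> last keypoint df
  active_frame <- integer()  # parallel: frame of the last detection
  track_len <- integer()     # track id -> consecutive-frame count

  frames <- sort(unique(p$frame))
  for (f in frames) {
    # terminate tracks not matched on the immediately preceding frame
    keep <- active_frame == f - 1L
    active <- active[keep]
    active_frame <- active_frame[keep]

    rows <- which(p$frame == f)
    # det_ids are sequential 1..n with 17 canonical keypoint rows each
    # (guaranteed by the pose_stream constructor), so slice blocks directly
    detections <- lapply(rows, function(i) {
      id <- p$det_id[i]
      list(keypoints = k[((id - 1L) * 17L + 1L):(id * 17L), ],
           score = p$score[i])
    })
    res <- associate_frame(active, detections, tparams, oparams)

    new_active <- list()
    new_frames <- integer()
    if (nrow(res$matches) > 0) {
      for (r in seq_len(nrow(res$matches))) {
        di <- res$matches$det_index[r]
        tid <- res$matches$track_id[r]
        assigned[rows[di]] <- tid
        track_len[tid] <- track_len[tid] + 1L
        new_active[[as.character(tid)]] <- detections[[di]]$keypoints
        new_frames <- c(new_frames, f)
      }
    }
    for (di in res$new_tracks) {
      tid <- next_id
      next_id <- next_id + 1L
      assigned[rows[di]] <- tid
      track_len[tid] <- 1L
      new_active[[as.character(tid)]] <- detections[[di]]$keypoints
      new_frames <- c(new_frames, f)
    }
    active <- new_active
    active_frame <- new_frames
  }

  survives <- which(track_len >= tparams$min_consecutive_frames)
  keep_rows <- !is.na(assigned) & assigned %in% survives
  p <- p[keep_rows, , drop = FALSE]
  p$track_id <- assigned[keep_rows]
  # renumber by first appearance
  first_seen <- unique(p$track_id[order(p$frame, p$track_id)])
  p$track_id <- match(p$track_id, first_seen)
  k <- k[k$det_id %in% p$det_id, , drop = FALSE]
  pose_stream(p, k, n_frames = stream$n_frames,
              fps_nominal = stream$fps_nominal)
}
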