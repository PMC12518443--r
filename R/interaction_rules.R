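#' Displacement of one keypoint over the motion span
#'
#' Net Euclidean distance in pixels between a keypoint's position at
#' `frame` and its position `f_motion` frames earlier within the same
#' tracklet. The displacement is undefined (`NA`) when either endpoint is
#' missing: the track has no detection at `frame - f_motion`, or the
#' keypoint is undetected at either endpoint.
#'
#' @param stream A tracked [pose_stream].
#' @param track_id Track identity.
#' @param frame Frame index; the track must have a detection here.
#' @param keypoint COCO keypoint name.
#' @param f_motion Motion span in frames.
#' @return Displacement in pixels, or `NA` when undefined.
#' @export
keypoint_displacement <- function(stream, track_id, frame, keypoint,
                                  f_motion = 5L) {
  .assert_keypoint_names(keypoint)
  p <- stream$poses
  now <- which(p$track_id == track_id & p$frame == frame)
  if (length(now) != 1) {
    stop(sprintf("track %s has no detection at frame %d",
                 format(track_id), frame), call. = FALSE)
  }
  prev <- which(p$track_id == track_id & p$frame == frame - f_motion)
  if (length(prev) != 1) return(NA_real_)
  k <- stream$keypoints
  a <- k[k$det_id == p$det_id[now] & k$keypoint == keypoint, ]
  b <- k[k$det_id == p$det_id[prev] & k$keypoint == keypoint, ]
  if (!a$detected || !b$detected) return(NA_real_)
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
}

#' Movement verdict for one subpose of one pose
#'
#' A keypoint counts as still if its displacement over the motion span is
#' defined and strictly below the subpose threshold `tau_m`, or if it
#' cannot be assessed (undetected, current-frame confidence strictly below
#' `gamma_m`, or displacement undefined) — unassessable keypoints are
#' assumed still. The subpose is still iff at least `m_keypoint` of its
#' keypoints are still.
#'
#' @param stream A tracked [pose_stream].
#' @param track_id,frame Identify the pose.
#' @param spec A [movement_subpose()].
#' @param f_motion Motion span in frames.
#' @return Logical: is the subpose still?
#' @export
classify_subpose_still <- function(stream, track_id, frame, spec,
                                   f_motion = 5L) {
  p <- stream$poses
  now <- which(p$track_id == track_id & p$frame == frame)
  if (length(now) != 1) {
    stop("pose not found in track", call. = FALSE)
  }
  k <- stream$keypoints[stream$keypoints$det_id == p$det_id[now], ]
  n_still <- 0L
  for (kp in spec$keypoints) {
    row <- k[k$keypoint == kp, ]
    still <- if (!row$detected || row$confidence < spec$gamma_m) {
      TRUE
    } else {
      d <- keypoint_displacement(stream, track_id, frame, kp, f_motion)
      is.na(d) || d < spec$tau_m
    }
    n_still <- n_still + still
  }
  n_still >= spec$m_keypoint
}

#' Movement verdict for one pose
#'
#' A pose is still iff at least `m_subpose` of its movement subposes are
#' still. With the default parameters (1 of shoulders/head) this is a
#' disjunction: shoulders-still OR head-still.
#'
#' @inheritParams classify_subpose_still
#' @param params An [interaction_params()] bundle.
#' @return List with `still` (logical) and `subposes` (named logical
#'   vector of per-subpose verdicts).
#' @export
classify_pose_still <- function(stream, track_id, frame,
                                params = interaction_params()) {
  verdicts <- vapply(params$movement_subposes, function(s) {
    classify_subpose_still(stream, track_id, frame, s, params$f_motion)
  }, logical(1))
  names(verdicts) <- vapply(params$movement_subposes, `[[`, character(1),
                            "name")
  list(still = sum(verdicts) >= params$m_subpose, subposes = verdicts)
}

#' Position verdict for one subpose of one pose
#'
#' A keypoint counts iff it is detected, its confidence is at least
#' `gamma_p`, and it lies within the subpose's annotated region polygon
#' (boundary inclusive, even-odd rule). The subpose is positioned iff at
#' least `p_keypoint` keypoints count.
#'
#' @inheritParams classify_subpose_still
#' @param regions A [region_set()].
#' @param spec A [position_subpose()].
#' @return Logical: is the subpose at the table?
#' @export
classify_subpose_position <- function(stream, track_id, frame, regions,
                                      spec) {
  p <- stream$poses
  now <- which(p$track_id == track_id & p$frame == frame)
  if (length(now) != 1) stop("pose not found in track", call. = FALSE)
  k <- stream$keypoints[stream$keypoints$det_id == p$det_id[now], ]
  poly <- regions[[spec$region_name]]
  n_in <- 0L
  for (kp in spec$keypoints) {
    row <- k[k$keypoint == kp, ]
    if (row$detected && row$confidence >= spec$gamma_p &&
        point_in_polygon(row$x, row$y, poly)) {
      n_in <- n_in + 1L
    }
  }
  n_in >= spec$p_keypoint
}

#' Position verdict for one pose
#'
#' A pose is by the table iff at least `p_subpose` of its position
#' subposes are positioned (default: at least 2 of wrists/shoulders/head).
#'
#' @inheritParams classify_subpose_position
#' @param params An [interaction_params()] bundle.
#' @return List with `by_table` (logical) and `subposes` (named logical).
#' @export
classify_pose_position <- function(stream, track_id, frame, regions,
                                   params = interaction_params()) {
  verdicts <- vapply(params$position_subposes, function(s) {
    classify_subpose_position(stream, track_id, frame, regions, s)
  }, logical(1))
  names(verdicts) <- vapply(params$position_subposes, `[[`, character(1),
                            "region_name")
  list(by_table = sum(verdicts) >= params$p_subpose, subposes = verdicts)
}

#' Classify every detection of a tracked pose stream
#'
#' Applies the combined rule: a pose interacts with the operating table
#' iff it is simultaneously still (movement rule) and by the table
#' (position rule). Returns one record per pose detection with the full
#' audit trail of per-subpose verdicts and the three-way display category:
#' `interacting`, `positioned_but_moving` (right position but moving too
#' fast to interact), or `wrong_position`.
#'
#' @param stream A tracked [pose_stream] (run [build_tracklets()] first if
#'   track ids are missing).
#' @param regions A [region_set()].
#' @param params An [interaction_params()] bundle (defaults to the
#'   published operating point).
#' @return data.frame with columns `frame`, `track_id`, `still`,
#'   `by_table`, `interacting`, `category`, one `still_<subpose>` column
#'   per movement subpose and one `pos_<region>` column per position
#'   subpose.
#' @export
classify_interaction <- function(stream, regions,
                                 params = interaction_params()) {
  stopifnot(inherits(stream, "pose_stream"), inherits(regions, "region_set"))
  p <- stream$poses
  n <- nrow(p)
  m_names <- vapply(params$movement_subposes, `[[`, character(1), "name")
  p_names <- vapply(params$position_subposes, `[[`, character(1),
                    "region_name")
  if (n == 0) {
    out <- data.frame(frame = integer(), track_id = integer(),
                      still = logical(), by_table = logical(),
                      interacting = logical(), category = character())
    for (nm in m_names) out[[paste0("still_", nm)]] <- logical()
    for (nm in p_names) out[[paste0("pos_", nm)]] <- logical()
    return(out)
  }
  if (anyNA(p$track_id)) {
    stop("stream is untracked; run build_tracklets() first", call. = FALSE)
  }
  k <- stream$keypoints
  idx <- match(k$det_id, p$det_id)
  frame <- p$frame[idx]
  track <- p$track_id[idx]

  # previous-endpoint lookup within the same tracklet, by frame arithmetic
  key_now <- paste(track, frame, k$keypoint)
  key_prev <- paste(track, frame - params$f_motion, k$keypoint)
  det <- k$detected
  prev_idx <- match(key_prev, key_now[det])
  prev_x <- k$x[det][prev_idx]
  prev_y <- k$y[det][prev_idx]
  disp <- sqrt((k$x - prev_x)^2 + (k$y - prev_y)^2)
  disp[!det] <- NA_real_

  # keypoints arrive in canonical COCO order per detection (.sort_stream),
  # so per-row vectors reshape into a 17 x n matrix
  kp_mat_names <- coco_keypoints()
  as_kp_matrix <- function(v) {
    m <- matrix(v, nrow = 17L)
    rownames(m) <- kp_mat_names
    m
  }
  conf_m <- as_kp_matrix(k$confidence)
  det_m <- as_kp_matrix(det)
  disp_m <- as_kp_matrix(disp)

  still_sub <- matrix(NA, nrow = n, ncol = length(m_names),
                      dimnames = list(NULL, m_names))
  for (j in seq_along(params$movement_subposes)) {
    s <- params$movement_subposes[[j]]
    sel <- s$keypoints
    kp_still <- !det_m[sel, , drop = FALSE] |
      conf_m[sel, , drop = FALSE] < s$gamma_m |
      is.na(disp_m[sel, , drop = FALSE]) |
      disp_m[sel, , drop = FALSE] < s$tau_m
    kp_still[is.na(kp_still)] <- TRUE  # NA arises only from NA displacement
    still_sub[, j] <- colSums(kp_still) >= s$m_keypoint
  }
  still <- rowSums(still_sub) >= params$m_subpose

  pos_sub <- matrix(NA, nrow = n, ncol = length(p_names),
                    dimnames = list(NULL, p_names))
  for (j in seq_along(params$position_subposes)) {
    s <- params$position_subposes[[j]]
    poly <- regions[[s$region_name]]
    inside <- rep(FALSE, nrow(k))
    inside[det] <- point_in_polygon(k$x[det], k$y[det], poly)
    counted <- det & k$confidence >= s$gamma_p & inside
    cnt_m <- as_kp_matrix(counted)[s$keypoints, , drop = FALSE]
    pos_sub[, j] <- colSums(cnt_m) >= s$p_keypoint
  }
  by_table <- rowSums(pos_sub) >= params$p_subpose

  interacting <- still & by_table
  category <- ifelse(interacting, "interacting",
                     ifelse(by_table, "positioned_but_moving",
                            "wrong_position"))
  out <- data.frame(frame = p$frame, track_id = p$track_id,
                    still = still, by_table = by_table,
                    interacting = interacting, category = category)
  for (j in seq_along(m_names)) {
    out[[paste0("still_", m_names[j])]] <- as.logical(still_sub[, j])
  }
  for (j in seq_along(p_names)) {
    out[[paste0("pos_", p_names[j])]] <- as.logical(pos_sub[, j])
  }
  out
}
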