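# Hand-built pose streams for rule tests.
#
# ts_pose(frame, track, score, kp) describes one detection; `kp` is a named
# list keypoint -> c(x, y, confidence). Unlisted keypoints are undetected.

ts_pose <- function(frame, track = 1L, score = 0.9, kp = list()) {
  list(frame = as.integer(frame), track = as.integer(track),
       score = score, kp = kp)
}

ts_stream <- function(poses, n_frames = NULL) {
  kp_names <- coco_keypoints()
  if (length(poses) == 0) {
    return(pose_stream(
      data.frame(det_id = integer(), frame = integer(),
                 track_id = integer(), score = numeric()),
      data.frame(det_id = integer(), keypoint = character(),
                 x = numeric(), y = numeric(), confidence = numeric(),
                 detected = logical()),
      n_frames = if (is.null(n_frames)) 0L else n_frames))
  }
  p <- do.call(rbind, lapply(seq_along(poses), function(i) {
    data.frame(det_id = i, frame = poses[[i]]$frame,
               track_id = poses[[i]]$track, score = poses[[i]]$score)
  }))
  k <- do.call(rbind, lapply(seq_along(poses), function(i) {
    kp <- poses[[i]]$kp
    det <- kp_names %in% names(kp)
    get <- function(j) vapply(kp_names, function(nm) {
      if (nm %in% names(kp)) kp[[nm]][j] else NA_real_
    }, numeric(1))
    data.frame(det_id = i, keypoint = kp_names,
               x = get(1), y = get(2),
               confidence = ifelse(det, get(3), 0), detected = det)
  }))
  if (is.null(n_frames)) n_frames <- max(p$frame) + 1L
  pose_stream(p, k, n_frames = n_frames)
}

# a full standing pose: all 17 keypoints at template-free positions around
# an anchor, all at the given confidence
ts_full_kp <- function(x, y, confidence = 0.9) {
  offs <- list(
    nose = c(0, -45), left_eye = c(8, -50), right_eye = c(-8, -50),
    left_ear = c(18, -45), right_ear = c(-18, -45),
    left_shoulder = c(40, 0), right_shoulder = c(-40, 0),
    left_elbow = c(50, 45), right_elbow = c(-50, 45),
    left_wrist = c(53, 85), right_wrist = c(-53, 85),
    left_hip = c(22, 95), right_hip = c(-22, 95),
    left_knee = c(24, 165), right_knee = c(-24, 165),
    left_ankle = c(26, 230), right_ankle = c(-26, 230))
  lapply(offs, function(o) c(x + o[1], y + o[2], confidence))
}

ts_rect <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

ts_regions <- function(x0 = 0, y0 = 0, x1 = 1000, y1 = 1000) {
  region_set(list(wrists = ts_rect(x0, y0, x1, y1),
                  shoulders = ts_rect(x0, y0, x1, y1),
                  head = ts_rect(x0, y0, x1, y1)))
}

# Random tracked streams exercising the rule set: keypoints scattered with
# per-frame steps straddling the displacement threshold, confidences
# straddling both gamma thresholds, and random dropout.
random_rule_stream <- function(n_tracks, n_per_track, seed,
                               box = c(0, 0, 600, 600),
                               dropout = 0.25, step_max = 40) {
  set.seed(seed)
  kp_names <- coco_keypoints()
  poses <- list()
  for (t in seq_len(n_tracks)) {
    f0 <- sample(0:3, 1)
    cx <- runif(1, box[1], box[3])
    cy <- runif(1, box[2], box[4])
    pos <- matrix(runif(17 * 2, -60, 60), ncol = 2) + cbind(rep(cx, 17), cy)
    for (j in seq_len(n_per_track)) {
      pos <- pos + matrix(runif(17 * 2, -step_max, step_max), ncol = 2)
      det <- runif(17) > dropout
      kp <- list()
      for (i in which(det)) {
        kp[[kp_names[i]]] <- c(pos[i, 1], pos[i, 2], runif(1))
      }
      poses[[length(poses) + 1L]] <-
        ts_pose(f0 + j - 1L, track = t, score = runif(1, 0.5, 1), kp = kp)
    }
  }
  ts_stream(poses)
}

random_regions <- function(seed, box = c(0, 0, 600, 600)) {
  set.seed(seed + 1000L)
  rand_poly <- function() {
    if (runif(1) < 0.5) {
      x <- sort(runif(2, box[1], box[3])); y <- sort(runif(2, box[2], box[4]))
      ts_rect(x[1], y[1], x[2], y[2])
    } else {
      cbind(x = runif(3, box[1], box[3]), y = runif(3, box[2], box[4]))
    }
  }
  suppressWarnings(region_set(list(wrists = rand_poly(),
                                   shoulders = rand_poly(),
                                   head = rand_poly())))
}
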