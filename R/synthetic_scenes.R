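# Upright 17-keypoint stick-figure template, in units of shoulder width,
# anchored at the shoulder midpoint; image convention (y grows downward).
# The classifier only reads head, shoulders and wrists, so gait realism is
# deliberately out of scope.
.skeleton_template <- matrix(c(
  #            x      y
  0.00, -0.55,   # nose
  0.10, -0.62,   # left_eye
  -0.10, -0.62,  # right_eye
  0.22, -0.55,   # left_ear
  -0.22, -0.55,  # right_ear
  0.50,  0.00,   # left_shoulder
  -0.50,  0.00,  # right_shoulder
  0.62,  0.55,   # left_elbow
  -0.62,  0.55,  # right_elbow
  0.66,  1.05,   # left_wrist
  -0.66,  1.05,  # right_wrist
  0.28,  1.20,   # left_hip
  -0.28,  1.20,  # right_hip
  0.30,  2.05,   # left_knee
  -0.30,  2.05,  # right_knee
  0.32,  2.90,   # left_ankle
  -0.32,  2.90), # right_ankle
  ncol = 2, byrow = TRUE,
  dimnames = list(c("nose", "left_eye", "right_eye", "left_ear",
                    "right_ear", "left_shoulder", "right_shoulder",
                    "left_elbow", "right_elbow", "left_wrist",
                    "right_wrist", "left_hip", "right_hip", "left_knee",
                    "right_knee", "left_ankle", "right_ankle"),
                  c("x", "y")))

#' Scripted actor for synthetic scenes
#'
#' An actor follows piecewise-linear waypoint trajectories (anchor = the
#' midpoint between the shoulders) and is present in the room from its
#' first to its last waypoint frame. During declared still intervals the
#' actor holds the position it had at the interval start. The role tag is
#' metadata only — the rule set never sees it, which allows
#' intent-vs-rule divergence experiments (e.g. a cleaner standing still by
#' the table fires the rule without intending patient interaction).
#'
#' @param actor_id Integer id (used as the ground-truth track id).
#' @param waypoints data.frame with columns `frame`, `x`, `y` (pixels),
#'   strictly increasing in `frame`.
#' @param still_intervals Optional data.frame with `start_frame`,
#'   `end_frame` (half-open), each within the waypoint span.
#' @param role_tag `"staff"`, `"spectator"` or `"patient"` (metadata).
#' @param body_scale Shoulder width in pixels.
#' @return An `actor_script` object.
#' @export
actor_script <- function(actor_id, waypoints, still_intervals = NULL,
                         role_tag = c("staff", "spectator", "patient"),
                         body_scale = 80) {
  role_tag <- match.arg(role_tag)
  stopifnot(all(c("frame", "x", "y") %in% names(waypoints)),
            nrow(waypoints) >= 1, body_scale > 0)
  if (is.unsorted(waypoints$frame, strictly = TRUE)) {
    stop("waypoints must be strictly increasing in frame", call. = FALSE)
  }
  if (is.null(still_intervals)) {
    still_intervals <- data.frame(start_frame = integer(),
                                  end_frame = integer())
  }
  if (nrow(still_intervals) > 0) {
    lo <- min(waypoints$frame); hi <- max(waypoints$frame)
    if (any(still_intervals$start_frame >= still_intervals$end_frame)) {
      stop("still intervals must satisfy start_frame < end_frame",
           call. = FALSE)
    }
    if (any(still_intervals$start_frame < lo |
            still_intervals$end_frame > hi + 1)) {
      stop("still interval outside the actor's waypoint span",
           call. = FALSE)
    }
  }
  structure(list(actor_id = as.integer(actor_id), waypoints = waypoints,
                 still_intervals = still_intervals, role_tag = role_tag,
                 body_scale = body_scale),
            class = "actor_script")
}

#' Observation noise model for synthetic scenes
#'
#' Emulates pose-detector imperfections: isotropic Gaussian jitter on
#' keypoint coordinates, independent per-keypoint dropout (elevated
#' during declared low-light intervals, when surgical room lights are
#' dimmed and detection collapses), and keypoint confidences drawn from a
#' Beta distribution. Dropped keypoints are written as undetected
#' (confidence 0), never as low-positive.
#'
#' @param jitter_sigma Keypoint coordinate jitter, pixels (sd).
#' @param dropout_prob Baseline per-keypoint dropout probability.
#' @param conf_shape1,conf_shape2 Beta parameters of detected-keypoint
#'   confidence (defaults mean 0.9, mimicking a confident detector).
#' @param lowlight_intervals Optional data.frame `start_frame`,
#'   `end_frame` (half-open) with elevated dropout.
#' @param lowlight_dropout Extra dropout probability added inside
#'   low-light intervals (total capped at 1).
#' @param seed Integer RNG seed; identical inputs and seed give
#'   bit-identical streams.
#' @return A `noise_model` object.
#' @export
noise_model <- function(jitter_sigma = 0, dropout_prob = 0,
                        conf_shape1 = 18, conf_shape2 = 2,
                        lowlight_intervals = NULL,
                        lowlight_dropout = 0.6, seed = 1L) {
  stopifnot(jitter_sigma >= 0, dropout_prob >= 0, dropout_prob <= 1,
            lowlight_dropout >= 0, lowlight_dropout <= 1)
  if (is.null(lowlight_intervals)) {
    lowlight_intervals <- data.frame(start_frame = integer(),
                                     end_frame = integer())
  }
  structure(list(jitter_sigma = jitter_sigma, dropout_prob = dropout_prob,
                 conf_shape1 = conf_shape1, conf_shape2 = conf_shape2,
                 lowlight_intervals = lowlight_intervals,
                 lowlight_dropout = lowlight_dropout,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# noise-free keypoint positions of one actor over its presence span
.actor_positions <- function(script, n_frames) {
  fs <- max(0L, min(script$waypoints$frame)):
    min(n_frames - 1L, max(script$waypoints$frame))
  pos <- .interp_waypoints(script$waypoints, fs)
  si <- script$still_intervals
  for (i in seq_len(nrow(si))) {
    hold <- .interp_waypoints(script$waypoints, si$start_frame[i])
    sel <- fs >= si$start_frame[i] & fs < si$end_frame[i]
    pos$x[sel] <- hold$x
    pos$y[sel] <- hold$y
  }
  list(frames = fs, x = pos$x, y = pos$y)
}

#' Simulate a synthetic operating-room pose stream
#'
#' Places each scripted actor's 17 keypoints on a fixed upright skeleton
#' template at its interpolated anchor position per frame, then applies
#' the noise model (jitter, dropout, confidence sampling). Ground truth
#' is defined by running the interaction rule set on the noise-free
#' scene, not by the scripts' intent flags. Actor-frames where every
#' keypoint drops out produce no detection (a missed person). The
#' returned stream carries the true actor ids as track ids.
#'
#' Random draws are consumed in a fixed order and quantity independent of
#' the noise parameter values, so runs with the same seed are coupled:
#' raising `dropout_prob` alone can only turn detected keypoints into
#' dropped ones, never the reverse.
#'
#' @param scripts List of [actor_script()] objects.
#' @param regions A [region_set()] (used for the ground-truth
#'   classification).
#' @param noise A [noise_model()].
#' @param n_frames Recording length in frames.
#' @param params [interaction_params()] used for the ground truth.
#' @param phases Optional [phase_intervals()]; defaults to four equal
#'   quarters (induction, preparation, surgery, recovery).
#' @param fps_nominal Framerate metadata.
#' @return List with elements `stream` (noisy tracked [pose_stream]),
#'   `truth` (ground-truth classification records of the noise-free
#'   scene), `truth_stream` (the noise-free stream), `activities`
#'   (interval annotations derived from the scripts, with `category`),
#'   `phases`, and `regions`.
#' @export
simulate_scene <- function(scripts, regions, noise = noise_model(),
                           n_frames, params = interaction_params(),
                           phases = NULL, fps_nominal = 25) {
  stopifnot(length(scripts) > 0,
            all(vapply(scripts, inherits, logical(1), "actor_script")))
  ids <- vapply(scripts, `[[`, integer(1), "actor_id")
  if (anyDuplicated(ids)) stop("duplicate actor_id", call. = FALSE)
  kp_names <- coco_keypoints()

  clean_poses <- list(); clean_kps <- list()
  noisy_poses <- list(); noisy_kps <- list()
  det_counter <- 0L
  set.seed(noise$seed)
  ll <- noise$lowlight_intervals

  for (s in scripts) {
    ap <- .actor_positions(s, n_frames)
    naf <- length(ap$frames)
    if (naf == 0) next
    # template keypoints at every frame: 17 x naf
    tx <- outer(.skeleton_template[, "x"] * s$body_scale, ap$x, `+`)
    ty <- outer(.skeleton_template[, "y"] * s$body_scale, ap$y, `+`)

    # fixed-order, fixed-count draws (coupling across noise settings)
    jx <- matrix(stats::rnorm(17 * naf), nrow = 17) * noise$jitter_sigma
    jy <- matrix(stats::rnorm(17 * naf), nrow = 17) * noise$jitter_sigma
    u_drop <- matrix(stats::runif(17 * naf), nrow = 17)
    u_conf <- matrix(stats::runif(17 * naf), nrow = 17)

    p_drop <- rep(noise$dropout_prob, naf)
    for (i in seq_len(nrow(ll))) {
      sel <- ap$frames >= ll$start_frame[i] & ap$frames < ll$end_frame[i]
      p_drop[sel] <- pmin(1, p_drop[sel] + noise$lowlight_dropout)
    }
    dropped <- sweep(u_drop, 2, p_drop, `<`)
    conf <- stats::qbeta(u_conf, noise$conf_shape1, noise$conf_shape2)

    ids <- det_counter + seq_len(naf)
    det_counter <- det_counter + naf
    a <- length(clean_poses) + 1L
    clean_poses[[a]] <- data.frame(
      det_id = ids, frame = ap$frames, track_id = s$actor_id, score = 1)
    clean_kps[[a]] <- data.frame(
      det_id = rep(ids, each = 17L), keypoint = rep(kp_names, naf),
      x = as.vector(tx), y = as.vector(ty), confidence = 1,
      detected = TRUE)

    det <- !dropped
    seen <- colSums(det) > 0L  # frames where the person is not missed
    if (any(seen)) {
      kx <- as.vector((tx + jx)[, seen, drop = FALSE])
      ky <- as.vector((ty + jy)[, seen, drop = FALSE])
      kc <- as.vector(conf[, seen, drop = FALSE])
      kd <- as.vector(det[, seen, drop = FALSE])
      noisy_poses[[a]] <- data.frame(
        det_id = ids[seen], frame = ap$frames[seen],
        track_id = s$actor_id,
        score = colSums((conf * det)[, seen, drop = FALSE]) /
          colSums(det[, seen, drop = FALSE]))
      noisy_kps[[a]] <- data.frame(
        det_id = rep(ids[seen], each = 17L),
        keypoint = rep(kp_names, sum(seen)),
        x = ifelse(kd, kx, NA_real_), y = ifelse(kd, ky, NA_real_),
        confidence = ifelse(kd, kc, 0), detected = kd)
    }
  }

  bind <- function(l) do.call(rbind, l[!vapply(l, is.null, logical(1))])
  empty_p <- data.frame(det_id = integer(), frame = integer(),
                        track_id = integer(), score = numeric())
  empty_k <- data.frame(det_id = integer(), keypoint = character(),
                        x = numeric(), y = numeric(),
                        confidence = numeric(), detected = logical())
  clean_stream <- pose_stream(bind(clean_poses) %||% empty_p,
                              bind(clean_kps) %||% empty_k,
                              n_frames, fps_nominal)
  noisy_stream <- pose_stream(bind(noisy_poses) %||% empty_p,
                              bind(noisy_kps) %||% empty_k,
                              n_frames, fps_nominal)

  truth <- classify_interaction(clean_stream, regions, params)
  if (is.null(phases)) {
    q <- floor(n_frames / 4)
    phases <- phase_intervals(
      c("induction", "preparation", "surgery", "recovery"),
      c(0, q, 2 * q, 3 * q), c(q, 2 * q, 3 * q, n_frames))
  }
  activities <- .script_activities(scripts, n_frames)
  list(stream = noisy_stream, truth = truth, truth_stream = clean_stream,
       activities = activities, phases = phases, regions = regions)
}

# interval activity annotations induced by the scripts: still intervals of
# staff become patient-facing work, the rest of the presence span 'other';
# frames outside the presence span are 'absence'
.script_activities <- function(scripts, n_frames) {
  rows <- list()
  add <- function(pid, s, e, label, cat) {
    if (s < e) rows[[length(rows) + 1L]] <<- data.frame(
      person_id = pid, start_frame = s, end_frame = e, label = label,
      category = cat)
  }
  for (sc in scripts) {
    lo <- max(0L, min(sc$waypoints$frame))
    hi <- min(n_frames, max(sc$waypoints$frame) + 1L)
    add(sc$actor_id, 0L, lo, "absence", "absence")
    cur <- lo
    si <- sc$still_intervals
    si <- si[order(si$start_frame), , drop = FALSE]
    busy_label <- if (sc$role_tag == "staff") "table_work" else "observing"
    busy_cat <- if (sc$role_tag == "staff") "patient_interaction" else "other"
    for (i in seq_len(nrow(si))) {
      add(sc$actor_id, cur, min(si$start_frame[i], hi), "moving_about",
          "other")
      add(sc$actor_id, max(cur, si$start_frame[i]), min(si$end_frame[i], hi),
          busy_label, busy_cat)
      cur <- min(si$end_frame[i], hi)
    }
    add(sc$actor_id, cur, hi, "moving_about", "other")
    add(sc$actor_id, hi, n_frames, "absence", "absence")
  }
  do.call(rbind, rows)
}

#' Canned synthetic scenes
#'
#' Deterministic small scenes for tests and documentation, in a 1280x720
#' view with the operating table region band across the image centre:
#' \describe{
#'   \item{quiet_room}{one staff member standing still at the table for
#'     all 2000 frames (expected interaction fraction 1 with zero noise).}
#'   \item{spectators}{two staff still at the table plus two spectators
#'     standing far from it (expected fraction 0.5 with zero noise).}
#'   \item{busy_table}{two staff still at the table and one who walks in,
#'     works, and walks out, over 2400 frames.}
#'   \item{lowlight}{two staff at the table with a marked low-light
#'     interval (frames 800-1200) of elevated keypoint dropout.}
#' }
#'
#' @param name Fixture name.
#' @param noise Optional [noise_model()] override (the lowlight fixture
#'   keeps its low-light interval unless you supply one).
#' @return List with `scripts`, `regions`, `noise`, `n_frames`, ready for
#'   [simulate_scene()].
#' @export
make_fixture <- function(name = c("quiet_room", "busy_table", "spectators",
                                  "lowlight"),
                         noise = NULL) {
  name <- match.arg(name)
  regions <- region_set(list(
    wrists = cbind(x = c(380, 900, 900, 380), y = c(340, 340, 470, 470)),
    shoulders = cbind(x = c(380, 900, 900, 380), y = c(235, 235, 345, 345)),
    head = cbind(x = c(380, 900, 900, 380), y = c(170, 170, 285, 285))))
  at_table <- function(id, x, n_frames) actor_script(
    id, data.frame(frame = c(0, n_frames), x = x, y = 300),
    still_intervals = data.frame(start_frame = 0, end_frame = n_frames),
    role_tag = "staff")
  spectator <- function(id, x, y, n_frames) actor_script(
    id, data.frame(frame = c(0, n_frames), x = x, y = y),
    still_intervals = data.frame(start_frame = 0, end_frame = n_frames),
    role_tag = "spectator")
  fx <- switch(name,
    quiet_room = list(
      scripts = list(at_table(1, 640, 2000)),
      n_frames = 2000L),
    spectators = list(
      scripts = list(at_table(1, 540, 2000), at_table(2, 740, 2000),
                     spectator(3, 150, 620, 2000),
                     spectator(4, 1130, 620, 2000)),
      n_frames = 2000L),
    busy_table = list(
      scripts = list(
        at_table(1, 520, 2400), at_table(2, 760, 2400),
        actor_script(3, data.frame(
          frame = c(0, 60, 2340, 2400),
          x = c(180, 640, 640, 180),
          y = c(620, 300, 300, 620)),
          still_intervals = data.frame(start_frame = 60, end_frame = 2340),
          role_tag = "staff")),
      n_frames = 2400L),
    lowlight = list(
      scripts = list(at_table(1, 540, 2000), at_table(2, 740, 2000)),
      n_frames = 2000L,
      noise = noise_model(jitter_sigma = 1, dropout_prob = 0.05,
                          lowlight_intervals = data.frame(
                            start_frame = 800, end_frame = 1200))))
  fx$regions <- regions
  if (!is.null(noise)) fx$noise <- noise
  if (is.null(fx$noise)) fx$noise <- noise_model()
  fx$name <- name
  fx
}
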