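#' Movement subpose specification
#'
#' A movement subpose is a named subset of keypoints classified as still or
#' moving as a unit. A keypoint counts as still when its displacement over
#' the motion span is defined and strictly below `tau_m` pixels, or when it
#' cannot be assessed: undetected, detected with confidence strictly below
#' `gamma_m` at the current frame, or lacking a displacement endpoint. The
#' subpose is still when at least `m_keypoint` of its keypoints are.
#'
#' @param name Subpose name (used for the audit column `still_<name>`).
#' @param keypoints Character vector of COCO keypoint names.
#' @param m_keypoint Minimum number of still keypoints (>= 1,
#'   <= `length(keypoints)`).
#' @param tau_m Displacement threshold in pixels (> 0) over the motion span.
#' @param gamma_m Keypoint confidence threshold in \[0, 1\].
#' @return A `movement_subpose` object.
#' @export
movement_subpose <- function(name, keypoints, m_keypoint, tau_m, gamma_m) {
  .assert_keypoint_names(keypoints)
  stopifnot(m_keypoint >= 1, m_keypoint <= length(keypoints),
            tau_m > 0, gamma_m >= 0, gamma_m <= 1)
  structure(list(name = name, keypoints = keypoints,
                 m_keypoint = as.integer(m_keypoint),
                 tau_m = tau_m, gamma_m = gamma_m),
            class = "movement_subpose")
}

#' Position subpose specification
#'
#' A position subpose is checked against the annotated room region of the
#' same name. A keypoint counts as inside when it is detected, has
#' confidence at least `gamma_p`, and falls within the region polygon
#' (boundary inclusive, even-odd rule). The subpose is positioned when at
#' least `p_keypoint` of its keypoints count.
#'
#' @param region_name One of `"wrists"`, `"shoulders"`, `"head"`.
#' @param keypoints Character vector of COCO keypoint names.
#' @param p_keypoint Minimum number of in-region keypoints.
#' @param gamma_p Keypoint confidence threshold in \[0, 1\]; keypoints
#'   below it are not counted within any region.
#' @return A `position_subpose` object.
#' @export
position_subpose <- function(region_name, keypoints, p_keypoint, gamma_p) {
  stopifnot(region_name %in% c("wrists", "shoulders", "head"))
  .assert_keypoint_names(keypoints)
  stopifnot(p_keypoint >= 1, p_keypoint <= length(keypoints),
            gamma_p >= 0, gamma_p <= 1)
  structure(list(region_name = region_name, keypoints = keypoints,
                 p_keypoint = as.integer(p_keypoint), gamma_p = gamma_p),
            class = "position_subpose")
}

#' Interaction classification parameters
#'
#' Bundles every tunable of the movement/position/interaction rule set.
#' The defaults are the published operating-point: motion measured over a
#' span of 5 frames; a pose is still when at least 1 of the two movement
#' subposes (shoulders, head) is still, each requiring 1 keypoint below
#' 17.5 px displacement at confidence threshold 0.3; a pose is by the
#' table when at least 2 of the three position subposes are positioned —
#' wrists (1 of 2 keypoints, confidence 0.3), shoulders (1 of 2,
#' confidence 0.3) and head (2 of the 5 face keypoints, confidence 0.15).
#' Legs are excluded (worst detection rates); arm movement is ignored
#' because arms legitimately move during table interaction.
#'
#' @param f_motion Motion span in frames (positive integer).
#' @param movement_subposes List of [movement_subpose()] specs.
#' @param m_subpose Minimum number of still subposes for a still pose.
#' @param position_subposes List of [position_subpose()] specs.
#' @param p_subpose Minimum number of positioned subposes for a by-table
#'   pose.
#' @return An `interaction_params` object.
#' @export
#' @examples
#' p <- interaction_params()
#' p$f_motion           # 5
#' p$movement_subposes[[1]]$tau_m   # 17.5
interaction_params <- function(
    f_motion = 5L,
    movement_subposes = list(
      movement_subpose("shoulders", c("left_shoulder", "right_shoulder"),
                       m_keypoint = 1L, tau_m = 17.5, gamma_m = 0.3),
      movement_subpose("head",
                       c("nose", "left_eye", "right_eye",
                         "left_ear", "right_ear"),
                       m_keypoint = 1L, tau_m = 17.5, gamma_m = 0.3)),
    m_subpose = 1L,
    position_subposes = list(
      position_subpose("wrists", c("left_wrist", "right_wrist"),
                       p_keypoint = 1L, gamma_p = 0.3),
      position_subpose("shoulders", c("left_shoulder", "right_shoulder"),
                       p_keypoint = 1L, gamma_p = 0.3),
      position_subpose("head",
                       c("nose", "left_eye", "right_eye",
                         "left_ear", "right_ear"),
                       p_keypoint = 2L, gamma_p = 0.15)),
    p_subpose = 2L) {
  stopifnot(f_motion >= 1,
            m_subpose >= 1, m_subpose <= length(movement_subposes),
            p_subpose >= 1, p_subpose <= length(position_subposes))
  stopifnot(all(vapply(movement_subposes, inherits, logical(1),
                       "movement_subpose")),
            all(vapply(position_subposes, inherits, logical(1),
                       "position_subpose")))
  structure(list(f_motion = as.integer(f_motion),
                 movement_subposes = movement_subposes,
                 m_subpose = as.integer(m_subpose),
                 position_subposes = position_subposes,
                 p_subpose = as.integer(p_subpose)),
            class = "interaction_params")
}

#' @export
print.interaction_params <- function(x, ...) {
  cat(sprintf("<interaction_params> f_motion=%d, M_subpose=%d/%d, P_subpose=%d/%d\n",
              x$f_motion, x$m_subpose, length(x$movement_subposes),
              x$p_subpose, length(x$position_subposes)))
  for (s in x$movement_subposes) {
    cat(sprintf("  movement %-10s M=%d tau=%.1fpx gamma=%.2f [%s]\n",
                s$name, s$m_keypoint, s$tau_m, s$gamma_m,
                paste(s$keypoints, collapse = ",")))
  }
  for (s in x$position_subposes) {
    cat(sprintf("  position %-10s P=%d gamma=%.2f [%s]\n",
                s$region_name, s$p_keypoint, s$gamma_p,
                paste(s$keypoints, collapse = ",")))
  }
  invisible(x)
}

#' Read interaction parameters from a YAML/JSON-style config
#'
#' Accepts a JSON file whose keys mirror the rule symbols
#' (`f_motion`, `m_subpose`, `p_subpose`, `movement_subposes`,
#' `position_subposes`); omitted keys keep their defaults.
#'
#' @param path JSON config path.
#' @return An `interaction_params` object.
#' @export
read_interaction_params <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  defaults <- interaction_params()
  ms <- if (is.null(cfg$movement_subposes)) defaults$movement_subposes else
    lapply(cfg$movement_subposes, function(s) {
      movement_subpose(s$name, unlist(s$keypoints), s$m_keypoint %||% 1L,
                       s$tau_m %||% 17.5, s$gamma_m %||% 0.3)
    })
  ps <- if (is.null(cfg$position_subposes)) defaults$position_subposes else
    lapply(cfg$position_subposes, function(s) {
      position_subpose(s$region_name, unlist(s$keypoints),
                       s$p_keypoint %||% 1L, s$gamma_p %||% 0.3)
    })
  interaction_params(
    f_motion = cfg$f_motion %||% defaults$f_motion,
    movement_subposes = ms,
    m_subpose = cfg$m_subpose %||% defaults$m_subpose,
    position_subposes = ps,
    p_subpose = cfg$p_subpose %||% defaults$p_subpose)
}
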