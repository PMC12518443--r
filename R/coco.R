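#' The 17 COCO keypoint names, in canonical order
#'
#' Anatomical landmark names used throughout the package, in the order the
#' 51-value `(x, y, confidence)` triplet arrays of COCO keypoint result
#' files are laid out.
#'
#' @return Character vector of length 17.
#' @export
#' @examples
#' coco_keypoints()
coco_keypoints <- function() {
  c("nose",
    "left_eye", "right_eye",
    "left_ear", "right_ear",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle")
}

# Per-keypoint COCO falloff constants k_i = 2 * sigma_i, where sigma_i are
# the standard COCO keypoint evaluation sigmas. Facial keypoints are tightly
# localised (small k), hips and legs loosely (large k).
.coco_sigmas <- c(
  nose = 0.026,
  left_eye = 0.025, right_eye = 0.025,
  left_ear = 0.035, right_ear = 0.035,
  left_shoulder = 0.079, right_shoulder = 0.079,
  left_elbow = 0.072, right_elbow = 0.072,
  left_wrist = 0.062, right_wrist = 0.062,
  left_hip = 0.107, right_hip = 0.107,
  left_knee = 0.087, right_knee = 0.087,
  left_ankle = 0.089, right_ankle = 0.089)

# Skeleton edges for overlay rendering (pairs of keypoint names).
.coco_skeleton <- matrix(c(
  "left_ankle", "left_knee",
  "left_knee", "left_hip",
  "right_ankle", "right_knee",
  "right_knee", "right_hip",
  "left_hip", "right_hip",
  "left_shoulder", "left_hip",
  "right_shoulder", "right_hip",
  "left_shoulder", "right_shoulder",
  "left_shoulder", "left_elbow",
  "left_elbow", "left_wrist",
  "right_shoulder", "right_elbow",
  "right_elbow", "right_wrist",
  "nose", "left_eye",
  "nose", "right_eye",
  "left_eye", "left_ear",
  "right_eye", "right_ear",
  "left_shoulder", "nose",
  "right_shoulder", "nose"), ncol = 2, byrow = TRUE)

.assert_keypoint_names <- function(names, what = "keypoints") {
  bad <- setdiff(names, coco_keypoints())
  if (length(bad) > 0) {
    stop(sprintf("unknown %s: %s (must be COCO keypoint names)",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(names)
}
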