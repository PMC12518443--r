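#' Time-fraction metric F over a set of classification records
#'
#' F is the mean of a binary indicator r(p) over all pose detections p in
#' the chosen span: the fraction of detections classified as interacting
#' (or, with `predicate = "moving"`, as moving, i.e. not still). Because F
#' averages over detections rather than identities or frames, it is
#' insensitive to missed detections and identity switches.
#'
#' @param records Classification data.frame from [classify_interaction()].
#' @param predicate `"interacting"` or `"moving"`.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' recs <- data.frame(interacting = c(TRUE, FALSE, TRUE, FALSE),
#'                    still = c(TRUE, TRUE, TRUE, TRUE))
#' fraction(recs)             # 0.5
fraction <- function(records, predicate = c("interacting", "moving")) {
  predicate <- match.arg(predicate)
  if (nrow(records) == 0) {
    stop("fraction undefined over an empty record set (|P| = 0)",
         call. = FALSE)
  }
  r <- switch(predicate,
              interacting = records$interacting,
              moving = !records$still)
  mean(r)
}

#' Sliding-window specification
#'
#' Default: windows of 7500 frames whose start frames are spaced 3750
#' frames apart, so adjacent windows overlap by 3750 frames. At 25 fps,
#' 7500 frames is 5 minutes.
#'
#' @param length Window length in frames.
#' @param step Spacing of window start frames (0 < step <= length).
#' @return A `window_spec` object.
#' @export
window_spec <- function(length = 7500L, step = 3750L) {
  stopifnot(step > 0, step <= length)
  structure(list(length = as.integer(length), step = as.integer(step)),
            class = "window_spec")
}

#' Per-window time fractions
#'
#' Computes F over a sequence of half-open windows `[start, start+length)`
#' starting at 0, step, 2*step, ... — every window whose start is below
#' `n_frames` is included; final windows may extend past the recording end
#' and then simply contain fewer frames. Windows with no pose detections
#' get an undefined (`NA`) value, distinct from 0.
#'
#' @param records Classification data.frame.
#' @param n_frames Recording length in frames.
#' @param spec A [window_spec()].
#' @param predicate `"interacting"` or `"moving"`.
#' @return data.frame with columns `window_start`, `window_length`,
#'   `n_poses`, `value`.
#' @export
windowed_fraction <- function(records, n_frames, spec = window_spec(),
                              predicate = c("interacting", "moving")) {
  predicate <- match.arg(predicate)
  starts <- as.integer(seq(0L, max(0, n_frames - 1), by = spec$step))
  starts <- starts[starts < n_frames]
  out <- data.frame(window_start = starts, window_length = spec$length,
                    n_poses = 0L, value = NA_real_)
  for (i in seq_along(starts)) {
    sel <- records$frame >= starts[i] &
      records$frame < starts[i] + spec$length
    out$n_poses[i] <- sum(sel)
    if (out$n_poses[i] > 0) {
      out$value[i] <- fraction(records[sel, , drop = FALSE], predicate)
    }
  }
  out
}

#' Per-window detection ratio
#'
#' Divides the number of pose detections by the number of annotated
#' persons per window. Values near 1 suggest that detected and annotated
#' person-frames agree in quantity; values above 1 occur when unannotated
#' persons (e.g. spectators) are detected or detections are spurious. The
#' ratio is undefined (`NA`) where no person-frames are annotated.
#'
#' @param detected_counts Integer vector: pose detections per window.
#' @param annotated_counts Integer vector: annotated person-frames per
#'   window (same length).
#' @return Numeric vector of ratios, `NA` where annotations are 0.
#' @export
detection_ratio <- function(detected_counts, annotated_counts) {
  stopifnot(length(detected_counts) == length(annotated_counts))
  ifelse(annotated_counts > 0, detected_counts / annotated_counts,
         NA_real_)
}

#' Annotated patient-interaction fraction
#'
#' Computes the patient-interaction time fraction from interval activity
#' annotations, sampled once per frame per annotated person. The sample
#' set P contains every annotated person-frame whose label is not
#' 'absence'; the fraction is the share of P whose activity category is
#' `patient_interaction`.
#'
#' @param activities data.frame of activity intervals with columns
#'   `person_id`, `start_frame`, `end_frame` (half-open) and `category`
#'   (from [category_map()]), one of `patient_interaction`, `other`,
#'   `absence`.
#' @param frame_range Length-2 vector `c(first, last_exclusive)`; only
#'   samples within it contribute.
#' @return Fraction in \[0, 1\].
#' @export
annotated_interaction_fraction <- function(activities,
                                           frame_range = NULL) {
  stopifnot(all(c("person_id", "start_frame", "end_frame", "category")
                %in% names(activities)))
  lo <- if (is.null(frame_range)) -Inf else frame_range[1]
  hi <- if (is.null(frame_range)) Inf else frame_range[2]
  n_frames_in <- pmax(0, pmin(activities$end_frame, hi) -
                        pmax(activities$start_frame, lo))
  present <- activities$category != "absence"
  n_p <- sum(n_frames_in[present])
  if (n_p == 0) {
    stop("fraction undefined: no annotated non-absence person-frames in range",
         call. = FALSE)
  }
  n_int <- sum(n_frames_in[present &
                             activities$category == "patient_interaction"])
  n_int / n_p
}

#' Global and movement summary of a classification run
#'
#' @param records Classification data.frame.
#' @return data.frame with one row: `n_poses`, `table_interaction`
#'   (global F), `movement` (moving fraction).
#' @export
summarize_classifications <- function(records) {
  data.frame(n_poses = nrow(records),
             table_interaction = fraction(records, "interacting"),
             movement = fraction(records, "moving"))
}
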