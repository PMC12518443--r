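#' Map activity labels to interaction categories
#'
#' Annotated personnel activities are grouped into three categories:
#' `patient_interaction` (activities involving the patient on the table),
#' `other`, and the reserved label `absence` (person not in the room).
#' The vocabulary of activity labels is site-specific configuration, not
#' code: the mapping is supplied as a named character vector. `'absence'`
#' always maps to `absence`.
#'
#' @param labels Character vector of activity labels.
#' @param mapping Named character vector label -> category, categories
#'   drawn from `patient_interaction`, `other`, `absence`.
#' @return Character vector of categories.
#' @export
#' @examples
#' m <- c(positioning = "patient_interaction", documenting = "other")
#' category_map(c("positioning", "absence"), m)
category_map <- function(labels, mapping) {
  mapping <- c(mapping, absence = "absence")
  bad_cat <- setdiff(unique(mapping),
                     c("patient_interaction", "other", "absence"))
  if (length(bad_cat) > 0) {
    stop("invalid categories in mapping: ",
         paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(labels), names(mapping))
  if (length(unknown) > 0) {
    stop("unmapped activity label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(mapping[labels])
}

#' Workflow phase intervals
#'
#' @param phase Character vector of phase names, conventionally
#'   `induction`, `preparation`, `surgery`, `recovery`.
#' @param start_frame,end_frame Half-open frame intervals; phases of one
#'   recording must be non-overlapping and ordered.
#' @return data.frame of phase intervals.
#' @export
phase_intervals <- function(phase, start_frame, end_frame) {
  stopifnot(length(phase) == length(start_frame),
            length(phase) == length(end_frame),
            all(start_frame < end_frame))
  ord <- order(start_frame)
  phase <- phase[ord]; start_frame <- start_frame[ord]
  end_frame <- end_frame[ord]
  if (length(phase) > 1 &&
      any(start_frame[-1] < end_frame[-length(end_frame)])) {
    stop("phase intervals must be non-overlapping", call. = FALSE)
  }
  data.frame(phase = phase, start_frame = as.integer(start_frame),
             end_frame = as.integer(end_frame))
}

# which phase contains each frame; 'unphased' when none does
.phase_of <- function(frames, phases) {
  out <- rep("unphased", length(frames))
  for (i in seq_len(nrow(phases))) {
    sel <- frames >= phases$start_frame[i] & frames < phases$end_frame[i]
    out[sel] <- phases$phase[i]
  }
  out
}

#' Stratify windows or records by workflow phase
#'
#' Assigns each classification record to the phase containing its frame,
#' or each window to the phase containing its window start frame (windows
#' may straddle phase boundaries; assignment by start frame keeps the
#' partition unambiguous). Frames outside every phase go to the reserved
#' phase `unphased`, with a warning.
#'
#' @param x A classification data.frame (with a `frame` column) or a
#'   window data.frame from [windowed_fraction()] (with `window_start`).
#' @param phases Phase data.frame from [phase_intervals()] (may have zero
#'   rows).
#' @return Named list of subsets of `x`, one per phase present (plus
#'   `unphased` when applicable); every row of `x` lands in exactly one.
#' @export
stratify_by_phase <- function(x, phases) {
  frames <- if ("window_start" %in% names(x)) x$window_start else x$frame
  ph <- .phase_of(frames, phases)
  if (any(ph == "unphased") && nrow(x) > 0) {
    warning(sum(ph == "unphased"),
            " record(s)/window(s) outside all phases; assigned 'unphased'",
            call. = FALSE)
  }
  split(x, factor(ph, levels = unique(c(phases$phase,
                                        intersect("unphased", ph)))))
}

#' Phase-stratified summary table
#'
#' Per-phase table-interaction and movement fractions from classification
#' records, optionally with the annotated patient-interaction fraction —
#' one row per phase plus an overall row.
#'
#' @param records Classification data.frame.
#' @param phases Phase data.frame from [phase_intervals()].
#' @param activities Optional activity data.frame with `category` column
#'   (see [annotated_interaction_fraction()]).
#' @return data.frame with columns `phase`, `n_poses`,
#'   `table_interaction`, `movement` and (if activities given)
#'   `patient_interaction`.
#' @export
phase_summary <- function(records, phases, activities = NULL) {
  strata <- suppressWarnings(stratify_by_phase(records, phases))
  rows <- lapply(names(strata), function(ph) {
    recs <- strata[[ph]]
    out <- data.frame(
      phase = ph, n_poses = nrow(recs),
      table_interaction = if (nrow(recs)) fraction(recs, "interacting")
                          else NA_real_,
      movement = if (nrow(recs)) fraction(recs, "moving") else NA_real_)
    if (!is.null(activities)) {
      rng <- if (ph == "unphased") NULL else {
        i <- match(ph, phases$phase)
        c(phases$start_frame[i], phases$end_frame[i])
      }
      out$patient_interaction <- tryCatch(
        annotated_interaction_fraction(activities, rng),
        error = function(e) NA_real_)
    }
    out
  })
  overall <- data.frame(phase = "overall", n_poses = nrow(records),
                        table_interaction = fraction(records, "interacting"),
                        movement = fraction(records, "moving"))
  if (!is.null(activities)) {
    overall$patient_interaction <- tryCatch(
      annotated_interaction_fraction(activities),
      error = function(e) NA_real_)
  }
  rbind(do.call(rbind, rows), overall)
}
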