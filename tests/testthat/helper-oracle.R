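# Independent brute-force evaluator of the movement/position/interaction
# rules, written literally from the rule statements with plain loops.
# Deliberately shares no code with the package implementation: the
# point-in-polygon step uses mgcv::in.out (random test points never lie on
# a polygon boundary, so its boundary convention does not matter).

oracle_classify <- function(stream, regions, params = interaction_params()) {
  p <- stream$poses
  k <- stream$keypoints
  one_kp <- function(det_id, name) {
    k[k$det_id == det_id & k$keypoint == name, ]
  }
  rows <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    # --- movement: a keypoint is assumed still when not detected or below
    # gamma_m; otherwise still iff its displacement over f_motion frames is
    # defined and below tau_m
    sub_still <- logical(0)
    for (s in params$movement_subposes) {
      n_still <- 0L
      for (nm in s$keypoints) {
        r <- one_kp(p$det_id[i], nm)
        if (!r$detected || r$confidence < s$gamma_m) {
          n_still <- n_still + 1L
          next
        }
        j <- which(p$track_id == p$track_id[i] &
                     p$frame == p$frame[i] - params$f_motion)
        still <- TRUE  # undefined displacement -> assumed still
        if (length(j) == 1) {
          r0 <- one_kp(p$det_id[j], nm)
          if (r0$detected) {
            d <- sqrt((r$x - r0$x)^2 + (r$y - r0$y)^2)
            still <- d < s$tau_m
          }
        }
        if (still) n_still <- n_still + 1L
      }
      sub_still[s$name] <- n_still >= s$m_keypoint
    }
    still <- sum(sub_still) >= params$m_subpose

    # --- position: a keypoint counts iff detected, confidence >= gamma_p,
    # and inside the region polygon
    sub_pos <- logical(0)
    for (s in params$position_subposes) {
      poly <- regions[[s$region_name]]
      n_in <- 0L
      for (nm in s$keypoints) {
        r <- one_kp(p$det_id[i], nm)
        if (r$detected && r$confidence >= s$gamma_p &&
            mgcv::in.out(poly, matrix(c(r$x, r$y), ncol = 2))) {
          n_in <- n_in + 1L
        }
      }
      sub_pos[s$region_name] <- n_in >= s$p_keypoint
    }
    by_table <- sum(sub_pos) >= params$p_subpose

    row <- data.frame(frame = p$frame[i], track_id = p$track_id[i],
                      still = still, by_table = by_table,
                      interacting = still && by_table)
    for (nm in names(sub_still)) row[[paste0("still_", nm)]] <- sub_still[[nm]]
    for (nm in names(sub_pos)) row[[paste0("pos_", nm)]] <- sub_pos[[nm]]
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
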