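# two-frame track helper: keypoint positions at t-5 and t
two_frame_stream <- function(kp_prev, kp_now, f_motion = 5L) {
  ts_stream(list(ts_pose(0, 1, kp = kp_prev),
                 ts_pose(f_motion, 1, kp = kp_now)),
            n_frames = f_motion + 1L)
}

test_that("keypoint displacement is the net endpoint distance", {
  s <- two_frame_stream(list(nose = c(100, 100, 0.9)),
                        list(nose = c(103, 104, 0.9)))
  expect_equal(keypoint_displacement(s, 1, 5, "nose"), 5)
  s0 <- two_frame_stream(list(nose = c(100, 100, 0.9)),
                         list(nose = c(100, 100, 0.9)))
  expect_equal(keypoint_displacement(s0, 1, 5, "nose"), 0)
})

test_that("displacement is undefined when an endpoint is missing", {
  # track starts at t-2: no pose at t-5
  s <- ts_stream(list(ts_pose(3, 1, kp = list(nose = c(1, 1, .9))),
                      ts_pose(5, 1, kp = list(nose = c(9, 9, .9)))))
  expect_true(is.na(keypoint_displacement(s, 1, 5, "nose")))
  # keypoint undetected at the earlier endpoint
  s2 <- two_frame_stream(list(left_ear = c(0, 0, .9)),
                         list(nose = c(5, 5, .9), left_ear = c(1, 1, .9)))
  expect_true(is.na(keypoint_displacement(s2, 1, 5, "nose")))
  expect_error(keypoint_displacement(s2, 1, 4, "nose"), "no detection")
})

shoulders_spec <- interaction_params()$movement_subposes[[1]]

test_that("subpose stillness follows the keypoint counting rule", {
  # both shoulders static and confident -> still
  s <- two_frame_stream(ts_full_kp(300, 300), ts_full_kp(300, 300))
  expect_true(classify_subpose_still(s, 1, 5, shoulders_spec))
  # low-confidence keypoints are assumed still regardless of motion
  s_low <- two_frame_stream(ts_full_kp(300, 300),
                            ts_full_kp(600, 300, confidence = 0.1))
  expect_true(classify_subpose_still(s_low, 1, 5, shoulders_spec))
  # one shoulder below threshold suffices when M_keypoint = 1
  prev <- ts_full_kp(300, 300)
  now <- ts_full_kp(300, 300)
  now$left_shoulder <- prev$left_shoulder + c(30, 0, 0)   # 30 px: moving
  now$right_shoulder <- prev$right_shoulder + c(5, 0, 0)  # 5 px: still
  expect_true(classify_subpose_still(two_frame_stream(prev, now), 1, 5,
                                     shoulders_spec))
  # both above threshold -> moving
  now$right_shoulder <- prev$right_shoulder + c(30, 0, 0)
  expect_false(classify_subpose_still(two_frame_stream(prev, now), 1, 5,
                                      shoulders_spec))
})

test_that("threshold boundaries are pinned: strict < for tau and gamma", {
  prev <- ts_full_kp(300, 300)
  at_tau <- ts_full_kp(300, 300)
  at_tau$left_shoulder <- prev$left_shoulder + c(17.5, 0, 0)
  at_tau$right_shoulder <- prev$right_shoulder + c(17.5, 0, 0)
  # displacement exactly 17.5 px is NOT below threshold -> moving
  expect_false(classify_subpose_still(two_frame_stream(prev, at_tau), 1, 5,
                                      shoulders_spec))
  # confidence exactly 0.3 IS reliable -> motion counts
  at_gamma <- lapply(at_tau, function(v) c(v[1], v[2], 0.3))
  expect_false(classify_subpose_still(two_frame_stream(prev, at_gamma), 1, 5,
                                      shoulders_spec))
})

test_that("pose stillness is a disjunction over subposes by default", {
  prev <- ts_full_kp(300, 300)
  # everything moves 30 px -> not still
  allmove <- ts_full_kp(330, 300)
  res <- classify_pose_still(two_frame_stream(prev, allmove), 1, 5)
  expect_false(res$still)
  expect_equal(unname(res$subposes), c(FALSE, FALSE))
  # shoulders move, head static -> still (M_subpose = 1)
  mixed <- ts_full_kp(300, 300)
  mixed$left_shoulder <- prev$left_shoulder + c(30, 0, 0)
  mixed$right_shoulder <- prev$right_shoulder + c(30, 0, 0)
  res2 <- classify_pose_still(two_frame_stream(prev, mixed), 1, 5)
  expect_true(res2$still)
  expect_equal(res2$subposes, c(shoulders = FALSE, head = TRUE))
  # all keypoints undetected -> everything assumed still
  s_empty <- ts_stream(list(ts_pose(0, 1, kp = list(nose = c(1, 1, .9))),
                            ts_pose(5, 1, kp = list())))
  expect_true(classify_pose_still(s_empty, 1, 5)$still)
})

test_that("subpose position counts confident in-region keypoints", {
  regions <- region_set(list(wrists = ts_rect(0, 0, 100, 100),
                             shoulders = ts_rect(0, 0, 100, 100),
                             head = ts_rect(0, 0, 100, 100)))
  params <- interaction_params()
  wrists <- params$position_subposes[[1]]
  head <- params$position_subposes[[3]]
  mk <- function(kp) ts_stream(list(ts_pose(0, 1, kp = kp)))
  # both wrists inside and confident
  s <- mk(list(left_wrist = c(50, 50, 0.9), right_wrist = c(60, 50, 0.9)))
  expect_true(classify_subpose_position(s, 1, 0, regions, wrists))
  # inside but below gamma_p 0.3 -> not counted in any region
  s2 <- mk(list(left_wrist = c(50, 50, 0.2), right_wrist = c(60, 50, 0.2)))
  expect_false(classify_subpose_position(s2, 1, 0, regions, wrists))
  # head: nose + one eye at 0.2 >= gamma 0.15 inside, ears outside -> 2 of 5
  s3 <- mk(list(nose = c(50, 50, 0.2), left_eye = c(55, 48, 0.2),
                left_ear = c(300, 300, 0.9), right_ear = c(310, 300, 0.9)))
  expect_true(classify_subpose_position(s3, 1, 0, regions, head))
  # only the nose inside -> below P_keypoint = 2
  s4 <- mk(list(nose = c(50, 50, 0.9), left_ear = c(300, 300, 0.9)))
  expect_false(classify_subpose_position(s4, 1, 0, regions, head))
})

test_that("pose position needs at least P_subpose positioned subposes", {
  inside <- ts_rect(0, 0, 1000, 1000)
  outside <- ts_rect(2000, 2000, 3000, 3000)
  mk_regions <- function(w, s, h) region_set(list(
    wrists = if (w) inside else outside,
    shoulders = if (s) inside else outside,
    head = if (h) inside else outside))
  s <- ts_stream(list(ts_pose(0, 1, kp = ts_full_kp(500, 500))))
  pp <- function(r) classify_pose_position(s, 1, 0, r)
  expect_true(pp(mk_regions(TRUE, TRUE, TRUE))$by_table)
  r2 <- pp(mk_regions(TRUE, FALSE, TRUE))   # wrists + head, 2 >= 2
  expect_true(r2$by_table)
  expect_equal(r2$subposes, c(wrists = TRUE, shoulders = FALSE, head = TRUE))
  expect_false(pp(mk_regions(TRUE, FALSE, FALSE))$by_table)
})

test_that("interaction combines stillness and position with categories", {
  regions <- ts_regions(0, 0, 1000, 1000)
  prev_in <- ts_full_kp(500, 500)
  still_in <- ts_full_kp(500, 500)
  moving_in <- ts_full_kp(540, 500)
  still_out <- ts_full_kp(5000, 5000)
  s <- ts_stream(list(
    ts_pose(0, 1, kp = prev_in), ts_pose(5, 1, kp = still_in),
    ts_pose(0, 2, kp = prev_in), ts_pose(5, 2, kp = moving_in),
    ts_pose(0, 3, kp = ts_full_kp(5000, 5000)),
    ts_pose(5, 3, kp = still_out)))
  recs <- classify_interaction(s, regions)
  r5 <- recs[recs$frame == 5, ]
  expect_equal(r5$interacting, c(TRUE, FALSE, FALSE))
  expect_equal(r5$category,
               c("interacting", "positioned_but_moving", "wrong_position"))
  expect_equal(recs$interacting, recs$still & recs$by_table)
})

test_that("classification is total, deterministic, and needs tracks", {
  s <- random_rule_stream(6, 10, seed = 99)
  regions <- random_regions(99)
  r1 <- classify_interaction(s, regions)
  expect_equal(nrow(r1), nrow(s$poses))
  expect_false(anyNA(r1$still) || anyNA(r1$by_table) || anyNA(r1$interacting))
  expect_identical(r1, classify_interaction(s, regions))

  untracked <- s
  untracked$poses$track_id[3] <- NA_integer_
  expect_error(classify_interaction(untracked, regions), "build_tracklets")
})

test_that("scalar classifiers agree with the vectorised batch path", {
  s <- random_rule_stream(5, 8, seed = 7)
  regions <- random_regions(7)
  params <- interaction_params()
  recs <- classify_interaction(s, regions, params)
  for (i in seq_len(nrow(recs))) {
    st <- classify_pose_still(s, recs$track_id[i], recs$frame[i], params)
    po <- classify_pose_position(s, recs$track_id[i], recs$frame[i],
                                 regions, params)
    expect_identical(unname(st$still), recs$still[i])
    expect_identical(unname(po$by_table), recs$by_table[i])
  }
})

test_that("rule classification agrees with the brute-force oracle", {
  n_checked <- 0
  for (seed in 1:4) {
    s <- random_rule_stream(5, 10, seed = seed)
    regions <- random_regions(seed)
    got <- classify_interaction(s, regions)
    want <- oracle_classify(s, regions)
    expect_identical(got[names(want)], want)
    n_checked <- n_checked + nrow(got)
  }
  expect_gte(n_checked, 200)
})
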