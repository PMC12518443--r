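test_that("actor scripts validate waypoints and still intervals", {
  expect_error(actor_script(1, data.frame(frame = c(5, 5), x = 1, y = 1)),
               "strictly increasing")
  expect_error(
    actor_script(1, data.frame(frame = c(10, 100), x = 1, y = 1),
                 still_intervals = data.frame(start_frame = 0,
                                              end_frame = 50)),
    "outside the actor's waypoint span")
  expect_error(
    actor_script(1, data.frame(frame = c(0, 10), x = 1, y = 1),
                 still_intervals = data.frame(start_frame = 5,
                                              end_frame = 5)),
    "start_frame < end_frame")
})

test_that("simulation is bit-identical per seed and differs across seeds", {
  fx <- make_fixture("spectators")
  nm <- noise_model(jitter_sigma = 1.5, dropout_prob = 0.08, seed = 4)
  a <- simulate_scene(fx$scripts, fx$regions, nm, fx$n_frames)
  b <- simulate_scene(fx$scripts, fx$regions, nm, fx$n_frames)
  expect_identical(a$stream, b$stream)
  expect_identical(a$truth, b$truth)
  nm2 <- nm; nm2$seed <- 5L
  c <- simulate_scene(fx$scripts, fx$regions, nm2, fx$n_frames)
  expect_false(identical(a$stream, c$stream))
})

test_that("degenerate scenes recover the expected fractions exactly", {
  regions <- make_fixture("quiet_room")$regions
  # one actor in-region and still the whole recording -> F = 1
  fx <- make_fixture("quiet_room")
  sc <- simulate_scene(fx$scripts, fx$regions, noise_model(), fx$n_frames)
  expect_equal(fraction(sc$truth), 1)
  expect_equal(fraction(classify_interaction(sc$stream, regions)), 1)
  # one actor far from every region -> F = 0
  far <- actor_script(1, data.frame(frame = c(0, 500), x = 3000, y = 3000),
                      still_intervals = data.frame(start_frame = 0,
                                                   end_frame = 500))
  sc0 <- simulate_scene(list(far), regions, noise_model(), 500)
  expect_equal(fraction(classify_interaction(sc0$stream, regions)), 0)
})

test_that("zero-noise measurement equals scripted ground truth", {
  for (name in c("spectators", "busy_table")) {
    fx <- make_fixture(name)
    sc <- simulate_scene(fx$scripts, fx$regions, noise_model(),
                         fx$n_frames)
    measured <- fraction(classify_interaction(sc$stream, fx$regions))
    expect_equal(measured, fraction(sc$truth))
  }
  # spectators: 2 of 4 equally-present actors interact -> 0.5 by counting
  fx <- make_fixture("spectators")
  sc <- simulate_scene(fx$scripts, fx$regions, noise_model(), fx$n_frames)
  expect_equal(fraction(sc$truth), 0.5)
})

test_that("moderate noise keeps the measured F near truth", {
  fx <- make_fixture("busy_table")
  errs <- vapply(1:3, function(s) {
    sc <- simulate_scene(fx$scripts, fx$regions,
                         noise_model(jitter_sigma = 2, dropout_prob = 0.1,
                                     seed = s),
                         fx$n_frames)
    abs(fraction(classify_interaction(sc$stream, fx$regions)) -
          fraction(sc$truth))
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})

test_that("dropout is coupled-monotone in the detected keypoint count", {
  fx <- make_fixture("spectators")
  probs <- c(0, 0.05, 0.2, 0.5, 0.9)
  for (seed in 1:3) {
    detected <- vapply(probs, function(p) {
      sc <- simulate_scene(fx$scripts, fx$regions,
                           noise_model(dropout_prob = p, seed = seed),
                           500)
      sum(sc$stream$keypoints$detected)
    }, numeric(1))
    expect_true(all(diff(detected) <= 0))
  }
})

test_that("low-light intervals raise dropout locally", {
  fx <- make_fixture("lowlight")
  sc <- simulate_scene(fx$scripts, fx$regions, fx$noise, fx$n_frames)
  k <- sc$stream$keypoints
  fr <- sc$stream$poses$frame[match(k$det_id, sc$stream$poses$det_id)]
  inside <- fr >= 800 & fr < 1200
  expect_lt(mean(k$detected[inside]), mean(k$detected[!inside]) - 0.3)
})

test_that("script-derived annotations cover presence and absence", {
  fx <- make_fixture("busy_table")
  sc <- simulate_scene(fx$scripts, fx$regions, noise_model(), fx$n_frames)
  acts <- sc$activities
  expect_true(all(c("person_id", "start_frame", "end_frame", "label",
                    "category") %in% names(acts)))
  # every actor's intervals tile [0, n_frames) without overlap
  for (pid in unique(acts$person_id)) {
    a <- acts[acts$person_id == pid, ]
    a <- a[order(a$start_frame), ]
    expect_equal(a$start_frame[1], 0)
    expect_equal(a$end_frame[nrow(a)], fx$n_frames)
    if (nrow(a) > 1) {
      expect_equal(a$start_frame[-1], a$end_frame[-nrow(a)])
    }
  }
  expect_equal(nrow(sc$phases), 4)
  f <- annotated_interaction_fraction(acts)
  expect_gt(f, 0.9)  # staff still intervals dominate this scene
  expect_lte(f, 1)
})

test_that("unknown fixture names are rejected", {
  expect_error(make_fixture("dance_hall"), "arg")
})
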