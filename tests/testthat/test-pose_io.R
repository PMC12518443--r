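write_json_records <- function(records, path, n_frames = NULL) {
  obj <- if (is.null(n_frames)) records else
    list(n_frames = n_frames, records = records)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

full_triplets <- function(x0 = 100, conf = 0.9) {
  as.numeric(rbind(x0 + seq_len(17), 200 + seq_len(17), conf))
}

test_that("empty and single-record streams read correctly", {
  f <- withr::local_tempfile(fileext = ".json")
  write_json_records(list(), f, n_frames = 100)
  s <- read_pose_stream(f)
  expect_s3_class(s, "pose_stream")
  expect_equal(nrow(s$poses), 0)
  expect_equal(s$n_frames, 100L)

  write_json_records(list(list(frame = 3, keypoints = full_triplets(),
                               score = 0.8)), f)
  s <- read_pose_stream(f)
  expect_equal(nrow(s$poses), 1)
  expect_true(all(s$keypoints$detected))
  expect_equal(s$poses$frame, 3L)
})

test_that("zero-confidence triplets are marked undetected", {
  trip <- full_triplets()
  # left_ankle is keypoint 16 -> values 46:48
  trip[46:48] <- c(0, 0, 0)
  f <- withr::local_tempfile(fileext = ".json")
  write_json_records(list(list(frame = 0, keypoints = trip, score = 0.9)), f)
  s <- read_pose_stream(f)
  la <- s$keypoints[s$keypoints$keypoint == "left_ankle", ]
  expect_false(la$detected)
  expect_true(is.na(la$x))
  expect_true(all(s$keypoints$detected[s$keypoints$keypoint != "left_ankle"]))
})

test_that("malformed input is rejected with the record index", {
  f <- withr::local_tempfile(fileext = ".json")
  write_json_records(list(
    list(frame = 0, keypoints = full_triplets(), score = 0.9),
    list(frame = 1, keypoints = as.numeric(1:30), score = 0.9)), f)
  expect_error(read_pose_stream(f), "record 2.*30.*51")
  writeLines("{not json", f)
  expect_error(read_pose_stream(f), "malformed JSON")
  expect_error(read_pose_stream(f, dialect = "nonsense"), "arg")
})

test_that("tracked dialect requires track ids", {
  f <- withr::local_tempfile(fileext = ".json")
  write_json_records(list(list(frame = 0, keypoints = full_triplets(),
                               score = 0.9)), f)
  expect_error(read_pose_stream(f, "tracked"), "track_id")
  write_json_records(list(list(frame = 0, track_id = 4,
                               keypoints = full_triplets(), score = 0.9)), f)
  s <- read_pose_stream(f, "tracked")
  expect_equal(s$poses$track_id, 4L)
})

test_that("reading is order-normalizing over input record permutations", {
  recs <- lapply(c(5, 1, 3, 0, 2), function(fr) {
    list(frame = fr, keypoints = full_triplets(x0 = 50 + 10 * fr),
         score = 0.7)
  })
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_json_records(recs, f1)
  write_json_records(rev(recs), f2)
  expect_identical(read_pose_stream(f1), read_pose_stream(f2))
})

test_that("pose stream JSON round-trips", {
  s <- random_rule_stream(3, 6, seed = 11)
  f <- withr::local_tempfile(fileext = ".json")
  write_pose_stream(s, f)
  s2 <- read_pose_stream(f, "tracked")
  expect_equal(s2$poses, s$poses)
  expect_equal(s2$n_frames, s$n_frames)
  k1 <- s$keypoints[s$keypoints$detected, ]
  k2 <- s2$keypoints[s2$keypoints$detected, ]
  expect_equal(k2$x, k1$x)
  expect_equal(k2$confidence, k1$confidence)
})

test_that("region files validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".json")
  tri <- list(c(0, 0), c(1, 0), c(0, 1))
  jsonlite::write_json(list(wrists = tri, shoulders = tri, head = tri), f,
                       digits = NA)
  r <- read_regions(f)
  expect_s3_class(r, "region_set")
  expect_length(r, 3)
  expect_equal(nrow(r$wrists), 3)

  jsonlite::write_json(list(wrists = tri, shoulders = tri), f, digits = NA)
  expect_error(read_regions(f), "head")

  jsonlite::write_json(list(wrists = tri[1:2], shoulders = tri, head = tri),
                       f, digits = NA)
  expect_error(read_regions(f), ">= 3 vertices")

  r2 <- ts_regions(10, 20, 400, 500)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_regions(r2, f2)
  expect_equal(read_regions(f2), r2)
})

test_that("self-intersecting region polygons warn but still classify", {
  bowtie <- cbind(x = c(0, 2, 2, 0), y = c(0, 2, 0, 2))
  expect_warning(
    region_set(list(wrists = bowtie, shoulders = ts_rect(0, 0, 2, 2),
                    head = ts_rect(0, 0, 2, 2))),
    "self-intersecting")
})

test_that("classification records round-trip through CSV", {
  expect_equal(nrow(read_classifications(
    write_classifications(
      classify_interaction(ts_stream(list()), ts_regions()),
      withr::local_tempfile(fileext = ".csv")))), 0)

  s <- random_rule_stream(8, 12, seed = 5)
  recs <- classify_interaction(s, random_regions(5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_classifications(recs, f)
  expect_equal(read_classifications(f), recs)
})
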