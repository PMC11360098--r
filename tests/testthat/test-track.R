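test_that("track initialization takes state from the second detection", {
  ts <- init_track(bbox(0, 0, 10, 10), bbox(2, 0, 10, 10))
  expect_equal(ts$x, c(2, 0, 10, 10, 2, 0))
  expect_equal(ts$status, "tracking")

  same <- init_track(bbox(5, 5, 10, 10), bbox(5, 5, 10, 10))
  expect_equal(same$x[5:6], c(0, 0))

  expect_error(init_track(bbox(0, 0, 10, 10), bbox(100, 100, 10, 10)),
               "init rejected")
})

test_that("candidate grids are deterministic, centered, and size-preserving", {
  ts <- track_state(c(50, 40, 20, 16, 0, 0), diag(6))
  one <- generate_candidates(ts, n = 1)
  expect_length(one, 1)
  expect_equal(as.numeric(one[[1]]$box), c(50, 40, 20, 16))

  cands <- generate_candidates(ts, n = 25, spread = 8)
  expect_length(cands, 25)
  ctrs <- t(vapply(cands, function(cd) cd$box[c("cx", "cy")], numeric(2)))
  expect_equal(nrow(unique(ctrs)), 25)
  expect_equal(unname(ctrs[1, ]), c(50, 40))  # prior center is candidate 1
  expect_lte(max(abs(ctrs[, 1] - 50)), 8)
  expect_lte(max(abs(ctrs[, 2] - 40)), 8)
  expect_true(all(vapply(cands, function(cd) cd$box[["w"]] == 20 &&
                           cd$box[["h"]] == 16, logical(1))))
  # identical inputs give identical grids
  expect_identical(generate_candidates(ts, n = 25, spread = 8), cands)
})

test_that("candidate matching picks the identical patch and applies tie-breaks", {
  set.seed(41)
  frame <- matrix(stats::runif(120 * 160, 0, 0.1), 120, 160)
  tex <- area_resize(matrix(stats::runif(20, 0.3, 1), 4, 5), 16, 20)
  frame[41:56, 51:70] <- tex  # object at rows 41-56, cols 51-70
  truth <- bbox(60, 48, 20, 16)
  ref <- dhash(neckwatch:::extract_patch(frame, truth))

  ts <- track_state(c(60, 48, 20, 16, 0, 0), diag(6))
  cands <- generate_candidates(ts, n = 25, spread = 6)
  best <- match_candidates(frame, cands, ref, threshold = 0.8)
  expect_equal(best$similarity, 1)
  expect_equal(unname(best$box[c("cx", "cy")]), c(60, 48))

  # complement reference: the true-box candidate scores exactly 0, so any
  # positive threshold rejects it
  comp <- structure(1L - unclass(ref), class = "dhash64")
  expect_null(match_candidates(frame, generate_candidates(ts, n = 1), comp,
                               threshold = 0.1))

  # tie-break: uniform frame makes all similarities equal; nearest to the
  # prior center (candidate 1) must win
  flat <- matrix(0.5, 120, 160)
  best_flat <- match_candidates(flat, cands, dhash(matrix(0.5, 16, 20)),
                                threshold = 0.5)
  expect_equal(unname(best_flat$box[c("cx", "cy")]), c(60, 48))
})

test_that("a detector-fed tracker equals the independent Kalman filter", {
  m <- constant_velocity_model()
  seq1 <- make_tracking_sequence(n_frames = 30, seed = 44)
  ts <- init_track(seq1$detections[[1]], seq1$detections[[2]],
                   seq1$frames[[2]], m)
  x0 <- ts$x; P0 <- ts$P
  zs <- lapply(3:30, function(k) as.numeric(seq1$detections[[k]]))
  oracle <- kf_oracle(x0, P0, m$F_jac(x0), m$H_jac(x0), m$Q, m$R, zs)
  for (k in 3:30) {
    st <- track_step(seq1$frames[[k]], seq1$detections[[k]], ts, m)
    ts <- st$state
    expect_equal(st$source, "detector")
    expect_equal(ts$x, oracle$x[[k - 2]], tolerance = 1e-9)
  }
})

test_that("the tracker bridges a detector dropout with hash matching", {
  m <- constant_velocity_model(); cfg <- tracker_config()
  seq1 <- make_tracking_sequence(n_frames = 60, dropout_frames = 30:34,
                                 seed = 42)
  ts <- init_track(seq1$detections[[1]], seq1$detections[[2]],
                   seq1$frames[[2]], m, cfg)
  ious <- numeric(0); sources <- character(0)
  for (k in 3:60) {
    st <- track_step(seq1$frames[[k]], seq1$detections[[k]], ts, m, cfg)
    ts <- st$state
    ious <- c(ious, bbox_iou(st$box, seq1$gt[[k]]))
    sources <- c(sources, st$source)
  }
  expect_gte(min(ious), 0.5)
  expect_true(any(sources[28:32] == "tracker"))  # hash re-acquisition engaged
  expect_equal(ts$status, "tracking")
})

test_that("an object that disappears drives the track to lost after max_coast", {
  m <- constant_velocity_model(); cfg <- tracker_config()
  seq2 <- make_tracking_sequence(n_frames = 80, velocity = c(0.5, 0),
                                 remove_frames = 11:80, seed = 43)
  ts <- init_track(seq2$detections[[1]], seq2$detections[[2]],
                   seq2$frames[[2]], m, cfg)
  lost_at <- NA_integer_
  for (k in 3:80) {
    st <- track_step(seq2$frames[[k]], seq2$detections[[k]], ts, m, cfg)
    ts <- st$state
    if (ts$status == "lost") { lost_at <- k; break }
  }
  expect_equal(lost_at, 10 + cfg$max_coast)
  expect_null(track_step(seq2$frames[[41]], NULL, ts, m, cfg)$box)
})

test_that("IoU is exact on hand-computable boxes", {
  expect_equal(bbox_iou(bbox(0, 0, 10, 10), bbox(0, 0, 10, 10)), 1)
  expect_equal(bbox_iou(bbox(0, 0, 10, 10), bbox(10, 10, 10, 10)), 0)
  expect_equal(bbox_iou(bbox(0, 0, 10, 10), bbox(5, 0, 10, 10)),
               50 / 150)
})
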