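test_that("posture specs derive labels from the generator margins", {
  expect_equal(posture_spec(0, 0)$label, "normal")
  expect_equal(posture_spec(40, 0)$label, "head_tilt")
  expect_equal(posture_spec(-30, 0)$label, "head_tilt")
  expect_equal(posture_spec(0, 40)$label, "dropped_head")
  expect_error(posture_spec(40, 40), "ambiguous")
  expect_error(posture_spec(18, 0), "ambiguous")  # inside the refused band
})

test_that("3D posing rotates only the nose, by the stated quarter-turns", {
  tmpl <- pose_template_3d()
  id <- make_skeleton3d(posture_spec(0, 0), tmpl)
  expect_equal(id[, "nose"], c(0, -0.16, 0.10))
  expect_equal(id[, "left_shoulder"], c(0.19, 0, 0))

  # tilt 90: the frontal-plane component lies along the shoulder line
  t90 <- make_skeleton3d(structure(list(tilt_deg = 90, drop_deg = 0,
                                        label = "head_tilt"),
                                   class = "posture_spec"), tmpl)
  expect_equal(t90[1:2, "nose"], c(0.16, 0), tolerance = 1e-12)
  expect_equal(t90[, "left_shoulder"], id[, "left_shoulder"])

  # drop 90: the neck-to-nose length moves into the forward axis
  d90 <- make_skeleton3d(structure(list(tilt_deg = 0, drop_deg = 90,
                                        label = "dropped_head"),
                                   class = "posture_spec"), tmpl)
  expect_equal(d90[, "nose"], c(0, 0.10, 0.16), tolerance = 1e-12)
})

test_that("projection is symmetric at zero yaw and scales with distance", {
  cam <- camera_model()
  sk <- synth_skeleton(yaw = 0, distance = 0.75)
  kp <- sk$kp
  expect_equal(kp["nose", "u"], kp["neck", "u"], tolerance = 1e-9)
  expect_equal(kp["left_shoulder", "u"] - kp["neck", "u"],
               -(kp["right_shoulder", "u"] - kp["neck", "u"]),
               tolerance = 1e-9)
  # doubling the distance roughly halves neck-relative offsets
  near <- synth_skeleton(yaw = 0, distance = 1)$kp
  far <- synth_skeleton(yaw = 0, distance = 2)$kp
  off_near <- near["left_shoulder", "u"] - near["neck", "u"]
  off_far <- far["left_shoulder", "u"] - far["neck", "u"]
  expect_equal(off_near / off_far, 2, tolerance = 0.02)
})

test_that("projection refuses points behind the camera and masks occluded sides", {
  expect_error(project_skeleton(make_skeleton3d(posture_spec(0, 0)),
                                scene_spec(0, 0.05), camera_model()),
               "behind camera")
  oc <- synth_skeleton(yaw = 65)
  expect_equal(oc$kp["left_shoulder", "confidence"], 0.3)
  expect_equal(oc$kp["right_shoulder", "confidence"], 1)
})

test_that("all generators are seed-deterministic", {
  s1 <- synth_skeleton(yaw = 30, noise = 2, seed = 77)
  s2 <- synth_skeleton(yaw = 30, noise = 2, seed = 77)
  expect_identical(s1$kp, s2$kp)

  d1 <- make_classification_dataset(n_per_cell = 3, yaws = c(0, 30),
                                    distances = 0.75, seed = 5)
  d2 <- make_classification_dataset(n_per_cell = 3, yaws = c(0, 30),
                                    distances = 0.75, seed = 5)
  expect_identical(d1$truth, d2$truth)
  expect_identical(lapply(d1$skeletons, `[[`, "kp"),
                   lapply(d2$skeletons, `[[`, "kp"))

  t1 <- make_tracking_sequence(n_frames = 10, seed = 9)
  t2 <- make_tracking_sequence(n_frames = 10, seed = 9)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$detections, t2$detections)
})

test_that("the classification dataset matches the study protocol shape", {
  ds <- make_classification_dataset(n_per_cell = 8, yaws = c(0, 30, -30),
                                    distances = c(0.5, 0.75), seed = 3)
  expect_equal(nrow(ds$truth), 8 * 2 * 3 * 2)
  per_cell <- table(ds$truth$cell)
  expect_true(all(per_cell == 16))
  bal <- tapply(ds$truth$label %in% c("head_tilt", "dropped_head"),
                ds$truth$cell, mean)
  expect_true(all(bal == 0.5))
  expect_length(ds$skeletons, nrow(ds$truth))
  # truth labels equal the posture-spec labels carried by the skeletons
  expect_equal(ds$truth$label,
               vapply(ds$skeletons, function(s) attr(s, "label"),
                      character(1)))
})

test_that("tracking sequences follow the requested trajectory exactly", {
  still <- make_tracking_sequence(n_frames = 12, velocity = c(0, 0), seed = 2)
  ctrs <- t(vapply(still$gt, function(b) b[c("cx", "cy")], numeric(2)))
  expect_true(all(ctrs[, 1] == ctrs[1, 1] & ctrs[, 2] == ctrs[1, 2]))

  mv <- make_tracking_sequence(n_frames = 50, velocity = c(2, 0),
                               start = c(20, 60), seed = 2)
  cx <- vapply(mv$gt, function(b) b[["cx"]], numeric(1))
  expect_equal(cx, seq(20, by = 2, length.out = 50))

  gap <- make_tracking_sequence(n_frames = 50, dropout_frames = 40:44,
                                seed = 2)
  expect_equal(sum(vapply(gap$detections, is.null, logical(1))), 5)

  expect_error(make_tracking_sequence(n_frames = 200, velocity = c(2, 0),
                                      start = c(20, 60), seed = 2),
               "refused")
})
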