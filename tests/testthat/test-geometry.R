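test_that("neck vectors are direct keypoint differences", {
  sk <- manual_skeleton(nose = c(100, 50), neck = c(100, 100),
                        rsho = c(150, 100))
  nv <- neck_vectors(sk)
  expect_equal(nv$a, c(0, -50))
  expect_equal(nv$b_right, c(50, 0))
  expect_null(nv$b_left)

  sk2 <- manual_skeleton(nose = c(100, 50), neck = c(100, 100),
                         rsho = c(150, 100), lsho = c(40, 95))
  nv2 <- neck_vectors(sk2)
  expect_equal(nv2$b_left, c(-60, -5))
  expect_equal(nv2$b_right, c(50, 0))
})

test_that("coincident nose and neck is flagged degenerate and refused downstream", {
  sk <- manual_skeleton(nose = c(0, 0), neck = c(0, 0), rsho = c(10, 0))
  nv <- neck_vectors(sk)
  expect_true(nv$degenerate_a)
  expect_error(neck_angle(nv$a, nv$b_right), "degenerate")
})

test_that("missing keypoints fail loudly with their indices", {
  sk <- manual_skeleton(nose = c(1, 1), rsho = c(10, 0))  # no neck
  expect_error(neck_vectors(sk), "insufficient keypoints.*1")
  sk2 <- manual_skeleton(nose = c(1, 1), neck = c(0, 0))  # no shoulders
  expect_error(neck_vectors(sk2), "insufficient keypoints")
  expect_error(body_orientation(manual_skeleton(nose = c(1, 1))),
               "insufficient keypoints")
})

test_that("neck angle matches closed-form cases", {
  expect_equal(neck_angle(c(0, -1), c(1, 0)), 90)
  expect_equal(neck_angle(c(1, 0), c(1, 0)), 0)
  expect_equal(neck_angle(c(1, 1), c(1, 0)), 45)
  expect_error(neck_angle(c(0, 0), c(1, 0)), "degenerate")
})

test_that("neck angle is symmetric, scale invariant and supplementary under negation", {
  set.seed(11)
  for (i in 1:50) {
    a <- stats::rnorm(2); b <- stats::rnorm(2)
    if (sqrt(sum(a^2)) < 1e-6 || sqrt(sum(b^2)) < 1e-6) next
    s <- stats::runif(1, 0.1, 50)
    expect_equal(neck_angle(a, b), neck_angle(b, a), tolerance = 1e-12)
    expect_equal(neck_angle(a, b), neck_angle(s * a, b), tolerance = 1e-9)
    expect_equal(neck_angle(a, b) + neck_angle(a, -b), 180, tolerance = 1e-9)
  }
})

test_that("dropped-head ratio follows vector lengths", {
  nv <- list(a = c(0, -50), b_right = c(50, 0), b_left = NULL,
             conf_left = 0, conf_right = 1)
  expect_equal(dropped_head_ratio(nv, "right"), 1.0)
  nv$a <- c(0, -25)
  expect_equal(dropped_head_ratio(nv, "right"), 0.5)
  nv$a <- c(3, -4); nv$b_right <- c(5, 0)
  expect_equal(dropped_head_ratio(nv, "right"), 1.0)
  expect_error(dropped_head_ratio(nv, "left"), "degenerate|absent")
})

test_that("dropped-head ratio is invariant under rigid motion of the skeleton", {
  base <- list(nose = c(100, 40), neck = c(100, 100), rsho = c(60, 102),
               lsho = c(141, 99))
  r0 <- dropped_head_ratio(neck_vectors(do.call(manual_skeleton, base)), "both")
  set.seed(5)
  for (i in 1:20) {
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
    shift <- stats::rnorm(2, 0, 100)
    moved <- lapply(base, function(p) as.numeric(R %*% p + shift))
    r1 <- dropped_head_ratio(neck_vectors(do.call(manual_skeleton, moved)),
                             "both")
    expect_equal(r1, r0, tolerance = 1e-9)
  }
})

test_that("body orientation reads symmetry and nose displacement", {
  frontal <- manual_skeleton(nose = c(100, 40), neck = c(100, 100),
                             rsho = c(60, 100), lsho = c(140, 100))
  expect_equal(body_orientation(frontal)$orientation, "frontal")

  rot <- body_orientation(synth_skeleton(yaw = 30))
  expect_equal(rot$orientation, "rotated_left")
  rot2 <- body_orientation(synth_skeleton(yaw = -30))
  expect_equal(rot2$orientation, "rotated_right")

  one_sh <- manual_skeleton(nose = c(100, 40), neck = c(100, 100),
                            rsho = c(60, 100))  # left shoulder absent
  o <- body_orientation(one_sh)
  expect_equal(o$orientation, "rotated_left")
  expect_lt(o$confidence, 1)
})
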