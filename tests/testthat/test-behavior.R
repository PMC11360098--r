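upright_sk <- function(scale = 1, shift = c(0, 0)) {
  manual_skeleton(nose = c(100, 60) * scale + shift,
                  neck = c(100, 100) * scale + shift,
                  rsho = c(55, 100) * scale + shift,
                  lsho = c(145, 100) * scale + shift)
}

test_that("the frame classifier applies thresholds and precedence", {
  # upright frontal: both angles 90, ratio ~0.89 under the default template
  pr <- classify_frame(upright_sk(), yaw = 0)
  expect_equal(pr$label, "normal")
  expect_equal(pr$w_left, 90)
  expect_equal(pr$w_right, 90)

  # nose displaced toward the left shoulder: w_left 45 < 65
  tilt <- manual_skeleton(nose = c(130, 70), neck = c(100, 100),
                          rsho = c(55, 100), lsho = c(145, 100))
  prt <- classify_frame(tilt, yaw = 0)
  expect_equal(prt$label, "head_tilt")
  expect_lt(min(prt$w_left, prt$w_right), 65)

  # nose pulled to half a shoulder length: dropped_head wins even though
  # an angle also trips
  drop <- manual_skeleton(nose = c(115, 85), neck = c(100, 100),
                          rsho = c(55, 100), lsho = c(145, 100))
  prd <- classify_frame(drop, yaw = 0)
  expect_lt(prd$ratio, 0.7)
  expect_lt(min(prd$w_left, prd$w_right), 65)
  expect_equal(prd$label, "dropped_head")
})

test_that("geometry failures give indeterminate with a reason, not an error", {
  no_neck <- manual_skeleton(nose = c(1, 1), rsho = c(10, 0))
  pr <- classify_frame(no_neck, yaw = 0)
  expect_equal(pr$label, "indeterminate")
  expect_match(pr$reason, "insufficient keypoints")
})

test_that("classification is invariant under translation and scaling", {
  base <- classify_frame(upright_sk(), yaw = 0)
  for (s in c(0.3, 2, 7)) {
    for (shift in list(c(40, -20), c(-300, 500))) {
      pr <- classify_frame(upright_sk(scale = s, shift = shift), yaw = 0)
      expect_equal(pr$label, base$label)
      expect_equal(pr$w_left, base$w_left, tolerance = 1e-9)
      expect_equal(pr$ratio, base$ratio, tolerance = 1e-9)
    }
  }
})

test_that("lowering a threshold never adds detections of its class", {
  set.seed(51)
  skels <- lapply(1:40, function(i) {
    if (i %% 2 == 1) {
      tilt <- sample(c(-45, -35, 0, 35, 45), 1); drop <- 0
    } else {
      tilt <- 0; drop <- sample(c(0, 35, 45), 1)
    }
    synth_skeleton(yaw = sample(c(-30, 0, 30), 1), tilt = tilt, drop = drop,
                   noise = 1, seed = i)
  })
  count_labels <- function(tilt_th, ratio_th) {
    labs <- vapply(skels, function(sk) {
      classify_frame(sk, yaw = NULL, cam = camera_model(),
                     th = thresholds(tilt_angle_deg = tilt_th,
                                     drop_ratio = ratio_th))$label
    }, character(1))
    c(tilt = sum(labs == "head_tilt"), drop = sum(labs == "dropped_head"))
  }
  for (th_pair in list(c(65, 0.7), c(50, 0.7), c(35, 0.7))) {
    lo <- count_labels(th_pair[1] - 10, th_pair[2])
    hi <- count_labels(th_pair[1], th_pair[2])
    expect_lte(lo[["tilt"]], hi[["tilt"]])
  }
  for (r in c(0.7, 0.5)) {
    expect_lte(count_labels(65, r - 0.15)[["drop"]],
               count_labels(65, r)[["drop"]])
  }
})

test_that("event logic enforces persistence, hysteresis and gap tolerance", {
  th <- thresholds()  # 3 s at 30 fps = 90 frames
  mk <- function(labels) data.frame(frame = seq_along(labels), label = labels)

  ev <- update_events(mk(rep("head_tilt", 90)), fps = 30, th = th)
  expect_equal(nrow(ev), 1)
  expect_gte(ev$duration_s, 3)

  expect_equal(nrow(update_events(mk(rep("head_tilt", 89)), fps = 30, th = th)),
               0)

  # one indeterminate frame inside the run: still a single event
  labs <- rep("head_tilt", 95); labs[50] <- "indeterminate"
  ev2 <- update_events(mk(labs), fps = 30, th = th)
  expect_equal(nrow(ev2), 1)

  # a long indeterminate gap splits (and here kills) the run
  labs3 <- c(rep("head_tilt", 60), rep("indeterminate", 5),
             rep("head_tilt", 60))
  expect_equal(nrow(update_events(mk(labs3), fps = 30, th = th)), 0)

  expect_error(update_events(data.frame(frame = c(2, 1),
                                        label = c("normal", "normal"))),
               "stream-order")
})

test_that("no event is shorter than the persistence and events never overlap", {
  th <- thresholds(min_duration_s = 1)
  set.seed(52)
  n_emitted <- 0L
  for (rep_i in 1:10) {
    # engineered runs of random length (some above, some below persistence)
    # separated by normal stretches
    labels <- character(0)
    for (j in 1:6) {
      labels <- c(labels,
                  rep(sample(c("head_tilt", "dropped_head"), 1),
                      sample(c(5, 20, 40, 70), 1)),
                  rep("normal", sample(5:20, 1)),
                  rep("indeterminate", sample(0:3, 1)))
    }
    ev <- update_events(data.frame(frame = seq_along(labels), label = labels),
                        fps = 30, th = th)
    n_emitted <- n_emitted + nrow(ev)
    if (nrow(ev)) {
      expect_true(all(ev$duration_s >= 1))
      if (nrow(ev) > 1) {
        expect_true(all(ev$start_frame[-1] > ev$end_frame[-nrow(ev)]))
      }
    }
  }
  expect_gt(n_emitted, 5)
})

test_that("node fusion is majority with a safety-biased tie rule", {
  expect_equal(fuse_nodes(c("normal", "head_tilt", "head_tilt")), "head_tilt")
  expect_equal(fuse_nodes(c("normal", "head_tilt")), "head_tilt")
  expect_equal(fuse_nodes("normal"), "normal")
  expect_equal(fuse_nodes(c("dropped_head", "head_tilt")), "dropped_head")
  expect_equal(fuse_nodes(c("normal", "normal", "dropped_head")), "normal")
  expect_error(fuse_nodes(character(0)), "fusion failure")
})
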