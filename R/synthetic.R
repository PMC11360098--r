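#' Posture specification for the synthetic skeleton generator
#'
#' `tilt_deg` is a lateral head tilt about the body's forward axis (the
#' nose swings toward a shoulder in the frontal plane); `drop_deg` is a
#' forward head pitch (chin toward chest). The ground-truth label follows
#' the generator margins: tilt >= 25 gives `head_tilt`, drop >= 30 gives
#' `dropped_head`, both clearly below gives `normal`. Combinations inside
#' the ambiguous band, or with both margins exceeded, are refused so that
#' ground truth is never debatable.
#'
#' @param tilt_deg Lateral tilt in degrees (positive tilts toward the
#'   subject's left / image right).
#' @param drop_deg Forward pitch in degrees.
#' @return List of class `posture_spec` with the derived `label`.
#' @export
posture_spec <- function(tilt_deg = 0, drop_deg = 0) {
  tilt_ab <- abs(tilt_deg) >= 25
  drop_ab <- drop_deg >= 30
  normal_ok <- abs(tilt_deg) <= 12 && drop_deg <= 15
  if (tilt_ab && drop_ab) {
    stop("ambiguous posture spec: both tilt and drop exceed their margins",
         call. = FALSE)
  }
  label <- if (drop_ab) "dropped_head" else if (tilt_ab) "head_tilt"
           else if (normal_ok) "normal"
           else stop("ambiguous posture spec: inside the refused margin band",
                     call. = FALSE)
  structure(list(tilt_deg = tilt_deg, drop_deg = drop_deg, label = label),
            class = "posture_spec")
}

#' Scene specification for the synthetic projector
#'
#' @param yaw_deg Body yaw relative to the camera, degrees (the study
#'   positions are 0, +/-30, +/-60).
#' @param distance_m Camera-to-neck distance in meters (study distances
#'   0.5 and 0.75).
#' @param noise_px Std of i.i.d. Gaussian pixel noise added to keypoints.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return List of class `scene_spec`.
#' @export
scene_spec <- function(yaw_deg = 0, distance_m = 0.75, noise_px = 0,
                       seed = 1L) {
  stopifnot(distance_m > 0, noise_px >= 0)
  structure(list(yaw_deg = yaw_deg, distance_m = distance_m,
                 noise_px = noise_px, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Pose a 3D skeleton from the template
#'
#' Starts from the upright template and rotates the nose about the neck:
#' first by `tilt_deg` in the frontal (x-y) plane, then by `drop_deg`
#' about the lateral (x) axis; shoulders and hips are unchanged.
#'
#' @param p A [posture_spec()].
#' @param tmpl A [pose_template_3d()].
#' @return A 3 x 6 matrix of subject-frame coordinates (columns named as
#'   in the template) with attributes `label` and `frontal_angle_left` /
#'   `frontal_angle_right` / `frontal_ratio` (the frontal-plane geometry
#'   the corrected 2D pipeline should recover).
#' @export
make_skeleton3d <- function(p, tmpl = pose_template_3d()) {
  stopifnot(inherits(p, "posture_spec"))
  pts <- vapply(tmpl$points, identity, numeric(3))
  nose <- pts[, "nose"]
  t_r <- p$tilt_deg * pi / 180
  # frontal-plane rotation about the z (forward) axis: positive tilt moves
  # the nose toward +x (image right)
  nose <- c(nose[1] * cos(t_r) - nose[2] * sin(t_r),
            nose[1] * sin(t_r) + nose[2] * cos(t_r),
            nose[3])
  d_r <- p$drop_deg * pi / 180
  # forward pitch about the lateral x axis: the head drops toward the chest
  nose <- c(nose[1],
            nose[2] * cos(d_r) + nose[3] * sin(d_r),
            -nose[2] * sin(d_r) + nose[3] * cos(d_r))
  pts[, "nose"] <- nose

  a2 <- c(nose[1], nose[2])  # frontal-plane head vector (neck at origin)
  bl <- pts[1:2, "left_shoulder"]; br <- pts[1:2, "right_shoulder"]
  attr(pts, "label") <- p$label
  attr(pts, "frontal_angle_left") <- tryCatch(neck_angle(a2, bl),
                                              error = function(e) NA_real_)
  attr(pts, "frontal_angle_right") <- tryCatch(neck_angle(a2, br),
                                               error = function(e) NA_real_)
  attr(pts, "frontal_ratio") <-
    sqrt(sum(a2^2)) / mean(c(sqrt(sum(bl^2)), sqrt(sum(br^2))))
  pts
}

#' Project a 3D skeleton to a 2D keypoint skeleton
#'
#' Rotates the body about its vertical axis through the neck by the scene
#' yaw, places the neck at `distance_m` on the optical axis, applies the
#' pinhole projection `u = f X/Z + cx`, `v = f Y/Z + cy`, and adds seeded
#' Gaussian pixel noise. Confidences are 1.0; beyond |yaw| > 60 degrees
#' the far-side (self-occluded) shoulder and hip get confidence 0.3.
#'
#' @param kp3d A 3 x 6 matrix from [make_skeleton3d()].
#' @param s A [scene_spec()].
#' @param cam A [camera_model()].
#' @param frame_index,node_id Metadata stamped on the skeleton.
#' @return A [skeleton()].
#' @export
project_skeleton <- function(kp3d, s, cam = camera_model(),
                             frame_index = 0L, node_id = "node0") {
  phi <- s$yaw_deg * pi / 180
  R <- rot_yaw(phi)
  rot <- R %*% kp3d
  # camera frame: subject z points toward the camera, so depth = D - z
  depth <- s$distance_m - rot[3, ]
  if (any(depth <= 0)) {
    stop("projection failure: point behind camera", call. = FALSE)
  }
  u6 <- cam$focal_px * rot[1, ] / depth + cam$cx
  v6 <- cam$focal_px * rot[2, ] / depth + cam$cy
  if (s$noise_px > 0) {
    set.seed(s$seed)
    u6 <- u6 + stats::rnorm(length(u6), 0, s$noise_px)
    v6 <- v6 + stats::rnorm(length(v6), 0, s$noise_px)
  }
  u <- rep(0, 18); v <- rep(0, 18); conf <- rep(0, 18)
  for (nm in colnames(kp3d)) {
    i <- TEMPLATE_SLOTS[[nm]] + 1L
    u[i] <- u6[[nm]]; v[i] <- v6[[nm]]; conf[i] <- 1
  }
  if (abs(s$yaw_deg) > 60) {
    far <- if (s$yaw_deg > 0) c("left_shoulder", "left_hip")
           else c("right_shoulder", "right_hip")
    conf[TEMPLATE_SLOTS[far] + 1L] <- 0.3
  }
  sk <- skeleton(u, v, conf, frame_index = frame_index, node_id = node_id)
  attr(sk, "label") <- attr(kp3d, "label")
  attr(sk, "frontal_angle_left") <- attr(kp3d, "frontal_angle_left")
  attr(sk, "frontal_angle_right") <- attr(kp3d, "frontal_angle_right")
  attr(sk, "frontal_ratio") <- attr(kp3d, "frontal_ratio")
  sk
}

# per-subject anthropometric jitter: each segment length scaled by an
# independent uniform factor in [1-amount, 1+amount]
jitter_template <- function(tmpl, amount = 0.10) {
  f <- stats::runif(5, 1 - amount, 1 + amount)
  pose_template_3d(shoulder_span = tmpl$shoulder_span * f[1],
                   neck_nose = tmpl$neck_nose * f[2],
                   nose_depth = tmpl$nose_depth * f[3],
                   hip_width = tmpl$hip_width * f[4],
                   hip_drop = tmpl$hip_drop * f[5])
}

#' Generate a labeled classification dataset mirroring the study protocol
#'
#' For every (yaw, distance) cell, generates `n_per_cell` subjects, each
#' performing one negative pose (near-upright) and one positive pose
#' (alternating head tilt, sampled in 35-55 degrees, and dropped head,
#' sampled in 35-50 degrees), so each cell holds `2 * n_per_cell` records
#' with a 50/50 positive/negative balance. Subjects carry independent
#' +/-10% anthropometric jitter standing in for the participants' height
#' range. Everything is driven by the single seed.
#'
#' @param n_per_cell Subjects per cell (the study used 80, i.e. 160
#'   records per cell).
#' @param yaws,distances Cell grid (defaults: the five study positions at
#'   the two study distances).
#' @param noise_px Keypoint noise std in pixels.
#' @param seed RNG seed.
#' @param cam A [camera_model()].
#' @param tmpl Base [pose_template_3d()].
#' @return List with `skeletons` (list of [skeleton()]s),
#'   `truth` (data frame: `record_id`, `yaw_deg`, `distance_m`, `cell`,
#'   `label`), `cam`, and the generation parameters.
#' @export
make_classification_dataset <- function(n_per_cell = 80L,
                                        yaws = c(0, 30, -30, 60, -60),
                                        distances = c(0.5, 0.75),
                                        noise_px = 2, seed = 1L,
                                        cam = camera_model(),
                                        tmpl = pose_template_3d()) {
  stopifnot(n_per_cell >= 1)
  set.seed(seed)
  skels <- list(); truth <- list()
  rec <- 0L
  for (d in distances) for (yaw in yaws) {
    cell <- sprintf("yaw%+03d_d%.2f", yaw, d)
    for (subj in seq_len(n_per_cell)) {
      subj_tmpl <- jitter_template(tmpl)
      neg <- posture_spec(tilt_deg = stats::runif(1, -8, 8),
                          drop_deg = stats::runif(1, 0, 10))
      pos <- if (subj %% 2L == 1L) {
        posture_spec(tilt_deg = sample(c(-1, 1), 1) * stats::runif(1, 35, 55))
      } else {
        posture_spec(drop_deg = stats::runif(1, 35, 50))
      }
      for (p in list(neg, pos)) {
        rec <- rec + 1L
        sc <- scene_spec(yaw_deg = yaw, distance_m = d, noise_px = noise_px,
                         seed = sample.int(.Machine$integer.max, 1))
        sk <- project_skeleton(make_skeleton3d(p, subj_tmpl), sc, cam,
                               frame_index = rec)
        skels[[rec]] <- sk
        truth[[rec]] <- data.frame(record_id = rec, yaw_deg = yaw,
                                   distance_m = d, cell = cell,
                                   label = p$label, stringsAsFactors = FALSE)
      }
    }
  }
  list(skeletons = skels, truth = do.call(rbind, truth), cam = cam,
       n_per_cell = n_per_cell, noise_px = noise_px, seed = seed)
}

#' Generate a synthetic tracking sequence with detector dropouts
#'
#' A textured rectangular patch (seeded random texture, fixed for the
#' sequence) moves along a constant-velocity or sinusoidal path over a
#' noise background. Detections equal ground truth plus seeded jitter,
#' except on dropout frames, where no detection is emitted. Optionally the
#' object is removed from the frames entirely on chosen frames (to
#' exercise the match-failure path).
#'
#' @param n_frames Number of frames.
#' @param frame_size `c(rows, cols)` of each frame.
#' @param start `c(cx, cy)` initial patch center.
#' @param velocity `c(vx, vy)` pixels/frame (constant-velocity path).
#' @param patch_size `c(w, h)` of the object in pixels.
#' @param dropout_frames Integer frames (1-based) with no detection.
#' @param remove_frames Integer frames on which the object is absent from
#'   the image as well.
#' @param det_jitter_px Std of detection-center jitter.
#' @param sinusoid Optional list `(amplitude, period)` adding a vertical
#'   sinusoid to the path.
#' @param seed RNG seed.
#' @return List with `frames` (list of matrices in `[0, 1]`), `gt` (list of
#'   ground-truth [bbox()]), `detections` (list of [bbox()] or `NULL`).
#' @export
make_tracking_sequence <- function(n_frames = 60L, frame_size = c(120L, 160L),
                                   start = c(30, 60), velocity = c(1.5, 0),
                                   patch_size = c(24, 18),
                                   dropout_frames = integer(0),
                                   remove_frames = integer(0),
                                   det_jitter_px = 0.5,
                                   sinusoid = NULL, seed = 1L) {
  set.seed(seed)
  # spatially coherent appearance: a coarse random grid upsampled to the
  # patch size, so the difference hash is stable under sub-pixel shifts
  texture <- area_resize(matrix(stats::runif(5 * 4, 0.2, 1), nrow = 4),
                         patch_size[2], patch_size[1])
  jit <- matrix(stats::rnorm(2 * n_frames, 0, det_jitter_px), ncol = 2)
  bg_seed <- sample.int(.Machine$integer.max, n_frames)

  frames <- vector("list", n_frames)
  gt <- vector("list", n_frames)
  detections <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    cx <- start[1] + velocity[1] * (k - 1)
    cy <- start[2] + velocity[2] * (k - 1)
    if (!is.null(sinusoid)) {
      cy <- cy + sinusoid$amplitude * sin(2 * pi * (k - 1) / sinusoid$period)
    }
    box <- bbox(cx, cy, patch_size[1], patch_size[2])
    if (cx - patch_size[1] / 2 < 0 || cx + patch_size[1] / 2 > frame_size[2] ||
        cy - patch_size[2] / 2 < 0 || cy + patch_size[2] / 2 > frame_size[1]) {
      stop("trajectory refused: object leaves the frame", call. = FALSE)
    }
    set.seed(bg_seed[k])
    fr <- matrix(stats::runif(prod(frame_size), 0, 0.15),
                 nrow = frame_size[1], ncol = frame_size[2])
    if (!(k %in% remove_frames)) {
      r0 <- round(cy - patch_size[2] / 2) + 1L
      c0 <- round(cx - patch_size[1] / 2) + 1L
      fr[r0:(r0 + patch_size[2] - 1L), c0:(c0 + patch_size[1] - 1L)] <- texture
    }
    frames[[k]] <- fr
    gt[[k]] <- box
    detections[[k]] <- if (k %in% dropout_frames || k %in% remove_frames) {
      NULL
    } else {
      bbox(cx + jit[k, 1], cy + jit[k, 2], patch_size[1], patch_size[2])
    }
  }
  list(frames = frames, gt = gt, detections = detections,
       texture = texture, seed = seed)
}
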