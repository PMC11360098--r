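#' Pinhole camera model
#'
#' Minimal intrinsics used by yaw estimation and the synthetic projector:
#' a focal length in pixels and a principal point. Lens distortion is
#' declared zero.
#'
#' @param focal_px Focal length in pixels (> 0).
#' @param cx,cy Principal point in pixels.
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(focal_px = 800, cx = 640, cy = 540) {
  stopifnot(focal_px > 0)
  structure(list(focal_px = focal_px, cx = cx, cy = cy),
            class = "camera_model")
}

#' Canonical upright 3D pose template
#'
#' Anthropometric 3D coordinates (meters) for the six torso/head landmarks
#' of an upright, frontal body: neck at the origin, x to the image right,
#' y downward, z toward the camera. The template is bilaterally symmetric
#' and the nose sits forward of the neck (positive z), which is what makes
#' the nose's horizontal parallax a usable yaw signal.
#'
#' @param shoulder_span Shoulder-to-shoulder width in meters.
#' @param neck_nose Neck-to-nose vertical length in meters.
#' @param nose_depth Forward offset of the nose from the neck plane, meters.
#' @param hip_width Hip-to-hip width in meters.
#' @param hip_drop Vertical neck-to-hip distance in meters.
#' @return Object of class `pose_template_3d`: a named list of 3-vectors
#'   plus the raw proportions.
#' @export
pose_template_3d <- function(shoulder_span = 0.38, neck_nose = 0.16,
                             nose_depth = 0.10, hip_width = 0.26,
                             hip_drop = 0.45) {
  stopifnot(shoulder_span > 0, neck_nose > 0, nose_depth > 0)
  hs <- shoulder_span / 2
  hh <- hip_width / 2
  structure(list(
    points = list(
      nose = c(0, -neck_nose, nose_depth),
      neck = c(0, 0, 0),
      right_shoulder = c(-hs, 0, 0),
      left_shoulder = c(hs, 0, 0),
      right_hip = c(-hh, hip_drop, 0),
      left_hip = c(hh, hip_drop, 0)
    ),
    shoulder_span = shoulder_span, neck_nose = neck_nose,
    nose_depth = nose_depth, hip_width = hip_width, hip_drop = hip_drop
  ), class = "pose_template_3d")
}

# zero-based keypoint slot for each template landmark
TEMPLATE_SLOTS <- c(nose = 0L, neck = 1L, right_shoulder = 2L,
                    left_shoulder = 5L, right_hip = 8L, left_hip = 11L)

# rotation about the vertical (y, image-down) axis; positive yaw moves
# points with positive z (toward camera) toward increasing x/u
rot_yaw <- function(phi_rad) {
  c_ <- cos(phi_rad); s_ <- sin(phi_rad)
  matrix(c(c_, 0, s_,
           0, 1, 0,
           -s_, 0, c_), nrow = 3, byrow = TRUE)
}

rot_pitch <- function(th) {
  c_ <- cos(th); s_ <- sin(th)
  matrix(c(1, 0, 0,
           0, c_, -s_,
           0, s_, c_), nrow = 3, byrow = TRUE)
}

rot_roll <- function(th) {
  c_ <- cos(th); s_ <- sin(th)
  matrix(c(c_, -s_, 0,
           s_, c_, 0,
           0, 0, 1), nrow = 3, byrow = TRUE)
}

#' Estimate the camera yaw of a skeleton
#'
#' Yaw is the rotation of the body about its vertical axis relative to the
#' camera; positive yaw displaces the nose toward increasing `u`. With
#' camera intrinsics, a perspective-n-point solve is run between the
#' observed 2D keypoints and the 3D template (multi-start Gauss-Newton
#' least squares over yaw/pitch/roll and translation; yaw is read directly
#' off the fitted Y-X-Z Euler parametrization, i.e. the rotation about the
#' image-vertical axis). Without intrinsics, or when the solve fails, a
#' weak-perspective asymmetry estimate is used:
#' `phi = arcsin(clamp(du_nose / (kappa * span_px), -1, 1))` with `kappa`
#' the template's nose-depth-to-shoulder-span ratio.
#'
#' @param skel A [skeleton()].
#' @param cam A [camera_model()] or `NULL` for asymmetry mode.
#' @param tmpl A [pose_template_3d()].
#' @return List of class `yaw_estimate`: `phi_deg` in `[-90, 90]`,
#'   `method` (`"pnp"` or `"asymmetry"`), `quality` in `[0, 1]`.
#' @export
estimate_yaw <- function(skel, cam = NULL, tmpl = pose_template_3d()) {
  present <- names(TEMPLATE_SLOTS)[vapply(TEMPLATE_SLOTS,
                                          function(i) kp_present(skel, i),
                                          logical(1))]
  # the nose moves with posture (tilt/drop); the rigid solve uses only the
  # torso landmarks, which the generator and real bodies keep template-like
  present <- setdiff(present, "nose")
  if (!is.null(cam) && length(present) >= 4L) {
    est <- tryCatch(pnp_yaw(skel, cam, tmpl, present), error = function(e) NULL)
    if (!is.null(est)) return(est)
    warning("PnP solve failed; falling back to asymmetry yaw estimate",
            call. = FALSE)
  }
  asymmetry_yaw(skel, tmpl)
}

asymmetry_yaw <- function(skel, tmpl) {
  require_keypoints(skel, c(KP_NOSE, KP_NECK))
  has_l <- kp_present(skel, KP_LSHO)
  has_r <- kp_present(skel, KP_RSHO)
  if (!has_l && !has_r) {
    stop("yaw unavailable: no shoulder keypoint for asymmetry mode",
         call. = FALSE)
  }
  neck_u <- kp_uv(skel, KP_NECK)[["u"]]
  span <- if (has_l && has_r) {
    abs(kp_uv(skel, KP_LSHO)[["u"]] - kp_uv(skel, KP_RSHO)[["u"]])
  } else if (has_l) {
    2 * abs(kp_uv(skel, KP_LSHO)[["u"]] - neck_u)
  } else {
    2 * abs(kp_uv(skel, KP_RSHO)[["u"]] - neck_u)
  }
  if (span == 0) stop("yaw unavailable: zero shoulder span", call. = FALSE)
  du <- kp_uv(skel, KP_NOSE)[["u"]] - neck_u
  kappa <- tmpl$nose_depth / tmpl$shoulder_span
  phi <- asin(max(-1, min(1, du / (kappa * span)))) * 180 / pi
  structure(list(phi_deg = phi, method = "asymmetry",
                 quality = if (has_l && has_r) 0.5 else 0.3),
            class = "yaw_estimate")
}

pnp_yaw <- function(skel, cam, tmpl, present) {
  P3 <- vapply(tmpl$points[present], identity, numeric(3))  # 3 x n
  obs <- vapply(present, function(nm) kp_uv(skel, TEMPLATE_SLOTS[[nm]]),
                numeric(2))                                 # 2 x n
  # initial translation from the neck pixel and the projected span
  span_px <- if (all(c("left_shoulder", "right_shoulder") %in% present)) {
    sqrt(sum((obs[, "left_shoulder"] - obs[, "right_shoulder"])^2))
  } else {
    NA_real_
  }
  tz0 <- if (is.finite(span_px) && span_px > 0) {
    cam$focal_px * tmpl$shoulder_span / span_px
  } else 1
  anchor <- if ("neck" %in% present) obs[, "neck"] else rowMeans(obs)
  tx0 <- (anchor[[1]] - cam$cx) * tz0 / cam$focal_px
  ty0 <- (anchor[[2]] - cam$cy) * tz0 / cam$focal_px

  residuals <- function(theta) {
    R <- rot_yaw(theta[1]) %*% rot_pitch(theta[2]) %*% rot_roll(theta[3])
    p <- R %*% P3
    # camera frame: Zc decreases as subject z (toward camera) grows
    pc <- rbind(p[1, ] + theta[4], p[2, ] + theta[5], theta[6] - p[3, ])
    if (any(pc[3, ] <= 1e-6)) return(rep(1e6, 2 * ncol(pc)))
    proj <- rbind(cam$focal_px * pc[1, ] / pc[3, ] + cam$cx,
                  cam$focal_px * pc[2, ] / pc[3, ] + cam$cy)
    as.numeric(proj - obs)
  }
  obj <- function(theta) sum(residuals(theta)^2)

  best <- NULL
  for (phi0 in c(-60, -30, 0, 30, 60) * pi / 180) {
    fit <- tryCatch(
      stats::optim(c(phi0, 0, 0, tx0, ty0, tz0), obj, method = "BFGS",
                   control = list(maxit = 400, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(fit$par))) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("PnP optimization failed", call. = FALSE)
  phi <- best$par[1] * 180 / pi
  phi <- ((phi + 180) %% 360) - 180
  phi <- max(-90, min(90, phi))
  rmse <- sqrt(best$value / length(present))
  structure(list(phi_deg = phi, method = "pnp",
                 quality = 1 / (1 + rmse)),
            class = "yaw_estimate")
}

#' @export
print.yaw_estimate <- function(x, ...) {
  cat(sprintf("<yaw_estimate> %.2f deg (%s, quality %.2f)\n",
              x$phi_deg, x$method, x$quality))
  invisible(x)
}
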