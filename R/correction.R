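#' Literal affine yaw map applied to a single point
#'
#' The printed foreshortening matrix maps a frontal point `(u, v)` to
#' `(u cos(phi), v - u sin(phi))` (`mode = "as_printed"`); its exact inverse
#' maps `(u, v)` to `(u / cos(phi), v + (u / cos(phi)) sin(phi))`
#' (`mode = "inverse"`, the default, since correcting an observed point
#' means undoing the forward model). Coordinates are taken relative to
#' `origin` (typically the neck) before the map and restored after.
#'
#' @param p Length-2 numeric `(u, v)`.
#' @param phi_deg Yaw angle in degrees; inverse mode requires
#'   `|phi_deg| < 90`.
#' @param mode `"inverse"` or `"as_printed"`.
#' @param origin Length-2 numeric subtracted before and added back after.
#' @return Corrected `(u, v)`.
#' @export
affine_correct_point <- function(p, phi_deg, mode = c("inverse", "as_printed"),
                                 origin = c(0, 0)) {
  mode <- match.arg(mode)
  phi <- phi_deg * pi / 180
  u <- p[1] - origin[1]; v <- p[2] - origin[2]
  if (mode == "as_printed") {
    out <- c(u * cos(phi), v - u * sin(phi))
  } else {
    if (abs(phi_deg) >= 90) {
      stop("singular correction: |phi| >= 90 degrees in inverse mode",
           call. = FALSE)
    }
    uc <- u / cos(phi)
    out <- c(uc, v + uc * sin(phi))
  }
  out + origin
}

#' Yaw-correct the neck vectors of a skeleton
#'
#' Undoes the horizontal foreshortening a camera yaw imposes on the
#' neck-to-nose and neck-to-shoulder vectors, so that the neck angle and
#' dropped-head ratio can be evaluated as if the body were frontal.
#'
#' The default `"inverse"` mode applies the physical inverse of yaw
#' foreshortening for points on the body's frontal plane: `u` is stretched
#' by `1/cos(phi)` relative to the neck and `v` is left unchanged (a pure
#' yaw rotation does not move image rows). Because the nose sits forward of
#' that plane, its projection also carries a parallax offset
#' `~ s * z_nose * sin(phi)`; this is removed first, with the scale `s`
#' estimated from the observed shoulder span (and, when camera intrinsics
#' are supplied, per-side depth estimates that also absorb most
#' near/far-shoulder perspective asymmetry). `"as_printed"` applies the
#' literal foreshortening matrix instead (see [affine_correct_point()]),
#' retained for reproducing the printed map verbatim.
#'
#' @param skel A [skeleton()].
#' @param phi_deg Yaw in degrees (estimated or known).
#' @param mode `"inverse"` (default) or `"as_printed"`.
#' @param cam Optional [camera_model()]; enables depth-aware parallax
#'   removal.
#' @param tmpl A [pose_template_3d()] supplying the nose-depth and
#'   shoulder-span proportions.
#' @return A `neck_vectors` list as from [neck_vectors()], computed on the
#'   corrected keypoints.
#' @export
yaw_correct_vectors <- function(skel, phi_deg, mode = c("inverse", "as_printed"),
                                cam = NULL, tmpl = pose_template_3d()) {
  mode <- match.arg(mode)
  nv <- neck_vectors(skel)
  if (phi_deg == 0) return(nv)
  phi <- phi_deg * pi / 180

  if (mode == "as_printed") {
    fwd <- function(p) {
      if (is.null(p)) return(NULL)
      c(p[1] * cos(phi), p[2] - p[1] * sin(phi))
    }
    nv$a <- fwd(nv$a)
    nv$b_left <- fwd(nv$b_left)
    nv$b_right <- fwd(nv$b_right)
    nv$degenerate_a <- sqrt(sum(nv$a^2)) == 0
    return(nv)
  }

  if (abs(phi_deg) >= 90) {
    stop("singular correction: |phi| >= 90 degrees in inverse mode",
         call. = FALSE)
  }
  half_span <- tmpl$shoulder_span / 2
  us <- c(left = if (is.null(nv$b_left)) NA_real_ else nv$b_left[1],
          right = if (is.null(nv$b_right)) NA_real_ else nv$b_right[1])
  us <- us[is.finite(us) & abs(us) > 1e-9]

  parallax <- 0
  if (length(us) > 0) {
    if (!is.null(cam)) {
      # per-side distance estimates; their mean cancels the near/far
      # shoulder depth offset, leaving the neck distance
      z_sides <- cam$focal_px * half_span * abs(cos(phi)) / abs(us)
      z_neck <- mean(z_sides)
      z_nose <- z_neck - tmpl$nose_depth * cos(phi)
      if (z_nose > 0.05 * z_neck) {
        parallax <- cam$focal_px * tmpl$nose_depth * sin(phi) / z_nose
      } else {
        parallax <- cam$focal_px * tmpl$nose_depth * sin(phi) / z_neck
      }
    } else {
      s_hat <- mean(abs(us)) / (half_span * abs(cos(phi)))
      parallax <- s_hat * tmpl$nose_depth * sin(phi)
    }
  }

  stretch <- function(p) {
    if (is.null(p)) return(NULL)
    c(p[1] / cos(phi), p[2])
  }
  nv$a <- stretch(c(nv$a[1] - parallax, nv$a[2]))
  nv$b_left <- stretch(nv$b_left)
  nv$b_right <- stretch(nv$b_right)
  nv$degenerate_a <- sqrt(sum(nv$a^2)) == 0
  nv
}

#' Yaw-corrected neck angle
#'
#' Applies the yaw correction of [yaw_correct_vectors()] and returns the
#' neck angle on the corrected vectors for the requested side.
#'
#' @param skel A [skeleton()].
#' @param yaw A `yaw_estimate` (from [estimate_yaw()]) or a plain number of
#'   degrees.
#' @param side `"auto"` (higher-confidence side), `"left"` or `"right"`.
#' @param mode Correction mode, see [yaw_correct_vectors()].
#' @param cam,tmpl Passed to [yaw_correct_vectors()].
#' @return Angle in degrees.
#' @export
corrected_neck_angle <- function(skel, yaw, side = c("auto", "left", "right"),
                                 mode = c("inverse", "as_printed"),
                                 cam = NULL, tmpl = pose_template_3d()) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  phi_deg <- if (inherits(yaw, "yaw_estimate")) yaw$phi_deg else as.numeric(yaw)
  nv <- yaw_correct_vectors(skel, phi_deg, mode = mode, cam = cam, tmpl = tmpl)
  if (nv$degenerate_a) {
    stop("degenerate geometry: zero-length head vector", call. = FALSE)
  }
  b <- switch(side,
    left = nv$b_left,
    right = nv$b_right,
    auto = if (nv$conf_left >= nv$conf_right && !is.null(nv$b_left)) {
      nv$b_left
    } else if (!is.null(nv$b_right)) nv$b_right else nv$b_left
  )
  if (is.null(b)) {
    stop(sprintf("insufficient keypoints: %s shoulder absent", side),
         call. = FALSE)
  }
  neck_angle(nv$a, b)
}
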