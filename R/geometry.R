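#' Neck vectors of a skeleton
#'
#' Computes the vector `a` from the neck to the nose (the head vector) and
#' the vectors `b_left`, `b_right` from the neck to each shoulder, in image
#' pixels. These are the raw ingredients of the neck angle and the
#' dropped-head ratio.
#'
#' @param skel A [skeleton()].
#' @return A list of class `neck_vectors` with components `a`, `b_left`,
#'   `b_right` (each a length-2 numeric `(du, dv)` or `NULL` when the
#'   corresponding shoulder is absent), `degenerate_a` (TRUE when nose and
#'   neck coincide), and the endpoint confidences `conf_left`, `conf_right`.
#' @export
neck_vectors <- function(skel) {
  require_keypoints(skel, c(KP_NOSE, KP_NECK))
  if (!kp_present(skel, KP_RSHO) && !kp_present(skel, KP_LSHO)) {
    stop(sprintf("insufficient keypoints: missing indices %d, %d (both shoulders)",
                 KP_RSHO, KP_LSHO), call. = FALSE)
  }
  neck <- kp_uv(skel, KP_NECK)
  a <- kp_uv(skel, KP_NOSE) - neck
  bl <- if (kp_present(skel, KP_LSHO)) kp_uv(skel, KP_LSHO) - neck else NULL
  br <- if (kp_present(skel, KP_RSHO)) kp_uv(skel, KP_RSHO) - neck else NULL
  structure(list(
    a = unname(a),
    b_left = unname(bl), b_right = unname(br),
    degenerate_a = sqrt(sum(a^2)) == 0,
    conf_left = if (is.null(bl)) 0 else
      mean(c(kp_conf(skel, KP_NECK), kp_conf(skel, KP_LSHO))),
    conf_right = if (is.null(br)) 0 else
      mean(c(kp_conf(skel, KP_NECK), kp_conf(skel, KP_RSHO)))
  ), class = "neck_vectors")
}

#' Angle between two 2D vectors, in degrees
#'
#' The neck angle `w = arccos(a.b / (|a||b|))`, in `[0, 180]` degrees.
#' For an upright frontal posture the angle between the neck-to-nose vector
#' and either neck-to-shoulder vector is close to 90 degrees.
#'
#' @param a,b Length-2 numeric vectors with nonzero length.
#' @return Angle in degrees.
#' @export
neck_angle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("degenerate geometry: zero-length vector in neck_angle", call. = FALSE)
  }
  cosw <- sum(a * b) / (na * nb)
  cosw <- max(-1, min(1, cosw))
  acos(cosw) * 180 / pi
}

#' Dropped-head ratio
#'
#' The ratio `|a| / |b_side|` of the neck-to-nose length to the
#' neck-to-shoulder length on one side. The ratio shrinks as the head
#' pitches forward (chin toward chest); values well below 1 indicate a
#' dropped head.
#'
#' @param nv A [neck_vectors()] result.
#' @param side `"left"`, `"right"`, `"auto"` (the side whose endpoints have
#'   the higher mean confidence), or `"both"` (the mean of the two shoulder
#'   lengths, which cancels most perspective asymmetry between the near and
#'   far shoulder).
#' @return Strictly positive ratio (dimensionless).
#' @export
dropped_head_ratio <- function(nv, side = c("auto", "left", "right", "both")) {
  side <- match.arg(side)
  la <- sqrt(sum(nv$a^2))
  lens <- c(left = if (is.null(nv$b_left)) NA_real_ else sqrt(sum(nv$b_left^2)),
            right = if (is.null(nv$b_right)) NA_real_ else sqrt(sum(nv$b_right^2)))
  lb <- switch(side,
    left = lens[["left"]],
    right = lens[["right"]],
    auto = {
      pick <- if (nv$conf_left >= nv$conf_right) "left" else "right"
      if (is.na(lens[[pick]])) pick <- setdiff(c("left", "right"), pick)
      lens[[pick]]
    },
    both = mean(lens, na.rm = TRUE)
  )
  if (is.na(lb) || lb == 0) {
    stop("degenerate geometry: zero-length or absent shoulder vector",
         call. = FALSE)
  }
  la / lb
}

#' Coarse body orientation from keypoint asymmetry
#'
#' Classifies the body as facing the camera (`frontal`) or rotated, from the
#' nose's horizontal offset relative to the neck (normalized by shoulder
#' span) and the left/right balance of the neck-to-shoulder extents.
#' Positive yaw displaces the nose toward increasing `u`, labelled
#' `rotated_left`; a skeleton with one shoulder occluded is classified as
#' rotated toward the missing side with reduced confidence.
#'
#' @param skel A [skeleton()].
#' @param frontal_offset Threshold on `|nose u-offset| / shoulder span`
#'   below which (with balanced shoulders) the body counts as frontal.
#' @param balance_tol Maximum relative imbalance of the two shoulder
#'   extents still considered frontal.
#' @return List with `orientation` in
#'   `{"frontal", "rotated_left", "rotated_right"}` and `confidence` in
#'   `[0, 1]`.
#' @export
body_orientation <- function(skel, frontal_offset = 0.15, balance_tol = 0.35) {
  require_keypoints(skel, KP_NECK)
  has_l <- kp_present(skel, KP_LSHO)
  has_r <- kp_present(skel, KP_RSHO)
  if (!has_l && !has_r) {
    stop(sprintf("insufficient keypoints: missing indices %d, %d (both shoulders)",
                 KP_RSHO, KP_LSHO), call. = FALSE)
  }
  if (!has_l) {
    return(list(orientation = "rotated_left", confidence = 0.5))
  }
  if (!has_r) {
    return(list(orientation = "rotated_right", confidence = 0.5))
  }
  neck <- kp_uv(skel, KP_NECK)
  ext_l <- abs(kp_uv(skel, KP_LSHO)[["u"]] - neck[["u"]])
  ext_r <- abs(kp_uv(skel, KP_RSHO)[["u"]] - neck[["u"]])
  span <- ext_l + ext_r
  if (span == 0) stop("degenerate geometry: zero shoulder span", call. = FALSE)
  du_nose <- if (kp_present(skel, KP_NOSE)) {
    kp_uv(skel, KP_NOSE)[["u"]] - neck[["u"]]
  } else 0
  rel_off <- du_nose / span
  imbalance <- abs(ext_l - ext_r) / max(ext_l, ext_r)
  if (abs(rel_off) < frontal_offset && imbalance <= balance_tol) {
    return(list(orientation = "frontal",
                confidence = 1 - abs(rel_off) / frontal_offset))
  }
  # rotated toward the side the nose displaces to; with no nose signal,
  # the near (camera-side) shoulder projects longer, and positive yaw
  # brings the right shoulder nearer
  dir <- if (rel_off != 0) sign(rel_off) else sign(ext_r - ext_l)
  list(orientation = if (dir >= 0) "rotated_left" else "rotated_right",
       confidence = min(1, max(abs(rel_off), imbalance)))
}
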