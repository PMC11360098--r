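#' @keywords internal
"_PACKAGE"

#' COCO-18 / OpenPose keypoint names, in slot order
#'
#' The fixed 18-slot body-keypoint layout emitted by OpenPose-family pose
#' estimators. Slots used by the geometry operations are 0 (nose), 1 (neck),
#' 2 (right shoulder), 5 (left shoulder), 8 (right hip) and 11 (left hip);
#' indices here are zero-based as in the upstream convention, and are mapped
#' to 1-based R indices internally.
#'
#' @format Character vector of length 18.
#' @export
coco18_names <- c(
  "nose", "neck",
  "right_shoulder", "right_elbow", "right_wrist",
  "left_shoulder", "left_elbow", "left_wrist",
  "right_hip", "right_knee", "right_ankle",
  "left_hip", "left_knee", "left_ankle",
  "right_eye", "left_eye", "right_ear", "left_ear"
)

# zero-based slot indices of the joints the geometry uses
KP_NOSE <- 0L
KP_NECK <- 1L
KP_RSHO <- 2L
KP_LSHO <- 5L
KP_RHIP <- 8L
KP_LHIP <- 11L

#' Construct a skeleton of 18 2D keypoints
#'
#' A skeleton is the unit of geometric analysis: an 18-row matrix of image
#' coordinates (origin top-left, `v` increasing downward) with per-keypoint
#' confidences. Missing keypoints are encoded with `confidence = 0` and are
#' ignored by all downstream operations.
#'
#' @param u,v Numeric vectors of length 18: horizontal and vertical pixel
#'   coordinates.
#' @param confidence Numeric vector of length 18 with scores in `[0, 1]`;
#'   a confidence of 0 marks the keypoint as absent.
#' @param frame_index Integer frame number the skeleton was observed in.
#' @param track_id Optional integer track identifier (`NA` if unassigned).
#' @param node_id Optional camera-node identifier for multi-node setups.
#' @return An object of class `skeleton`: a list with a `kp` matrix
#'   (columns `u`, `v`, `confidence`) and metadata fields.
#' @export
skeleton <- function(u, v, confidence = rep(1, 18), frame_index = 0L,
                     track_id = NA_integer_, node_id = "node0") {
  stopifnot(length(u) == 18L, length(v) == 18L, length(confidence) == 18L)
  if (any(confidence < 0 | confidence > 1, na.rm = TRUE)) {
    stop("keypoint confidences must lie in [0, 1]")
  }
  kp <- cbind(u = as.numeric(u), v = as.numeric(v),
              confidence = as.numeric(confidence))
  rownames(kp) <- coco18_names
  structure(
    list(kp = kp, frame_index = as.integer(frame_index),
         track_id = as.integer(track_id), node_id = node_id),
    class = "skeleton"
  )
}

#' @export
print.skeleton <- function(x, ...) {
  npres <- sum(x$kp[, "confidence"] > 0)
  cat(sprintf("<skeleton> frame %d, node %s, %d/18 keypoints present\n",
              x$frame_index, x$node_id, npres))
  invisible(x)
}

# is keypoint (zero-based index) present?
kp_present <- function(skel, idx0) {
  skel$kp[idx0 + 1L, "confidence"] > 0
}

# keypoint (u, v) by zero-based index
kp_uv <- function(skel, idx0) {
  skel$kp[idx0 + 1L, c("u", "v")]
}

kp_conf <- function(skel, idx0) {
  skel$kp[idx0 + 1L, "confidence"]
}

# fail loudly naming the missing slots, per the missing-keypoint policy
require_keypoints <- function(skel, idx0) {
  missing <- idx0[!vapply(idx0, function(i) kp_present(skel, i), logical(1))]
  if (length(missing)) {
    stop(sprintf("insufficient keypoints: missing indices %s (%s)",
                 paste(missing, collapse = ", "),
                 paste(coco18_names[missing + 1L], collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}
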