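#' Bounding box (center parametrization)
#'
#' @param cx,cy Center in pixels.
#' @param w,h Width and height in pixels (> 0).
#' @return Named numeric vector of class `bbox`.
#' @export
bbox <- function(cx, cy, w, h) {
  stopifnot(w > 0, h > 0)
  structure(c(cx = cx, cy = cy, w = w, h = h), class = "bbox")
}

#' Intersection-over-union of two boxes
#' @param b1,b2 [bbox()] objects.
#' @return IoU in `[0, 1]`.
#' @export
bbox_iou <- function(b1, b2) {
  ix <- max(0, min(b1["cx"] + b1["w"] / 2, b2["cx"] + b2["w"] / 2) -
               max(b1["cx"] - b1["w"] / 2, b2["cx"] - b2["w"] / 2))
  iy <- max(0, min(b1["cy"] + b1["h"] / 2, b2["cy"] + b2["h"] / 2) -
               max(b1["cy"] - b1["h"] / 2, b2["cy"] - b2["h"] / 2))
  inter <- ix * iy
  uni <- b1[["w"]] * b1[["h"]] + b2[["w"]] * b2[["h"]] - inter
  unname(inter / uni)
}

# extract a box's pixel patch from a grayscale frame matrix, clipped to the
# frame bounds; image rows index v, columns index u
extract_patch <- function(frame, box) {
  r0 <- max(1L, floor(box[["cy"]] - box[["h"]] / 2) + 1L)
  r1 <- min(nrow(frame), ceiling(box[["cy"]] + box[["h"]] / 2))
  c0 <- max(1L, floor(box[["cx"]] - box[["w"]] / 2) + 1L)
  c1 <- min(ncol(frame), ceiling(box[["cx"]] + box[["w"]] / 2))
  if (r1 < r0 || c1 < c0) {
    stop("hash failure: box lies outside the frame", call. = FALSE)
  }
  frame[r0:r1, c0:c1, drop = FALSE]
}

#' Default tracker configuration
#'
#' @param match_threshold Minimum dhash similarity for a candidate to be
#'   accepted as the re-acquired object.
#' @param max_coast Frames without a detector hit or hash match before the
#'   track is declared lost.
#' @param n_candidates Number of candidate regions (laid out on a square
#'   grid; 25 gives 5x5).
#' @param spread_floor_px Minimum half-extent of the candidate grid.
#' @param init_iou_floor Minimum IoU between the two initializing
#'   detections.
#' @param init_P Diagonal of the initial covariance.
#' @param refresh_hash_on_match Whether a hash-matched candidate also
#'   refreshes the reference hash (default FALSE: refresh only on detector
#'   frames, to avoid appearance drift).
#' @return List of tracker settings.
#' @export
tracker_config <- function(match_threshold = 0.80, max_coast = 30L,
                           n_candidates = 25L, spread_floor_px = 8,
                           init_iou_floor = 0.1,
                           init_P = c(10, 10, 10, 10, 25, 25),
                           refresh_hash_on_match = FALSE) {
  list(match_threshold = match_threshold, max_coast = as.integer(max_coast),
       n_candidates = as.integer(n_candidates),
       spread_floor_px = spread_floor_px, init_iou_floor = init_iou_floor,
       init_P = init_P, refresh_hash_on_match = refresh_hash_on_match)
}

#' Initialize a track from two consecutive detections
#'
#' The first two detection frames seed the tracker: position and size from
#' the second detection, velocity from the finite difference of the two
#' centers, the reference appearance hash from the second detection's
#' patch.
#'
#' @param det1,det2 [bbox()] detections in consecutive frames.
#' @param frame2 Grayscale frame matrix of the second detection (or `NULL`
#'   to skip hashing, e.g. in keypoint-only replay).
#' @param m An [ekf_model()].
#' @param cfg A [tracker_config()].
#' @return A [track_state()] with status `"tracking"`.
#' @export
init_track <- function(det1, det2, frame2 = NULL, m = constant_velocity_model(),
                       cfg = tracker_config()) {
  if (bbox_iou(det1, det2) < cfg$init_iou_floor) {
    stop(sprintf("init rejected: detection IoU %.3f below floor %.2f",
                 bbox_iou(det1, det2), cfg$init_iou_floor), call. = FALSE)
  }
  x <- c(det2[["cx"]], det2[["cy"]], det2[["w"]], det2[["h"]],
         det2[["cx"]] - det1[["cx"]], det2[["cy"]] - det1[["cy"]])
  ref <- if (!is.null(frame2)) dhash(extract_patch(frame2, det2)) else NULL
  track_state(x, diag(cfg$init_P), ref_hash = ref, status = "tracking")
}

#' Generate candidate regions around the predicted state
#'
#' A deterministic square grid of boxes with the prior's size, spanning
#' +/- `spread` pixels around the predicted center; the prior center is
#' always candidate 1. The default spread is twice the prediction's
#' position standard deviation, floored at `spread_floor_px`.
#'
#' @param prior A [track_state()] after [ekf_predict()].
#' @param n Number of candidates (a perfect square gives a full grid).
#' @param spread Half-extent of the grid in pixels, or `NULL` for the
#'   uncertainty-scaled default.
#' @param cfg A [tracker_config()].
#' @return List of candidates, each `list(box, hash = NULL, similarity = NA)`.
#' @export
generate_candidates <- function(prior, n = NULL, spread = NULL,
                                cfg = tracker_config()) {
  if (prior$status == "lost") stop("cannot seed candidates from a lost track",
                                   call. = FALSE)
  if (is.null(n)) n <- cfg$n_candidates
  if (is.null(spread)) {
    pos_sd <- sqrt(max(prior$P[1, 1], prior$P[2, 2], 0))
    spread <- max(cfg$spread_floor_px, 2 * pos_sd)
  }
  ctr <- prior$x[1:2]
  sz <- prior$x[3:4]
  if (n <= 1) {
    return(list(list(box = bbox(ctr[1], ctr[2], sz[1], sz[2]),
                     hash = NULL, similarity = NA_real_)))
  }
  g <- ceiling(sqrt(n))
  offs <- seq(-spread, spread, length.out = g)
  grid <- expand.grid(du = offs, dv = offs)
  # exact prior center first, then the remaining grid points in row-major
  # order (for odd grids the central cell is the prior center itself)
  ctr_i <- which.min(grid$du^2 + grid$dv^2)
  grid <- grid[c(ctr_i, setdiff(seq_len(nrow(grid)), ctr_i)), , drop = FALSE]
  grid[1, ] <- c(0, 0)
  grid <- grid[seq_len(min(n, nrow(grid))), , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    list(box = bbox(ctr[1] + grid$du[i], ctr[2] + grid$dv[i], sz[1], sz[2]),
         hash = NULL, similarity = NA_real_)
  })
}

#' Match candidate regions against the reference appearance hash
#'
#' Scores every candidate by `1 - hamming(dhash(patch), ref)/64` and
#' returns the best-scoring one iff its similarity reaches the threshold;
#' ties are broken by distance to the prior center, then by candidate
#' order. All choices are deterministic.
#'
#' @param frame Grayscale frame matrix.
#' @param cands Candidates from [generate_candidates()].
#' @param ref_hash Reference `dhash64`.
#' @param threshold Minimum similarity to accept.
#' @param prior_center Length-2 center used for tie-breaking (defaults to
#'   candidate 1's center).
#' @return The winning candidate (with `hash` and `similarity` filled in),
#'   or `NULL` on match failure (the tracker must then wait for the
#'   detector).
#' @export
match_candidates <- function(frame, cands, ref_hash, threshold = 0.80,
                             prior_center = NULL) {
  stopifnot(length(cands) >= 1)
  if (is.null(prior_center)) {
    prior_center <- cands[[1]]$box[c("cx", "cy")]
  }
  scored <- lapply(cands, function(cand) {
    cand$hash <- tryCatch(dhash(extract_patch(frame, cand$box)),
                          error = function(e) NULL)
    cand$similarity <- if (is.null(cand$hash)) -Inf else
      hash_similarity(cand$hash, ref_hash)
    cand
  })
  sims <- vapply(scored, function(cand) cand$similarity, numeric(1))
  dists <- vapply(scored, function(cand) {
    sqrt(sum((cand$box[c("cx", "cy")] - prior_center)^2))
  }, numeric(1))
  best <- order(-sims, dists, seq_along(scored))[1]
  if (!is.finite(sims[best]) || sims[best] < threshold) return(NULL)
  scored[[best]]
}

#' One step of the tracking control loop
#'
#' With a detection: EKF predict, update with the detection, refresh the
#' reference hash from the detection patch. Without one: predict, lay out
#' candidate regions, hash-match them against the reference; a match is
#' used as the observation, a failure coasts on the prior and increments
#' `frames_since_detection`, and after `cfg$max_coast` unmatched frames the
#' track is declared lost (and emits nothing).
#'
#' @param frame Grayscale frame matrix, or `NULL` if no imagery is
#'   available (coast on prediction alone during dropouts).
#' @param detection A [bbox()] or `NULL` for a detector-failure frame.
#' @param ts A [track_state()].
#' @param m An [ekf_model()].
#' @param cfg A [tracker_config()].
#' @return List with `state` (updated [track_state()]), `box` (emitted
#'   [bbox()] or `NULL` once lost), and `source`
#'   (`"detector"`, `"tracker"`, or `"coast"`).
#' @export
track_step <- function(frame, detection, ts, m = constant_velocity_model(),
                       cfg = tracker_config()) {
  if (ts$status == "lost") {
    return(list(state = ts, box = NULL, source = "lost"))
  }
  prior <- ekf_predict(ts, m)
  if (!is.null(detection)) {
    post <- ekf_update(prior, detection, m)
    if (!is.null(frame)) {
      post$ref_hash <- dhash(extract_patch(frame, detection))
    }
    post$status <- "tracking"
    return(list(state = post, box = state_box(post), source = "detector"))
  }
  matched <- NULL
  if (!is.null(frame) && !is.null(prior$ref_hash)) {
    cands <- generate_candidates(prior, cfg = cfg)
    matched <- match_candidates(frame, cands, prior$ref_hash,
                                threshold = cfg$match_threshold)
  }
  if (!is.null(matched)) {
    post <- ekf_update(prior, matched$box, m)
    if (cfg$refresh_hash_on_match) {
      post$ref_hash <- matched$hash
    }
    post$status <- "tracking"
    return(list(state = post, box = state_box(post), source = "tracker"))
  }
  prior$frames_since_detection <- ts$frames_since_detection + 1L
  if (prior$frames_since_detection >= cfg$max_coast) {
    prior$status <- "lost"
    return(list(state = prior, box = NULL, source = "lost"))
  }
  list(state = prior, box = state_box(prior), source = "coast")
}

state_box <- function(ts) {
  bbox(ts$x[1], ts$x[2], max(ts$x[3], 1e-6), max(ts$x[4], 1e-6))
}
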