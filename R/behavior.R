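#' Posture classification thresholds
#'
#' @param tilt_angle_deg Head-tilt trigger: a corrected neck angle (either
#'   side) below this raises `head_tilt`. An upright frontal posture sits
#'   near 90 degrees, so 65 leaves a wide normal band.
#' @param drop_ratio Dropped-head trigger: a corrected neck-to-nose /
#'   neck-to-shoulder length ratio below this raises `dropped_head`
#'   (upright postures sit near 0.85-1.0 under the default template).
#' @param min_duration_s Persistence required before an abnormal run
#'   becomes an event ("long-term" behaviour).
#' @param release_hysteresis Fraction of `min_duration_s` of contrary
#'   frames needed to close an open event.
#' @return List of class `thresholds`.
#' @export
thresholds <- function(tilt_angle_deg = 65, drop_ratio = 0.70,
                       min_duration_s = 3.0, release_hysteresis = 0.1) {
  stopifnot(tilt_angle_deg > 0, tilt_angle_deg < 90, drop_ratio > 0,
            min_duration_s >= 0, release_hysteresis >= 0)
  structure(list(tilt_angle_deg = tilt_angle_deg, drop_ratio = drop_ratio,
                 min_duration_s = min_duration_s,
                 release_hysteresis = release_hysteresis),
            class = "thresholds")
}

#' Classify the posture of a single skeleton
#'
#' Computes the yaw-corrected neck angles on both sides and the corrected
#' dropped-head ratio, then applies the decision rule: `dropped_head` iff
#' the ratio falls below `drop_ratio` (this takes precedence), else
#' `head_tilt` iff the smaller neck angle falls below `tilt_angle_deg`,
#' else `normal`. Geometry failures yield `indeterminate` with the reason
#' recorded, never an error.
#'
#' @param skel A [skeleton()].
#' @param yaw A `yaw_estimate`, a number of degrees, or `NULL` to estimate
#'   internally via [estimate_yaw()].
#' @param th A [thresholds()].
#' @param cam Optional [camera_model()] (improves the correction and
#'   enables PnP yaw).
#' @param tmpl A [pose_template_3d()].
#' @param mode Correction mode, see [yaw_correct_vectors()].
#' @param ratio_side Side rule for the dropped-head ratio (default
#'   `"both"`: mean of the two shoulder lengths).
#' @return List of class `posture_result`: `label`, `w_left`, `w_right`,
#'   `ratio`, `yaw_deg`, `reason`.
#' @export
classify_frame <- function(skel, yaw = NULL, th = thresholds(), cam = NULL,
                           tmpl = pose_template_3d(),
                           mode = c("inverse", "as_printed"),
                           ratio_side = "both") {
  mode <- match.arg(mode)
  res <- list(label = "indeterminate", w_left = NA_real_, w_right = NA_real_,
              ratio = NA_real_,
              yaw_deg = NA_real_, reason = NA_character_)
  class(res) <- "posture_result"
  out <- tryCatch({
    if (is.null(yaw)) yaw <- estimate_yaw(skel, cam = cam, tmpl = tmpl)
    phi <- if (inherits(yaw, "yaw_estimate")) yaw$phi_deg else as.numeric(yaw)
    nv <- yaw_correct_vectors(skel, phi, mode = mode, cam = cam, tmpl = tmpl)
    res$yaw_deg <- phi
    res$ratio <- dropped_head_ratio(nv, side = ratio_side)
    res$w_left <- if (!is.null(nv$b_left) && !nv$degenerate_a) {
      neck_angle(nv$a, nv$b_left)
    } else NA_real_
    res$w_right <- if (!is.null(nv$b_right) && !nv$degenerate_a) {
      neck_angle(nv$a, nv$b_right)
    } else NA_real_
    if (res$ratio < th$drop_ratio) {
      res$label <- "dropped_head"
    } else {
      wmin <- suppressWarnings(min(res$w_left, res$w_right, na.rm = TRUE))
      if (!is.finite(wmin)) {
        res$label <- "indeterminate"
        res$reason <- "degenerate head vector"
      } else if (wmin < th$tilt_angle_deg) {
        res$label <- "head_tilt"
      } else {
        res$label <- "normal"
      }
    }
    res
  }, error = function(e) {
    res$reason <- conditionMessage(e)
    res
  })
  out
}

#' @export
print.posture_result <- function(x, ...) {
  cat(sprintf("<posture_result> %s (w_l %.1f, w_r %.1f, ratio %.2f, yaw %.1f)\n",
              x$label, x$w_left, x$w_right, x$ratio, x$yaw_deg))
  invisible(x)
}

ABNORMAL_LABELS <- c("head_tilt", "dropped_head")

#' Turn a per-frame posture stream into persistent behaviour events
#'
#' A run of at least `ceil(min_duration_s * fps)` consecutive frames with
#' the same abnormal label opens an event; it closes after
#' `ceil(release_hysteresis * min_duration_s * fps)` consecutive frames of
#' a different label (minimum 1). Isolated `indeterminate` frames (up to a
#' 2-frame gap) neither extend nor break a run; longer indeterminate gaps
#' break it.
#'
#' @param postures Data frame with columns `frame` (monotone increasing)
#'   and `label`, for a single track.
#' @param fps Frames per second of the stream.
#' @param th A [thresholds()].
#' @param track_id,node_id Provenance recorded on the events.
#' @return Data frame of events: `label`, `track_id`, `node_id`,
#'   `start_frame`, `end_frame`, `duration_s`.
#' @export
update_events <- function(postures, fps = 30, th = thresholds(),
                          track_id = NA_integer_, node_id = "node0") {
  if (nrow(postures) && is.unsorted(postures$frame, strictly = TRUE)) {
    stop("stream-order failure: frame indices must be strictly increasing",
         call. = FALSE)
  }
  min_frames <- ceiling(th$min_duration_s * fps)
  release_frames <- max(1L, ceiling(th$release_hysteresis *
                                      th$min_duration_s * fps))
  gap_tolerance <- 2L

  events <- list()
  run_label <- NULL; run_start <- NA_integer_; run_end <- NA_integer_
  open <- FALSE
  contrary <- 0L; indet_gap <- 0L

  close_run <- function() {
    if (!is.null(run_label) && open) {
      dur <- (run_end - run_start + 1) / fps
      events[[length(events) + 1L]] <<- data.frame(
        label = run_label, track_id = track_id, node_id = node_id,
        start_frame = run_start, end_frame = run_end, duration_s = dur,
        stringsAsFactors = FALSE)
    }
    run_label <<- NULL; open <<- FALSE; contrary <<- 0L; indet_gap <<- 0L
  }

  for (i in seq_len(nrow(postures))) {
    lab <- postures$label[i]
    frm <- postures$frame[i]
    if (identical(lab, "indeterminate")) {
      if (!is.null(run_label)) {
        indet_gap <- indet_gap + 1L
        if (indet_gap > gap_tolerance) close_run()
      }
      next
    }
    indet_gap <- 0L
    if (!is.null(run_label) && lab == run_label) {
      run_end <- frm
      contrary <- 0L
      if (!open && frm - run_start + 1 >= min_frames) open <- TRUE
      next
    }
    # a different concrete label
    if (!is.null(run_label)) {
      contrary <- contrary + 1L
      if (contrary >= release_frames || !open) close_run()
    }
    if (is.null(run_label) && lab %in% ABNORMAL_LABELS) {
      run_label <- lab; run_start <- frm; run_end <- frm
      open <- frm - run_start + 1 >= min_frames
      contrary <- 0L; indet_gap <- 0L
    }
  }
  close_run()
  if (!length(events)) {
    return(data.frame(label = character(), track_id = integer(),
                      node_id = character(), start_frame = integer(),
                      end_frame = integer(), duration_s = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, events)
}

#' Fuse per-node posture labels into one decision
#'
#' Majority vote over the node labels for one frame window. Ties that
#' involve an abnormal label resolve to that abnormal label (safety bias);
#' a tie between the two abnormal labels resolves to `dropped_head`.
#'
#' @param labels Character vector of per-node labels (length >= 1).
#' @return A single label.
#' @export
fuse_nodes <- function(labels) {
  if (!length(labels)) stop("fusion failure: no node labels", call. = FALSE)
  counts <- table(factor(labels,
                         levels = c("normal", "head_tilt", "dropped_head",
                                    "indeterminate")))
  top <- max(counts)
  winners <- names(counts)[counts == top]
  if (length(winners) == 1L) return(winners)
  ab <- intersect(c("dropped_head", "head_tilt"), winners)
  if (length(ab)) return(ab[1])  # dropped_head preferred on abnormal ties
  winners[1]
}
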