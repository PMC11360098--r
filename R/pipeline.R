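#' Replay detector over a keypoint stream
#'
#' The detector interface of the pipeline: a function of a frame index
#' returning zero or more `(bbox, skeleton)` pairs. This implementation
#' replays a recorded keypoint JSON-lines stream deterministically; the
#' bounding box is the extent of the present keypoints, padded slightly.
#' A frame with no record is a no-detection frame.
#'
#' @param skels List of [skeleton()]s (e.g. from
#'   [read_keypoint_stream()]).
#' @param pad Fractional padding added to the keypoint extent box.
#' @return A function `detector(frame_index)` returning a list of
#'   `list(box, skeleton)` (possibly empty).
#' @export
replay_detector <- function(skels, pad = 0.15) {
  idx <- split(seq_along(skels),
               vapply(skels, function(s) s$frame_index, integer(1)))
  function(frame_index) {
    hits <- idx[[as.character(frame_index)]]
    if (is.null(hits)) return(list())
    lapply(hits, function(i) {
      sk <- skels[[i]]
      list(box = skeleton_bbox(sk, pad = pad), skeleton = sk)
    })
  }
}

#' Bounding box of a skeleton's present keypoints
#' @param skel A [skeleton()].
#' @param pad Fractional padding on each side.
#' @return A [bbox()].
#' @export
skeleton_bbox <- function(skel, pad = 0.15) {
  pres <- skel$kp[, "confidence"] > 0
  if (!any(pres)) stop("cannot box a skeleton with no keypoints", call. = FALSE)
  us <- skel$kp[pres, "u"]; vs <- skel$kp[pres, "v"]
  w <- max(diff(range(us)), 1) * (1 + 2 * pad)
  h <- max(diff(range(vs)), 1) * (1 + 2 * pad)
  bbox(mean(range(us)), mean(range(vs)), w, h)
}

#' Alert sink constructors
#'
#' A sink is a function taking one alert payload (a named list). The
#' payload body is the same for every transport:
#' `{timestamp_iso, node_id, track_id, label, duration_s, evidence}`.
#' `sink_collect` accumulates payloads in memory, `sink_jsonl` appends
#' them to a JSON-lines file, `sink_stdout` prints them.
#'
#' @param path File path for `sink_jsonl`.
#' @return A sink function; `sink_collect`'s has a `drain()` attribute
#'   returning the collected payloads.
#' @export
sink_jsonl <- function(path) {
  force(path)
  if (file.exists(path)) file.remove(path)
  function(payload) {
    cat(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), "\n",
        sep = "", file = path, append = TRUE)
  }
}

#' @rdname sink_jsonl
#' @export
sink_stdout <- function() {
  function(payload) {
    cat(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), "\n",
        sep = "")
  }
}

#' @rdname sink_jsonl
#' @export
sink_collect <- function() {
  env <- new.env()
  env$payloads <- list()
  f <- function(payload) {
    env$payloads[[length(env$payloads) + 1L]] <- payload
  }
  attr(f, "drain") <- function() env$payloads
  f
}

alert_payload <- function(event, cfg) {
  t0 <- as.POSIXct(cfg$epoch, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  ts <- t0 + event$start_frame / cfg$behavior$fps
  list(timestamp_iso = format(ts, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
       node_id = event$node_id, track_id = event$track_id,
       label = event$label, duration_s = event$duration_s,
       evidence = list(w_left = event$w_left, w_right = event$w_right,
                       ratio = event$ratio, yaw_deg = event$yaw_deg))
}

#' Run the full detection pipeline over a keypoint stream
#'
#' Per frame: replay the detector, advance the single-object tracker
#' (bridging detector dropouts), run the keypoint geometry and posture
#' classification, accumulate temporal events per node, fuse node labels
#' over the fusion window when several camera nodes are present, and emit
#' one alert per event through the sink. Deterministic for a fixed
#' config: rerunning yields identical outputs.
#'
#' @param skels List of [skeleton()]s in frame order (multi-node streams
#'   are distinguished by their `node_id`).
#' @param cfg A [pipeline_config()].
#' @param frames Optional list of grayscale frame matrices, indexed by
#'   frame number, enabling appearance matching during dropouts.
#' @param sink An alert sink (default [sink_collect()]).
#' @return List with `tracks`, `postures`, `events` (data frames),
#'   `alerts` (list of payloads), and `manifest` (config hash and seed).
#' @export
run_pipeline <- function(skels, cfg = pipeline_config(), frames = NULL,
                         sink = sink_collect()) {
  detector <- replay_detector(skels)
  cam <- cfg_camera(cfg)
  tmpl <- cfg_template(cfg)
  th <- cfg_thresholds(cfg)
  tcfg <- cfg_tracker(cfg)
  model <- cfg_model(cfg)

  frame_ids <- sort(unique(vapply(skels, function(s) s$frame_index,
                                  integer(1))))
  node_ids <- unique(vapply(skels, function(s) s$node_id, character(1)))

  tracks <- list(); postures <- list()
  tstate <- NULL; prev_det <- NULL
  for (fi in frame_ids) {
    dets <- detector(fi)
    frame_img <- if (!is.null(frames) && fi >= 1 && fi <= length(frames)) {
      frames[[fi]]
    } else NULL
    det_box <- if (length(dets)) dets[[1]]$box else NULL

    if (is.null(tstate)) {
      if (!is.null(det_box) && !is.null(prev_det)) {
        tstate <- tryCatch(
          init_track(prev_det, det_box, frame_img, model, tcfg),
          error = function(e) NULL)
      }
      if (!is.null(det_box)) prev_det <- det_box
    }
    if (!is.null(tstate) && tstate$status != "lost") {
      step <- track_step(frame_img, det_box, tstate, model, tcfg)
      tstate <- step$state
      if (!is.null(step$box)) {
        tracks[[length(tracks) + 1L]] <- data.frame(
          frame = fi, track_id = 1L,
          cx = step$box[["cx"]], cy = step$box[["cy"]],
          w = step$box[["w"]], h = step$box[["h"]],
          source = step$source, stringsAsFactors = FALSE)
      }
    }

    for (det in dets) {
      sk <- det$skeleton
      pr <- classify_frame(sk, yaw = NULL, th = th, cam = cam, tmpl = tmpl,
                           mode = cfg$geometry$correction_mode)
      postures[[length(postures) + 1L]] <- data.frame(
        frame = fi, node_id = sk$node_id, track_id = 1L,
        label = pr$label, w_left = pr$w_left, w_right = pr$w_right,
        ratio = pr$ratio, yaw_deg = pr$yaw_deg, stringsAsFactors = FALSE)
    }
  }

  tracks <- if (length(tracks)) do.call(rbind, tracks) else
    data.frame(frame = integer(), track_id = integer(), cx = numeric(),
               cy = numeric(), w = numeric(), h = numeric(),
               source = character(), stringsAsFactors = FALSE)
  postures <- if (length(postures)) do.call(rbind, postures) else
    data.frame(frame = integer(), node_id = character(),
               track_id = integer(), label = character(),
               w_left = numeric(), w_right = numeric(), ratio = numeric(),
               yaw_deg = numeric(), stringsAsFactors = FALSE)

  event_input <- if (length(node_ids) > 1L) {
    fuse_posture_stream(postures, cfg)
  } else {
    postures
  }
  events <- update_events(event_input[order(event_input$frame), ],
                          fps = cfg$behavior$fps, th = th,
                          track_id = 1L,
                          node_id = if (length(node_ids) > 1L) "fused"
                                    else node_ids[1] %||% "node0")
  events <- annotate_events(events, event_input)

  alerts <- list()
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      payload <- alert_payload(events[i, ], cfg)
      sink(payload)
      alerts[[length(alerts) + 1L]] <- payload
    }
  }

  manifest <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                   n_frames = length(frame_ids), n_nodes = length(node_ids))
  list(tracks = tracks, postures = postures, events = events,
       alerts = alerts, manifest = manifest)
}

# majority-fuse multi-node posture labels over the fusion window
fuse_posture_stream <- function(postures, cfg) {
  win <- max(1L, round(cfg$fusion$window_s * cfg$behavior$fps))
  postures$bucket <- postures$frame %/% win
  out <- lapply(split(postures, postures$bucket), function(df) {
    node_label <- vapply(split(df$label, df$node_id), function(labs) {
      tl <- table(labs)
      names(tl)[which.max(tl)]
    }, character(1))
    fused <- fuse_nodes(node_label)
    data.frame(frame = sort(unique(df$frame)), node_id = "fused",
               track_id = 1L, label = fused,
               w_left = stats::median(df$w_left, na.rm = TRUE),
               w_right = stats::median(df$w_right, na.rm = TRUE),
               ratio = stats::median(df$ratio, na.rm = TRUE),
               yaw_deg = stats::median(df$yaw_deg, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# attach representative evidence (medians over the event span) to events
annotate_events <- function(events, postures) {
  if (!nrow(events)) {
    events$w_left <- numeric(0); events$w_right <- numeric(0)
    events$ratio <- numeric(0); events$yaw_deg <- numeric(0)
    return(events)
  }
  ev <- lapply(seq_len(nrow(events)), function(i) {
    span <- postures$frame >= events$start_frame[i] &
      postures$frame <= events$end_frame[i]
    cbind(events[i, ],
          w_left = stats::median(postures$w_left[span], na.rm = TRUE),
          w_right = stats::median(postures$w_right[span], na.rm = TRUE),
          ratio = stats::median(postures$ratio[span], na.rm = TRUE),
          yaw_deg = stats::median(postures$yaw_deg[span], na.rm = TRUE))
  })
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

# stable md5 of the canonical JSON form of the config
config_hash <- function(cfg) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(js, tf)
  unname(tools::md5sum(tf))
}

#' Evaluate posture classification against ground truth
#'
#' Runs [classify_frame()] on every record of a labeled dataset, counts
#' the confusion per (yaw, distance) cell treating any abnormal label as
#' the positive class, and reports precision, recall and accuracy per cell
#' plus the unweighted mean row per distance.
#'
#' @param skels List of [skeleton()]s.
#' @param truth Data frame with `record_id`, `yaw_deg`, `distance_m`,
#'   `cell`, `label`, one row per skeleton (in order).
#' @param cfg A [pipeline_config()].
#' @return List with `cells` (per-cell metric data frame), `means`
#'   (per-distance mean rows), and `confusion` (per-cell counts).
#' @export
evaluate_dataset <- function(skels, truth, cfg = pipeline_config()) {
  if (length(skels) != nrow(truth)) {
    stop(sprintf("truth/record mismatch: %d records vs %d truth rows",
                 length(skels), nrow(truth)), call. = FALSE)
  }
  cam <- cfg_camera(cfg)
  tmpl <- cfg_template(cfg)
  th <- cfg_thresholds(cfg)
  pred <- vapply(skels, function(sk) {
    classify_frame(sk, yaw = NULL, th = th, cam = cam, tmpl = tmpl,
                   mode = cfg$geometry$correction_mode)$label
  }, character(1))
  truth$positive <- truth$label %in% ABNORMAL_LABELS
  truth$pred_positive <- pred %in% ABNORMAL_LABELS

  cells <- lapply(split(truth, truth$cell), function(df) {
    cc <- confusion_counts(
      TP = sum(df$positive & df$pred_positive),
      FP = sum(!df$positive & df$pred_positive),
      TN = sum(!df$positive & !df$pred_positive),
      FN = sum(df$positive & !df$pred_positive))
    m <- compute_metrics(cc)
    data.frame(cell = df$cell[1], yaw_deg = df$yaw_deg[1],
               distance_m = df$distance_m[1],
               recall = m[["recall"]], precision = m[["precision"]],
               accuracy = m[["accuracy"]],
               TP = cc[["TP"]], FP = cc[["FP"]], TN = cc[["TN"]],
               FN = cc[["FN"]], stringsAsFactors = FALSE)
  })
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  cells <- cells[order(cells$distance_m, abs(cells$yaw_deg),
                       -sign(cells$yaw_deg)), ]

  means <- lapply(split(cells, cells$distance_m), function(df) {
    agg <- aggregate_positions(df[, c("recall", "precision", "accuracy")])
    data.frame(distance_m = df$distance_m[1], recall = agg[["recall"]],
               precision = agg[["precision"]], accuracy = agg[["accuracy"]],
               stringsAsFactors = FALSE)
  })
  means <- do.call(rbind, means)
  rownames(means) <- NULL
  list(cells = cells, means = means)
}

#' Format an evaluation report as text
#' @param ev Result of [evaluate_dataset()].
#' @return Character vector of report lines.
#' @export
format_report <- function(ev) {
  lines <- c(sprintf("%-18s %8s %10s %9s", "cell", "recall", "precision",
                     "accuracy"))
  for (i in seq_len(nrow(ev$cells))) {
    r <- ev$cells[i, ]
    lines <- c(lines, sprintf("%-18s %8.2f %10.2f %9.2f", r$cell, r$recall,
                              r$precision, r$accuracy))
  }
  for (i in seq_len(nrow(ev$means))) {
    r <- ev$means[i, ]
    lines <- c(lines, sprintf("%-18s %8.2f %10.2f %9.2f",
                              sprintf("mean_d%.2f", r$distance_m),
                              r$recall, r$precision, r$accuracy))
  }
  lines
}
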