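#' Write skeletons as a keypoint JSON-lines stream
#'
#' One JSON object per line:
#' `{"frame": i, "node_id": "...", "track_hint": t, "keypoints": [[u,v,conf] x 18]}`.
#' Absent keypoints are encoded with confidence 0.
#'
#' @param skels List of [skeleton()]s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_keypoint_stream <- function(skels, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sk in skels) {
    obj <- list(frame = sk$frame_index, node_id = sk$node_id,
                keypoints = lapply(seq_len(18), function(i) {
                  as.numeric(sk$kp[i, c("u", "v", "confidence")])
                }))
    if (!is.na(sk$track_id)) obj$track_hint <- sk$track_id
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a keypoint JSON-lines stream into skeletons
#'
#' The inverse of [write_keypoint_stream()]; `write` then `read` is the
#' identity on valid files. A line whose `keypoints` array does not have
#' exactly 18 entries of 3 numbers raises an error naming the line.
#'
#' @param path Input file path.
#' @return List of [skeleton()]s (empty list for an empty file).
#' @export
read_keypoint_stream <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) {
                      stop(sprintf("line %d: malformed JSON (%s)", i,
                                   conditionMessage(e)), call. = FALSE)
                    })
    kps <- obj$keypoints
    if (length(kps) != 18L) {
      stop(sprintf("line %d: schema error, expected 18 keypoints, got %d",
                   i, length(kps)), call. = FALSE)
    }
    bad <- which(vapply(kps, length, integer(1)) != 3L)
    if (length(bad)) {
      stop(sprintf("line %d: schema error, keypoint %d is not [u, v, conf]",
                   i, bad[1]), call. = FALSE)
    }
    m <- do.call(rbind, lapply(kps, as.numeric))
    skeleton(m[, 1], m[, 2], m[, 3],
             frame_index = obj$frame %||% 0L,
             track_id = obj$track_hint %||% NA_integer_,
             node_id = obj$node_id %||% "node0")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default pipeline configuration
#'
#' All tunables of the camera, geometry, tracker and behaviour stages in
#' one validated list. Values can be overridden programmatically or loaded
#' from a JSON/YAML file with [load_config()].
#'
#' @param ... Named overrides of the defaults, using dotted paths for
#'   nesting (e.g. `behavior = list(fps = 25)` replaces only `fps`).
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    camera = list(focal_px = 800, cx = 640, cy = 540),
    geometry = list(correction_mode = "inverse",
                    template = list(shoulder_span = 0.38, neck_nose = 0.16,
                                    nose_depth = 0.10, hip_width = 0.26,
                                    hip_drop = 0.45)),
    tracker = list(match_threshold = 0.80, max_coast = 30, n_candidates = 25,
                   spread_floor_px = 8, init_iou_floor = 0.1,
                   Q = c(1, 1, 0.25, 0.25, 4, 4), R = c(4, 4, 4, 4)),
    behavior = list(tilt_angle_deg = 65, drop_ratio = 0.70,
                    min_duration_s = 3.0, release_hysteresis = 0.1,
                    fps = 30),
    fusion = list(window_s = 1.0),
    seed = 1L,
    epoch = "2024-01-01T00:00:00Z"
  )
  cfg <- merge_config(cfg, list(...))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  check <- function(ok, what) {
    if (!ok) stop(sprintf("invalid config: %s", what), call. = FALSE)
  }
  check(cfg$camera$focal_px > 0, "camera.focal_px must be > 0")
  check(cfg$geometry$correction_mode %in% c("inverse", "as_printed"),
        "geometry.correction_mode must be 'inverse' or 'as_printed'")
  check(cfg$behavior$tilt_angle_deg > 0 && cfg$behavior$tilt_angle_deg < 90,
        "behavior.tilt_angle_deg must be in (0, 90)")
  check(cfg$behavior$drop_ratio > 0, "behavior.drop_ratio must be > 0")
  check(cfg$behavior$min_duration_s >= 0,
        "behavior.min_duration_s must be >= 0")
  check(cfg$behavior$fps > 0, "behavior.fps must be > 0")
  check(length(cfg$tracker$Q) == 6, "tracker.Q must have 6 diagonal entries")
  check(length(cfg$tracker$R) == 4, "tracker.R must have 4 diagonal entries")
  check(cfg$fusion$window_s > 0, "fusion.window_s must be > 0")
  invisible(cfg)
}

#' Load a pipeline configuration from JSON or YAML
#'
#' @param path A `.json`, `.yaml` or `.yml` file whose keys override the
#'   defaults of [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, raw)
}

# derived helper objects from a config
cfg_camera <- function(cfg) {
  camera_model(cfg$camera$focal_px, cfg$camera$cx, cfg$camera$cy)
}
cfg_template <- function(cfg) {
  do.call(pose_template_3d, cfg$geometry$template)
}
cfg_thresholds <- function(cfg) {
  thresholds(cfg$behavior$tilt_angle_deg, cfg$behavior$drop_ratio,
             cfg$behavior$min_duration_s, cfg$behavior$release_hysteresis)
}
cfg_tracker <- function(cfg) {
  tracker_config(match_threshold = cfg$tracker$match_threshold,
                 max_coast = cfg$tracker$max_coast,
                 n_candidates = cfg$tracker$n_candidates,
                 spread_floor_px = cfg$tracker$spread_floor_px,
                 init_iou_floor = cfg$tracker$init_iou_floor)
}
cfg_model <- function(cfg) {
  constant_velocity_model(Q = diag(cfg$tracker$Q), R = diag(cfg$tracker$R))
}
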