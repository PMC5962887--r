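# Reading and writing pose-keypoint sequences and the tabular study inputs.
#
# Two keypoint dialects are supported:
#   * per_frame_json: {"video_id": ..., "fps": ..., "frames": [
#       {"frame": 0, "joints": {"nose": {"x":..,"y":..,"confidence":..}, ...}}, ...]}
#   * flat_csv: columns video_id, frame, joint, x, y, confidence
# Image coordinate convention throughout: x to the viewer's right, y increases
# DOWNWARD (standard image axes).

#' Joint names consumed by the pipeline
#'
#' The eight upper-body joints required (when present) in a pose sequence.
#' @export
POSE_JOINTS <- c("nose", "neck", "left_shoulder", "right_shoulder",
                 "left_elbow", "left_wrist", "right_elbow", "right_wrist")

#' Construct a frame-indexed pose sequence
#'
#' A `frame_pose_sequence` holds per-frame 2D joint coordinates with detection
#' confidences for one video. A joint with confidence 0 (or below the reader's
#' confidence floor) counts as not detected.
#'
#' @param video_id video identifier.
#' @param keypoints data frame with columns `frame`, `joint`, `x`, `y`,
#'   `confidence`, one row per detected-or-not joint observation.
#' @param fps optional frames/second, metadata only.
#' @return object of class `frame_pose_sequence`.
#' @export
frame_pose_sequence <- function(video_id, keypoints, fps = NULL) {
  req <- c("frame", "joint", "x", "y", "confidence")
  abort_if(!all(req %in% names(keypoints)),
           "keypoints must have columns: %s", paste(req, collapse = ", "))
  kp <- as.data.frame(keypoints)[req]
  kp$frame <- as.integer(kp$frame)
  kp$joint <- as.character(kp$joint)
  det <- kp$confidence > 0
  abort_if(any(!is.finite(kp$x[det])) || any(!is.finite(kp$y[det])),
           "non-finite coordinates for detected joints in video '%s'", video_id)
  abort_if(any(kp$confidence < 0 | kp$confidence > 1, na.rm = TRUE),
           "confidence outside [0,1] in video '%s'", video_id)
  kp <- kp[order(kp$frame, match(kp$joint, POSE_JOINTS)), , drop = FALSE]
  rownames(kp) <- NULL
  structure(list(video_id = as.character(video_id),
                 keypoints = kp,
                 frames = sort(unique(kp$frame)),
                 fps = fps),
            class = "frame_pose_sequence")
}

#' @export
print.frame_pose_sequence <- function(x, ...) {
  cat(sprintf("<frame_pose_sequence> video '%s': %d frames, %d joint records\n",
              x$video_id, length(x$frames), nrow(x$keypoints)))
  invisible(x)
}

#' Per-frame coordinates of one joint
#'
#' @param seq a `frame_pose_sequence`.
#' @param joint joint name.
#' @return list with `xy` (n x 2 matrix, NA where undetected) and `detected`
#'   (logical vector), aligned with `seq$frames`.
#' @export
joint_track <- function(seq, joint) {
  kp <- seq$keypoints[seq$keypoints$joint == joint, , drop = FALSE]
  n <- length(seq$frames)
  xy <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
  detected <- logical(n)
  if (nrow(kp)) {
    i <- match(kp$frame, seq$frames)
    ok <- kp$confidence > 0
    xy[i[ok], 1] <- kp$x[ok]
    xy[i[ok], 2] <- kp$y[ok]
    detected[i[ok]] <- TRUE
  }
  list(xy = xy, detected = detected)
}

#' Read a pose-keypoint file
#'
#' Joints whose confidence falls below `conf_floor` are marked not detected
#' (confidence set to 0). Frames listed out of order are sorted with a
#' warning; unknown joint names are dropped with a warning.
#'
#' @param path file path.
#' @param schema `"auto"` (by extension), `"per_frame_json"` or `"flat_csv"`.
#' @param conf_floor detection threshold on confidence, default 0.1. The
#'   original study does not state its threshold, so it is configuration here.
#' @return a [frame_pose_sequence()].
#' @export
read_keypoints <- function(path, schema = c("auto", "per_frame_json", "flat_csv"),
                           conf_floor = 0.1) {
  schema <- match.arg(schema)
  abort_if(!file.exists(path), "keypoint file not found: %s", path)
  if (schema == "auto") {
    schema <- if (grepl("\\.json$", path, ignore.case = TRUE)) "per_frame_json" else "flat_csv"
  }
  if (schema == "per_frame_json") {
    obj <- tryCatch(jsonlite::read_json(path),
                    error = function(e) stop(sprintf(
                      "malformed keypoint JSON '%s': %s", path, conditionMessage(e)),
                      call. = FALSE))
    frames <- obj$frames
    abort_if(is.null(frames), "keypoint JSON '%s' has no 'frames' array", path)
    rows <- vector("list", length(frames))
    for (k in seq_along(frames)) {
      fr <- frames[[k]]
      if (is.null(fr$frame) || is.null(fr$joints)) {
        stop(sprintf("malformed keypoint JSON '%s' at frame entry %d", path, k),
             call. = FALSE)
      }
      jn <- names(fr$joints)
      rows[[k]] <- data.frame(
        frame = as.integer(fr$frame),
        joint = jn,
        x = vapply(fr$joints, function(j) as.numeric(j$x %||% NA_real_), 0),
        y = vapply(fr$joints, function(j) as.numeric(j$y %||% NA_real_), 0),
        confidence = vapply(fr$joints, function(j) as.numeric(j$confidence %||% 0), 0),
        stringsAsFactors = FALSE)
    }
    kp <- do.call(rbind, rows)
    video_id <- obj$video_id %||% sub("\\.json$", "", basename(path))
    fps <- obj$fps
  } else {
    kp <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) stop(sprintf(
                     "malformed keypoint CSV '%s': %s", path, conditionMessage(e)),
                     call. = FALSE))
    req <- c("video_id", "frame", "joint", "x", "y", "confidence")
    abort_if(!all(req %in% names(kp)),
             "keypoint CSV '%s' must have columns: %s", path, paste(req, collapse = ", "))
    video_id <- unique(kp$video_id)
    abort_if(length(video_id) != 1, "keypoint CSV '%s' holds %d videos, expected 1",
             path, length(video_id))
    fps <- NULL
  }
  unknown <- setdiff(unique(kp$joint), POSE_JOINTS)
  if (length(unknown)) {
    warning(sprintf("ignoring unknown joints in '%s': %s",
                    path, paste(unknown, collapse = ", ")), call. = FALSE)
    kp <- kp[kp$joint %in% POSE_JOINTS, , drop = FALSE]
  }
  if (is.unsorted(kp$frame)) {
    warning(sprintf("frames in '%s' listed out of order; sorted by index", path),
            call. = FALSE)
  }
  # below-floor detections become not-detected
  kp$confidence[kp$confidence < conf_floor] <- 0
  frame_pose_sequence(video_id, kp, fps = fps)
}

#' Write a pose-keypoint sequence
#'
#' @param seq a [frame_pose_sequence()].
#' @param path output path; dialect chosen from `schema`.
#' @param schema `"per_frame_json"` or `"flat_csv"`.
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(seq, path, schema = c("per_frame_json", "flat_csv")) {
  schema <- match.arg(schema)
  kp <- seq$keypoints
  if (schema == "flat_csv") {
    out <- data.frame(video_id = seq$video_id, frame = kp$frame, joint = kp$joint,
                      x = fmt_num(kp$x), y = fmt_num(kp$y),
                      confidence = fmt_num(kp$confidence))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    frames <- lapply(split(kp, kp$frame), function(d) {
      joints <- lapply(seq_len(nrow(d)), function(i) {
        list(x = d$x[i], y = d$y[i], confidence = d$confidence[i])
      })
      names(joints) <- d$joint
      list(frame = d$frame[1], joints = joints)
    })
    names(frames) <- NULL
    obj <- list(video_id = seq$video_id, frames = frames)
    if (!is.null(seq$fps)) obj$fps <- seq$fps
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a normalized sign trajectory to CSV
#'
#' Round-trips through [read_trajectory()] to better than 1e-9 per coordinate
#' (coordinates are serialized with 17 significant digits).
#'
#' @param traj a [sign_trajectory()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "sign_trajectory"))
  n <- traj$n_frames
  out <- data.frame(
    video_id = rep(traj$video_id, 2L * n),
    concept_id = rep(traj$concept_id %||% "", 2L * n),
    language = rep(traj$language %||% "", 2L * n),
    frame = rep(traj$frame, 2L),
    hand = rep(c("left", "right"), each = n),
    x = fmt_num(c(traj$left[, 1], traj$right[, 1])),
    y = fmt_num(c(traj$left[, 2], traj$right[, 2])),
    detected = c(traj$left_detected, traj$right_detected),
    stringsAsFactors = FALSE)
  if (n == 0L) out <- out[0, , drop = FALSE]
  ok <- tryCatch({utils::write.csv(out, path, row.names = FALSE, quote = FALSE); TRUE},
                 error = function(e) FALSE)
  abort_if(!ok, "cannot write trajectory to '%s'", path)
  invisible(path)
}

#' Read a normalized sign trajectory written by [write_trajectory()]
#'
#' @param path CSV path.
#' @return a [sign_trajectory()].
#' @export
read_trajectory <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(x = "numeric", y = "numeric"))
  if (nrow(d) == 0L) {
    return(sign_trajectory(video_id = "", concept_id = "", language = "",
                           frame = integer(0),
                           left = matrix(numeric(0), 0, 2),
                           right = matrix(numeric(0), 0, 2),
                           left_detected = logical(0), right_detected = logical(0)))
  }
  dl <- d[d$hand == "left", , drop = FALSE]
  dr <- d[d$hand == "right", , drop = FALSE]
  sign_trajectory(video_id = d$video_id[1], concept_id = d$concept_id[1],
                  language = d$language[1], frame = dl$frame,
                  left = cbind(dl$x, dl$y), right = cbind(dr$x, dr$y),
                  left_detected = as.logical(dl$detected),
                  right_detected = as.logical(dr$detected))
}

#' Read and validate the tabular study inputs
#'
#' Expected headers:
#' * `concepts.csv`: concept_id, english_name, category, is_single_english_word,
#'   in_swadesh_core
#' * `ratings.csv`: concept_id, rater_id, rating (integer 1-7)
#' * `frequencies.csv`: concept_id, log_frequency
#' * `location_ratings.csv`: concept_id, rater_id, x_min, x_max, y_min, y_max
#'   (normalized body units; boxes are mirrored across the body midline on load)
#'
#' @param concepts,ratings,frequencies,location_ratings file paths; any may be
#'   `NULL` to skip that table.
#' @return list with elements `concepts`, `ratings`, `frequencies`,
#'   `location_ratings` (each `NULL` if not requested).
#' @export
read_tables <- function(concepts = NULL, ratings = NULL, frequencies = NULL,
                        location_ratings = NULL) {
  out <- list(concepts = NULL, ratings = NULL, frequencies = NULL,
              location_ratings = NULL)
  if (!is.null(concepts)) {
    d <- utils::read.csv(concepts, stringsAsFactors = FALSE)
    req <- c("concept_id", "english_name", "category",
             "is_single_english_word", "in_swadesh_core")
    abort_if(!all(req %in% names(d)), "concepts table needs columns: %s",
             paste(req, collapse = ", "))
    dup <- duplicated(d$concept_id)
    abort_if(any(dup), "duplicate concept_id in concepts table: %s",
             paste(unique(d$concept_id[dup]), collapse = ", "))
    d$is_single_english_word <- as.logical(d$is_single_english_word)
    d$in_swadesh_core <- as.logical(d$in_swadesh_core)
    out$concepts <- d
  }
  if (!is.null(ratings)) {
    d <- utils::read.csv(ratings, stringsAsFactors = FALSE)
    req <- c("concept_id", "rater_id", "rating")
    abort_if(!all(req %in% names(d)), "ratings table needs columns: %s",
             paste(req, collapse = ", "))
    bad <- which(!(d$rating %in% 1:7))
    abort_if(length(bad) > 0,
             "rating outside the 1-7 scale at row(s): %s",
             paste(utils::head(bad, 5), collapse = ", "))
    dup <- duplicated(d[c("concept_id", "rater_id")])
    abort_if(any(dup), "duplicate (concept, rater) rating at row(s): %s",
             paste(utils::head(which(dup), 5), collapse = ", "))
    d$rating <- as.integer(d$rating)
    out$ratings <- d
  }
  if (!is.null(frequencies)) {
    d <- utils::read.csv(frequencies, stringsAsFactors = FALSE)
    req <- c("concept_id", "log_frequency")
    abort_if(!all(req %in% names(d)), "frequencies table needs columns: %s",
             paste(req, collapse = ", "))
    abort_if(any(!is.finite(d$log_frequency)), "non-finite log_frequency values")
    out$frequencies <- d
  }
  if (!is.null(location_ratings)) {
    d <- utils::read.csv(location_ratings, stringsAsFactors = FALSE)
    req <- c("concept_id", "rater_id", "x_min", "x_max", "y_min", "y_max")
    abort_if(!all(req %in% names(d)), "location_ratings table needs columns: %s",
             paste(req, collapse = ", "))
    bad <- which(d$x_max <= d$x_min | d$y_max <= d$y_min)
    abort_if(length(bad) > 0, "degenerate (zero-area) rectangle at row(s): %s",
             paste(utils::head(bad, 5), collapse = ", "))
    out$location_ratings <- d
  }
  out
}
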