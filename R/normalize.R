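# Hand extrapolation and signer-centred body normalization.
#
# The pose estimator gives wrists and elbows but not hands. The hand centre is
# approximated by extending the elbow->wrist line beyond the wrist by half the
# forearm length (a straight wrist, knuckles at the hand centre; any wrist
# flexion is deliberately ignored). Coordinates are then mapped into a body
# frame: origin at the mean nose position, x in mean shoulder-width units,
# y in mean nose-neck units (y increases downward, image convention).

#' Construct a normalized sign trajectory
#'
#' @param video_id,concept_id,language identifiers (concept/language may be "").
#' @param frame integer frame indices.
#' @param left,right n x 2 matrices of hand coordinates in body units; rows for
#'   masked frames must be NA.
#' @param left_detected,right_detected logical detection masks.
#' @return object of class `sign_trajectory`.
#' @export
sign_trajectory <- function(video_id, concept_id = "", language = "",
                            frame, left, right, left_detected, right_detected) {
  n <- length(frame)
  left <- matrix(as.numeric(left), ncol = 2)
  right <- matrix(as.numeric(right), ncol = 2)
  abort_if(nrow(left) != n || nrow(right) != n ||
             length(left_detected) != n || length(right_detected) != n,
           "trajectory fields disagree on frame count")
  abort_if(any(!is.finite(left[left_detected, , drop = FALSE])) ||
             any(!is.finite(right[right_detected, , drop = FALSE])),
           "non-finite coordinates on detected frames")
  left[!left_detected, ] <- NA_real_
  right[!right_detected, ] <- NA_real_
  structure(list(video_id = as.character(video_id),
                 concept_id = as.character(concept_id),
                 language = as.character(language),
                 frame = as.integer(frame),
                 left = left, right = right,
                 left_detected = as.logical(left_detected),
                 right_detected = as.logical(right_detected),
                 n_frames = n),
            class = "sign_trajectory")
}

#' @export
print.sign_trajectory <- function(x, ...) {
  cat(sprintf("<sign_trajectory> video '%s' (%s/%s): %d frames, left %d / right %d detected\n",
              x$video_id, x$concept_id, x$language, x$n_frames,
              sum(x$left_detected), sum(x$right_detected)))
  invisible(x)
}

#' Extrapolate the hand centre from elbow and wrist
#'
#' Returns `wrist + 0.5 * (wrist - elbow)`: the elbow-wrist line extended
#' outwards by half the forearm length. A zero-length forearm returns the
#' wrist itself.
#'
#' @param elbow,wrist numeric length-2 points (or n x 2 matrices) in pixels.
#' @return point(s) of the same shape as `wrist`.
#' @export
extrapolate_hand <- function(elbow, wrist) {
  wrist + 0.5 * (wrist - elbow)
}

#' Normalize a pose sequence into the signer body frame
#'
#' For each frame where a hand's elbow and wrist are both detected, the hand
#' position is extrapolated ([extrapolate_hand()]) and mapped to
#' `x' = (x - mean_nose_x) / mean_shoulder_dist`,
#' `y' = (y - mean_nose_y) / mean_noseneck_dist`. Reference means are taken
#' per video over frames where the respective reference joints are detected
#' (set `reference_frames = "all"` to average raw values regardless of
#' detection). Hands with a missing elbow or wrist are masked out. If the neck
#' is absent from the dialect the shoulder midpoint is used as a proxy, with a
#' message.
#'
#' @param seq a [frame_pose_sequence()].
#' @param concept_id,language metadata carried onto the trajectory.
#' @param reference_frames `"detected"` (default) or `"all"`.
#' @return a [sign_trajectory()] in body units.
#' @export
normalize_sequence <- function(seq, concept_id = "", language = "",
                               reference_frames = c("detected", "all")) {
  reference_frames <- match.arg(reference_frames)
  stopifnot(inherits(seq, "frame_pose_sequence"))
  nose <- joint_track(seq, "nose")
  neck <- joint_track(seq, "neck")
  lsh <- joint_track(seq, "left_shoulder")
  rsh <- joint_track(seq, "right_shoulder")

  if (!any(neck$detected)) {
    both <- lsh$detected & rsh$detected
    if (any(both)) {
      message(sprintf("video '%s': neck missing, using shoulder midpoint as proxy",
                      seq$video_id))
      neck$xy <- (lsh$xy + rsh$xy) / 2
      neck$detected <- both
    }
  }

  use <- function(tr) if (reference_frames == "detected") tr$detected else
    rep(TRUE, length(tr$detected))

  abort_if(!any(use(nose)), "video '%s': nose never detected, cannot normalize",
           seq$video_id)
  mean_nose <- colMeans(nose$xy[use(nose), , drop = FALSE], na.rm = TRUE)

  sh_ok <- use(lsh) & use(rsh)
  abort_if(!any(sh_ok), "video '%s': shoulders never jointly detected", seq$video_id)
  sh_d <- sqrt(rowSums((lsh$xy[sh_ok, , drop = FALSE] -
                          rsh$xy[sh_ok, , drop = FALSE])^2))
  shoulder_dist <- mean(sh_d, na.rm = TRUE)

  nn_ok <- use(nose) & use(neck)
  abort_if(!any(nn_ok), "video '%s': nose-neck pair never detected", seq$video_id)
  nn_d <- sqrt(rowSums((nose$xy[nn_ok, , drop = FALSE] -
                          neck$xy[nn_ok, , drop = FALSE])^2))
  noseneck_dist <- mean(nn_d, na.rm = TRUE)

  abort_if(!is.finite(shoulder_dist) || shoulder_dist <= 0,
           "video '%s': mean shoulder distance is not positive", seq$video_id)
  abort_if(!is.finite(noseneck_dist) || noseneck_dist <= 0,
           "video '%s': mean nose-neck distance is not positive", seq$video_id)

  hand_coords <- function(side) {
    elbow <- joint_track(seq, paste0(side, "_elbow"))
    wrist <- joint_track(seq, paste0(side, "_wrist"))
    det <- elbow$detected & wrist$detected
    hand <- extrapolate_hand(elbow$xy, wrist$xy)
    out <- cbind((hand[, 1] - mean_nose[1]) / shoulder_dist,
                 (hand[, 2] - mean_nose[2]) / noseneck_dist)
    out[!det, ] <- NA_real_
    list(xy = out, detected = det)
  }
  L <- hand_coords("left")
  R <- hand_coords("right")
  sign_trajectory(video_id = seq$video_id, concept_id = concept_id,
                  language = language, frame = seq$frames,
                  left = L$xy, right = R$xy,
                  left_detected = L$detected, right_detected = R$detected)
}
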