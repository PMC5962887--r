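# Shared fixture builders. Everything is generated in code; nothing binary.

# Minimal full-skeleton keypoint frame set: static torso, hands parameterized.
fix_pose_df <- function(n_frames = 3, conf = 0.9,
                        wrist_l = c(260, 330), wrist_r = c(380, 330),
                        elbow_l = c(250, 400), elbow_r = c(390, 400)) {
  do.call(rbind, lapply(seq_len(n_frames) - 1L, function(t) {
    data.frame(
      frame = t,
      joint = c("nose", "neck", "left_shoulder", "right_shoulder",
                "left_elbow", "left_wrist", "right_elbow", "right_wrist"),
      x = c(320, 320, 380, 260, elbow_l[1], wrist_l[1], elbow_r[1], wrist_r[1]),
      y = c(160, 240, 240, 240, elbow_l[2], wrist_l[2], elbow_r[2], wrist_r[2]),
      confidence = conf,
      stringsAsFactors = FALSE)
  }))
}

# Trajectory straight from coordinate matrices (body units).
fix_traj <- function(left, right,
                     left_detected = rep(TRUE, nrow(left)),
                     right_detected = rep(TRUE, nrow(right)),
                     video_id = "v1", concept_id = "c1", language = "L1") {
  sign_trajectory(video_id = video_id, concept_id = concept_id,
                  language = language, frame = seq_len(nrow(left)) - 1L,
                  left = left, right = right,
                  left_detected = left_detected,
                  right_detected = right_detected)
}

# A single-hand trajectory: right hand follows `pts`, left hand undetected.
fix_right_traj <- function(pts, ...) {
  pts <- matrix(pts, ncol = 2)
  fix_traj(left = matrix(NA_real_, nrow(pts), 2), right = pts,
           left_detected = rep(FALSE, nrow(pts)), ...)
}

# Random trajectory for property tests (coordinates in roughly body range).
fix_random_traj <- function(n = NULL, p_detect = 0.8) {
  n <- n %||% sample(1:20, 1)
  mk <- function() {
    det <- stats::runif(n) < p_detect
    xy <- matrix(stats::rnorm(2 * n, 0, 1.5), n, 2)
    xy[!det, ] <- NA_real_
    list(xy = xy, det = det)
  }
  l <- mk(); r <- mk()
  fix_traj(l$xy, r$xy, l$det, r$det)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
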