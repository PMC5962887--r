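# Study 2: location iconicity — scoring sign trajectories against
# non-signer location ratings given as midline-mirrored rectangles.

#' Construct a location rating
#'
#' A single rater's axis-aligned rectangle on the normalized body silhouette,
#' together with its mirror image across the body midline (x = 0). The pair
#' is treated as one rating: hand positions covered by either box count as
#' inside.
#'
#' @param concept_id,rater_id identifiers.
#' @param x_min,x_max,y_min,y_max rectangle bounds in body units; must have
#'   positive area.
#' @return object of class `location_rating` with `rect` and `mirrored`
#'   (each `c(x_min, x_max, y_min, y_max)`).
#' @export
location_rating <- function(concept_id, rater_id, x_min, x_max, y_min, y_max) {
  abort_if(x_max <= x_min || y_max <= y_min,
           "degenerate rectangle for (%s, %s)", concept_id, rater_id)
  structure(list(concept_id = as.character(concept_id),
                 rater_id = as.character(rater_id),
                 rect = c(x_min = x_min, x_max = x_max,
                          y_min = y_min, y_max = y_max),
                 mirrored = c(x_min = -x_max, x_max = -x_min,
                              y_min = y_min, y_max = y_max)),
            class = "location_rating")
}

#' Location ratings from a table
#'
#' @param d data frame with columns `concept_id`, `rater_id`, `x_min`,
#'   `x_max`, `y_min`, `y_max` (see [read_tables()]).
#' @return list of [location_rating()] objects.
#' @export
location_ratings_from_table <- function(d) {
  lapply(seq_len(nrow(d)), function(i) {
    location_rating(d$concept_id[i], d$rater_id[i],
                    d$x_min[i], d$x_max[i], d$y_min[i], d$y_max[i])
  })
}

#' Dominant hand of a sign
#'
#' The hand with the longer traced path; exact ties go to the right hand
#' (the choice is arbitrary for symmetric signs and does not affect
#' symmetric downstream scores).
#'
#' @param traj a [sign_trajectory()].
#' @return `"left"` or `"right"`.
#' @export
dominant_hand <- function(traj) {
  stopifnot(inherits(traj, "sign_trajectory"))
  abort_if(!any(traj$left_detected) && !any(traj$right_detected),
           "no detected frames on either hand in video '%s'", traj$video_id)
  lp <- path_length(traj$left, traj$left_detected)
  rp <- path_length(traj$right, traj$right_detected)
  if (lp > rp) "left" else "right"
}

#' Trim transport movements from a frame list
#'
#' Removes `floor(fraction * n)` frames from each end of an already
#' detection-filtered frame list (default 20%), dropping the movements from
#' and to neutral position. Never returns an empty list for non-empty input:
#' if trimming would remove everything, the middle frame is kept.
#'
#' @param idx indices (or any vector) of detected frames, in order.
#' @param fraction fraction trimmed from each end, default 0.2.
#' @return the trimmed vector.
#' @export
trim_frames <- function(idx, fraction = 0.2) {
  n <- length(idx)
  if (n == 0L) return(idx)
  k <- floor(fraction * n)
  if (n - 2L * k < 1L) return(idx[ceiling(n / 2)])
  idx[(k + 1L):(n - k)]
}

#' Distance from a point to a location rating
#'
#' Zero when the point lies inside the original or the mirrored rectangle;
#' otherwise the Euclidean distance to the nearest boundary point over both
#' boxes.
#'
#' @param point numeric length-2 `(x, y)` in body units.
#' @param rating a [location_rating()].
#' @return non-negative distance in body units.
#' @export
rectangle_distance <- function(point, rating) {
  stopifnot(inherits(rating, "location_rating"))
  box_dist <- function(b) {
    dx <- max(b[["x_min"]] - point[1], 0, point[1] - b[["x_max"]])
    dy <- max(b[["y_min"]] - point[2], 0, point[2] - b[["y_max"]])
    sqrt(dx^2 + dy^2)
  }
  min(box_dist(rating$rect), box_dist(rating$mirrored))
}

#' Iconicity score of one sign against one location rating
#'
#' Negative mean rectangle distance of the dominant hand over its trimmed
#' detected frames. The maximum, zero, occurs iff every trimmed frame lies
#' inside the rated region; increasingly negative values mean increasing
#' divergence from the rating.
#'
#' @param traj a [sign_trajectory()].
#' @param rating a [location_rating()].
#' @param trim_fraction passed to [trim_frames()], default 0.2.
#' @return score in `(-Inf, 0]`.
#' @export
iconicity_score <- function(traj, rating, trim_fraction = 0.2) {
  hand <- dominant_hand(traj)
  det <- if (hand == "left") traj$left_detected else traj$right_detected
  xy <- if (hand == "left") traj$left else traj$right
  keep <- trim_frames(which(det), trim_fraction)
  d <- vapply(keep, function(i) rectangle_distance(xy[i, ], rating), 0)
  -mean(d)
}

#' Concept-level iconicity with vocabulary chance baseline
#'
#' Scores every (sign, rating) combination for the concept (N languages x
#' M ratings) and averages. For context, the same M ratings are scored
#' against every concept in the vocabulary; the baseline mean and SD of
#' those per-concept means estimate chance similarity, and the concept's
#' percentile is its rank among vocabulary concepts ordered from the highest
#' (least negative) score: `round(100 * rank / |vocabulary|)`, so low
#' percentiles indicate high similarity.
#'
#' @param signs list of [sign_trajectory()], the concept's signs across
#'   languages.
#' @param ratings list of [location_rating()] for the concept.
#' @param vocabulary named list: concept_id -> list of trajectories; may be
#'   empty, in which case baseline and percentile are `NA`.
#' @param concept_id identifier for reporting; defaults to the first sign's.
#' @param trim_fraction passed to [iconicity_score()].
#' @return list of class `iconicity_result`: `concept_id`, `mean_score`,
#'   `scores` (N x M matrix), `percentile`, `baseline_mean`, `baseline_sd`,
#'   `vocabulary_scores` (named vector of per-concept means).
#' @export
concept_iconicity <- function(signs, ratings, vocabulary = list(),
                              concept_id = NULL, trim_fraction = 0.2) {
  abort_if(length(signs) < 1 || length(ratings) < 1,
           "need at least one sign and one rating")
  concept_id <- concept_id %||% signs[[1]]$concept_id
  score_set <- function(trajs) {
    m <- vapply(ratings, function(rt) {
      vapply(trajs, iconicity_score, 0, rating = rt,
             trim_fraction = trim_fraction)
    }, numeric(length(trajs)))
    matrix(m, nrow = length(trajs))
  }
  scores <- score_set(signs)
  mean_score <- mean(scores)
  vocab_means <- vapply(vocabulary, function(trajs) mean(score_set(trajs)), 0)
  if (length(vocab_means)) {
    rank <- 1L + sum(vocab_means > mean_score)
    percentile <- round(100 * rank / length(vocab_means))
    baseline_mean <- mean(vocab_means)
    baseline_sd <- stats::sd(vocab_means)
  } else {
    percentile <- NA_real_; baseline_mean <- NA_real_; baseline_sd <- NA_real_
  }
  structure(list(concept_id = concept_id, mean_score = mean_score,
                 scores = scores, percentile = percentile,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 vocabulary_scores = vocab_means),
            class = "iconicity_result")
}

#' @export
print.iconicity_result <- function(x, ...) {
  cat(sprintf("<iconicity_result> '%s': mean score %.3f (percentile %s; chance %.3f +/- %.3f)\n",
              x$concept_id, x$mean_score,
              ifelse(is.na(x$percentile), "NA", x$percentile),
              x$baseline_mean, x$baseline_sd))
  invisible(x)
}
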