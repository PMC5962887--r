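# Study 1 mechanics: hand path lengths, one-/two-handed classification,
# vocabulary proportions and precision arithmetic.

#' Total path length of a masked hand trajectory
#'
#' Sum of Euclidean distances between consecutive *detected* frames. Detection
#' dropouts are bridged: each detected frame pairs with the nearest previous
#' detected frame, so a gap contributes the straight-line displacement across
#' it rather than splitting the path. Zero or one detected frames give 0.
#'
#' @param xy n x 2 coordinate matrix (body units).
#' @param detected logical mask, default: rows with finite coordinates.
#' @return non-negative path length in body units.
#' @export
path_length <- function(xy, detected = NULL) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  if (is.null(detected)) detected <- stats::complete.cases(xy)
  pts <- xy[detected, , drop = FALSE]
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Classify a sign as one- or two-handed
#'
#' A sign is discarded when hand detection failed in too few frames
#' (`< min_frames`); otherwise it is one-handed iff one hand's path length
#' exceeds the other's by strictly more than `ratio_threshold`, else
#' two-handed. A still hand (path 0) against a moving hand is one-handed;
#' both hands still is two-handed (symmetric stillness).
#'
#' @param traj a [sign_trajectory()].
#' @param ratio_threshold path-length ratio above which a sign is one-handed;
#'   default 3 (strict inequality at the boundary).
#' @param min_frames minimum detected frames before a sign is kept; default 10.
#' @param min_frames_rule `"either"` (default): keep the sign if the
#'   better-detected hand reaches `min_frames`; `"both"`: require both hands.
#' @return a one-row data frame of class `handedness_call` with columns
#'   `video_id`, `concept_id`, `language`, `call` (one of `"one_handed"`,
#'   `"two_handed"`, `"discarded"`), `left_path`, `right_path`,
#'   `left_frames`, `right_frames`.
#' @export
classify_handedness <- function(traj, ratio_threshold = 3, min_frames = 10,
                                min_frames_rule = c("either", "both")) {
  min_frames_rule <- match.arg(min_frames_rule)
  stopifnot(inherits(traj, "sign_trajectory"))
  nl <- sum(traj$left_detected)
  nr <- sum(traj$right_detected)
  lp <- path_length(traj$left, traj$left_detected)
  rp <- path_length(traj$right, traj$right_detected)
  enough <- if (min_frames_rule == "either") max(nl, nr) >= min_frames else
    min(nl, nr) >= min_frames
  call <- if (!enough) {
    "discarded"
  } else {
    hi <- max(lp, rp); lo <- min(lp, rp)
    if (lo == 0 && hi > 0) "one_handed"
    else if (lo > 0 && hi / lo > ratio_threshold) "one_handed"
    else "two_handed"            # includes both-paths-zero: symmetric stillness
  }
  out <- data.frame(video_id = traj$video_id, concept_id = traj$concept_id,
                    language = traj$language, call = call,
                    left_path = lp, right_path = rp,
                    left_frames = nl, right_frames = nr,
                    stringsAsFactors = FALSE)
  class(out) <- c("handedness_call", class(out))
  out
}

#' One-/two-handed proportions by language and vocabulary
#'
#' Tabulates, for each group, the number of one-handed (1H) and two-handed
#' (2H) calls and the percentage 100*2H/(1H+2H) rounded to one decimal.
#' Vocabulary membership comes from the concept table: `core` selects
#' concepts with `in_swadesh_core`, `extended` those with
#' `is_single_english_word`. Discarded calls are dropped first.
#'
#' @param calls data frame of [classify_handedness()] rows.
#' @param concepts concept table (see [read_tables()]).
#' @param grouping `"per_language"` (per-language rows plus a Total row) or
#'   `"total"` (Total row only).
#' @param vocabulary `"core"` or `"extended"`.
#' @return data frame with columns `language`, `vocabulary`, `n_one`, `n_two`,
#'   `pct_two`.
#' @export
vocabulary_proportions <- function(calls, concepts,
                                   grouping = c("per_language", "total"),
                                   vocabulary = c("core", "extended")) {
  grouping <- match.arg(grouping)
  vocabulary <- match.arg(vocabulary)
  keep_col <- if (vocabulary == "core") "in_swadesh_core" else "is_single_english_word"
  vocab_ids <- concepts$concept_id[as.logical(concepts[[keep_col]])]
  d <- calls[calls$call != "discarded" & calls$concept_id %in% vocab_ids, , drop = FALSE]
  one_row <- function(lang, sub) {
    n1 <- sum(sub$call == "one_handed")
    n2 <- sum(sub$call == "two_handed")
    if (n1 + n2 == 0L) {
      warning(sprintf("no classified %s-vocabulary signs for '%s'; row omitted",
                      vocabulary, lang), call. = FALSE)
      return(NULL)
    }
    data.frame(language = lang, vocabulary = vocabulary, n_one = n1, n_two = n2,
               pct_two = round(100 * n2 / (n1 + n2), 1), stringsAsFactors = FALSE)
  }
  rows <- list()
  if (grouping == "per_language") {
    for (lang in sort(unique(calls$language))) {
      rows[[lang]] <- one_row(lang, d[d$language == lang, , drop = FALSE])
    }
  }
  rows[["Total"]] <- one_row("Total", d)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Detection precision from an error count
#'
#' `100 * (n - errors) / n`, rounded to one decimal: the percentage of
#' manually checked classifications that were correct.
#'
#' @param errors number of misclassified signs among the checked sample.
#' @param n size of the checked sample; must be positive.
#' @return precision in percent, one decimal.
#' @export
precision_from_counts <- function(errors, n) {
  abort_if(n <= 0, "precision undefined for n = 0")
  abort_if(errors < 0 || errors > n, "need 0 <= errors <= n")
  round(100 * (n - errors) / n, 1)
}
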