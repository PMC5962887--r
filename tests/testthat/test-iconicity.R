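# Rectangle-distance iconicity scoring.

test_that("dominant hand is the longer path, ties to the right", {
  line <- function(len, n = 12) cbind(seq(0, len, length.out = n), 0)
  expect_equal(dominant_hand(fix_traj(line(1), line(5))), "right")
  expect_equal(dominant_hand(fix_traj(line(5), line(1))), "left")
  expect_equal(dominant_hand(fix_traj(line(2), line(2))), "right")
  none <- fix_traj(line(1), line(1), rep(FALSE, 12), rep(FALSE, 12))
  expect_error(dominant_hand(none), "no detected frames")
})

test_that("trim_frames drops floor(20%) per end and never empties", {
  expect_equal(trim_frames(1:10), 3:8)
  expect_equal(trim_frames(1:7), 2:6)
  expect_equal(trim_frames(1:5), 2:4)
  expect_equal(trim_frames(42L), 42L)
  expect_equal(trim_frames(integer(0)), integer(0))
  # aggressive fraction: middle frame kept
  expect_equal(trim_frames(1:4, fraction = 0.5), 2L)
})

test_that("rectangle_distance handles inside, edge, corner and the mirror", {
  r <- location_rating("c", "q", x_min = 0, x_max = 1, y_min = -1, y_max = 1)
  expect_equal(rectangle_distance(c(0.5, 0), r), 0)
  expect_equal(rectangle_distance(c(2, 0), r), 1)
  expect_equal(rectangle_distance(c(2, 2), r), sqrt(2))
  # mirrored twin covers the other side of the midline
  expect_equal(rectangle_distance(c(-0.5, 0), r), 0)
  expect_equal(rectangle_distance(c(-2, 0), r), 1)
})

test_that("rectangle_distance matches a dense boundary-sampling oracle", {
  oracle <- function(point, rating) {
    for (b in list(rating$rect, rating$mirrored)) {
      if (point[1] >= b[["x_min"]] && point[1] <= b[["x_max"]] &&
          point[2] >= b[["y_min"]] && point[2] <= b[["y_max"]]) return(0)
    }
    best <- Inf
    for (b in list(rating$rect, rating$mirrored)) {
      xs <- seq(b[["x_min"]], b[["x_max"]], length.out = 400)
      ys <- seq(b[["y_min"]], b[["y_max"]], length.out = 400)
      edge <- rbind(cbind(xs, b[["y_min"]]), cbind(xs, b[["y_max"]]),
                    cbind(b[["x_min"]], ys), cbind(b[["x_max"]], ys))
      best <- min(best, sqrt(min((edge[, 1] - point[1])^2 +
                                   (edge[, 2] - point[2])^2)))
    }
    best
  }
  set.seed(99)
  for (i in 1:60) {
    x0 <- runif(1, -2, 2); y0 <- runif(1, -1, 4)
    r <- location_rating("c", "q", x0, x0 + runif(1, 0.1, 1.5),
                         y0, y0 + runif(1, 0.1, 1.5))
    pt <- c(runif(1, -3, 3), runif(1, -2, 5))
    expect_lt(abs(rectangle_distance(pt, r) - oracle(pt, r)), 1e-3)
  }
})

test_that("iconicity_score is the negative mean distance over trimmed frames", {
  box <- location_rating("c", "q", 0, 1, 0, 1)
  inside <- fix_right_traj(cbind(runif(10, 0.05, 0.95), runif(10, 0.05, 0.95)))
  expect_equal(iconicity_score(inside, box), 0)
  # two kept frames at distances 1 and 3 -> -2
  two <- fix_right_traj(rbind(c(0.5, 2), c(0.5, 4)))
  expect_equal(iconicity_score(two, box), -2)
})

test_that("iconicity_score is mirror-invariant and never positive", {
  set.seed(5)
  for (i in 1:20) {
    tr <- fix_random_traj(n = sample(5:20, 1))
    r <- location_rating("c", "q", runif(1, -1, 0.5), runif(1, 0.6, 2),
                         runif(1, -1, 1), runif(1, 1.1, 3))
    s <- iconicity_score(tr, r)
    expect_lte(s, 0)
    mirrored <- fix_traj(cbind(-tr$left[, 1], tr$left[, 2]),
                         cbind(-tr$right[, 1], tr$right[, 2]),
                         tr$left_detected, tr$right_detected)
    expect_equal(iconicity_score(mirrored, r), s)
  }
})

test_that("moving a wholly-outside trajectory further away never raises the score", {
  box <- location_rating("c", "q", -0.5, 0.5, -0.5, 0.5)
  base <- fix_right_traj(cbind(runif(8, 1, 1.5), runif(8, 1, 1.5)))
  scores <- vapply(seq(0, 5, by = 0.5), function(d) {
    sh <- fix_right_traj(cbind(base$right[, 1] + d, base$right[, 2] + d))
    iconicity_score(sh, box)
  }, 0)
  expect_true(all(diff(scores) <= 1e-12))
})

test_that("concept_iconicity averages N x M scores and ranks percentiles", {
  boxA <- location_rating("c", "qa", 0, 1, 0, 1)
  boxB <- location_rating("c", "qb", 0, 1, -2, -1)
  sign1 <- fix_right_traj(rbind(c(0.5, 1)))   # dist 0 to A, 2 to B
  sign2 <- fix_right_traj(rbind(c(0.5, 2)))   # dist 1 to A, 3 to B
  res <- concept_iconicity(list(sign1, sign2), list(boxA, boxB),
                           concept_id = "c")
  expect_equal(sort(as.vector(res$scores)), c(-3, -2, -1, 0))
  expect_equal(res$mean_score, -1.5)
  expect_true(is.na(res$percentile))

  # rank-1 convention: best of a 100-concept vocabulary -> 1st percentile
  vocab <- lapply(seq_len(100), function(k) {
    list(fix_right_traj(rbind(c(0.5, 1 + 0.1 * k))))
  })
  names(vocab) <- sprintf("w%03d", seq_len(100))
  best <- concept_iconicity(list(sign1), list(boxA), vocabulary = vocab)
  expect_equal(best$percentile, 1)
  expect_equal(best$baseline_mean, mean(best$vocabulary_scores))
})

test_that("signs articulated at the rated location beat the vocabulary baseline", {
  # planted-location simulation: concept signs inside the rated box,
  # vocabulary signs uniform over the signing space
  hits <- 0L
  for (rep in 1:100) {
    set.seed(rep)
    box <- location_rating("c", "q", -0.3, 0.3, 0.8, 1.4)
    concept_signs <- lapply(1:3, function(i) {
      fix_right_traj(cbind(runif(8, -0.25, 0.25), runif(8, 0.85, 1.35)))
    })
    vocab <- lapply(1:30, function(k) {
      list(fix_right_traj(cbind(runif(8, -2, 2), runif(8, -1, 4))))
    })
    names(vocab) <- sprintf("w%02d", 1:30)
    res <- concept_iconicity(concept_signs, list(box), vocabulary = vocab)
    if (res$mean_score > res$baseline_mean) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
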