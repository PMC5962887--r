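# The synthetic-data generator: determinism, generative moments, and
# end-to-end consistency with the classifiers it feeds.

test_that("fixed seeds give byte-identical datasets, different seeds differ", {
  a <- gen_plurality_dataset(synth_config(n_concepts = 10, n_raters = 4,
                                          n_languages = 5), seed = 3)
  b <- gen_plurality_dataset(synth_config(n_concepts = 10, n_raters = 4,
                                          n_languages = 5), seed = 3)
  expect_identical(a, b)
  c <- gen_plurality_dataset(synth_config(n_concepts = 10, n_raters = 4,
                                          n_languages = 5), seed = 4)
  expect_false(identical(a$ratings, c$ratings))
  v1 <- gen_sign_video("v", c(0, 1), "two", frames = 10, seed = 12)
  v2 <- gen_sign_video("v", c(0, 1), "two", frames = 10, seed = 12)
  expect_identical(v1$keypoints, v2$keypoints)
  # generators restore the caller's RNG state
  set.seed(1); before <- .Random.seed
  invisible(gen_plurality_dataset(synth_config(n_concepts = 3, n_raters = 2,
                                               n_languages = 2), seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("ratings are the rounded clamped normal draws around 1 + 6p", {
  # noise-free limit: ratings deterministically equal clamp(round(1 + 6 p_c))
  cfg <- synth_config(n_concepts = 40, n_raters = 3, n_languages = 2,
                      sigma_Q = 1e-9, sigma_R = 1e-9)
  gen <- gen_plurality_dataset(cfg, seed = 17)
  expected <- pmin(pmax(round(1 + 6 * gen$truth$p[gen$ratings$concept_id]), 1), 7)
  expect_equal(gen$ratings$rating, unname(expected))
  # with noise, empirical moments match the generative model at scale
  cfg2 <- synth_config(n_concepts = 100, n_raters = 100, n_languages = 1,
                       sigma_Q = 1.52, sigma_R = 0)
  gen2 <- gen_plurality_dataset(cfg2, seed = 18)
  mu <- 1 + 6 * gen2$truth$p[gen2$ratings$concept_id]
  resid <- gen2$ratings$rating - unname(mu)
  inner <- mu > 2.5 & mu < 5.5        # away from the clamp boundaries
  expect_equal(mean(resid[inner]), 0, tolerance = 3 * 1.52 / sqrt(sum(inner)))
})

test_that("a saturated plurality coefficient makes plural concepts two-handed", {
  cfg <- synth_config(n_concepts = 60, n_raters = 1, n_languages = 30,
                      beta_p = 50, beta_f = 0, a = 0,
                      sigma_L = 1e-9, sigma_C = 1e-9)
  gen <- gen_plurality_dataset(cfg, seed = 23)
  plural <- names(gen$truth$p)[gen$truth$p > 0.1]
  sub <- gen$outcomes[gen$outcomes$concept_id %in% plural, ]
  expect_gt(mean(sub$two_handed), 0.999)
})

test_that("a zero linear predictor yields a binomial half split", {
  cfg <- synth_config(n_concepts = 100, n_raters = 1, n_languages = 100,
                      beta_p = 0, beta_f = 0, a = 0,
                      sigma_L = 1e-12, sigma_C = 1e-12)
  gen <- gen_plurality_dataset(cfg, seed = 29)
  expect_equal(nrow(gen$outcomes), 10000L)
  expect_lt(abs(mean(gen$outcomes$two_handed) - 0.5), 0.015)
})

test_that("generated videos realize their planted handedness", {
  one <- gen_sign_video("v1", c(0.3, 1), "one", frames = 30, noise_sd = 0,
                        dropout_p = 0, seed = 5)
  expect_equal(classify_handedness(normalize_sequence(one))$call, "one_handed")
  two <- gen_sign_video("v2", c(0.3, 1), "two", frames = 30, noise_sd = 0,
                        dropout_p = 0, seed = 5)
  expect_equal(classify_handedness(normalize_sequence(two))$call, "two_handed")
  # low noise: labels recovered essentially always
  calls <- vapply(1:40, function(i) {
    h <- if (i %% 2) "one" else "two"
    v <- gen_sign_video(paste0("v", i), c(-0.2, 0.8), h, frames = 30,
                        noise_sd = 0.02, dropout_p = 0.05, seed = 100 + i)
    classify_handedness(normalize_sequence(v))$call
  }, "")
  expect_equal(calls, rep(c("one_handed", "two_handed"), 20))
})

test_that("a sign articulated inside its rated box scores a perfect zero", {
  forehead <- c(0, -0.6)
  v <- gen_sign_video("v", forehead, "one", frames = 30, noise_sd = 0,
                      dropout_p = 0, orbit_radius = 0.1, seed = 6)
  tr <- normalize_sequence(v)
  box <- location_rating("think", "q1", forehead[1] - 0.3, forehead[1] + 0.3,
                         forehead[2] - 0.3, forehead[2] + 0.3)
  expect_equal(iconicity_score(tr, box), 0)
})

test_that("location ratings jitter around their targets and mirror correctly", {
  tg <- list(brow = c(-0.3, 0.3, -0.8, -0.4))
  same <- gen_location_ratings(tg, M = 5, jitter_sd = 0, seed = 1)
  expect_length(same, 5)
  for (r in same) expect_equal(unname(r$rect), tg$brow)
  # box centred on the midline: mirrored twin coincides with the original
  expect_equal(unname(same[[1]]$mirrored), tg$brow)
  # off-centre box mirrors to the opposite side
  off <- gen_location_ratings(list(ear = c(0.4, 0.8, -0.6, -0.2)), M = 1,
                              jitter_sd = 0, seed = 1)[[1]]
  expect_equal(unname(off$mirrored), c(-0.8, -0.4, -0.6, -0.2))
  # jittered boxes almost always still contain the target centre
  many <- gen_location_ratings(list(b = c(-0.25, 0.25, 0.75, 1.25)), M = 400,
                               jitter_sd = 0.05, seed = 2)
  hit <- vapply(many, function(r) {
    r$rect[["x_min"]] <= 0 && r$rect[["x_max"]] >= 0 &&
      r$rect[["y_min"]] <= 1 && r$rect[["y_max"]] >= 1
  }, TRUE)
  expect_gte(mean(hit), 0.99)
})
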