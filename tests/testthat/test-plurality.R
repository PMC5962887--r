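# The hierarchical plurality model: joint density, sampler, diagnostics.

# independent longhand oracle for the joint log-density: every term written
# out one observation at a time with textbook density calls
oracle_log_joint <- function(pr, ratings, outcomes, f) {
  lp <- 0
  for (k in seq_len(nrow(ratings))) {
    mu <- 1 + 6 * pr$p[[ratings$concept_id[k]]] + pr$r[[ratings$rater_id[k]]]
    lp <- lp + dnorm(ratings$rating[k], mu, pr$sigma_Q, log = TRUE)
  }
  for (k in seq_len(nrow(outcomes))) {
    cid <- outcomes$concept_id[k]
    eta <- pr$beta_p * pr$p[[cid]] + pr$beta_f * f[[cid]] +
      pr$alpha_L[[outcomes$language[k]]] + pr$alpha_C[[cid]] + pr$a
    prob <- 1 / (1 + exp(-eta))
    lp <- lp + dbinom(outcomes$two_handed[k], 1, prob, log = TRUE)
  }
  lp <- lp + dnorm(pr$beta_p, 0, 5, log = TRUE) +
    dnorm(pr$beta_f, 0, 5, log = TRUE) + dnorm(pr$a, 0, 5, log = TRUE)
  for (v in pr$r) lp <- lp + dnorm(v, 0, pr$sigma_R, log = TRUE)
  for (v in pr$alpha_L) lp <- lp + dnorm(v, 0, pr$sigma_L, log = TRUE)
  for (v in pr$alpha_C) lp <- lp + dnorm(v, 0, pr$sigma_C, log = TRUE)
  for (v in pr$p) lp <- lp + dunif(v, 0, 1, log = TRUE)
  for (s in c(pr$sigma_Q, pr$sigma_R, pr$sigma_L, pr$sigma_C)) {
    lp <- lp + dexp(s, rate = 1 / 5, log = TRUE)
  }
  lp
}

small_dataset <- function(seed = 1) {
  gen <- gen_plurality_dataset(
    synth_config(n_concepts = 5, n_raters = 3, n_languages = 4), seed = seed)
  gen
}

random_params <- function(d) {
  list(beta_p = rnorm(1), beta_f = rnorm(1), a = rnorm(1),
       r = setNames(rnorm(d$n_raters, 0, 0.5), d$raters),
       alpha_L = setNames(rnorm(d$n_languages, 0, 0.5), d$languages),
       alpha_C = setNames(rnorm(d$n_concepts, 0, 0.5), d$concepts),
       p = setNames(runif(d$n_concepts), d$concepts),
       sigma_Q = runif(1, 0.5, 2), sigma_R = runif(1, 0.3, 1),
       sigma_L = runif(1, 0.3, 1), sigma_C = runif(1, 0.3, 1))
}

test_that("log_joint matches a term-by-term textbook oracle", {
  set.seed(21)
  for (rep in 1:5) {
    gen <- small_dataset(seed = rep)
    d <- gen$data
    pr <- random_params(d)
    expect_equal(plurality_log_joint(pr, d),
                 oracle_log_joint(pr, gen$ratings, gen$outcomes,
                                  setNames(gen$frequencies$log_frequency,
                                           gen$frequencies$concept_id)),
                 tolerance = 1e-8)
  }
})

test_that("log_joint rejects out-of-support parameters", {
  gen <- small_dataset()
  pr <- random_params(gen$data)
  bad <- pr; bad$p[1] <- 1.2
  expect_identical(plurality_log_joint(bad, gen$data), -Inf)
  bad2 <- pr; bad2$sigma_Q <- 0
  expect_identical(plurality_log_joint(bad2, gen$data), -Inf)
})

test_that("rating mean hits the scale endpoints at p = 0 and p = 1", {
  # a single rating of 7 under p = 1, r = 0 sits exactly at the mean;
  # its likelihood term is dnorm(0) / sigma_Q
  ratings <- data.frame(concept_id = "c1", rater_id = "r1", rating = 7L)
  outcomes <- data.frame(concept_id = "c1", language = "l1", two_handed = 1L)
  freq <- data.frame(concept_id = "c1", log_frequency = 0.5)
  d <- plurality_data(ratings, outcomes, freq, scale_frequency = FALSE)
  pr <- list(beta_p = 0, beta_f = 0, a = 0, r = 0, alpha_L = 0, alpha_C = 0,
             p = 1, sigma_Q = 1, sigma_R = 1, sigma_L = 1, sigma_C = 1)
  at7 <- plurality_log_joint(pr, d)
  pr0 <- pr; pr0$p <- 0
  ratings1 <- ratings; ratings1$rating <- 1L
  d1 <- plurality_data(ratings1, outcomes, freq, scale_frequency = FALSE)
  at1 <- plurality_log_joint(pr0, d1)
  # both sit at their mean -> identical rating terms; and the all-zero
  # linear predictor makes each outcome worth exactly log(0.5)
  expect_equal(at7, at1)
  no_out <- plurality_log_joint(
    pr, plurality_data(ratings, outcomes[0, ], freq, scale_frequency = FALSE))
  expect_equal(at7 - no_out, log(0.5))
})

test_that("shifting rater biases against latent plurality leaves the rating likelihood flat", {
  # soft-centering degeneracy: r_i + delta with p_c - delta/6 preserves the
  # rating means; with no outcomes the data likelihood is unchanged
  gen <- small_dataset(seed = 3)
  d <- plurality_data(gen$ratings, gen$outcomes[0, ], gen$frequencies,
                      scale_frequency = FALSE)
  pr <- random_params(gen$data)
  pr$p[] <- runif(length(pr$p), 0.3, 0.7)
  delta <- 0.6
  sh <- pr
  sh$r <- pr$r + delta
  sh$p <- pr$p - delta / 6
  strip_priors <- function(q) {
    sum(dnorm(q$r, 0, q$sigma_R, log = TRUE))
  }
  # difference of log joints equals the difference of the r priors alone
  expect_equal(plurality_log_joint(sh, d) - plurality_log_joint(pr, d),
               strip_priors(sh) - strip_priors(pr), tolerance = 1e-10)
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(8)
  mixed <- matrix(rnorm(4000), ncol = 4)
  expect_lt(gelman_rubin(mixed), 1.01)
  apart <- cbind(rnorm(1000, 0), rnorm(1000, 100))
  expect_gt(gelman_rubin(apart), 1.1)
  expect_warning(r <- gelman_rubin(matrix(5, 100, 4)), "zero variance")
  expect_equal(r, 1.0)
})

test_that("posterior_summary uses linear percentile interpolation", {
  gen <- small_dataset()
  post <- suppressWarnings(fit_plurality(gen$data, chains = 2, burn_in = 50,
                                         draws = 50, seed = 1, max_leapfrog = 8))
  fake <- post
  fake$draws[, , "beta_p"] <- matrix(1:100, 50, 2)
  s <- posterior_summary(fake, percentiles = c(2.5, 50, 97.5),
                         parameters = "beta_p")
  expect_equal(s$p50, 50.5)
  expect_equal(s$p2.5, unname(quantile(1:100, 0.025)))
  # symmetric samples give percentiles symmetric about the median
  sym <- post
  sym$draws[, , "beta_p"] <- matrix(c(-(50:1), 1:50), 50, 2)
  ss <- posterior_summary(sym, percentiles = c(2.5, 50, 97.5),
                          parameters = "beta_p")
  expect_equal(ss$p50, 0)
  expect_equal(ss$p2.5, -ss$p97.5)
})

test_that("exceedance_prob matches a counting oracle", {
  gen <- small_dataset()
  post <- suppressWarnings(fit_plurality(gen$data, chains = 2, burn_in = 50,
                                         draws = 50, seed = 2, max_leapfrog = 8))
  s <- as.vector(post$draws[, , "beta_p"])
  expect_equal(exceedance_prob(post, "beta_p", 0.5, "greater"),
               sum(s > 0.5) / length(s))
  expect_equal(exceedance_prob(post, "beta_p", 0.5, "less"),
               sum(s < 0.5) / length(s))
  pos <- post; pos$draws[, , "beta_p"] <- abs(s) + 0.1
  expect_equal(exceedance_prob(pos, "beta_p", 0, "greater"), 1)
  expect_error(exceedance_prob(post, "no_such", 0), "unknown parameter")
})

test_that("duplicate-seeded fits are identical and different seeds differ", {
  gen <- small_dataset()
  a <- suppressWarnings(fit_plurality(gen$data, chains = 2, burn_in = 100,
                                      draws = 100, seed = 7, max_leapfrog = 8))
  b <- suppressWarnings(fit_plurality(gen$data, chains = 2, burn_in = 100,
                                      draws = 100, seed = 7, max_leapfrog = 8))
  expect_identical(a$draws, b$draws)
  c <- suppressWarnings(fit_plurality(gen$data, chains = 2, burn_in = 100,
                                      draws = 100, seed = 8, max_leapfrog = 8))
  expect_false(identical(a$draws, c$draws))
})

test_that("a prior-only fit reproduces the prior moments", {
  empty <- plurality_data(
    data.frame(concept_id = character(0), rater_id = character(0),
               rating = integer(0)),
    data.frame(concept_id = character(0), language = character(0),
               two_handed = integer(0)),
    data.frame(concept_id = character(0), log_frequency = numeric(0)),
    scale_frequency = FALSE)
  post <- fit_plurality(empty, chains = 4, burn_in = 500, draws = 1000,
                        seed = 4, max_leapfrog = 12)
  s <- as.vector(post$draws[, , "beta_p"])
  expect_equal(sd(s), 5, tolerance = 0.1)          # N(0,5) prior
  expect_equal(mean(s), 0, tolerance = 0.4)
  sq <- as.vector(post$draws[, , "sigma_Q"])
  expect_equal(mean(sq), 5, tolerance = 0.5)       # Exp(1/5) prior mean
})

test_that("credible intervals tighten and stay calibrated as the design grows", {
  small <- gen_plurality_dataset(
    synth_config(n_concepts = 20, n_raters = 6, n_languages = 6), seed = 31)
  large <- gen_plurality_dataset(
    synth_config(n_concepts = 80, n_raters = 23, n_languages = 27), seed = 31)
  fit <- function(g) suppressWarnings(
    fit_plurality(g$data, chains = 2, burn_in = 400, draws = 400, seed = 31))
  ci <- function(post) quantile(as.vector(post$draws[, , "beta_p"]),
                                c(0.025, 0.975))
  ci_s <- ci(fit(small)); ci_l <- ci(fit(large))
  expect_lt(diff(ci_l), diff(ci_s))
  expect_true(ci_l[1] <= 2.25 && ci_l[2] >= 2.25)
})

test_that("the sampler converges and flags non-convergence honestly", {
  gen <- small_dataset()
  expect_warning(fit_plurality(gen$data, chains = 2, burn_in = 20, draws = 20,
                               seed = 1, max_leapfrog = 4),
                 "convergence|R-hat")
  post <- fit_plurality(gen$data, chains = 4, burn_in = 400, draws = 400,
                        seed = 5, rhat_warn = 1.05)
  expect_lt(max(post$rhat, na.rm = TRUE), 1.05)
  expect_true(all(c("beta_p", "sigma_Q") %in% names(post$ess)))
})
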