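# Hierarchical Bayesian model linking latent lexical plurality to integer
# 1-7 ratings and to the probability that a concept's sign is two-handed.
#
# Model (all priors weakly informative):
#   R_{c,i} ~ Normal(1 + 6 p_c + r_i, sigma_Q)          ratings, continuous
#   S_{c,l} ~ Bernoulli(plogis(beta_p p_c + beta_f f_c + alpha_L_l + alpha_C_c + a))
#   p_c ~ Uniform(0,1); r_i ~ N(0, sigma_R); alpha_L ~ N(0, sigma_L);
#   alpha_C ~ N(0, sigma_C); beta_p, beta_f, a ~ N(0,5);
#   sigma_{Q,R,L,C} ~ Exponential(rate 1/5).
# The continuous normal likelihood over integer ratings is kept deliberately
# (no ordinal link); see the methods vignette.

#' Assemble a plurality study dataset
#'
#' Validates and indexes ratings, two-handedness outcomes, and concept
#' frequencies into the structure the model consumes. Log-frequencies are
#' min-max scaled to [0,1] over the modeled concept set when
#' `scale_frequency = TRUE` (the default; set `FALSE` if the `log_frequency`
#' column is already in [0,1]).
#'
#' @param ratings data frame: `concept_id`, `rater_id`, `rating` (integers 1-7).
#' @param outcomes data frame: `concept_id`, `language`, `two_handed` (0/1).
#' @param frequencies data frame: `concept_id`, `log_frequency`.
#' @param scale_frequency min-max scale log-frequency to [0,1]?
#' @return object of class `plurality_data` with concept/rater/language level
#'   tables and 0-based index vectors.
#' @export
plurality_data <- function(ratings, outcomes, frequencies, scale_frequency = TRUE) {
  abort_if(any(!(ratings$rating %in% 1:7)), "ratings must be integers in 1..7")
  abort_if(any(!(outcomes$two_handed %in% c(0, 1))), "outcomes must be 0/1")
  concepts <- sort(unique(c(ratings$concept_id, outcomes$concept_id)))
  missing_r <- setdiff(unique(outcomes$concept_id), unique(ratings$concept_id))
  abort_if(length(missing_r) > 0,
           "concepts with outcomes but no ratings: %s",
           paste(utils::head(missing_r, 5), collapse = ", "))
  missing_f <- setdiff(concepts, frequencies$concept_id)
  abort_if(length(missing_f) > 0,
           "concepts without a frequency: %s",
           paste(utils::head(missing_f, 5), collapse = ", "))
  raters <- sort(unique(ratings$rater_id))
  languages <- sort(unique(outcomes$language))
  f <- frequencies$log_frequency[match(concepts, frequencies$concept_id)]
  if (scale_frequency) {
    rng <- range(f)
    f <- if (diff(rng) > 0) (f - rng[1]) / diff(rng) else rep(0.5, length(f))
  }
  abort_if(any(f < 0 | f > 1), "frequencies must lie in [0,1] after scaling")
  structure(list(
    concepts = concepts, raters = raters, languages = languages,
    n_concepts = length(concepts), n_raters = length(raters),
    n_languages = length(languages),
    rating_concept = match(ratings$concept_id, concepts) - 1L,
    rating_rater = match(ratings$rater_id, raters) - 1L,
    rating_value = as.numeric(ratings$rating),
    outcome_concept = match(outcomes$concept_id, concepts) - 1L,
    outcome_language = match(outcomes$language, languages) - 1L,
    outcome_value = as.numeric(outcomes$two_handed),
    frequency = as.numeric(f)),
    class = "plurality_data")
}

#' @export
print.plurality_data <- function(x, ...) {
  cat(sprintf("<plurality_data> %d concepts, %d raters, %d languages; %d ratings, %d outcomes\n",
              x$n_concepts, x$n_raters, x$n_languages,
              length(x$rating_value), length(x$outcome_value)))
  invisible(x)
}

#' Joint log-density of the plurality model
#'
#' Sum of the rating and outcome log-likelihoods and all prior log-densities
#' at a fixed parameter setting (constrained, centred scale — this is the
#' density the sampler explores, up to its reparameterization Jacobians).
#' Returns `-Inf` when any `p_c` is outside [0,1] or any sigma is
#' non-positive.
#'
#' @param params list with elements `beta_p`, `beta_f`, `a` (scalars),
#'   `r` (length n_raters), `alpha_L` (n_languages), `alpha_C` (n_concepts),
#'   `p` (n_concepts, each in [0,1]), `sigma_Q`, `sigma_R`, `sigma_L`,
#'   `sigma_C` (positive scalars).
#' @param data a [plurality_data()].
#' @return scalar log-density.
#' @export
plurality_log_joint <- function(params, data) {
  stopifnot(inherits(data, "plurality_data"))
  pr <- params
  if (any(pr$p < 0 | pr$p > 1) ||
      any(c(pr$sigma_Q, pr$sigma_R, pr$sigma_L, pr$sigma_C) <= 0)) {
    return(-Inf)
  }
  mu <- 1 + 6 * pr$p[data$rating_concept + 1L] + pr$r[data$rating_rater + 1L]
  lp <- sum(stats::dnorm(data$rating_value, mu, pr$sigma_Q, log = TRUE))
  eta <- pr$beta_p * pr$p[data$outcome_concept + 1L] +
    pr$beta_f * data$frequency[data$outcome_concept + 1L] +
    pr$alpha_L[data$outcome_language + 1L] +
    pr$alpha_C[data$outcome_concept + 1L] + pr$a
  lp <- lp + sum(data$outcome_value * eta - log1p(exp(-abs(eta))) - pmax(eta, 0))
  lp <- lp + sum(stats::dnorm(c(pr$beta_p, pr$beta_f, pr$a), 0, 5, log = TRUE))
  lp <- lp + sum(stats::dnorm(pr$r, 0, pr$sigma_R, log = TRUE))
  lp <- lp + sum(stats::dnorm(pr$alpha_L, 0, pr$sigma_L, log = TRUE))
  lp <- lp + sum(stats::dnorm(pr$alpha_C, 0, pr$sigma_C, log = TRUE))
  # p_c ~ U(0,1) contributes 0
  lp + sum(stats::dexp(c(pr$sigma_Q, pr$sigma_R, pr$sigma_L, pr$sigma_C),
                       rate = 1 / 5, log = TRUE))
}

plurality_param_names <- function(data) {
  c("beta_p", "beta_f", "a",
    if (data$n_raters) paste0("r[", data$raters, "]"),
    if (data$n_languages) paste0("alpha_L[", data$languages, "]"),
    if (data$n_concepts) paste0("alpha_C[", data$concepts, "]"),
    if (data$n_concepts) paste0("p[", data$concepts, "]"),
    "sigma_Q", "sigma_R", "sigma_L", "sigma_C")
}

#' Fit the plurality model by Hamiltonian Monte Carlo
#'
#' Runs `chains` independent HMC chains (dual-averaging step-size adaptation,
#' diagonal mass matrix estimated during warmup, jittered leapfrog length,
#' non-centred hierarchical parameterization). Split R-hat is computed for
#' every parameter; a warning is raised if any exceeds `rhat_warn`.
#'
#' @param data a [plurality_data()].
#' @param chains number of chains (default 4).
#' @param burn_in warmup iterations per chain (default 5000).
#' @param draws sampling iterations per chain (default 5000).
#' @param seed integer seed; fully determines the run.
#' @param target_accept dual-averaging target acceptance rate.
#' @param max_leapfrog leapfrog steps per iteration are drawn uniformly in
#'   `max_leapfrog/2 .. max_leapfrog` (jittered to avoid resonances).
#' @param rhat_warn convergence warning threshold (default 1.01).
#' @return object of class `plurality_posterior`: `draws` array
#'   (iterations x chains x parameters, named), per-parameter `rhat`,
#'   effective sample sizes `ess` for the headline parameters, chain
#'   geometry, and sampler diagnostics.
#' @export
fit_plurality <- function(data, chains = 4, burn_in = 5000, draws = 5000,
                          seed = 1, target_accept = 0.8, max_leapfrog = 48,
                          rhat_warn = 1.01) {
  stopifnot(inherits(data, "plurality_data"))
  abort_if(chains < 1 || draws < 2, "need >= 1 chain and >= 2 draws")
  pn <- plurality_param_names(data)
  P <- length(pn)
  arr <- array(NA_real_, dim = c(draws, chains, P),
               dimnames = list(NULL, NULL, pn))
  diag_info <- vector("list", chains)
  for (ch in seq_len(chains)) {
    res <- hmc_plurality_chain(unclass(data), as.integer(burn_in),
                               as.integer(draws), target_accept,
                               as.integer(max_leapfrog), 0.05,
                               as.integer(seed), as.integer(ch))
    arr[, ch, ] <- res$draws
    diag_info[[ch]] <- list(step_size = res$step_size,
                            mean_accept = res$mean_accept)
  }
  rhat <- apply(arr, 3, function(x) gelman_rubin(x, quiet = TRUE))
  names(rhat) <- pn
  headline <- c("beta_p", "beta_f", "a", "sigma_Q", "sigma_R", "sigma_L", "sigma_C")
  headline <- intersect(headline, pn)
  ess <- vapply(headline, function(p) ess_pooled(arr[, , p, drop = TRUE]), 0)
  post <- structure(list(draws = arr, chains = chains, burn_in = burn_in,
                         n_draws = draws, rhat = rhat, ess = ess,
                         sampler = diag_info, seed = seed,
                         parameters = pn),
                    class = "plurality_posterior")
  if (max(rhat, na.rm = TRUE) > rhat_warn) {
    warning(sprintf("convergence not reached: max R-hat = %.3f (%s) > %.2f",
                    max(rhat, na.rm = TRUE), pn[which.max(rhat)], rhat_warn),
            call. = FALSE)
  }
  post
}

#' @export
print.plurality_posterior <- function(x, ...) {
  cat(sprintf("<plurality_posterior> %d chains x %d draws (burn-in %d), %d parameters\n",
              x$chains, x$n_draws, x$burn_in, length(x$parameters)))
  cat(sprintf("  max R-hat %.4f; min headline ESS %.0f\n",
              max(x$rhat, na.rm = TRUE), min(x$ess)))
  invisible(x)
}

#' Gelman-Rubin split R-hat
#'
#' Potential scale reduction factor computed on split chains: each chain is
#' halved, within-chain variance W and between-chain variance B are combined
#' as `sqrt(((n-1)/n * W + B/n) / W)`. Zero total variance is defined as 1
#' (with a warning unless `quiet`).
#'
#' @param x matrix of samples, iterations in rows, one column per chain
#'   (at least 2 columns or >= 4 rows in 1 column).
#' @param quiet suppress the degenerate-variance warning.
#' @return scalar R-hat.
#' @export
gelman_rubin <- function(x, quiet = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  abort_if(n < 4, "need >= 4 draws per chain for split R-hat")
  half <- floor(n / 2)
  splits <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(splits); nn <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (!is.finite(W) || W == 0) {
    if (B == 0 || !is.finite(B)) {
      if (!quiet) warning("zero variance across all chains; R-hat defined as 1",
                          call. = FALSE)
      return(1.0)
    }
    return(Inf)
  }
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size of pooled chains
#'
#' Autocorrelation-based ESS following the split-chain estimator: per-chain
#' autocovariances are combined with the between-chain variance, and the
#' autocorrelation sum is truncated by Geyer's initial monotone positive
#' sequence.
#'
#' @param x matrix iterations x chains (a vector is treated as one chain).
#' @return estimated effective sample size.
#' @export
ess_pooled <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  vars <- apply(x, 2, stats::var)
  W <- mean(vars)
  means <- colMeans(x)
  B_n <- if (m > 1) stats::var(means) else 0
  var_plus <- (n - 1) / n * W + B_n
  if (!is.finite(var_plus) || var_plus == 0) return(n * m)
  max_lag <- min(n - 2, 1000)
  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(x[, j], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  })
  acov <- as.matrix(acov)
  rho <- 1 - (W - rowMeans(acov[-1, , drop = FALSE])) / var_plus
  # Geyer: pairwise sums, stop at first negative, enforce monotone decrease
  np <- floor(length(rho) / 2)
  if (np < 1) return(n * m)
  pair <- rho[2 * seq_len(np) - 1] + rho[2 * seq_len(np)]
  k <- which(pair < 0)[1]
  if (!is.na(k)) pair <- pair[seq_len(k - 1)]
  if (length(pair)) pair <- cummin(pair)
  tau <- 1 + 2 * rho[1] + 2 * sum(pair)
  max(n * m / max(tau, 1e-12), 1)
}

#' Percentile summary of a posterior
#'
#' Pooled-chain percentiles per parameter (linear interpolation), laid out
#' one row per parameter with one column per percentile.
#'
#' @param post a `plurality_posterior`.
#' @param percentiles percent points, default `c(2.5, 25, 50, 75, 97.5)`.
#' @param parameters subset of parameter names; default: headline parameters
#'   (coefficients, intercept, sigmas) followed by nothing else.
#' @return data frame: `parameter`, one numeric column per percentile, `rhat`.
#' @export
posterior_summary <- function(post, percentiles = c(2.5, 25, 50, 75, 97.5),
                              parameters = NULL) {
  stopifnot(inherits(post, "plurality_posterior"))
  if (is.null(parameters)) {
    parameters <- intersect(c("beta_p", "beta_f", "a", "sigma_C", "sigma_L",
                              "sigma_R", "sigma_Q"), post$parameters)
  }
  bad <- setdiff(parameters, post$parameters)
  abort_if(length(bad) > 0, "unknown parameter(s): %s", paste(bad, collapse = ", "))
  rows <- lapply(parameters, function(p) {
    s <- as.vector(post$draws[, , p])
    q <- stats::quantile(s, probs = percentiles / 100, type = 7, names = FALSE)
    out <- data.frame(parameter = p, stringsAsFactors = FALSE)
    for (i in seq_along(percentiles)) out[[sprintf("p%.4g", percentiles[i])]] <- q[i]
    out$rhat <- unname(post$rhat[p])
    out
  })
  do.call(rbind, rows)
}

#' Posterior exceedance probability
#'
#' Fraction of pooled samples of `parameter` beyond `threshold` in the stated
#' direction.
#'
#' @param post a `plurality_posterior`.
#' @param parameter parameter name.
#' @param threshold numeric threshold.
#' @param direction `"greater"` or `"less"`.
#' @return probability in [0,1].
#' @export
exceedance_prob <- function(post, parameter, threshold,
                            direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(inherits(post, "plurality_posterior"))
  abort_if(!parameter %in% post$parameters, "unknown parameter: %s", parameter)
  s <- as.vector(post$draws[, , parameter])
  if (direction == "greater") mean(s > threshold) else mean(s < threshold)
}
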