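# Synthetic data: keypoint videos, plurality ratings, two-handedness
# outcomes and location ratings with the statistical structure the analyses
# assume, so the whole pipeline runs and is testable without external data.
#
# Defaults mirror the study being emulated: 23 questionnaire raters, a
# modeled concept set of ~80, 27 analysed languages, and generative-model
# truths at the posterior medians reported for the original fit.

#' Default configuration for the synthetic study
#'
#' @param n_concepts,n_raters,n_languages study dimensions. Defaults 80
#'   concepts, 23 raters, 27 languages (the analysed-language count after
#'   excluding the four with unreliable video processing).
#' @param beta_p,beta_f,a,sigma_Q,sigma_R,sigma_L,sigma_C generative truths;
#'   defaults at the reported posterior medians (2.25, 0.18, 0.29, 1.52,
#'   0.83, 0.41, 1.61).
#' @param frames frames per synthetic sign video (default 40, ~1.6 s at 25 fps).
#' @param noise_sd articulation jitter SD in body units (default 0.05).
#' @param dropout_p per-frame probability that a hand's joints go undetected
#'   (default 0.05).
#' @param seed integer seed driving all generation.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_concepts = 80, n_raters = 23, n_languages = 27,
                         beta_p = 2.25, beta_f = 0.18, a = 0.29,
                         sigma_Q = 1.52, sigma_R = 0.83, sigma_L = 0.41,
                         sigma_C = 1.61, frames = 40, noise_sd = 0.05,
                         dropout_p = 0.05, seed = 1) {
  abort_if(n_concepts < 1 || n_raters < 0 || n_languages < 1,
           "invalid study dimensions")
  abort_if(dropout_p < 0 || dropout_p > 1, "dropout_p must be in [0,1]")
  structure(list(n_concepts = n_concepts, n_raters = n_raters,
                 n_languages = n_languages,
                 beta_p = beta_p, beta_f = beta_f, a = a,
                 sigma_Q = sigma_Q, sigma_R = sigma_R, sigma_L = sigma_L,
                 sigma_C = sigma_C, frames = frames, noise_sd = noise_sd,
                 dropout_p = dropout_p, seed = seed),
            class = "synth_config")
}

#' Generate a plurality study dataset from the generative model
#'
#' Draws `p_c ~ U(0,1)`, `f_c ~ U(0,1)`, rater biases `r_i ~ N(0, sigma_R)`,
#' ratings `R_{c,i} ~ N(1 + 6 p_c + r_i, sigma_Q)` rounded and clamped to the
#' observable 1..7 scale, language/concept effects `alpha ~ N(0, sigma)`, and
#' outcomes `S_{c,l} ~ Bernoulli(plogis(beta_p p_c + beta_f f_c + alpha_L +
#' alpha_C + a))`. The rounding/clamping mismatch with the continuous fitted
#' likelihood is intentional (it is the observable scale).
#'
#' @param cfg a [synth_config()].
#' @param seed overrides `cfg$seed` when given.
#' @return list: `data` (a [plurality_data()]), `truth` (all generative
#'   parameters), and the raw `ratings`, `outcomes`, `frequencies` tables.
#' @export
gen_plurality_dataset <- function(cfg = synth_config(), seed = NULL) {
  seed <- seed %||% cfg$seed
  with_local_seed(seed, {
    C <- cfg$n_concepts; I <- cfg$n_raters; L <- cfg$n_languages
    concepts <- sprintf("c%03d", seq_len(C))
    raters <- sprintf("r%02d", seq_len(I))
    languages <- sprintf("lang%02d", seq_len(L))
    p <- stats::runif(C)
    f <- stats::runif(C)
    r <- if (I) stats::rnorm(I, 0, cfg$sigma_R) else numeric(0)
    alpha_L <- stats::rnorm(L, 0, cfg$sigma_L)
    alpha_C <- stats::rnorm(C, 0, cfg$sigma_C)
    ratings <- if (I) {
      g <- expand.grid(ci = seq_len(C), ii = seq_len(I))
      raw <- stats::rnorm(nrow(g), 1 + 6 * p[g$ci] + r[g$ii], cfg$sigma_Q)
      data.frame(concept_id = concepts[g$ci], rater_id = raters[g$ii],
                 rating = pmin(pmax(round(raw), 1), 7),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(concept_id = character(0), rater_id = character(0),
                 rating = integer(0))
    }
    g <- expand.grid(ci = seq_len(C), li = seq_len(L))
    eta <- cfg$beta_p * p[g$ci] + cfg$beta_f * f[g$ci] +
      alpha_L[g$li] + alpha_C[g$ci] + cfg$a
    outcomes <- data.frame(concept_id = concepts[g$ci],
                           language = languages[g$li],
                           two_handed = stats::rbinom(nrow(g), 1, stats::plogis(eta)),
                           stringsAsFactors = FALSE)
    frequencies <- data.frame(concept_id = concepts, log_frequency = f,
                              stringsAsFactors = FALSE)
    truth <- list(beta_p = cfg$beta_p, beta_f = cfg$beta_f, a = cfg$a,
                  sigma_Q = cfg$sigma_Q, sigma_R = cfg$sigma_R,
                  sigma_L = cfg$sigma_L, sigma_C = cfg$sigma_C,
                  p = stats::setNames(p, concepts),
                  r = stats::setNames(r, raters),
                  alpha_L = stats::setNames(alpha_L, languages),
                  alpha_C = stats::setNames(alpha_C, concepts),
                  f = stats::setNames(f, concepts))
    data <- plurality_data(ratings, outcomes, frequencies, scale_frequency = FALSE)
    list(data = data, truth = truth, ratings = ratings, outcomes = outcomes,
         frequencies = frequencies)
  })
}

# Static synthetic torso in pixel coordinates (y down): a 2x-scale signer
# centred at nose (320, 160), shoulder width 120 px, nose-neck 80 px.
synth_torso <- function() {
  list(nose = c(320, 160), neck = c(320, 240),
       left_shoulder = c(380, 240), right_shoulder = c(260, 240),
       shoulder_dist = 120, noseneck_dist = 80)
}

# body units -> raw pixels under the synthetic torso geometry
synth_body_to_px <- function(pt) {
  tor <- synth_torso()
  c(tor$nose[1] + pt[1] * tor$shoulder_dist,
    tor$nose[2] + pt[2] * tor$noseneck_dist)
}

#' Generate one synthetic sign video
#'
#' Builds a pose-keypoint sequence whose extrapolated, normalized hand
#' positions orbit a target body location with Gaussian jitter. Two-handed
#' signs move both hands on mirrored orbits; one-handed signs keep the
#' non-dominant (left) hand resting at hip level, so the path-length ratio
#' exceeds 3 by construction when `noise_sd` is small. Each hand's
#' elbow/wrist pair independently drops out per frame with probability
#' `dropout_p` (confidence 0).
#'
#' @param video_id,concept_id,language identifiers (metadata; concept and
#'   language travel with the returned sequence's attributes).
#' @param target length-2 target location in body units (x right, y down,
#'   nose at origin).
#' @param handedness `"one"` or `"two"`.
#' @param frames number of frames.
#' @param noise_sd articulation jitter SD in body units.
#' @param dropout_p per-frame per-hand dropout probability.
#' @param orbit_radius radius of the circular articulation orbit in body
#'   units (default 0.15).
#' @param seed integer seed.
#' @return a [frame_pose_sequence()] (raw pixel coordinates).
#' @export
gen_sign_video <- function(video_id, target, handedness = c("two", "one"),
                           frames = 40, noise_sd = 0.05, dropout_p = 0,
                           orbit_radius = 0.15, seed = 1,
                           concept_id = "", language = "") {
  handedness <- match.arg(handedness)
  tor <- synth_torso()
  with_local_seed(seed, {
    rows <- list()
    rest <- c(0.45, 3.2)              # idle right-side-of-body hip position
    for (t in seq_len(frames)) {
      ang <- 2 * pi * (t - 1) / max(frames - 1, 1)
      jitter <- function() stats::rnorm(2, 0, noise_sd)
      # dominant (right) hand orbits the target
      h_r <- target + orbit_radius * c(cos(ang), sin(ang)) + jitter()
      h_l <- if (handedness == "two") {
        c(-h_r[1], h_r[2]) + jitter()      # mirrored orbit
      } else {
        c(-rest[1], rest[2]) + stats::rnorm(2, 0, noise_sd / 50)
      }
      joints <- list(nose = tor$nose, neck = tor$neck,
                     left_shoulder = tor$left_shoulder,
                     right_shoulder = tor$right_shoulder)
      # forearm points straight up (image y down): hand = wrist + 0.5*(wrist-elbow)
      fore <- c(0, 60)
      for (side in c("left", "right")) {
        h_px <- synth_body_to_px(if (side == "left") h_l else h_r)
        wrist <- h_px + fore / 2    # so extrapolation lands exactly on h_px
        elbow <- wrist + fore
        conf <- if (stats::runif(1) < dropout_p) 0 else 0.9
        joints[[paste0(side, "_wrist")]] <- c(wrist, conf)
        joints[[paste0(side, "_elbow")]] <- c(elbow, conf)
      }
      rows[[t]] <- data.frame(
        frame = t - 1L,
        joint = names(joints),
        x = vapply(joints, `[`, 0, 1),
        y = vapply(joints, `[`, 0, 2),
        confidence = vapply(joints, function(j) if (length(j) > 2) j[3] else 1, 0),
        stringsAsFactors = FALSE)
    }
    seq <- frame_pose_sequence(video_id, do.call(rbind, rows), fps = 25)
    attr(seq, "concept_id") <- concept_id
    attr(seq, "language") <- language
    seq
  })
}

#' Generate jittered location ratings for target boxes
#'
#' For each concept target box and each of `M` raters, the box centre and
#' log-extent are perturbed with Gaussian jitter; the mirrored twin is added
#' by construction of [location_rating()].
#'
#' @param targets named list: concept_id -> c(x_min, x_max, y_min, y_max) in
#'   body units.
#' @param M raters per concept (default 10, the size of the original
#'   location-rating panel).
#' @param jitter_sd SD of the centre jitter in body units (log-extent jitter
#'   uses `jitter_sd` as well); 0 gives M identical ratings.
#' @param seed integer seed.
#' @return list of [location_rating()].
#' @export
gen_location_ratings <- function(targets, M = 10, jitter_sd = 0.05, seed = 1) {
  with_local_seed(seed, {
    out <- list()
    for (cid in names(targets)) {
      b <- targets[[cid]]
      cx <- mean(b[1:2]); cy <- mean(b[3:4])
      wx <- diff(b[1:2]); wy <- diff(b[3:4])
      for (m in seq_len(M)) {
        ctr <- c(cx, cy) + stats::rnorm(2, 0, jitter_sd)
        ext <- c(wx, wy) * exp(stats::rnorm(2, 0, jitter_sd))
        out[[length(out) + 1L]] <- location_rating(
          cid, sprintf("lr%02d", m),
          ctr[1] - ext[1] / 2, ctr[1] + ext[1] / 2,
          ctr[2] - ext[2] / 2, ctr[2] + ext[2] / 2)
      }
    }
    out
  })
}
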