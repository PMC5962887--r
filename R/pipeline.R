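# End-to-end orchestration: simulate a dataset to disk, run Study 1
# (handedness + plurality model) and Study 2 (heatmaps + iconicity) from a
# declarative JSON config, with seeds threaded everywhere and a manifest of
# output hashes for reproducibility checks.

#' Default run configuration
#'
#' Every threshold of the analysis is a named key defaulting to the study's
#' stated value: classifier ratio 3 and 10-frame minimum, 20% trajectory
#' trim, heatmap blur factor 0.03125, R-hat warning threshold 1.01,
#' 4 chains x (5000 + 5000) iterations.
#'
#' @param data_dir directory holding the input files (as written by
#'   [simulate_dataset()]).
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param ... overrides for any default key.
#' @return list of class `run_config`.
#' @export
run_config <- function(data_dir, out_dir, seed = 1, ...) {
  cfg <- list(
    data_dir = data_dir, out_dir = out_dir, seed = seed,
    confidence_floor = 0.1,
    exclude_languages = character(0),
    classifier = list(ratio_threshold = 3, min_frames = 10,
                      min_frames_rule = "either"),
    model = list(chains = 4, burn_in = 5000, draws = 5000, rhat_warn = 1.01),
    heatmap = list(resolution_x = 128, blur_factor = 0.03125, png = FALSE),
    trim_fraction = 0.2)
  dots <- list(...)
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      utils::modifyList(cfg[[nm]], dots[[nm]])
    } else dots[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with at least `data_dir` and `out_dir`.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  abort_if(is.null(obj$data_dir) || is.null(obj$out_dir),
           "config must name data_dir and out_dir")
  do.call(run_config, obj)
}

manifest_write <- function(out_dir, stage, cfg, files) {
  files <- files[file.exists(files)]
  manifest <- list(stage = stage, config = unclass(cfg),
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(files)), basename(files))))
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' Simulate a full study dataset to disk
#'
#' Generates the plurality dataset, one keypoint video per (concept,
#' language) outcome whose handedness realizes the sampled outcome, concept
#' target locations, and location ratings; writes `concepts.csv`,
#' `ratings.csv`, `frequencies.csv`, `location_ratings.csv`, `videos.csv`,
#' `targets.csv`, a `keypoints/` directory of per-video JSON files, and
#' `truth.json` with the generative parameters.
#'
#' @param cfg a [synth_config()].
#' @param out_dir output directory (created if needed).
#' @param location_raters raters per concept for location ratings (default 10).
#' @return invisibly, the list of written files.
#' @export
simulate_dataset <- function(cfg = synth_config(), out_dir,
                             location_raters = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kp_dir <- file.path(out_dir, "keypoints")
  dir.create(kp_dir, showWarnings = FALSE)
  gen <- gen_plurality_dataset(cfg)
  d <- gen$data

  utils::write.csv(gen$ratings, file.path(out_dir, "ratings.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(gen$frequencies, file.path(out_dir, "frequencies.csv"),
                   row.names = FALSE, quote = FALSE)
  concepts <- data.frame(concept_id = d$concepts,
                         english_name = d$concepts,
                         category = "synthetic",
                         is_single_english_word = TRUE,
                         in_swadesh_core = TRUE,
                         stringsAsFactors = FALSE)
  utils::write.csv(concepts, file.path(out_dir, "concepts.csv"),
                   row.names = FALSE, quote = FALSE)

  # concept target locations in signing space (upper body, both sides)
  targets_df <- with_local_seed(cfg$seed + 1L, {
    data.frame(concept_id = d$concepts,
               x = stats::runif(d$n_concepts, -0.8, 0.8),
               y = stats::runif(d$n_concepts, -0.5, 3.0),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(targets_df, file.path(out_dir, "targets.csv"),
                   row.names = FALSE, quote = FALSE)

  targets <- lapply(seq_len(nrow(targets_df)), function(i) {
    c(targets_df$x[i] - 0.25, targets_df$x[i] + 0.25,
      targets_df$y[i] - 0.25, targets_df$y[i] + 0.25)
  })
  names(targets) <- targets_df$concept_id
  lr <- gen_location_ratings(targets, M = location_raters,
                             jitter_sd = 0.05, seed = cfg$seed + 2L)
  lr_df <- do.call(rbind, lapply(lr, function(r) {
    data.frame(concept_id = r$concept_id, rater_id = r$rater_id,
               x_min = r$rect[["x_min"]], x_max = r$rect[["x_max"]],
               y_min = r$rect[["y_min"]], y_max = r$rect[["y_max"]],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(lr_df, file.path(out_dir, "location_ratings.csv"),
                   row.names = FALSE, quote = FALSE)

  videos <- gen$outcomes
  videos$video_id <- sprintf("v_%s_%s", videos$concept_id, videos$language)
  videos$file <- file.path("keypoints", paste0(videos$video_id, ".json"))
  for (i in seq_len(nrow(videos))) {
    cid <- videos$concept_id[i]
    tgt <- unlist(targets_df[targets_df$concept_id == cid, c("x", "y")])
    seq <- gen_sign_video(videos$video_id[i], target = tgt,
                          handedness = if (videos$two_handed[i] == 1) "two" else "one",
                          frames = cfg$frames, noise_sd = cfg$noise_sd,
                          dropout_p = cfg$dropout_p,
                          seed = cfg$seed + 100L + i,
                          concept_id = cid, language = videos$language[i])
    write_keypoints(seq, file.path(out_dir, videos$file[i]))
  }
  utils::write.csv(videos[c("video_id", "concept_id", "language", "file")],
                   file.path(out_dir, "videos.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(lapply(gen$truth, unclass),
                       file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(file.path(out_dir, c("ratings.csv", "frequencies.csv",
                                  "concepts.csv", "targets.csv",
                                  "location_ratings.csv", "videos.csv",
                                  "truth.json")),
             file.path(out_dir, videos$file))
  manifest_write(out_dir, "simulate", cfg, files)
  invisible(files)
}

# Load and normalize every video listed in <data_dir>/videos.csv
load_trajectories <- function(cfg) {
  videos <- utils::read.csv(file.path(cfg$data_dir, "videos.csv"),
                            stringsAsFactors = FALSE)
  trajs <- vector("list", nrow(videos))
  for (i in seq_len(nrow(videos))) {
    seq <- read_keypoints(file.path(cfg$data_dir, videos$file[i]),
                          conf_floor = cfg$confidence_floor)
    trajs[[i]] <- normalize_sequence(seq, concept_id = videos$concept_id[i],
                                     language = videos$language[i])
  }
  trajs
}

#' Run Study 1: handedness calls, vocabulary proportions, plurality model
#'
#' Classifies every video, writes `calls.csv` and `proportions.csv`
#' (languages on `exclude_languages` stay in the proportion tables but are
#' dropped from model fitting), fits the plurality model on the classified
#' outcomes joined with the rating and frequency tables, and writes
#' `posterior_summary.csv` and `exceedance.csv`.
#'
#' @param cfg a [run_config()].
#' @return list with `calls`, `proportions`, `posterior`, `summary`,
#'   `exceedance`, `manifest`.
#' @export
run_study1 <- function(cfg) {
  for (f in c("videos.csv", "concepts.csv", "ratings.csv", "frequencies.csv")) {
    abort_if(!file.exists(file.path(cfg$data_dir, f)),
             "missing input file: %s", file.path(cfg$data_dir, f))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- read_tables(concepts = file.path(cfg$data_dir, "concepts.csv"),
                      ratings = file.path(cfg$data_dir, "ratings.csv"),
                      frequencies = file.path(cfg$data_dir, "frequencies.csv"))
  trajs <- load_trajectories(cfg)
  calls <- do.call(rbind, lapply(trajs, classify_handedness,
                                 ratio_threshold = cfg$classifier$ratio_threshold,
                                 min_frames = cfg$classifier$min_frames,
                                 min_frames_rule = cfg$classifier$min_frames_rule))
  utils::write.csv(calls, file.path(cfg$out_dir, "calls.csv"), row.names = FALSE)

  props <- rbind(
    vocabulary_proportions(calls, tabs$concepts, "per_language", "core"),
    vocabulary_proportions(calls, tabs$concepts, "per_language", "extended"))
  utils::write.csv(props, file.path(cfg$out_dir, "proportions.csv"),
                   row.names = FALSE)

  model_calls <- calls[calls$call != "discarded" &
                         !(calls$language %in% cfg$exclude_languages), ]
  outcomes <- data.frame(concept_id = model_calls$concept_id,
                         language = model_calls$language,
                         two_handed = as.integer(model_calls$call == "two_handed"),
                         stringsAsFactors = FALSE)
  keep <- outcomes$concept_id %in% unique(tabs$ratings$concept_id)
  pdat <- plurality_data(tabs$ratings, outcomes[keep, , drop = FALSE],
                         tabs$frequencies)
  post <- fit_plurality(pdat, chains = cfg$model$chains,
                        burn_in = cfg$model$burn_in, draws = cfg$model$draws,
                        seed = cfg$seed, rhat_warn = cfg$model$rhat_warn)
  summ <- posterior_summary(post)
  utils::write.csv(summ, file.path(cfg$out_dir, "posterior_summary.csv"),
                   row.names = FALSE)
  exc <- data.frame(
    parameter = c("beta_p", "beta_p", "beta_f"),
    threshold = c(0, 1, 0),
    direction = c("greater", "greater", "less"),
    probability = c(exceedance_prob(post, "beta_p", 0, "greater"),
                    exceedance_prob(post, "beta_p", 1, "greater"),
                    exceedance_prob(post, "beta_f", 0, "less")))
  utils::write.csv(exc, file.path(cfg$out_dir, "exceedance.csv"),
                   row.names = FALSE)
  manifest <- manifest_write(cfg$out_dir, "study1", cfg,
                             file.path(cfg$out_dir,
                                       c("calls.csv", "proportions.csv",
                                         "posterior_summary.csv", "exceedance.csv")))
  list(calls = calls, proportions = props, posterior = post, summary = summ,
       exceedance = exc, manifest = manifest)
}

#' Run Study 2: heatmaps and location iconicity
#'
#' Builds per-concept activity grids (written as dense matrices; PNGs when
#' `cfg$heatmap$png` and a PNG device exist), and the iconicity table
#' (concept, mean similarity, vocabulary percentile, all-signs baseline mean
#' and SD) for all concepts present in the location-rating table.
#'
#' @param cfg a [run_config()].
#' @return list with `grids`, `iconicity` (the table), `manifest`.
#' @export
run_study2 <- function(cfg) {
  for (f in c("videos.csv", "location_ratings.csv")) {
    abort_if(!file.exists(file.path(cfg$data_dir, f)),
             "missing input file: %s", file.path(cfg$data_dir, f))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- read_tables(location_ratings = file.path(cfg$data_dir,
                                                   "location_ratings.csv"))
  trajs <- load_trajectories(cfg)
  by_concept <- split(trajs, vapply(trajs, function(t) t$concept_id, ""))
  ratings <- location_ratings_from_table(tabs$location_ratings)
  rated_concepts <- unique(tabs$location_ratings$concept_id)

  grids <- list()
  rows <- list()
  for (cid in rated_concepts) {
    if (is.null(by_concept[[cid]])) {
      warning(sprintf("concept '%s' has no signs; skipped", cid), call. = FALSE)
      next
    }
    grid <- build_heatmap(by_concept[[cid]],
                          resolution_x = cfg$heatmap$resolution_x,
                          blur_sigma = cfg$heatmap$blur_factor *
                            cfg$heatmap$resolution_x)
    grids[[cid]] <- grid
    write_grid(grid, file.path(cfg$out_dir, paste0("heatmap_", cid)))
    if (isTRUE(cfg$heatmap$png) && capabilities("png")) {
      write_heatmap_png(grid, file.path(cfg$out_dir, paste0("heatmap_", cid, ".png")))
    }
    cr <- ratings[vapply(ratings, function(r) r$concept_id == cid, TRUE)]
    res <- concept_iconicity(by_concept[[cid]], cr, vocabulary = by_concept,
                             concept_id = cid,
                             trim_fraction = cfg$trim_fraction)
    rows[[cid]] <- data.frame(concept = cid,
                              mean_sim = round(res$mean_score, 2),
                              percentile = res$percentile,
                              all_mean = round(res$baseline_mean, 2),
                              all_sd = round(res$baseline_sd, 2))
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.csv(tab, file.path(cfg$out_dir, "table_iconicity.csv"),
                   row.names = FALSE)
  manifest <- manifest_write(
    cfg$out_dir, "study2", cfg,
    c(file.path(cfg$out_dir, "table_iconicity.csv"),
      unlist(lapply(names(grids), function(cid) {
        file.path(cfg$out_dir, paste0("heatmap_", cid, c("_left.csv", "_right.csv")))
      }))))
  list(grids = grids, iconicity = tab, manifest = manifest)
}
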