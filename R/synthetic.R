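#' Configuration for the synthetic lifespan cohort generator
#'
#' Defaults emulate the study conditions the pipeline was designed around: a
#' lifespan sample of 266 adults aged 20-89 with at least 30 per decade;
#' seven fMRI runs in four task families with the study's frame counts; a
#' log-normal motion propensity rising with age (targeting an age-motion
#' correlation near 0.44 and cross-run rank correlations in 0.70-0.90);
#' two ordinal raters coupled to motion with inter-rater kappa near 0.48; and
#' thickness maps with age-related thinning plus a regionally confined motion
#' bias. See the methods vignette for the calibration of each value.
#'
#' @param n_participants Sample size; default 266.
#' @param age_range Years; default `c(20, 89)`.
#' @param per_decade_min Minimum participants per decade; default 30.
#' @param runs Tibble `task`, `run_id`, `n_frames`; defaults to the
#'   seven-run session (VV1/VV2 202, words 231, scenes1-3 171, rest 154).
#' @param motion List: `intercept` and `age_slope` (per year) on log mean-FD,
#'   `between_run_sd` (between-participant residual SD of log propensity),
#'   `within_run_sd` (run-to-run SD of log FD-bar around the propensity).
#' @param rating List: `latent_noise_sd` (T1w artifact severity around the
#'   motion propensity), `rater_thresholds` (list of two cut points per
#'   rater on the latent scale: below the first is "pass", above the second
#'   "fail"), `rater_noise_sd`.
#' @param thickness List: `n_vertices`, `n_parcels`, `baseline_mean` (mm),
#'   `age_slope_mean`/`age_slope_sd` (mm/year per vertex), `gender_effect`
#'   (mm added for the second gender level), `motion_beta` (mm per unit of
#'   latent severity, applied only in the bias region), `bias_fraction`
#'   (share of vertices carrying bias, grouped into contiguous parcels),
#'   `subject_sd` (mm; a per-participant global offset shared across
#'   vertices, representing anatomical individual differences that do not
#'   average away over the surface), `residual_sd` (mm; independent
#'   per-vertex noise).
#' @param prop_female Probability of gender "F"; default 169/266.
#' @param radius Rotation-to-mm radius used when synthesising realignment
#'   increments; default 50.
#' @return A list of class `mf_config`.
#' @export
cohort_config <- function(n_participants = 266,
                          age_range = c(20, 89),
                          per_decade_min = 30,
                          runs = NULL,
                          motion = list(intercept = -2.67, age_slope = 0.0101,
                                        between_run_sd = 0.40,
                                        within_run_sd = 0.2236),
                          rating = list(latent_noise_sd = 0.30,
                                        rater_thresholds = list(
                                          rater1 = c(-1.80, -1.00),
                                          rater2 = c(-1.80, -1.00)),
                                        rater_noise_sd = 0.30),
                          thickness = list(n_vertices = 2000,
                                           n_parcels = 148,
                                           baseline_mean = 2.5,
                                           age_slope_mean = -0.005,
                                           age_slope_sd = 0.002,
                                           gender_effect = 0.02,
                                           motion_beta = -0.12,
                                           bias_fraction = 0.20,
                                           subject_sd = 0.085,
                                           residual_sd = 0.15),
                          prop_female = 169 / 266,
                          radius = 50) {
  if (is.null(runs))
    runs <- tibble(
      task = c("VV", "VV", "words", "scenes", "scenes", "scenes", "rest"),
      run_id = c("VV1", "VV2", "words", "scenes1", "scenes2", "scenes3",
                 "rest"),
      n_frames = c(202L, 202L, 231L, 171L, 171L, 171L, 154L))
  stopifnot(motion$between_run_sd >= 0, motion$within_run_sd >= 0,
            rating$latent_noise_sd >= 0, rating$rater_noise_sd >= 0,
            thickness$residual_sd >= 0,
            thickness$bias_fraction >= 0, thickness$bias_fraction <= 1)
  for (th in rating$rater_thresholds)
    if (length(th) != 2 || diff(th) <= 0)
      abort("each rater needs two ordered thresholds")
  structure(list(n_participants = n_participants, age_range = age_range,
                 per_decade_min = per_decade_min, runs = runs,
                 motion = motion, rating = rating, thickness = thickness,
                 prop_female = prop_female, radius = radius),
            class = "mf_config")
}

#' Generate a complete synthetic cohort
#'
#' Ages satisfy the per-decade minimum; each participant gets a log-normal
#' motion propensity increasing with age; each run gets a target mean FD
#' around that propensity, realised as six random-walk realignment series
#' whose increments are scaled so the computed mean FD equals the target;
#' two raters threshold a noisy latent artifact severity into pass/warn/fail;
#' and thickness at vertex v is
#' `baseline + subject_offset + age_slope_v * age + gender_effect * male +
#' motion_beta * severity * [v in bias region] + noise`.
#'
#' @param config From [cohort_config()].
#' @param seed Integer seed; the cohort is fully reproducible from
#'   (config, seed).
#' @return Object of class `mf_cohort`: `cohort`, `manifest`, `realignment`,
#'   `ratings`, `thickness` and a `truth` list of generating parameters and
#'   per-participant latents.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  set.seed(sub_seed(seed, "generate_cohort"))
  n <- config$n_participants
  lo <- config$age_range[1]; hi <- config$age_range[2]
  decades <- seq(floor(lo / 10) * 10, floor(hi / 10) * 10, by = 10)
  if (length(decades) * config$per_decade_min > n)
    abort(sprintf("per-decade minimum of %d infeasible for n = %d over %d decades",
                  config$per_decade_min, n, length(decades)))
  ages <- c(
    unlist(lapply(decades, function(d)
      runif(config$per_decade_min, max(d, lo), min(d + 10, hi)))),
    runif(n - length(decades) * config$per_decade_min, lo, hi))
  ages <- sample(ages)    # shuffle so IDs carry no age order
  ids <- sprintf("sub%04d", seq_len(n))
  gender <- ifelse(runif(n) < config$prop_female, "F", "M")
  cohort <- tibble(participant_id = ids, age = ages,
                   gender = factor(gender, levels = c("F", "M")))

  mo <- config$motion
  propensity <- mo$intercept + mo$age_slope * ages +
    rnorm(n, 0, mo$between_run_sd)

  runs <- config$runs
  manifest <- tidyr::crossing(participant_id = ids, runs) %>%
    select(all_of(c("participant_id", "task", "run_id", "n_frames"))) %>%
    arrange(match(.data$participant_id, ids), match(.data$run_id, runs$run_id))

  realign <- vector("list", nrow(runs))
  run_targets <- matrix(NA_real_, n, nrow(runs),
                        dimnames = list(ids, runs$run_id))
  for (j in seq_len(nrow(runs))) {
    Tn <- runs$n_frames[j]
    target <- exp(propensity + rnorm(n, 0, mo$within_run_sd))
    run_targets[, j] <- target
    # random-walk increments in displacement units, rescaled per participant
    # so the run's computed mean FD equals its target
    E <- matrix(rnorm(n * (Tn - 1) * 6), ncol = 6)
    g <- rep(seq_len(n), each = Tn - 1)
    fd_raw <- rowSums(abs(E))
    mean_raw <- as.numeric(rowsum(fd_raw, g)) / (Tn - 1)
    E <- E * (target / mean_raw)[g]
    pos <- apply(E, 2, function(col) stats::ave(col, g, FUN = cumsum))
    full <- matrix(0, n * Tn, 6)
    keep <- rep(seq_len(Tn), n) != 1
    full[keep, ] <- pos
    realign[[j]] <- tibble(
      participant_id = rep(ids, each = Tn),
      run_id = runs$run_id[j],
      frame = rep(seq_len(Tn), n),
      trans_x = full[, 1], trans_y = full[, 2], trans_z = full[, 3],
      rot_x = full[, 4] / config$radius, rot_y = full[, 5] / config$radius,
      rot_z = full[, 6] / config$radius)
  }
  realignment <- bind_rows(realign)

  ra <- config$rating
  severity <- propensity + rnorm(n, 0, ra$latent_noise_sd)
  cut3 <- function(x, th) c("pass", "warn", "fail")[1 + (x >= th[1]) + (x >= th[2])]
  ratings <- bind_rows(lapply(names(ra$rater_thresholds), function(rr) {
    x <- severity + rnorm(n, 0, ra$rater_noise_sd)
    tibble(participant_id = ids, rater_id = rr,
           rating = as_rating(cut3(x, ra$rater_thresholds[[rr]])))
  }))

  tc <- config$thickness
  nv <- tc$n_vertices
  parcel_map <- rep(seq_len(tc$n_parcels), length.out = nv)
  parcel_map <- sort(parcel_map)
  n_bias_parcels <- max(1, round(tc$bias_fraction * tc$n_parcels))
  start <- sample.int(tc$n_parcels - n_bias_parcels + 1, 1)
  bias_parcels <- seq(start, start + n_bias_parcels - 1)
  bias_vertices <- which(parcel_map %in% bias_parcels)
  age_slope_v <- rnorm(nv, tc$age_slope_mean, tc$age_slope_sd)
  male <- as.numeric(cohort$gender == "M")
  beta_v <- ifelse(seq_len(nv) %in% bias_vertices, tc$motion_beta, 0)
  subject_offset <- rnorm(n, 0, tc$subject_sd %||% 0)
  thick <- tc$baseline_mean + subject_offset +
    outer(ages, age_slope_v) +
    outer(male * tc$gender_effect, rep(1, nv)) +
    outer(severity, beta_v) +
    matrix(rnorm(n * nv, 0, tc$residual_sd), n, nv)
  rownames(thick) <- ids
  thickness <- new_thickness(thick, parcel_map)

  structure(list(
    cohort = cohort,
    manifest = manifest %>% select(-all_of("n_frames")),
    realignment = realignment,
    ratings = ratings,
    thickness = thickness,
    truth = list(config = config, seed = seed,
                 propensity = setNames(propensity, ids),
                 severity = setNames(severity, ids),
                 subject_offset = setNames(subject_offset, ids),
                 run_targets = run_targets,
                 age_slope_v = age_slope_v,
                 bias_vertices = bias_vertices,
                 bias_parcels = bias_parcels)
  ), class = "mf_cohort")
}

#' @export
print.mf_cohort <- function(x, ...) {
  cat(sprintf("<mf_cohort> %d participants, %d runs/participant, %d vertices (seed %d)\n",
              nrow(x$cohort), nrow(x$truth$config$runs),
              ncol(x$thickness$thickness), x$truth$seed))
  invisible(x)
}

#' Ground-truth report for a synthetic cohort
#'
#' @param cohort `mf_cohort` object.
#' @return List with `coefficients` (the generating parameter values),
#'   `participants` (per-participant latents) and `bias_vertices`.
#' @export
truth_report <- function(cohort) {
  cfg <- cohort$truth$config
  list(
    coefficients = list(motion = cfg$motion, rating = cfg$rating,
                        thickness = cfg$thickness, radius = cfg$radius,
                        seed = cohort$truth$seed),
    participants = tibble(
      participant_id = names(cohort$truth$propensity),
      propensity = unname(cohort$truth$propensity),
      severity = unname(cohort$truth$severity),
      subject_offset = unname(cohort$truth$subject_offset)),
    run_targets = cohort$truth$run_targets,
    bias_vertices = cohort$truth$bias_vertices
  )
}

#' Write a synthetic cohort as the pipeline's input files
#'
#' Emits exactly the formats the readers consume: one realignment text file
#' per (participant, run) in the chosen dialect, `manifest.csv` (with a
#' `file` column), `ratings.csv`, `covariates.csv`, `thickness.tsv`,
#' `parcels.txt` and `truth.json`.
#'
#' @param cohort `mf_cohort` object.
#' @param dir Output directory (created if needed).
#' @param dialect Realignment column order to write.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir,
                         dialect = c("spm_order", "mcflirt_order")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rp_dir <- file.path(dir, "realignment")
  dir.create(rp_dir, showWarnings = FALSE)
  man <- cohort$manifest %>%
    mutate(file = file.path("realignment",
                            sprintf("rp_%s_%s.txt", .data$participant_id,
                                    .data$run_id)))
  by_run <- split(cohort$realignment,
                  paste(cohort$realignment$participant_id,
                        cohort$realignment$run_id, sep = "\r"))
  for (s in by_run) {
    write_realignment(
      s, file.path(dir, sprintf("realignment/rp_%s_%s.txt",
                                s$participant_id[1], s$run_id[1])),
      dialect = dialect)
  }
  readr::write_csv(man, file.path(dir, "manifest.csv"))
  readr::write_csv(cohort$ratings %>%
                     mutate(rating = as.character(.data$rating)),
                   file.path(dir, "ratings.csv"))
  readr::write_csv(cohort$cohort, file.path(dir, "covariates.csv"))
  write_thickness(cohort$thickness, file.path(dir, "thickness.tsv"),
                  file.path(dir, "parcels.txt"))
  tr <- truth_report(cohort)
  tr$run_targets <- as.data.frame(tr$run_targets)
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}
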