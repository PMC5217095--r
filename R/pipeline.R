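#' Default pipeline parameters
#'
#' @param radius Rotation-to-mm sphere radius (mm).
#' @param stat Run summary statistic, `"mean"` or `"median"`.
#' @param k High-mover SD multiplier.
#' @param n_perm_stability,n_perm_overlap,n_perm_esc Permutation counts for
#'   the stability matrix, the overlap analysis and the effect-size-change
#'   test.
#' @param n_boot Matched-bootstrap draws.
#' @param n_groups_envelope Leave-one-out control cohorts for the envelope.
#' @param pool_size Matched-pool size.
#' @param fdr_alpha FDR significance threshold used in reports.
#' @param seed Master seed; each randomized stage derives its own sub-seed
#'   from it by stage name, so adding a stage never perturbs the others.
#' @return Named list.
#' @export
pipeline_params <- function(radius = 50, stat = "mean", k = 1.5,
                            n_perm_stability = 2000, n_perm_overlap = 10000,
                            n_perm_esc = 1000, n_boot = 10000,
                            n_groups_envelope = 200, pool_size = 10,
                            fdr_alpha = 0.05, seed = 1) {
  stopifnot(n_perm_stability >= 1, n_perm_overlap >= 1, n_perm_esc >= 1,
            n_boot >= 1, n_groups_envelope >= 1)
  as.list(environment())
}

#' Read a pipeline configuration file
#'
#' YAML with two blocks: `inputs` (paths: `manifest`, `ratings`,
#' `covariates`, optional `thickness`, `parcels`, and `data_dir` the paths
#' are relative to) and `params` (any of [pipeline_params()]'s arguments),
#' plus optional `out_dir`.
#'
#' @param path YAML file.
#' @return List with `inputs`, `params`, `out_dir`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- do.call(pipeline_params, cfg$params %||% list())
  list(inputs = cfg$inputs, params = params, out_dir = cfg$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_pipeline_inputs <- function(inputs, params) {
  root <- inputs$data_dir %||% "."
  pth <- function(p) if (is.null(p)) NULL else file.path(root, p)
  manifest <- read_manifest(pth(inputs$manifest))
  if (!"file" %in% names(manifest))
    abort("manifest needs a 'file' column pointing at realignment files")
  dialect <- inputs$dialect %||% "spm_order"
  realignment <- bind_rows(lapply(seq_len(nrow(manifest)), function(i)
    read_realignment(file.path(root, manifest$file[i]), dialect = dialect,
                     participant_id = manifest$participant_id[i],
                     run_id = manifest$run_id[i],
                     drop_frames = inputs$drop_frames %||% 0L)))
  cohort <- read_covariates(pth(inputs$covariates))
  ratings <- read_ratings(pth(inputs$ratings))
  thickness <- NULL
  if (!is.null(inputs$thickness))
    thickness <- read_thickness(pth(inputs$thickness), pth(inputs$parcels),
                                cohort = cohort)
  list(cohort = cohort, manifest = manifest %>% select(-all_of("file")),
       realignment = realignment, ratings = ratings, thickness = thickness)
}

#' Run the full motion-bias analysis pipeline
#'
#' Executes, in order: FD computation and the motion-summary hierarchy;
#' cross-run stability; composite ratings, inter-rater agreement and
#' age-cohort rating comparisons; motion-by-rating group tests and the
#' motion ANCOVA; high-mover and combined flagging; the rating/FD overlap
#' analysis; then, when thickness data are present, the thickness ANCOVA and
#' effect-size-change test, whole-brain partial correlations, vertex-wise
#' partial-correlation maps before/after flag removal, the leave-one-out
#' control envelope, the matched-bootstrap group null, a flagged-vs-matched
#' vertex-wise t-map, and the before/after age-effect comparison.
#' Thickness-dependent stages are skipped with a notice when no thickness
#' input is given. When `out_dir` is set, every stage writes its report
#' (TSV/JSON) there and a `manifest.json` records parameters, seeds and
#' stage timings.
#'
#' @param input An `mf_cohort` from [generate_cohort()], a directory written
#'   by [write_cohort()], a config list as from [read_pipeline_config()], or
#'   a path to a YAML config file.
#' @param params [pipeline_params()] list.
#' @param out_dir Optional output directory.
#' @return Invisibly, a named list with every stage result and the run
#'   manifest.
#' @export
run_pipeline <- function(input, params = pipeline_params(), out_dir = NULL) {
  t0 <- Sys.time()
  if (is.character(input) && length(input) == 1 && dir.exists(input)) {
    input <- list(inputs = list(data_dir = input, manifest = "manifest.csv",
                                ratings = "ratings.csv",
                                covariates = "covariates.csv",
                                thickness = if (file.exists(file.path(input, "thickness.tsv")))
                                  "thickness.tsv" else NULL,
                                parcels = if (file.exists(file.path(input, "parcels.txt")))
                                  "parcels.txt" else NULL),
                  params = params, out_dir = out_dir)
  } else if (is.character(input) && length(input) == 1) {
    input <- read_pipeline_config(input)
  }
  if (inherits(input, "mf_cohort")) {
    dat <- list(cohort = input$cohort, manifest = input$manifest,
                realignment = input$realignment, ratings = input$ratings,
                thickness = input$thickness)
  } else {
    params <- input$params %||% params
    out_dir <- out_dir %||% input$out_dir
    dat <- load_pipeline_inputs(input$inputs, params)
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  results <- list()
  timings <- list()
  emit_tsv <- function(df, name) {
    if (!is.null(out_dir))
      readr::write_tsv(df, file.path(out_dir, paste0(name, ".tsv")))
  }
  emit_json <- function(x, name) {
    if (!is.null(out_dir))
      jsonlite::write_json(x, file.path(out_dir, paste0(name, ".json")),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  stage <- function(name, expr) {
    st <- Sys.time()
    val <- tryCatch(expr, error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e))))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    results[[name]] <<- val
    val
  }

  fd <- stage("fd", compute_fd(dat$realignment, radius = params$radius))
  run_summ <- stage("run_summaries", summarize_runs(fd))
  motion <- stage("motion_summary",
                  aggregate_motion(run_summ, dat$manifest, stat = params$stat))
  emit_tsv(run_summ, "run_summaries"); emit_tsv(motion, "motion_summary")

  stab <- stage("stability", stability_matrix(
    run_summ, value = if (params$stat == "mean") "fd_mean" else "fd_median",
    n_perm = params$n_perm_stability, seed = sub_seed(params$seed, "stability")))
  emit_tsv(tidy(stab), "stability_matrix")
  emit_json(list(rho = stab$rho, p_perm = stab$p_perm, m = stab$m,
                 n_perm = stab$n_perm, seed = stab$seed), "stability_matrix")
  results$scan_order <- stage("scan_order", scan_order_test(run_summ))
  emit_tsv(results$scan_order, "scan_order_test")

  comp <- stage("composite_ratings", composite_ratings(dat$ratings))
  emit_tsv(comp %>% mutate(rating = as.character(.data$rating)),
           "composite_ratings")
  raters <- sort(unique(dat$ratings$rater_id))
  kap <- NULL
  if (length(raters) == 2) {
    wide <- dat$ratings %>%
      mutate(rating = as.character(.data$rating)) %>%
      tidyr::pivot_wider(names_from = "rater_id", values_from = "rating")
    kap <- stage("kappa", cohen_kappa(wide[[raters[1]]], wide[[raters[2]]]))
    emit_json(as.list(tidy(kap)), "kappa")
  }
  dist <- stage("rating_distribution", rating_distribution(comp))
  emit_tsv(dist %>% mutate(rating = as.character(.data$rating)),
           "rating_distribution")
  results$cohort_chisq <- stage("cohort_chisq",
                                age_cohort_chisq(comp, dat$cohort))
  emit_tsv(results$cohort_chisq, "cohort_chisq")

  analysis <- motion %>%
    left_join(dat$cohort, by = "participant_id") %>%
    left_join(comp %>% select(all_of(c("participant_id", "rating"))),
              by = "participant_id")
  results$group_tests <- stage("group_tests",
                               group_difference_tests(motion, comp))
  emit_tsv(results$group_tests, "group_tests")
  results$motion_ancova <- stage("motion_ancova", ancova_with_fallback(
    analysis %>% mutate(qc = .data$rating), outcome = "fd_all_task",
    predictors = c("age", "qc")))
  emit_tsv(tidy(results$motion_ancova), "motion_ancova")

  flags <- stage("flags", flag_high_movers(motion, k = params$k))
  combined <- stage("combined_flags", combine_flags(flags, comp))
  emit_tsv(combined, "flag_report")
  emit_json(c(as.list(glance(flags)),
              list(flagged_ids = flags$flags$participant_id[flags$flags$flagged])),
            "threshold_report")

  fd_ids <- flags$flags$participant_id[flags$flags$flagged]
  qc_ids <- comp$participant_id[comp$rating == "fail"]
  if (length(fd_ids) > 0) {
    ov <- stage("overlap", overlap_analysis(
      fd_ids, qc_ids, universe = dat$cohort$participant_id,
      n_perm = params$n_perm_overlap, seed = sub_seed(params$seed, "overlap")))
    emit_json(as.list(tidy(ov)), "overlap")
  } else {
    results$overlap <- "skipped: no FD-flagged participants"
  }

  if (is.null(dat$thickness)) {
    results$bias <- "skipped: no thickness input"
    message("thickness input absent: bias stages skipped")
  } else {
    th <- dat$thickness
    analysis <- analysis %>%
      mutate(mean_thickness = rowMeans(th$thickness)[.data$participant_id],
             qc = .data$rating,
             qc_score = as.integer(.data$rating) - 1L)  # fail 0 .. pass 2
    results$thickness_ancova <- stage("thickness_ancova", ancova_with_fallback(
      analysis %>% rename(fd = "fd_all_task"),
      outcome = "mean_thickness", predictors = c("age", "fd", "qc", "gender")))
    emit_tsv(tidy(results$thickness_ancova), "thickness_ancova")
    results$effect_size_change <- stage("effect_size_change",
      effect_size_change(analysis %>% rename(fd = "fd_all_task"),
                         outcome = "mean_thickness",
                         n_perm = params$n_perm_esc,
                         seed = sub_seed(params$seed, "esc")))
    emit_json(as.list(tidy(results$effect_size_change)), "effect_size_change")
    results$partial_qc <- stage("partial_qc", partial_correlation(
      analysis, "mean_thickness", "qc_score",
      covariates = c("age", "gender", "fd_all_task")))
    results$partial_fd <- stage("partial_fd", partial_correlation(
      analysis, "mean_thickness", "fd_all_task",
      covariates = c("age", "gender", "qc_score")))
    emit_tsv(bind_rows(results$partial_qc %>% mutate(x = "qc_score"),
                       results$partial_fd %>% mutate(x = "fd_all_task")),
             "partial_correlations")

    flagged_ids <- combined$participant_id[combined$flagged]
    retained_ids <- setdiff(dat$cohort$participant_id, flagged_ids)
    map_before <- stage("vertex_map_before",
                        vertexwise_partial_corr(th, analysis))
    map_after <- stage("vertex_map_after", vertexwise_partial_corr(
      subset_thickness(th, retained_ids), analysis))
    emit_tsv(tidy(map_before), "vertex_map_before")
    emit_tsv(tidy(map_after), "vertex_map_after")

    pools <- stage("matched_pools",
                   matched_pools(flagged_ids, dat$cohort,
                                 pool_size = params$pool_size))
    emit_tsv(pools, "matched_pools")
    results$envelope <- stage("envelope", leaveout_control_envelope(
      th, analysis, flagged_ids, pools,
      n_groups = params$n_groups_envelope,
      seed = sub_seed(params$seed, "envelope")))
    emit_json(list(exits = results$envelope$exits,
                   prop_outside = results$envelope$prop_outside,
                   mean_shift = results$envelope$mean_shift,
                   n_groups = results$envelope$n_groups),
              "envelope")
    results$boot <- stage("matched_bootstrap", matched_bootstrap_null(
      pools, analysis %>% select(all_of(c("participant_id", "mean_thickness"))) %>%
        rename(value = "mean_thickness"),
      n_boot = params$n_boot, seed = sub_seed(params$seed, "boot")))
    emit_json(as.list(tidy(results$boot)), "matched_bootstrap")

    # one matched control sample for the group t-map
    set.seed(sub_seed(params$seed, "control_sample"))
    ctrl <- vapply(split(pools$candidate_id, pools$flagged_id),
                   function(cand) cand[sample.int(length(cand), 1)], "")
    results$group_tmap <- stage("group_tmap", vertexwise_group_ttest(
      th, flagged_ids, unique(ctrl)))
    emit_tsv(results$group_tmap, "group_tmap")

    results$age_comparison <- stage("age_comparison", age_effect_comparison(
      th, dat$cohort, retained_ids))
    emit_tsv(glance(results$age_comparison), "age_effect_comparison")
    if (!is.null(results$age_comparison$parcel))
      emit_tsv(tidy(results$age_comparison), "age_effect_parcels")
  }

  outputs <- if (is.null(out_dir)) character(0) else
    sort(setdiff(list.files(out_dir), c("manifest.json", "run_log.json")))
  run_manifest <- list(
    package_version = as.character(utils::packageVersion("motionflag")),
    seed = params$seed, params = params[setdiff(names(params), "seed")],
    stages = names(timings), outputs = outputs)
  emit_json(run_manifest, "manifest")
  # wall-clock log kept separate so manifest and reports are reproducible
  # byte for byte under a fixed (config, seed)
  emit_json(list(timings_sec = timings,
                 total_sec = as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs"))),
            "run_log")
  results$manifest <- run_manifest
  results$timings <- timings
  invisible(results)
}

# Factorial ANCOVA when the design allows it; empty factor cells make the
# interaction model rank-deficient, in which case the main-effects model is
# fitted directly and a warning records the fallback.
ancova_with_fallback <- function(data, outcome, predictors) {
  tryCatch(
    ancova(data, outcome, predictors),
    error = function(e) {
      if (!grepl("rank-deficient", conditionMessage(e))) stop(e)
      warn(sprintf("ANCOVA of %s: factorial design rank-deficient; fitting main effects only",
                   outcome))
      ancova(data, outcome, predictors, interactions = FALSE)
    })
}

# Pass/warn/fail counts per age cohort, each non-reference cohort tested
# against the youngest cohort's distribution.
age_cohort_chisq <- function(composites, cohort,
                             breaks = c(20, 35, 50, 65, 90),
                             labels = c("YA", "ME", "ML", "OA")) {
  d <- composites %>% left_join(cohort, by = "participant_id") %>%
    mutate(cohort = cut(.data$age, breaks = breaks, labels = labels,
                        right = FALSE, include.lowest = TRUE))
  counts <- d %>%
    count(.data$cohort, .data$rating) %>%
    tidyr::pivot_wider(names_from = "rating", values_from = "n",
                       values_fill = 0L)
  for (lv in rating_levels())
    if (!lv %in% names(counts)) counts[[lv]] <- 0L
  ref <- counts %>% filter(.data$cohort == labels[1])
  out <- list()
  for (lab in labels[-1]) {
    row <- counts %>% filter(.data$cohort == lab)
    if (nrow(row) == 0) next
    ht <- suppressWarnings(cohort_rating_chisq(
      unlist(ref[, c("pass", "warn", "fail")]),
      unlist(row[, c("pass", "warn", "fail")])))
    out[[lab]] <- tidy(ht) %>% mutate(cohort = lab, reference = labels[1])
  }
  bind_rows(out) %>% select(all_of(c("cohort", "reference", "statistic",
                                     "df", "p.value")))
}
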