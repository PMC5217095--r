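#' Framewise displacement from realignment parameters
#'
#' FD for frame *t* (t = 2..T) is the sum of the absolute first differences of
#' the six rigid-body parameters, with the three rotations first converted
#' from radians to arc length on a sphere of radius `radius` mm — the
#' approximate distance from the cerebral cortex to the centre of the head.
#'
#' @param realignment Tibble of per-frame parameters for one or more runs, as
#'   returned by [read_realignment()] (columns `participant_id`, `run_id`,
#'   `frame`, `trans_*` mm, `rot_*` rad).
#' @param radius Sphere radius in mm used to convert rotations; default 50.
#' @param include_leading_zero If `TRUE`, prepend a structural 0 for the first
#'   frame of each run so `fd` has length T. Default `FALSE` (FD is undefined
#'   for the first frame); including a forced zero deflates run means.
#' @return Tibble `participant_id`, `run_id`, `frame`, `fd` (mm). With the
#'   default convention `frame` starts at 2 within each run.
#' @export
compute_fd <- function(realignment, radius = 50, include_leading_zero = FALSE) {
  stopifnot(radius > 0)
  d <- realignment %>%
    arrange(.data$participant_id, .data$run_id, .data$frame)
  n_by_run <- d %>% count(.data$participant_id, .data$run_id)
  if (any(n_by_run$n < 2))
    abort("every run needs at least 2 frames to define framewise displacement")
  par6 <- cbind(d$trans_x, d$trans_y, d$trans_z,
                d$rot_x * radius, d$rot_y * radius, d$rot_z * radius)
  dif <- rbind(rep(NA_real_, 6), abs(diff(par6)))
  fd <- rowSums(dif)
  first <- !duplicated(paste(d$participant_id, d$run_id, sep = "\r"))
  out <- tibble(participant_id = d$participant_id, run_id = d$run_id,
                frame = d$frame, fd = fd)
  if (include_leading_zero) {
    out$fd[first] <- 0
    out
  } else {
    out[!first, ]
  }
}

#' Per-run FD summaries
#'
#' @param fd Tibble from [compute_fd()].
#' @return Tibble with one row per (participant, run): `n_fd`, `fd_mean`,
#'   `fd_median` (mm).
#' @export
summarize_runs <- function(fd) {
  if (nrow(fd) == 0) abort("empty FD table")
  fd %>%
    group_by(.data$participant_id, .data$run_id) %>%
    summarise(n_fd = n(), fd_mean = mean(.data$fd),
              fd_median = median(.data$fd), .groups = "drop")
}

#' Aggregate run FD summaries into task and all-task values
#'
#' A participant's task value is the unweighted mean of their per-run
#' summaries over that task's available runs, and the all-task value is the
#' unweighted mean of the available task values. Both averages deliberately
#' ignore frame counts, so long runs do not dominate, and missing runs are
#' dropped — never imputed.
#'
#' @param run_summaries Tibble from [summarize_runs()].
#' @param manifest Tibble mapping `participant_id`, `task`, `run_id`. Runs in
#'   the manifest without a summary are treated as missing.
#' @param stat `"mean"` (default) or `"median"`: which per-run summary feeds
#'   the hierarchy.
#' @return Tibble with one row per participant: one `task_<name>` column per
#'   task plus `fd_all_task` (mm).
#' @export
aggregate_motion <- function(run_summaries, manifest, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  col <- if (stat == "mean") "fd_mean" else "fd_median"
  joined <- manifest %>%
    left_join(run_summaries, by = c("participant_id", "run_id"))
  present <- joined %>% filter(!is.na(.data[[col]]))
  none <- setdiff(unique(manifest$participant_id),
                  unique(present$participant_id))
  if (length(none) > 0)
    abort(sprintf("participant(s) with zero available runs: %s",
                  paste(head(none, 5), collapse = ", ")))
  task_fd <- present %>%
    group_by(.data$participant_id, .data$task) %>%
    summarise(fd_task = mean(.data[[col]]), .groups = "drop")
  all_task <- task_fd %>%
    group_by(.data$participant_id) %>%
    summarise(fd_all_task = mean(.data$fd_task), .groups = "drop")
  task_fd %>%
    tidyr::pivot_wider(names_from = "task", values_from = "fd_task",
                       names_prefix = "task_") %>%
    left_join(all_task, by = "participant_id")
}

#' Flag high movers by all-task FD
#'
#' Flags participants whose all-task FD exceeds the sample mean plus `k`
#' sample standard deviations (n-1 denominator). The inequality is strict, so
#' a value exactly at the threshold is not flagged; with zero spread nobody
#' is.
#'
#' @param motion Tibble with `participant_id` and the value column.
#' @param k SD multiplier; default 1.5.
#' @param value Name of the value column; default `"fd_all_task"`.
#' @return An object of class `mf_flags`: tibble accessor via [tidy()], scalar
#'   summary via [glance()].
#' @export
flag_high_movers <- function(motion, k = 1.5, value = "fd_all_task") {
  stopifnot(k > 0)
  x <- motion[[value]]
  if (length(x) < 2) abort("need at least 2 participants to form a threshold")
  if (any(!is.finite(x))) abort("non-finite motion values")
  m <- mean(x); s <- sd(x)
  thr <- m + k * s
  structure(list(
    flags = tibble(participant_id = motion$participant_id, value = x,
                   flagged = x > thr),
    k = k, sample_mean = m, sample_sd = s, threshold = thr,
    value_col = value
  ), class = "mf_flags")
}

#' @export
print.mf_flags <- function(x, ...) {
  cat(sprintf(
    "<mf_flags> %d/%d flagged (threshold = mean %.4f + %.1f SD %.4f = %.4f mm)\n",
    sum(x$flags$flagged), nrow(x$flags), x$sample_mean, x$k, x$sample_sd,
    x$threshold))
  invisible(x)
}

#' @export
tidy.mf_flags <- function(x, ...) x$flags

#' @export
glance.mf_flags <- function(x, ...) {
  tibble(n = nrow(x$flags), n_flagged = sum(x$flags$flagged), k = x$k,
         sample_mean = x$sample_mean, sample_sd = x$sample_sd,
         threshold = x$threshold)
}

#' @describeIn flag_high_movers Histogram of the flagged value with the
#'   threshold marked.
#' @param object `mf_flags` object.
#' @param ... Unused.
#' @export
autoplot.mf_flags <- function(object, ...) {
  ggplot2::ggplot(object$flags, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$threshold,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = sprintf("%s (mm)", object$value_col), y = "participants",
                  title = sprintf("High-mover threshold: mean + %.1f SD = %.3f mm",
                                  object$k, object$threshold))
}
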