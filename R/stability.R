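#' Cross-run stability of per-run FD summaries
#'
#' Spearman rank correlations (average ranks for ties) between every pair of
#' runs' FD summaries across participants, each accompanied by a one-sided
#' (positive-association) permutation p-value: one run's vector is randomly
#' reordered without replacement, the correlation with the intact vector is
#' recomputed, and the observed value is compared against the null
#' distribution. Significance flags use Bonferroni correction over the
#' k(k-1)/2 pairs. Participants missing a run contribute pairwise-complete
#' observations.
#'
#' @param run_summaries Tibble from [summarize_runs()].
#' @param value Summary column to correlate; default `"fd_mean"`.
#' @param n_perm Permutations per pair; default 10000.
#' @param seed Integer seed.
#' @param alpha Family-wise significance level before Bonferroni; default 0.05.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Object of class `mf_stability` with matrices `rho`, `p_perm`,
#'   `n_pairs`, logical `significant` (Bonferroni-adjusted), plus `m`,
#'   `n_perm`, `seed`.
#' @export
stability_matrix <- function(run_summaries, value = "fd_mean",
                             n_perm = 10000, seed = 1, alpha = 0.05,
                             method = c("spearman", "pearson")) {
  method <- match.arg(method)
  wide <- run_summaries %>%
    select(all_of(c("participant_id", "run_id", value))) %>%
    tidyr::pivot_wider(names_from = "run_id", values_from = all_of(value))
  runs <- setdiff(names(wide), "participant_id")
  k <- length(runs)
  if (k < 2) abort("need at least 2 runs")
  m <- k * (k - 1) / 2
  rho <- diag(1, k); p_perm <- matrix(NA_real_, k, k); np <- matrix(NA_real_, k, k)
  dimnames(rho) <- dimnames(p_perm) <- dimnames(np) <- list(runs, runs)
  set.seed(sub_seed(seed, "stability_matrix"))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- wide[[runs[i]]]; y <- wide[[runs[j]]]
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]; n <- length(x)
    if (n < 3) abort(sprintf("fewer than 3 complete pairs for runs %s/%s",
                             runs[i], runs[j]))
    if (sd(x) == 0 || sd(y) == 0)
      abort(sprintf("constant values for run pair %s/%s: correlation undefined",
                    runs[i], runs[j]))
    xs <- if (method == "spearman") rank(x) else x
    ys <- if (method == "spearman") rank(y) else y
    obs <- cor(xs, ys)
    cy <- ys - mean(ys)
    cx <- xs - mean(xs)
    denom <- sqrt(sum(cx^2) * sum(cy^2))
    # permute x against intact y; correlation reduces to a cross-product
    perm <- matrix(0, n, n_perm)
    for (b in seq_len(n_perm)) perm[, b] <- cx[sample.int(n)]
    null_rho <- as.numeric(crossprod(perm, cy)) / denom
    rho[i, j] <- rho[j, i] <- obs
    p <- perm_pvalue(sum(null_rho >= obs), n_perm)
    p_perm[i, j] <- p_perm[j, i] <- p
    np[i, j] <- np[j, i] <- n
  }
  structure(list(rho = rho, p_perm = p_perm, n_pairs = np,
                 significant = p_perm < alpha / m,
                 m = m, n_perm = n_perm, seed = seed, alpha = alpha,
                 method = method),
            class = "mf_stability")
}

#' @export
print.mf_stability <- function(x, ...) {
  cat(sprintf("<mf_stability> %d runs, %s; rho range %.3f-%.3f; %d/%d pairs significant (Bonferroni m = %d)\n",
              nrow(x$rho), x$method,
              min(x$rho[upper.tri(x$rho)]), max(x$rho[upper.tri(x$rho)]),
              sum(x$significant[upper.tri(x$rho)], na.rm = TRUE), x$m, x$m))
  invisible(x)
}

#' @export
tidy.mf_stability <- function(x, ...) {
  runs <- rownames(x$rho)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble(run1 = runs[idx[, 1]], run2 = runs[idx[, 2]],
         rho = x$rho[idx], p_perm = x$p_perm[idx], n = x$n_pairs[idx],
         significant = x$significant[idx])
}

#' @describeIn stability_matrix Correlation-matrix heat map.
#' @param object `mf_stability` object.
#' @param ... Unused.
#' @export
autoplot.mf_stability <- function(object, ...) {
  df <- as.data.frame(as.table(object$rho))
  names(df) <- c("run1", "run2", "rho")
  ggplot2::ggplot(df, ggplot2::aes(.data$run1, .data$run2, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rho)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Cross-run FD-bar stability")
}

#' Effect of scan order on run FD summaries
#'
#' One-way ANOVA of the per-run FD summary across run positions, treating
#' each (participant, run) observation as a unit.
#'
#' @param run_summaries Tibble from [summarize_runs()].
#' @param value Summary column; default `"fd_mean"`.
#' @return One-row tibble: `statistic_name` ("F"), `statistic`, `df1`, `df2`,
#'   `p.value`.
#' @export
scan_order_test <- function(run_summaries, value = "fd_mean") {
  g <- factor(run_summaries$run_id)
  if (nlevels(g) < 2) abort("need at least 2 runs")
  if (any(table(g) < 2)) abort("every run needs at least 2 observations")
  fit <- stats::aov(run_summaries[[value]] ~ g)
  tab <- summary(fit)[[1]]
  tibble(statistic_name = "F", statistic = tab$`F value`[1],
         df1 = tab$Df[1], df2 = tab$Df[2], p.value = tab$`Pr(>F)`[1])
}

# Tie-corrected rank-sum z for two samples (normal approximation, no
# continuity correction). Returns U for the first sample, z and two-sided p.
ranksum_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- (U1 - n1 * n2 / 2) / sqrt(sigma2)
  list(U = min(U1, n1 * n2 - U1), U1 = U1, z = z, p = 2 * pnorm(-abs(z)))
}

#' Motion differences across quality-rating groups
#'
#' Tie-corrected Kruskal-Wallis H-test of all-task FD across composite rating
#' groups, followed by pairwise rank-sum tests with normal-approximation z,
#' an approximate rank eta-squared (z^2 / n), and Bonferroni correction over
#' the three pairwise comparisons. The convention follows the better rating
#' first, so negative z means the better-rated group moves less.
#'
#' @param motion Tibble with `participant_id` and `fd_all_task`.
#' @param composites Tibble from [composite_ratings()].
#' @return Tibble with one row for the H test and one per pairwise test:
#'   `test`, `groups`, `statistic_name`, `statistic`, `z`, `p.value`,
#'   `p.adjusted`, `eta_sq`, `n`.
#' @export
group_difference_tests <- function(motion, composites) {
  d <- motion %>%
    left_join(composites, by = "participant_id") %>%
    filter(!is.na(.data$rating))
  grp <- droplevels(d$rating)
  if (nlevels(grp) < 2) abort("need at least 2 non-empty rating groups")
  kw <- kruskal.test(d$fd_all_task, grp)
  out <- tibble(test = "kruskal_wallis", groups = paste(levels(grp), collapse = "/"),
                statistic_name = "H", statistic = unname(kw$statistic),
                z = NA_real_, p.value = kw$p.value, p.adjusted = kw$p.value,
                eta_sq = NA_real_, n = nrow(d))
  lv <- rev(levels(grp))   # best rating first
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  m <- length(pairs)
  for (pr in pairs) {
    x <- d$fd_all_task[grp == pr[1]]; y <- d$fd_all_task[grp == pr[2]]
    if (length(x) < 2 || length(y) < 2) {
      warn(sprintf("skipping pairwise test %s vs %s: group with <2 members",
                   pr[1], pr[2]))
      next
    }
    rs <- ranksum_z(x, y)
    n <- length(x) + length(y)
    out <- bind_rows(out, tibble(
      test = "rank_sum", groups = paste(pr, collapse = " vs "),
      statistic_name = "U", statistic = rs$U, z = rs$z, p.value = rs$p,
      p.adjusted = min(1, rs$p * m), eta_sq = rs$z^2 / n, n = n))
  }
  out
}

#' Combine FD-based and rating-based flags
#'
#' A participant is flagged when they are an FD high mover, have a composite
#' rating of "fail", or both; the source of each flag is recorded.
#'
#' @param flags `mf_flags` from [flag_high_movers()] (or its [tidy()] tibble).
#' @param composites Tibble from [composite_ratings()].
#' @return Tibble `participant_id`, `flagged`, `source`
#'   (`"fd"`/`"qc"`/`"both"`/`"none"`).
#' @export
combine_flags <- function(flags, composites) {
  ftab <- if (inherits(flags, "mf_flags")) flags$flags else flags
  only_f <- setdiff(ftab$participant_id, composites$participant_id)
  only_q <- setdiff(composites$participant_id, ftab$participant_id)
  if (length(only_f) > 0 || length(only_q) > 0)
    abort(sprintf("participant universes differ (e.g. %s)",
                  paste(head(c(only_f, only_q), 5), collapse = ", ")))
  d <- ftab %>%
    select(all_of(c("participant_id", "flagged"))) %>%
    rename(fd_flag = "flagged") %>%
    left_join(composites %>%
                mutate(qc_fail = .data$rating == "fail") %>%
                select(all_of(c("participant_id", "qc_fail"))),
              by = "participant_id")
  d %>%
    mutate(flagged = .data$fd_flag | .data$qc_fail,
           source = dplyr::case_when(
             .data$fd_flag & .data$qc_fail ~ "both",
             .data$fd_flag ~ "fd",
             .data$qc_fail ~ "qc",
             TRUE ~ "none")) %>%
    select(all_of(c("participant_id", "flagged", "source")))
}

#' Sensitivity and specificity of "fail" ratings for FD high movers
#'
#' Sensitivity is the proportion of FD-flagged participants also rated
#' "fail"; specificity is the proportion of non-FD-flagged participants rated
#' pass or warn. Permutation significance draws random pseudo-"fail" sets of
#' the same size (without replacement) from the full sample and compares them
#' against the fixed FD-flag set; both p-values are upper-tail with the
#' plus-one rule.
#'
#' @param fd_ids Character vector of FD-flagged participant IDs.
#' @param qc_ids Character vector of participant IDs rated "fail".
#' @param universe Character vector of all participant IDs.
#' @param n_perm Number of resampled sets; default 10000.
#' @param seed Integer seed.
#' @return Object of class `mf_overlap`.
#' @export
overlap_analysis <- function(fd_ids, qc_ids, universe, n_perm = 10000,
                             seed = 1) {
  if (length(fd_ids) == 0) abort("empty FD-flag set: sensitivity undefined")
  if (!all(fd_ids %in% universe) || !all(qc_ids %in% universe))
    abort("flag sets must be subsets of the universe")
  n_total <- length(universe)
  n_fd <- length(fd_ids); n_qc <- length(qc_ids)
  n_overlap <- length(intersect(fd_ids, qc_ids))
  sens <- n_overlap / n_fd
  spec <- (n_total - n_fd - (n_qc - n_overlap)) / (n_total - n_fd)

  in_fd <- universe %in% fd_ids
  set.seed(sub_seed(seed, "overlap_analysis"))
  null_sens <- numeric(n_perm); null_spec <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    draw <- sample.int(n_total, n_qc)
    ov <- sum(in_fd[draw])
    null_sens[b] <- ov / n_fd
    null_spec[b] <- (n_total - n_fd - (n_qc - ov)) / (n_total - n_fd)
  }
  structure(list(
    sensitivity = sens, specificity = spec,
    p_sens = perm_pvalue(sum(null_sens >= sens), n_perm),
    p_spec = perm_pvalue(sum(null_spec >= spec), n_perm),
    counts = list(n_total = n_total, n_fd_flagged = n_fd, n_qc_fail = n_qc,
                  n_overlap = n_overlap,
                  n_union = n_fd + n_qc - n_overlap),
    null_mean_sens = mean(null_sens), null_mean_spec = mean(null_spec),
    n_perm = n_perm, seed = seed
  ), class = "mf_overlap")
}

#' @export
print.mf_overlap <- function(x, ...) {
  cat(sprintf("sensitivity = %.2f (p = %.3g), specificity = %.2f (p = %.3g); union = %d of %d\n",
              x$sensitivity, x$p_sens, x$specificity, x$p_spec,
              x$counts$n_union, x$counts$n_total))
  invisible(x)
}

#' @export
tidy.mf_overlap <- function(x, ...) {
  tibble(sensitivity = x$sensitivity, specificity = x$specificity,
         p_sens = x$p_sens, p_spec = x$p_spec,
         n_total = x$counts$n_total, n_fd_flagged = x$counts$n_fd_flagged,
         n_qc_fail = x$counts$n_qc_fail, n_overlap = x$counts$n_overlap,
         n_union = x$counts$n_union)
}
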