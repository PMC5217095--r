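#' Age- and gender-matched candidate pools for flagged participants
#'
#' For each flagged participant, the pool is the `pool_size` retained
#' (unflagged) participants of the same gender with the smallest absolute age
#' difference. Ties at the pool boundary are broken deterministically by
#' participant ID (lexicographically smaller first), so pools are stable
#' across runs.
#'
#' @param flagged_ids Character vector of flagged participant IDs.
#' @param cohort Covariate tibble (`participant_id`, `age`, `gender`) covering
#'   flagged and retained participants.
#' @param pool_size Candidates per flagged member; default 10.
#' @return Tibble `flagged_id`, `candidate_id`, `rank`, `age_diff`.
#' @export
matched_pools <- function(flagged_ids, cohort, pool_size = 10) {
  miss <- setdiff(flagged_ids, cohort$participant_id)
  if (length(miss) > 0)
    abort(sprintf("flagged participant(s) absent from cohort: %s",
                  paste(head(miss, 5), collapse = ", ")))
  retained <- cohort %>% filter(!.data$participant_id %in% flagged_ids)
  out <- vector("list", length(flagged_ids))
  for (i in seq_along(flagged_ids)) {
    fid <- flagged_ids[i]
    frow <- cohort[cohort$participant_id == fid, ]
    cand <- retained %>% filter(.data$gender == frow$gender)
    if (nrow(cand) < pool_size)
      abort(sprintf("participant %s: only %d same-gender retained candidates (< pool_size %d)",
                    fid, nrow(cand), pool_size))
    diff <- abs(cand$age - frow$age)
    ord <- order(diff, cand$participant_id)[seq_len(pool_size)]
    out[[i]] <- tibble(flagged_id = fid,
                       candidate_id = cand$participant_id[ord],
                       rank = seq_len(pool_size),
                       age_diff = diff[ord])
  }
  bind_rows(out)
}

#' Matched-bootstrap null for a flagged-group statistic
#'
#' Builds a null distribution of the flagged group's mean of a
#' per-participant scalar (e.g. mean cortical thickness) from matched control
#' groups: each replicate draws, with replacement across replicates, one
#' candidate per flagged member from that member's matched pool and takes the
#' group mean. The tail probability uses the plus-one rule; the default
#' direction is "lower" because motion bias is expected to depress thickness.
#'
#' @param pools Tibble from [matched_pools()].
#' @param metric Tibble (`participant_id`, `value`) or named numeric vector of
#'   the per-participant scalar.
#' @param n_boot Number of control groups; default 10000 (values below 100
#'   warn, 0 errors).
#' @param seed Integer seed.
#' @param direction `"lower"` (default) or `"upper"` tail.
#' @return Object of class `mf_boot`.
#' @export
matched_bootstrap_null <- function(pools, metric, n_boot = 10000, seed = 1,
                                   direction = c("lower", "upper")) {
  direction <- match.arg(direction)
  if (n_boot < 1) abort("n_boot must be positive")
  if (n_boot < 100) warn("n_boot < 100: null distribution will be coarse")
  if (is.data.frame(metric))
    metric <- setNames(metric$value, metric$participant_id)
  flagged <- unique(pools$flagged_id)
  need <- unique(c(flagged, pools$candidate_id))
  miss <- setdiff(need, names(metric))
  if (length(miss) > 0)
    abort(sprintf("metric missing for participant(s): %s",
                  paste(head(miss, 5), collapse = ", ")))
  observed <- mean(metric[flagged])

  # pools tibble is ordered in consecutive blocks of pool_size per flagged id
  ps <- nrow(pools) / length(flagged)
  pool_vals <- matrix(metric[pools$candidate_id], ncol = ps, byrow = TRUE)

  set.seed(sub_seed(seed, "matched_bootstrap_null"))
  draws <- matrix(sample.int(ps, length(flagged) * n_boot, replace = TRUE),
                  nrow = length(flagged))
  picked <- matrix(pool_vals[cbind(rep(seq_len(nrow(pool_vals)), n_boot),
                                   as.vector(draws))],
                   nrow = length(flagged))
  null <- colMeans(picked)
  p <- if (direction == "lower")
    perm_pvalue(sum(null <= observed), n_boot) else
    perm_pvalue(sum(null >= observed), n_boot)
  structure(list(observed = observed,
                 null = list(mean = mean(null), sd = sd(null),
                             quantiles = quantile(null, c(0.025, 0.5, 0.975))),
                 null_values = null, p = p, direction = direction,
                 n_boot = n_boot, pool_size = ps, seed = seed,
                 n_flagged = length(flagged)),
            class = "mf_boot")
}

#' @export
print.mf_boot <- function(x, ...) {
  cat(sprintf("observed flagged-group mean = %.4f; null %.4f +/- %.4f; %s-tail p = %.3g (%d draws)\n",
              x$observed, x$null$mean, x$null$sd, x$direction, x$p, x$n_boot))
  invisible(x)
}

#' @export
tidy.mf_boot <- function(x, ...) {
  tibble(observed = x$observed, null_mean = x$null$mean, null_sd = x$null$sd,
         p.value = x$p, direction = x$direction, n_boot = x$n_boot,
         n_flagged = x$n_flagged)
}

#' @describeIn matched_bootstrap_null Null histogram with the observed value
#'   marked.
#' @param object `mf_boot` object.
#' @param ... Unused.
#' @export
autoplot.mf_boot <- function(object, ...) {
  ggplot2::ggplot(data.frame(null = object$null_values),
                  ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "matched control-group mean", y = "control samples")
}

#' Leave-one-out control envelope for the after-flagging correlation CDF
#'
#' Re-computes the vertex-wise thickness-motion partial-correlation map for
#' control cohorts of the same size as the retained sample: each control
#' cohort removes, instead of the flagged participants, one distinct
#' randomly chosen member of each flagged participant's matched pool. The
#' pointwise 2.5/97.5 percentile envelope of the sorted correlation vectors
#' (the empirical CDF) is compared with the true after-flagging CDF.
#'
#' @param thickness `mf_thickness` or matrix with ID rownames (full sample).
#' @param data Data frame with `participant_id`, the `x` column and
#'   covariates.
#' @param flagged_ids Flagged participant IDs.
#' @param pools Tibble from [matched_pools()].
#' @param x,covariates Passed to [vertexwise_partial_corr()].
#' @param n_groups Number of control cohorts; default 1000 (minimum 1; a
#'   single group gives a degenerate envelope and warns).
#' @param probs Envelope percentiles; default `c(0.025, 0.975)`.
#' @param seed Integer seed.
#' @return Object of class `mf_envelope` with the sorted after-flagging
#'   correlations, the envelope (and its mean CDF), the proportion of CDF
#'   positions outside it, the directional `mean_shift` of the after-flagging
#'   correlations relative to the control mean (positive = shifted toward
#'   zero for negative-bias maps), and `exits` — whether more positions fall
#'   outside than the pointwise coverage allows. Because control cohorts
#'   share most participants, the envelope is narrow and `exits` is
#'   anticonservative; `mean_shift` carries the direction.
#' @export
leaveout_control_envelope <- function(thickness, data, flagged_ids, pools,
                                      x = "fd_all_task",
                                      covariates = c("age", "gender"),
                                      n_groups = 1000,
                                      probs = c(0.025, 0.975), seed = 1) {
  th <- if (inherits(thickness, "mf_thickness")) thickness else
    new_thickness(thickness)
  if (n_groups < 1) abort("n_groups must be positive")
  if (n_groups == 1) warn("n_groups = 1: envelope is degenerate")
  all_ids <- rownames(th$thickness)
  retained <- setdiff(all_ids, flagged_ids)

  after <- vertexwise_partial_corr(
    subset_thickness(th, retained), data, x = x, covariates = covariates)
  after_sorted <- sort(after$map$r[!is.na(after$map$r)])
  nv <- length(after_sorted)

  pool_list <- split(pools$candidate_id, pools$flagged_id)
  set.seed(sub_seed(seed, "leaveout_control_envelope"))
  null_sorted <- matrix(NA_real_, n_groups, nv)
  for (g in seq_len(n_groups)) {
    removed <- character(0)
    for (cand in pool_list) {
      avail <- setdiff(cand, removed)
      if (length(avail) == 0) avail <- cand  # all taken: allow reuse
      removed <- c(removed, avail[sample.int(length(avail), 1)])
    }
    keep <- setdiff(all_ids, unique(removed))
    vm <- vertexwise_partial_corr(subset_thickness(th, keep), data,
                                  x = x, covariates = covariates)
    rs <- sort(vm$map$r[!is.na(vm$map$r)])
    null_sorted[g, ] <- rs[seq_len(nv)]
  }
  lo <- apply(null_sorted, 2, quantile, probs = probs[1])
  hi <- apply(null_sorted, 2, quantile, probs = probs[2])
  null_mean <- colMeans(null_sorted)
  outside <- after_sorted < lo | after_sorted > hi
  coverage_excess <- 1 - diff(probs)
  structure(list(after_sorted = after_sorted, lower = lo, upper = hi,
                 null_mean = null_mean,
                 outside = outside, prop_outside = mean(outside),
                 mean_shift = mean(after_sorted) - mean(null_mean),
                 exits = mean(outside) > coverage_excess, probs = probs,
                 n_groups = n_groups, seed = seed, x = x,
                 covariates = covariates),
            class = "mf_envelope")
}

subset_thickness <- function(th, ids) {
  new_thickness(th$thickness[ids, , drop = FALSE], th$parcel_map,
                th$hemisphere)
}

#' @export
print.mf_envelope <- function(x, ...) {
  cat(sprintf("<mf_envelope> after-flagging CDF %s the %.0f%% control envelope (%.1f%% of positions outside; %d control cohorts)\n",
              if (x$exits) "exits" else "stays inside",
              100 * diff(x$probs), 100 * x$prop_outside, x$n_groups))
  invisible(x)
}

#' @describeIn leaveout_control_envelope After-flagging CDF over the control
#'   envelope.
#' @param object `mf_envelope` object.
#' @param ... Unused.
#' @export
autoplot.mf_envelope <- function(object, ...) {
  nv <- length(object$after_sorted)
  df <- data.frame(p = seq_len(nv) / nv, after = object$after_sorted,
                   lo = object$lower, hi = object$upper)
  ggplot2::ggplot(df, ggplot2::aes(y = .data$p)) +
    ggplot2::geom_ribbon(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_step(ggplot2::aes(x = .data$after), colour = "red") +
    ggplot2::labs(x = "vertex-wise partial r", y = "cumulative proportion")
}

#' Vertex-wise two-sample t-tests between groups
#'
#' Two-sample t-test (pooled variance by default; Welch optional) at every
#' vertex between two participant groups, with Benjamini-Hochberg FDR applied
#' within each hemisphere separately.
#'
#' @param thickness `mf_thickness` or matrix with ID rownames.
#' @param ids_a,ids_b Participant IDs of the two groups (each >= 2).
#' @param var_equal Pooled variance (`TRUE`, default) or Welch.
#' @return Tibble `vertex`, `hemisphere`, `estimate` (mean A - mean B),
#'   `statistic`, `df`, `p.value`, `q.value`.
#' @export
vertexwise_group_ttest <- function(thickness, ids_a, ids_b, var_equal = TRUE) {
  th <- if (inherits(thickness, "mf_thickness")) thickness else
    new_thickness(thickness)
  mat <- th$thickness
  if (length(ids_a) < 2 || length(ids_b) < 2)
    abort("both groups need at least 2 members")
  A <- mat[ids_a, , drop = FALSE]; B <- mat[ids_b, , drop = FALSE]
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- apply(A, 2, var); vb <- apply(B, 2, var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, ncol(mat))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (ma - mb) / se
  p <- 2 * pt(-abs(tstat), df)
  qv <- rep(NA_real_, length(p))
  for (h in unique(th$hemisphere)) {
    sel <- th$hemisphere == h
    qv[sel] <- p.adjust(p[sel], method = "BH")
  }
  tibble(vertex = seq_len(ncol(mat)), hemisphere = th$hemisphere,
         estimate = ma - mb, statistic = tstat, df = df, p.value = p,
         q.value = qv)
}

#' Age-effect comparison before and after flag removal
#'
#' Compares the age effect on thickness in the full sample against the
#' retained (after-flagging) subset: Bartlett's test on the variance of
#' participant mean thickness, a Fisher-z z-test on the two age-thickness
#' correlations (using the independent-samples standard error
#' sqrt(1/(n1-3) + 1/(n2-3)) — an approximation, since the samples overlap),
#' a two-sample Kolmogorov-Smirnov test on the vertex-wise age-correlation
#' distributions, and, when a parcel map is present, the per-parcel change in
#' Fisher-z transformed correlations of mean parcel thickness with age.
#'
#' @param thickness `mf_thickness` or matrix with ID rownames (full sample).
#' @param cohort Covariate tibble with `participant_id` and `age`.
#' @param after_ids Retained participant IDs (must be a subset of the rows).
#' @return Object of class `mf_agecomp`.
#' @export
age_effect_comparison <- function(thickness, cohort, after_ids) {
  th <- if (inherits(thickness, "mf_thickness")) thickness else
    new_thickness(thickness)
  mat <- th$thickness
  before_ids <- rownames(mat)
  if (!all(after_ids %in% before_ids))
    abort("after-set must be a subset of the thickness participants")
  age <- setNames(cohort$age, cohort$participant_id)
  age_b <- age[before_ids]; age_a <- age[after_ids]
  mt_b <- rowMeans(mat); mt_a <- rowMeans(mat[after_ids, , drop = FALSE])

  n1 <- length(mt_b); n2 <- length(mt_a)
  r_b <- cor(age_b, mt_b); r_a <- cor(age_a, mt_a)
  z_diff <- (atanh(r_a) - atanh(r_b)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p_z <- 2 * pnorm(-abs(z_diff))

  bt <- bartlett.test(list(before = mt_b, after = mt_a))

  vr_b <- as.numeric(cor(age_b, mat))
  vr_a <- as.numeric(cor(age_a, mat[after_ids, , drop = FALSE]))
  kst <- suppressWarnings(ks.test(vr_b, vr_a))

  parcel <- NULL
  if (!is.null(th$parcel_map)) {
    labs <- sort(unique(th$parcel_map))
    pm_b <- vapply(labs, function(l)
      cor(age_b, rowMeans(mat[, th$parcel_map == l, drop = FALSE])), 0)
    pm_a <- vapply(labs, function(l)
      cor(age_a, rowMeans(mat[after_ids, th$parcel_map == l, drop = FALSE])), 0)
    parcel <- tibble(parcel = labs, r_before = pm_b, r_after = pm_a,
                     z_before = atanh(pm_b), z_after = atanh(pm_a),
                     delta_z = atanh(pm_a) - atanh(pm_b))
  }
  structure(list(
    r_before = r_b, r_after = r_a, n_before = n1, n_after = n2,
    z_diff = z_diff, p_z = p_z,
    var_before = var(mt_b), var_after = var(mt_a),
    bartlett = list(statistic = unname(bt$statistic),
                    df = unname(bt$parameter), p = bt$p.value),
    ks = list(D = unname(kst$statistic), p = kst$p.value),
    parcel = parcel
  ), class = "mf_agecomp")
}

#' @export
print.mf_agecomp <- function(x, ...) {
  cat(sprintf("age~thickness r: %.3f (n = %d) -> %.3f (n = %d); Fisher z = %.2f, p = %.3g\n",
              x$r_before, x$n_before, x$r_after, x$n_after, x$z_diff, x$p_z))
  cat(sprintf("variance: %.4g -> %.4g (Bartlett X^2(%d) = %.2f, p = %.3g)\n",
              x$var_before, x$var_after, x$bartlett$df, x$bartlett$statistic,
              x$bartlett$p))
  cat(sprintf("vertex-wise correlation CDFs: KS D = %.4f, p = %.3g\n",
              x$ks$D, x$ks$p))
  if (!is.null(x$parcel))
    cat(sprintf("parcel delta z(r) >= 0 (attenuation) in %.0f%% of %d parcels\n",
                100 * mean(x$parcel$delta_z >= 0), nrow(x$parcel)))
  invisible(x)
}

#' @export
glance.mf_agecomp <- function(x, ...) {
  tibble(r_before = x$r_before, r_after = x$r_after, z_diff = x$z_diff,
         p_z = x$p_z, var_before = x$var_before, var_after = x$var_after,
         bartlett_stat = x$bartlett$statistic, bartlett_p = x$bartlett$p,
         ks_D = x$ks$D, ks_p = x$ks$p,
         prop_parcels_attenuated = if (is.null(x$parcel)) NA_real_ else
           mean(x$parcel$delta_z >= 0))
}

#' @export
tidy.mf_agecomp <- function(x, ...) {
  if (is.null(x$parcel)) abort("no parcel map available")
  x$parcel
}

#' @describeIn age_effect_comparison Parcel-wise before/after Fisher-z
#'   scatter.
#' @param object `mf_agecomp` object.
#' @param ... Unused.
#' @export
autoplot.mf_agecomp <- function(object, ...) {
  if (is.null(object$parcel)) abort("no parcel map available")
  ggplot2::ggplot(object$parcel,
                  ggplot2::aes(.data$z_before, .data$z_after)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "z(r) before flagging", y = "z(r) after flagging",
                  title = "Parcel-wise age effect before vs after flag removal")
}
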