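#' Composite (worst-of-raters) quality rating
#'
#' The final label for each scan is the more stringent of the contributing
#' ratings: one "warn" and one "pass" yields "warn". Order of records and
#' repeated application do not change the result.
#'
#' @param ratings Tibble from [read_ratings()] (`participant_id`, `rater_id`,
#'   `rating`).
#' @return Tibble `participant_id`, `rating` (ordered factor), `n_raters`.
#' @export
composite_ratings <- function(ratings) {
  if (nrow(ratings) == 0) abort("no rating records")
  ratings %>%
    group_by(.data$participant_id) %>%
    summarise(rating = min(.data$rating), n_raters = n(), .groups = "drop")
}

#' Cohen's kappa for two raters
#'
#' Unweighted kappa on the raters' cross-table, with the asymptotic (Fleiss)
#' standard error for the 95% CI and a significance test of kappa = 0 using
#' the null standard error.
#'
#' @param rater1,rater2 Equal-length vectors of ratings (character or factor
#'   over pass/warn/fail, or any common level set).
#' @param conf_level Confidence level for the interval; default 0.95.
#' @return Object of class `mf_kappa` with `kappa`, `ci_low`, `ci_high`, `p`,
#'   `n` and the cross-table.
#' @export
cohen_kappa <- function(rater1, rater2, conf_level = 0.95) {
  if (length(rater1) != length(rater2))
    abort("rater vectors must have equal length")
  lev <- sort(unique(c(as.character(rater1), as.character(rater2))))
  if (length(lev) < 2)
    abort("kappa undefined: only one category present across both raters")
  tab <- table(factor(as.character(rater1), lev),
               factor(as.character(rater2), lev))
  n <- sum(tab)
  p <- tab / n
  pi_ <- rowSums(p); pj <- colSums(p)
  po <- sum(diag(p)); pe <- sum(pi_ * pj)
  kappa <- (po - pe) / (1 - pe)

  # Fleiss, Cohen & Everitt asymptotic variance of kappa-hat
  a <- sum(diag(p) * (1 - (pi_ + pj) * (1 - kappa))^2)
  b <- (1 - kappa)^2 *
    (sum(p * outer(pj, pi_, "+")^2) - sum(diag(p) * (pi_ + pj)^2))
  c_ <- (kappa - pe * (1 - kappa))^2
  se <- sqrt((a + b - c_) / (n * (1 - pe)^2))
  # null (kappa = 0) variance for the significance test
  se0 <- sqrt((pe + pe^2 - sum(pi_ * pj * (pi_ + pj))) / (n * (1 - pe)^2))

  zq <- qnorm(1 - (1 - conf_level) / 2)
  z <- kappa / se0
  structure(list(kappa = kappa, se = se, se0 = se0,
                 ci_low = kappa - zq * se, ci_high = kappa + zq * se,
                 statistic = z, p = 2 * pnorm(-abs(z)), n = n, table = tab,
                 conf_level = conf_level),
            class = "mf_kappa")
}

#' @export
print.mf_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f, %d%% CI = %.3f-%.3f, p = %.3g (n = %d)\n",
              x$kappa, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$p, x$n))
  invisible(x)
}

#' @export
tidy.mf_kappa <- function(x, ...) {
  tibble(kappa = x$kappa, ci_low = x$ci_low, ci_high = x$ci_high,
         statistic = x$statistic, p.value = x$p, n = x$n)
}

#' Chi-square comparison of rating distributions between cohorts
#'
#' Pearson chi-square on the 2 x 3 contingency table formed by a reference
#' cohort's pass/warn/fail counts and a test cohort's counts (no continuity
#' correction). A published variant of this comparison describes expected
#' counts taken from the reference cohort's proportions; the printed
#' statistics of that report are in fact reproduced by this two-sample
#' contingency form, which is what is implemented. A rating level absent from
#' both cohorts is dropped with a warning and the degrees of freedom reduced.
#'
#' @param counts_ref,counts_test Integer vectors of counts per rating level
#'   (same order), e.g. pass/warn/fail.
#' @param levels Optional level names; defaults to pass/warn/fail when length
#'   3.
#' @return Object of class `mf_chisq` with `statistic`, `df`, `p`, `observed`
#'   and `expected`.
#' @export
cohort_rating_chisq <- function(counts_ref, counts_test, levels = NULL) {
  if (length(counts_ref) != length(counts_test))
    abort("count vectors must have equal length")
  if (any(counts_ref < 0) || any(counts_test < 0)) abort("negative counts")
  if (sum(counts_ref) == 0 || sum(counts_test) == 0)
    abort("each cohort needs a positive total")
  if (is.null(levels))
    levels <- if (length(counts_ref) == 3) c("pass", "warn", "fail") else
      paste0("level", seq_along(counts_ref))
  obs <- rbind(reference = counts_ref, test = counts_test)
  colnames(obs) <- levels
  empty <- colSums(obs) == 0
  if (any(empty)) {
    warn(sprintf("dropping rating level(s) with zero total: %s",
                 paste(levels[empty], collapse = ", ")))
    obs <- obs[, !empty, drop = FALSE]
  }
  if (ncol(obs) < 2) abort("fewer than 2 non-empty rating levels")
  ht <- suppressWarnings(stats::chisq.test(obs, correct = FALSE))
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, observed = obs, expected = ht$expected),
            class = "mf_chisq")
}

#' @export
print.mf_chisq <- function(x, ...) {
  cat(sprintf("X^2(%d) = %.2f, p = %.3g\n", x$df, x$statistic, x$p))
  invisible(x)
}

#' @export
tidy.mf_chisq <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p)
}

#' Counts and percentages of composite ratings
#'
#' @param composites Tibble from [composite_ratings()].
#' @return Tibble `rating`, `n`, `pct` (percent of total, full precision).
#' @export
rating_distribution <- function(composites) {
  if (nrow(composites) == 0) abort("no composite ratings")
  tab <- table(composites$rating)
  tibble(rating = factor(names(tab), levels = rating_levels(), ordered = TRUE),
         n = as.integer(tab),
         pct = 100 * as.integer(tab) / nrow(composites)) %>%
    arrange(dplyr::desc(.data$rating))
}
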