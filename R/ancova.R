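#' ANCOVA of a morphometric outcome with partial eta-squared
#'
#' Ordinary-least-squares ANCOVA of a per-participant outcome (e.g. mean
#' cortical thickness) on continuous and categorical predictors. The model is
#' first fitted with all interaction terms (full factorial crossing) using
#' Type III sums of squares and sum-to-zero contrasts; if no interaction term
#' reaches `alpha`, main effects are re-estimated from a main-effects-only
#' refit (where Type III and Type II coincide). Each term's partial
#' eta-squared is SS_term / (SS_term + SS_residual).
#'
#' @param data Data frame with the outcome and predictors.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor columns; factors are
#'   treated categorically, numerics continuously.
#' @param screen_interactions Apply the interaction screen and refit? Default
#'   `TRUE`.
#' @param alpha Significance level for the interaction screen; default 0.05.
#' @param interactions Include interaction terms at all? With `FALSE` the
#'   main-effects model is fitted directly (useful when empty factor cells
#'   make the factorial design rank-deficient, which otherwise errors).
#' @return Object of class `mf_ancova`; [tidy()] gives the term table,
#'   [glance()] the model summary.
#' @export
ancova <- function(data, outcome, predictors = c("age", "fd", "qc", "gender"),
                   screen_interactions = TRUE, alpha = 0.05,
                   interactions = TRUE) {
  miss <- setdiff(c(outcome, predictors), names(data))
  if (length(miss) > 0)
    abort(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  d <- as.data.frame(data[, c(outcome, predictors)])
  for (p in predictors) if (is.character(d[[p]])) d[[p]] <- factor(d[[p]])
  for (p in predictors)
    if (is.factor(d[[p]]) && any(table(droplevels(d[[p]])) == 0))
      abort(sprintf("empty level in predictor '%s'", p))
  for (p in predictors) if (is.factor(d[[p]])) d[[p]] <- droplevels(d[[p]])

  contr <- lapply(predictors[vapply(d[predictors], is.factor, TRUE)],
                  function(p) "contr.sum")
  names(contr) <- predictors[vapply(d[predictors], is.factor, TRUE)]

  main_formula <- stats::as.formula(
    paste(outcome, "~", paste(predictors, collapse = " + ")))
  if (interactions) {
    full_formula <- stats::as.formula(
      paste(outcome, "~", paste(predictors, collapse = " * ")))
    fit_full <- stats::lm(full_formula, data = d, contrasts = contr)
    if (fit_full$rank < ncol(stats::model.matrix(fit_full))) {
      aliased <- names(which(is.na(coef(fit_full))))
      abort(sprintf("rank-deficient design; aliased columns: %s",
                    paste(aliased, collapse = ", ")))
    }
    tab <- as.data.frame(car::Anova(fit_full, type = 3))
    is_inter <- grepl(":", rownames(tab))
    any_sig <- any(tab$`Pr(>F)`[is_inter] < alpha, na.rm = TRUE)
    refit <- screen_interactions && !any_sig
    if (refit) {
      fit <- stats::lm(main_formula, data = d, contrasts = contr)
      tab <- as.data.frame(car::Anova(fit, type = 3))
    } else {
      fit <- fit_full
    }
  } else {
    fit <- fit_full <- stats::lm(main_formula, data = d, contrasts = contr)
    if (fit$rank < ncol(stats::model.matrix(fit))) {
      aliased <- names(which(is.na(coef(fit))))
      abort(sprintf("rank-deficient design; aliased columns: %s",
                    paste(aliased, collapse = ", ")))
    }
    tab <- as.data.frame(car::Anova(fit, type = 3))
    any_sig <- NA
    refit <- FALSE
  }
  keep <- !rownames(tab) %in% c("(Intercept)", "Residuals")
  ss_res <- tab["Residuals", "Sum Sq"]
  terms <- tibble(
    term = rownames(tab)[keep],
    sumsq = tab$`Sum Sq`[keep], df = tab$Df[keep],
    statistic = tab$`F value`[keep], p.value = tab$`Pr(>F)`[keep],
    partial_eta_sq = tab$`Sum Sq`[keep] / (tab$`Sum Sq`[keep] + ss_res))
  sm <- summary(fit)
  structure(list(
    terms = terms,
    model = list(adj_r_sq = sm$adj.r.squared,
                 r_sq = sm$r.squared,
                 statistic = unname(sm$fstatistic[1]),
                 df_model = unname(sm$fstatistic[2]),
                 df_resid = unname(sm$fstatistic[3]),
                 sigma = sm$sigma),
    interaction_screen = list(tested = screen_interactions && interactions,
                              any_significant = any_sig,
                              refit_main_effects = refit,
                              alpha = alpha),
    fit = fit, fit_full = fit_full, outcome = outcome,
    predictors = predictors
  ), class = "mf_ancova")
}

#' @export
print.mf_ancova <- function(x, ...) {
  cat(sprintf("<mf_ancova> %s ~ %s%s\n  F(%d, %d) = %.2f, adj. R^2 = %.3f\n",
              x$outcome, paste(x$predictors, collapse = " + "),
              if (x$interaction_screen$refit_main_effects)
                " (main effects; no significant interactions)" else
                " (with interactions)",
              x$model$df_model, x$model$df_resid, x$model$statistic,
              x$model$adj_r_sq))
  print(as.data.frame(x$terms), digits = 4)
  invisible(x)
}

#' @export
tidy.mf_ancova <- function(x, ...) x$terms

#' @export
glance.mf_ancova <- function(x, ...) {
  tibble(adj.r.squared = x$model$adj_r_sq, r.squared = x$model$r_sq,
         statistic = x$model$statistic, df = x$model$df_model,
         df.residual = x$model$df_resid, sigma = x$model$sigma,
         refit_main_effects = x$interaction_screen$refit_main_effects)
}

# Partial eta-squared of one continuous term from main-effects model
# matrices, via full-vs-reduced residual sums of squares.
eta_sq_term <- function(y, X_full, drop_col) {
  rss_full <- sum(stats::lm.fit(X_full, y)$residuals^2)
  rss_red <- sum(stats::lm.fit(X_full[, -drop_col, drop = FALSE], y)$residuals^2)
  ss <- rss_red - rss_full
  ss / (ss + rss_full)
}

#' Change in the age effect size when controlling for motion and QC
#'
#' Computes the partial eta-squared of age on the outcome from a model
#' ignoring QC ratings and all-task FD, and again from a model controlling
#' for them (main effects), and tests whether the reduction exceeds chance by
#' jointly permuting the (FD, QC) rows against the fixed (age, gender,
#' outcome) rows. The p-value is upper-tail with the plus-one rule.
#'
#' @inheritParams ancova
#' @param age,fd,qc,gender Column names for the four predictors.
#' @param n_perm Number of permutations; default 1000.
#' @param seed Integer seed.
#' @return Object of class `mf_esc` with `eta_sq_without`, `eta_sq_with`,
#'   `delta`, `p_perm`.
#' @export
effect_size_change <- function(data, outcome, age = "age", fd = "fd",
                               qc = "qc", gender = "gender",
                               n_perm = 1000, seed = 1) {
  if (n_perm < 1) abort("n_perm must be at least 1 (degenerate null)")
  d <- as.data.frame(data[, c(outcome, age, fd, qc, gender)])
  names(d) <- c("y", "age", "fd", "qc", "gender")
  d$qc <- droplevels(factor(d$qc)); d$gender <- droplevels(factor(d$gender))
  y <- d$y
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  X_without <- stats::model.matrix(~ age + gender, data = d)
  X_with <- stats::model.matrix(~ age + fd + qc + gender, data = d)
  age_w <- which(colnames(X_without) == "age")
  age_f <- which(colnames(X_with) == "age")
  eta_without <- eta_sq_term(y, X_without, age_w)
  eta_with <- eta_sq_term(y, X_with, age_f)
  delta <- eta_without - eta_with

  nuis <- which(!colnames(X_with) %in% colnames(X_without))
  set.seed(sub_seed(seed, "effect_size_change"))
  null_delta <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(nrow(d))
    Xp <- X_with
    Xp[, nuis] <- X_with[idx, nuis]     # permute FD and QC rows jointly
    null_delta[b] <- eta_without - eta_sq_term(y, Xp, age_f)
  }
  structure(list(eta_sq_without = eta_without, eta_sq_with = eta_with,
                 delta = delta,
                 p_perm = perm_pvalue(sum(null_delta >= delta), n_perm),
                 null_delta = summary(null_delta),
                 n_perm = n_perm, seed = seed),
            class = "mf_esc")
}

#' @export
print.mf_esc <- function(x, ...) {
  cat(sprintf("age eta^2: %.3f (without QC/FD) -> %.3f (with); delta = %.3f, perm p = %.3g\n",
              x$eta_sq_without, x$eta_sq_with, x$delta, x$p_perm))
  invisible(x)
}

#' @export
tidy.mf_esc <- function(x, ...) {
  tibble(eta_sq_without = x$eta_sq_without, eta_sq_with = x$eta_sq_with,
         delta = x$delta, p_perm = x$p_perm, n_perm = x$n_perm)
}
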