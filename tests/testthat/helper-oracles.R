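# Independent oracles and fixture builders shared across the suite. Each
# oracle is a deliberately naive re-implementation (loops, enumeration,
# normal equations) kept free of any package internals.

# per-frame loop oracle for framewise displacement
fd_oracle <- function(series, radius = 50) {
  s <- series[order(series$frame), ]
  p <- cbind(s$trans_x, s$trans_y, s$trans_z,
             s$rot_x * radius, s$rot_y * radius, s$rot_z * radius)
  out <- numeric(nrow(p) - 1)
  for (t in 2:nrow(p)) {
    acc <- 0
    for (j in 1:6) acc <- acc + abs(p[t, j] - p[t - 1, j])
    out[t - 1] <- acc
  }
  out
}

random_series <- function(n_frames, participant_id = "p1", run_id = "r1",
                          scale = 0.1) {
  tibble::tibble(
    participant_id = participant_id, run_id = run_id,
    frame = seq_len(n_frames),
    trans_x = cumsum(rnorm(n_frames, 0, scale)),
    trans_y = cumsum(rnorm(n_frames, 0, scale)),
    trans_z = cumsum(rnorm(n_frames, 0, scale)),
    rot_x = cumsum(rnorm(n_frames, 0, scale / 50)),
    rot_y = cumsum(rnorm(n_frames, 0, scale / 50)),
    rot_z = cumsum(rnorm(n_frames, 0, scale / 50)))
}

# Spearman via explicit rank transform then Pearson
rank_pearson <- function(x, y) cor(rank(x), rank(y))

# Cohen's kappa straight from a cross-table
kappa_hand <- function(tab) {
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

# Type III sums of squares by normal equations: RSS(model without the
# term's columns) minus RSS(full model), under sum-to-zero contrasts.
type3_oracle <- function(d, outcome, rhs_formula) {
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  mf <- stats::model.frame(stats::as.formula(paste(outcome, rhs_formula)), d)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  y <- stats::model.response(mf)
  asg <- attr(X, "assign")
  labs <- attr(stats::terms(mf), "term.labels")
  rss <- function(M) sum(stats::lm.fit(M, y)$residuals^2)
  rss_full <- rss(X)
  df_res <- nrow(X) - ncol(X)
  out <- lapply(seq_along(labs), function(k) {
    drop <- which(asg == k)
    ss <- rss(X[, -drop, drop = FALSE]) - rss_full
    df <- length(drop)
    data.frame(term = labs[k], sumsq = ss, df = df,
               statistic = (ss / df) / (rss_full / df_res),
               partial_eta_sq = ss / (ss + rss_full))
  })
  list(terms = do.call(rbind, out), rss = rss_full, df_resid = df_res)
}

# partial correlation via the precision (inverse correlation) matrix
partial_corr_oracle <- function(y, x, Z) {
  M <- cbind(y, x, Z)
  P <- solve(cor(M))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

small_cohort <- function(n = 60, seed = 99, n_vertices = 40, n_parcels = 8,
                         ...) {
  cfg <- motionflag::cohort_config(
    n_participants = n, per_decade_min = max(1, floor(n / 14)),
    thickness = utils::modifyList(
      motionflag::cohort_config()$thickness,
      c(list(n_vertices = n_vertices, n_parcels = n_parcels), list(...))),
    runs = tibble::tibble(
      task = c("VV", "VV", "words", "scenes", "rest"),
      run_id = c("VV1", "VV2", "words", "scenes1", "rest"),
      n_frames = c(30L, 30L, 35L, 25L, 20L)))
  motionflag::generate_cohort(cfg, seed = seed)
}
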