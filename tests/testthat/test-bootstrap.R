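mk_cohort_table <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(participant_id = sprintf("p%03d", 1:n),
                 age = runif(n, 20, 89),
                 gender = factor(sample(c("F", "M"), n, TRUE)))
}

test_that("matched pools equal a brute-force sort of candidates", {
  cohort <- mk_cohort_table(120, seed = 70)
  flagged <- cohort$participant_id[c(3, 40, 77)]
  pools <- matched_pools(flagged, cohort, pool_size = 10)
  for (fid in flagged) {
    frow <- cohort[cohort$participant_id == fid, ]
    cand <- cohort[!cohort$participant_id %in% flagged &
                     cohort$gender == frow$gender, ]
    ord <- order(abs(cand$age - frow$age), cand$participant_id)
    expect_equal(pools$candidate_id[pools$flagged_id == fid],
                 cand$participant_id[ord][1:10])
  }
})

test_that("pool ties at the boundary break lexicographically and stably", {
  cohort <- tibble::tibble(
    participant_id = c("f1", sprintf("c%02d", 1:12)),
    age = c(50, rep(49, 6), rep(51, 6)),
    gender = factor("F", levels = c("F", "M")))
  p1 <- matched_pools("f1", cohort, pool_size = 10)
  p2 <- matched_pools("f1", cohort, pool_size = 10)
  expect_identical(p1, p2)
  # all 12 candidates tie at |diff| = 1; the 10 smallest IDs win
  expect_equal(sort(p1$candidate_id),
               sort(cohort$participant_id[2:13])[1:10])
  small <- cohort[1:5, ]
  expect_error(matched_pools("f1", small, pool_size = 10),
               "only 4 same-gender")
})

test_that("degenerate metrics give p = 1 and planted shifts give minimal p", {
  cohort <- mk_cohort_table(100, seed = 71)
  flagged <- cohort$participant_id[1:8]
  pools <- matched_pools(flagged, cohort, pool_size = 10)
  const <- setNames(rep(2.5, 100), cohort$participant_id)
  b <- suppressWarnings(matched_bootstrap_null(pools, const, n_boot = 50,
                                               seed = 1))
  expect_equal(b$observed, 2.5)
  expect_equal(b$p, 1)

  set.seed(72)
  metric <- setNames(rnorm(100, 2.5, 0.05), cohort$participant_id)
  metric[flagged] <- metric[flagged] - 3 * 0.05   # -3 SD planted shift
  b2 <- matched_bootstrap_null(pools, metric, n_boot = 2000, seed = 2)
  expect_equal(b2$p, 1 / 2001, tolerance = 20 / 2001)
  expect_error(matched_bootstrap_null(pools, metric, n_boot = 0), "positive")
  expect_warning(matched_bootstrap_null(pools, metric, n_boot = 50, seed = 1),
                 "coarse")
})

test_that("the bootstrap null centres on the mean of pool-candidate means", {
  cohort <- mk_cohort_table(150, seed = 73)
  flagged <- cohort$participant_id[1:10]
  pools <- matched_pools(flagged, cohort, pool_size = 10)
  set.seed(74)
  metric <- setNames(rnorm(150, 2.5, 0.1), cohort$participant_id)
  b <- matched_bootstrap_null(pools, metric, n_boot = 20000, seed = 3)
  expected <- mean(tapply(metric[pools$candidate_id], pools$flagged_id, mean))
  expect_lt(abs(b$null$mean - expected), 0.003)
  # bit-reproducible under a fixed seed
  b2 <- matched_bootstrap_null(pools, metric, n_boot = 20000, seed = 3)
  expect_identical(b$null_values, b2$null_values)
})

test_that("vertex-wise t-tests match a hand-computed two-by-two case", {
  mat <- rbind(a1 = c(2.0, 3.0), a2 = c(2.2, 3.2),
               b1 = c(2.6, 3.1), b2 = c(2.8, 3.3))
  res <- vertexwise_group_ttest(mat, c("a1", "a2"), c("b1", "b2"))
  # vertex 1: means 2.1 vs 2.7, pooled sd 0.1414..., se 0.1414, t = -4.2426
  sp <- sqrt((0.02 + 0.02) / 2)
  expect_equal(res$statistic[1], (2.1 - 2.7) / (sp * sqrt(1)),
               tolerance = 1e-10)
  expect_equal(res$df[1], 2)
  expect_equal(res$p.value[1],
               t.test(c(2.0, 2.2), c(2.6, 2.8), var.equal = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("group t-maps are calibrated under the null and powered when shifted", {
  set.seed(75)
  n <- 30; nv <- 400
  mat <- matrix(rnorm(2 * n * nv, 2.5, 0.2), 2 * n, nv)
  rownames(mat) <- sprintf("p%03d", 1:(2 * n))
  ids_a <- rownames(mat)[1:n]; ids_b <- rownames(mat)[(n + 1):(2 * n)]
  null_res <- vertexwise_group_ttest(mat, ids_a, ids_b)
  expect_lte(mean(null_res$q.value < 0.05), 0.02)

  shifted <- mat
  shifted[ids_a, 1:80] <- shifted[ids_a, 1:80] - 0.3
  res <- vertexwise_group_ttest(shifted, ids_a, ids_b)
  expect_gt(mean(res$q.value[1:80] < 0.05), 0.9)
  expect_error(vertexwise_group_ttest(mat, ids_a[1], ids_b), "at least 2")
})

test_that("FDR in the t-map is applied within each hemisphere", {
  set.seed(76)
  mat <- matrix(rnorm(40 * 20, 2.5, 0.2), 40, 20)
  rownames(mat) <- sprintf("p%03d", 1:40)
  th <- motionflag:::new_thickness(mat)   # first 10 lh, last 10 rh
  res <- vertexwise_group_ttest(th, rownames(mat)[1:20], rownames(mat)[21:40])
  expect_equal(res$q.value[res$hemisphere == "lh"],
               p.adjust(res$p.value[res$hemisphere == "lh"], "BH"),
               tolerance = 1e-12)
  expect_equal(res$q.value[res$hemisphere == "rh"],
               p.adjust(res$p.value[res$hemisphere == "rh"], "BH"),
               tolerance = 1e-12)
})

test_that("age-effect comparison is exactly null when nothing is removed", {
  set.seed(77)
  co <- small_cohort(n = 56, seed = 77)
  res <- age_effect_comparison(co$thickness, co$cohort,
                               co$cohort$participant_id)
  expect_equal(res$z_diff, 0)
  expect_equal(res$ks$D, 0)
  expect_equal(res$bartlett$statistic, 0, tolerance = 1e-10)
  expect_error(age_effect_comparison(co$thickness, co$cohort, "nobody"),
               "subset")
})

test_that("KS statistic matches the hand computation on 5-element vectors", {
  a <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  b <- c(0.15, 0.25, 0.35, 0.45, 0.55)
  # hand max CDF gap: at x = 0.1..: CDFs step by 0.2 alternating -> D = 0.2
  got <- suppressWarnings(ks.test(a, b)$statistic)
  expect_equal(unname(got), 0.2)
  mat <- matrix(runif(5 * 6, 2, 3), 5, 6,
                dimnames = list(sprintf("p%d", 1:5), NULL))
  cohort <- tibble::tibble(participant_id = sprintf("p%d", 1:5),
                           age = c(25, 35, 45, 55, 65))
  res <- age_effect_comparison(mat, cohort, sprintf("p%d", 1:4))
  va <- as.numeric(cor(cohort$age, mat))
  vb <- as.numeric(cor(cohort$age[1:4], mat[1:4, ]))
  cdf_gap <- max(abs(ecdf(va)(sort(c(va, vb))) - ecdf(vb)(sort(c(va, vb)))))
  expect_equal(res$ks$D, cdf_gap, tolerance = 1e-12)
})

test_that("removing combined-rule flags attenuates the age effect overall", {
  co <- small_cohort(n = 140, seed = 78, n_vertices = 120, n_parcels = 24)
  m <- aggregate_motion(summarize_runs(compute_fd(co$realignment)),
                        co$manifest)
  comp <- composite_ratings(co$ratings)
  combined <- combine_flags(flag_high_movers(m), comp)
  retained <- combined$participant_id[!combined$flagged]
  res <- age_effect_comparison(co$thickness, co$cohort, retained)
  # motion bias inflates the negative age correlation; removal moves the
  # Fisher-z values toward zero in most parcels
  expect_gt(mean(res$parcel$delta_z >= 0), 0.5)
  expect_gte(res$r_after, res$r_before)   # less negative overall
})

test_that("the control envelope separates planted bias from its absence", {
  # subject_sd off: a shared anatomical offset adds a map-wide random
  # component that swamps CDF comparisons at this scale (see vignette)
  run_env <- function(beta, seed) {
    co <- small_cohort(n = 120, seed = seed, n_vertices = 80, n_parcels = 16,
                       motion_beta = beta, subject_sd = 0)
    m <- aggregate_motion(summarize_runs(compute_fd(co$realignment)),
                          co$manifest)
    analysis <- dplyr::left_join(m, co$cohort, by = "participant_id")
    flagged <- names(sort(co$truth$severity, decreasing = TRUE))[1:15]
    pools <- matched_pools(flagged, co$cohort, pool_size = 8)
    leaveout_control_envelope(co$thickness, analysis, flagged, pools,
                              n_groups = 60, seed = 4)
  }
  env_bias <- run_env(-0.5, 79)
  env_null <- run_env(0, 80)
  # strong negative bias: removing the biased scans shifts the correlation
  # CDF toward zero, well beyond the control envelope
  expect_true(env_bias$exits)
  expect_gt(env_bias$mean_shift, 0)
  expect_gt(env_bias$prop_outside, env_null$prop_outside)
  expect_gt(env_bias$mean_shift, abs(env_null$mean_shift))
})

test_that("a single control group degrades to a degenerate envelope", {
  co <- small_cohort(n = 60, seed = 81, n_vertices = 20, n_parcels = 4)
  m <- aggregate_motion(summarize_runs(compute_fd(co$realignment)),
                        co$manifest)
  analysis <- dplyr::left_join(m, co$cohort, by = "participant_id")
  flagged <- names(sort(co$truth$severity, decreasing = TRUE))[1:6]
  pools <- matched_pools(flagged, co$cohort, pool_size = 5)
  expect_warning(
    leaveout_control_envelope(co$thickness, analysis, flagged, pools,
                              n_groups = 1, seed = 6),
    "degenerate")
})
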