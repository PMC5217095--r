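mk_run_summaries <- function(...) {
  cols <- list(...)
  n <- length(cols[[1]])
  dplyr::bind_rows(lapply(names(cols), function(r)
    tibble::tibble(participant_id = sprintf("p%03d", seq_len(n)),
                   run_id = r, n_fd = 10L, fd_mean = cols[[r]],
                   fd_median = cols[[r]])))
}

test_that("rank correlations hit the exact extremes for monotone inputs", {
  set.seed(30)
  x <- rlnorm(20, -2, 0.5)
  st <- stability_matrix(mk_run_summaries(r1 = x, r2 = exp(x)),
                         n_perm = 200, seed = 1)
  expect_equal(st$rho["r1", "r2"], 1)
  expect_equal(st$p_perm["r1", "r2"], 1 / 201)
  st2 <- stability_matrix(mk_run_summaries(r1 = x, r2 = -x), n_perm = 100)
  expect_equal(st2$rho["r1", "r2"], -1)
})

test_that("the Spearman matrix equals rank-then-Pearson everywhere", {
  set.seed(31)
  runs <- setNames(lapply(1:4, function(i) rlnorm(12, -2, 0.4)),
                   paste0("r", 1:4))
  st <- stability_matrix(do.call(mk_run_summaries, runs), n_perm = 50)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(st$rho[i, j], rank_pearson(runs[[i]], runs[[j]]),
                 tolerance = 1e-12)
})

test_that("permutation p agrees with exhaustive enumeration at n = 6", {
  set.seed(32)
  x <- c(0.11, 0.25, 0.08, 0.31, 0.19, 0.14)
  y <- c(0.13, 0.22, 0.10, 0.24, 0.30, 0.12)
  perms <- gtools_permutations <- NULL
  # enumerate all 720 orderings of x against intact y
  idx <- expand.grid(rep(list(1:6), 6))
  idx <- idx[apply(idx, 1, function(r) length(unique(r)) == 6), ]
  obs <- rank_pearson(x, y)
  null <- apply(idx, 1, function(r) rank_pearson(x[unlist(r)], y))
  exact_p <- mean(null >= obs - 1e-12)
  st <- stability_matrix(mk_run_summaries(r1 = x, r2 = y),
                         n_perm = 4000, seed = 7)
  p <- st$p_perm["r1", "r2"]
  ci <- qbinom(c(0.0005, 0.9995), 4000, exact_p) / 4000
  expect_gte(p, ci[1])
  expect_lte(p, ci[2] + 1 / 4000)
})

test_that("permutation p-values are never zero and uniform under the null", {
  set.seed(33)
  n_rep <- 400
  ps <- replicate(n_rep, {
    st <- stability_matrix(mk_run_summaries(r1 = rnorm(15), r2 = rnorm(15)),
                           n_perm = 99, seed = sample.int(1e6, 1))
    st$p_perm["r1", "r2"]
  })
  expect_true(all(ps > 0))
  rej <- mean(ps <= 0.05)
  ci <- qbinom(c(0.005, 0.995), n_rep, 0.05) / n_rep
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])
})

test_that("constant runs are rejected rather than returning NaN", {
  expect_error(stability_matrix(mk_run_summaries(r1 = rep(0.2, 10),
                                                 r2 = runif(10)),
                                n_perm = 10),
               "constant")
})

test_that("scan-order ANOVA matches a hand-computed two-group case", {
  rs <- mk_run_summaries(r1 = c(1, 2, 3), r2 = c(4, 5, 6))
  got <- scan_order_test(rs)
  # hand ANOVA: grand mean 3.5, SSB = 2*3*(1.5^2)/... = 13.5, SSW = 4
  expect_equal(got$statistic, (13.5 / 1) / (4 / 4), tolerance = 1e-12)
  expect_equal(got$df1, 1)
  expect_equal(got$df2, 4)

  sep <- mk_run_summaries(r1 = rnorm(20, 0, 0.01), r2 = rnorm(20, 5, 0.01))
  expect_lt(scan_order_test(sep)$p.value, 1e-6)
})

mk_comp <- function(ratings) {
  tibble::tibble(participant_id = sprintf("p%03d", seq_along(ratings)),
                 rating = factor(ratings, levels = rating_levels(),
                                 ordered = TRUE),
                 n_raters = 2L)
}

test_that("group tests separate rating groups and match enumeration", {
  motion <- tibble::tibble(participant_id = sprintf("p%03d", 1:6),
                           fd_all_task = c(1, 2, 3, 4, 5, 6))
  comp <- mk_comp(c("pass", "pass", "pass", "warn", "warn", "warn"))
  res <- group_difference_tests(motion, comp)
  pair <- res[res$test == "rank_sum", ]
  expect_equal(pair$statistic, 0)   # complete separation
  expect_lt(pair$z, 0)              # pass group lower

  # normal-approximation p close to the exact rank-sum p at moderate n
  set.seed(34)
  x <- rnorm(9); y <- rnorm(9, 0.8)
  motion2 <- tibble::tibble(participant_id = sprintf("p%03d", 1:18),
                            fd_all_task = c(x, y))
  comp2 <- mk_comp(rep(c("pass", "warn"), each = 9))
  res2 <- group_difference_tests(motion2, comp2)
  exact <- wilcox.test(x, y, exact = TRUE)$p.value
  got <- res2$p.value[res2$test == "rank_sum"]
  expect_lt(abs(got - exact), 0.02)
})

test_that("Kruskal-Wallis output matches the base implementation", {
  set.seed(35)
  motion <- tibble::tibble(participant_id = sprintf("p%03d", 1:60),
                           fd_all_task = rlnorm(60, -2, 0.5))
  comp <- mk_comp(sample(rating_levels(), 60, TRUE))
  res <- group_difference_tests(motion, comp)
  kw <- kruskal.test(motion$fd_all_task, factor(as.character(comp$rating)))
  expect_equal(res$statistic[res$test == "kruskal_wallis"],
               unname(kw$statistic), tolerance = 1e-12)
})

test_that("combined flags follow inclusion-exclusion on constructed sets", {
  ids <- sprintf("p%03d", 1:266)
  fd_set <- ids[1:18]
  fail_set <- c(ids[15:18], ids[30:42])   # overlap of 4, 17 fails
  flags <- tibble::tibble(participant_id = ids, flagged = ids %in% fd_set)
  comp <- mk_comp(ifelse(ids %in% fail_set, "fail", "pass"))
  out <- combine_flags(flags, comp)
  expect_equal(sum(out$flagged), 31)
  expect_equal(sum(out$source == "both"), 4)
  expect_equal(sum(out$source == "fd"), 14)
  expect_equal(sum(out$source == "qc"), 13)
  expect_true(all(out$flagged == (out$source != "none")))

  # disjoint and identical sets
  flags2 <- tibble::tibble(participant_id = ids[1:10],
                           flagged = ids[1:10] %in% ids[1:3])
  comp2 <- mk_comp(ifelse(ids[1:10] %in% ids[4:5], "fail", "pass"))
  expect_equal(sum(combine_flags(flags2, comp2)$flagged), 5)
  comp3 <- mk_comp(ifelse(ids[1:10] %in% ids[1:3], "fail", "pass"))
  expect_equal(sum(combine_flags(flags2, comp3)$flagged), 3)
  expect_error(combine_flags(flags2, mk_comp(rep("pass", 3))),
               "universes differ")
})

test_that("overlap analysis reproduces printed sensitivity and specificity", {
  ids <- sprintf("p%03d", 1:266)
  fd_set <- ids[1:18]
  fail_set <- c(ids[1:4], ids[100:112])   # 17 fails, 4 overlapping
  ov <- overlap_analysis(fd_set, fail_set, ids, n_perm = 500, seed = 2)
  expect_equal(round(ov$sensitivity, 2), 0.22)
  expect_equal(round(ov$specificity, 2), 0.95)
  expect_equal(ov$counts$n_union, 31)

  same <- overlap_analysis(fd_set, fd_set, ids, n_perm = 100, seed = 2)
  expect_equal(same$sensitivity, 1)
  expect_equal(same$specificity, 1)
})

test_that("the permutation null sensitivity centres on |qc|/n", {
  set.seed(36)
  ids <- sprintf("p%03d", 1:200)
  fd_set <- sample(ids, 25)
  qc_set <- sample(ids, 20)
  ov <- overlap_analysis(fd_set, qc_set, ids, n_perm = 5000, seed = 9)
  expect_lt(abs(ov$null_mean_sens - 20 / 200), 0.01)
  expect_error(overlap_analysis(character(0), qc_set, ids), "empty FD")
})
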