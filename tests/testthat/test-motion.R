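test_that("FD is zero for a motionless series and matches the direct formula", {
  s <- tibble::tibble(participant_id = "p", run_id = "r", frame = 1:5,
                      trans_x = 1.2, trans_y = -0.4, trans_z = 0,
                      rot_x = 0.01, rot_y = 0, rot_z = -0.02)
  expect_true(all(compute_fd(s)$fd == 0))

  two <- tibble::tibble(participant_id = "p", run_id = "r", frame = 1:2,
                        trans_x = c(0, 0.1), trans_y = 0, trans_z = 0,
                        rot_x = c(0, 0.002), rot_y = 0, rot_z = 0)
  expect_equal(compute_fd(two, radius = 50)$fd, 0.1 + 50 * 0.002)
})

test_that("FD equals a per-frame loop oracle on random series", {
  set.seed(10)
  for (i in 1:25) {
    s <- random_series(sample(5:30, 1))
    expect_equal(compute_fd(s)$fd, fd_oracle(s), tolerance = 1e-12)
  }
})

test_that("FD is linear in rotation scaling and translation invariant", {
  set.seed(11)
  s <- random_series(15)
  # scale-then-difference equals difference-then-scale
  pre <- s
  pre$rot_x <- pre$rot_x * 50; pre$rot_y <- pre$rot_y * 50
  pre$rot_z <- pre$rot_z * 50
  expect_equal(compute_fd(s, radius = 50)$fd, compute_fd(pre, radius = 1)$fd,
               tolerance = 1e-12)
  # constant offset on any parameter leaves FD unchanged
  shifted <- s
  shifted$trans_y <- shifted$trans_y + 7.3
  shifted$rot_z <- shifted$rot_z + 0.5
  expect_equal(compute_fd(shifted)$fd, compute_fd(s)$fd, tolerance = 1e-12)
})

test_that("leading-zero convention adds a structural first frame", {
  set.seed(12)
  s <- random_series(8)
  with0 <- compute_fd(s, include_leading_zero = TRUE)
  without <- compute_fd(s)
  expect_equal(nrow(with0), 8)
  expect_equal(nrow(without), 7)
  expect_equal(with0$fd[1], 0)
  expect_equal(with0$fd[-1], without$fd)
  expect_error(compute_fd(s[1, ]), "at least 2 frames")
})

test_that("run summaries use mean and median as stated", {
  fd <- tibble::tibble(participant_id = "p", run_id = "r", frame = 2:3,
                       fd = c(0.1, 0.3))
  sm <- summarize_runs(fd)
  expect_equal(sm$fd_mean, 0.2)
  spike <- tibble::tibble(participant_id = "p", run_id = "r", frame = 2:4,
                          fd = c(0.1, 0.1, 10))
  expect_equal(summarize_runs(spike)$fd_median, 0.1)
  set.seed(13)
  x <- runif(50)
  rnd <- tibble::tibble(participant_id = "p", run_id = "r",
                        frame = seq_along(x) + 1, fd = x)
  expect_equal(summarize_runs(rnd)$fd_mean, mean(x), tolerance = 1e-12)
  expect_equal(summarize_runs(rnd)$fd_median, median(x), tolerance = 1e-12)
})

make_summaries <- function(vals) {
  tibble::tibble(
    participant_id = "p",
    run_id = names(vals),
    n_fd = 10L, fd_mean = unname(vals), fd_median = unname(vals))
}

test_that("task and all-task aggregation averages runs then tasks", {
  man <- tibble::tibble(participant_id = "p",
                        task = c("A", "A", "B"),
                        run_id = c("a1", "a2", "b1"))
  agg <- aggregate_motion(make_summaries(c(a1 = 0.1, a2 = 0.3, b1 = 0.2)), man)
  expect_equal(agg$task_A, 0.2)
  expect_equal(agg$task_B, 0.2)
  expect_equal(agg$fd_all_task, 0.2)

  # four tasks: all-task equals the hand sum over 4
  man4 <- tibble::tibble(participant_id = "p", task = c("A", "B", "C", "D"),
                         run_id = c("a", "b", "c", "d"))
  agg4 <- aggregate_motion(
    make_summaries(c(a = 0.1, b = 0.2, c = 0.4, d = 0.5)), man4)
  expect_equal(agg4$fd_all_task, (0.1 + 0.2 + 0.4 + 0.5) / 4)
})

test_that("missing runs are dropped from task means, never imputed", {
  man <- tibble::tibble(participant_id = "p",
                        task = c("A", "A", "A", "B"),
                        run_id = c("a1", "a2", "a3", "b1"))
  # a3 absent from the summaries (incomplete scan)
  agg <- aggregate_motion(make_summaries(c(a1 = 0.1, a2 = 0.3, b1 = 0.4)), man)
  expect_equal(agg$task_A, 0.2)
  expect_equal(agg$fd_all_task, 0.3)
  none <- make_summaries(c(x = 0.1))
  expect_error(aggregate_motion(none, man), "zero available runs")
})

test_that("high-mover flagging matches the hand computation with n-1 SD", {
  vals <- tibble::tibble(participant_id = sprintf("p%02d", 1:10),
                         fd_all_task = c(rep(0.1, 9), 1.0))
  fl <- flag_high_movers(vals, k = 1.5)
  expect_equal(fl$sample_mean, 0.19)
  expect_equal(fl$sample_sd, sqrt(sum((vals$fd_all_task - 0.19)^2) / 9))
  expect_equal(fl$threshold, 0.19 + 1.5 * fl$sample_sd)
  expect_equal(fl$flags$participant_id[fl$flags$flagged], "p10")
})

test_that("flagging is translation invariant and empty when SD is zero", {
  set.seed(14)
  vals <- tibble::tibble(participant_id = sprintf("p%03d", 1:40),
                         fd_all_task = rlnorm(40, -2, 0.5))
  base <- flag_high_movers(vals)
  shifted <- flag_high_movers(vals %>%
                                dplyr::mutate(fd_all_task = fd_all_task + 3))
  expect_equal(base$flags$flagged, shifted$flags$flagged)
  expect_equal(shifted$threshold, base$threshold + 3)
  same <- flag_high_movers(tibble::tibble(participant_id = c("a", "b", "c"),
                                          fd_all_task = 0.2))
  expect_false(any(same$flags$flagged))
})

test_that("flagging equals a brute-force re-implementation on random samples", {
  set.seed(15)
  for (i in 1:20) {
    n <- sample(5:1000, 1)
    x <- rlnorm(n, -2, 0.6)
    tab <- tibble::tibble(participant_id = sprintf("p%04d", 1:n),
                          fd_all_task = x)
    k <- runif(1, 0.5, 3)
    got <- flag_high_movers(tab, k = k)
    thr <- mean(x) + k * sqrt(sum((x - mean(x))^2) / (n - 1))
    expect_equal(got$flags$flagged, x > thr)
  }
})
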