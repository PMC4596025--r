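test_that("velocity series matches displacement over time", {
  # stationary fish
  still <- new_trajectory(seq(0, 1, by = 0.04), rep(1.5, 26), rep(-2, 26))
  expect_true(all(velocity_series(still)$velocity_mm_s == 0))
  # constant 2 mm displacement per frame at 25 Hz -> 50 mm/s
  n <- 50
  tr <- new_trajectory(seq_len(n) / 25, cumsum(rep(2, n)), rep(0, n))
  v <- velocity_series(tr)
  expect_equal(nrow(v), n - 1)
  expect_equal(v$velocity_mm_s, rep(50, n - 1))
})

test_that("velocity series integrates back to path length", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(50:500, 1)
    tr <- new_trajectory(cumsum(runif(n, 0.01, 0.1)),
                         cumsum(rnorm(n, 0, 0.3)), cumsum(rnorm(n, 0, 0.3)))
    # brute-force path length, point by point
    path <- 0
    for (j in 2:n) {
      path <- path + sqrt((tr$x_mm[j] - tr$x_mm[j - 1])^2 +
                            (tr$y_mm[j] - tr$y_mm[j - 1])^2)
    }
    v <- velocity_series(tr)
    expect_equal(sum(v$velocity_mm_s * diff(tr$time_s)), path,
                 tolerance = 1e-12)
    expect_true(all(v$velocity_mm_s >= 0))
  }
})

test_that("non-monotone timestamps are rejected", {
  expect_error(new_trajectory(c(0, 1, 1), 1:3, 1:3), "increasing")
  expect_error(new_trajectory(c(0, 2, 1), 1:3, 1:3), "increasing")
  expect_error(velocity_series(data.frame(time_s = 1, x_mm = 1, y_mm = 1)),
               "two samples")
})

test_that("locomotion metrics satisfy their definitions", {
  # 600 s epoch, 6000 mm path -> mean velocity 10 mm/s
  n <- 600 * 25
  tr <- trajectory_from_speeds(rep(10, n), rate = 25)
  m <- locomotion_metrics(tr)
  expect_equal(m$distance, 6000, tolerance = 1e-9)
  expect_equal(m$epoch_duration, 600)
  expect_equal(m$mean_velocity, 10, tolerance = 1e-9)
  expect_equal(m$mean_velocity, m$distance / m$epoch_duration)
  expect_equal(m$active_fraction, 1)
  # stationary
  still <- new_trajectory(seq(0, 600, by = 0.04), rep(0, 15001), rep(0, 15001))
  ms <- locomotion_metrics(still)
  expect_equal(ms$distance, 0)
  expect_equal(ms$mean_velocity, 0)
  expect_equal(score_stage(still), 0L)
})

test_that("mean velocity is invariant to spatial unit-preserving rescale of time grid", {
  # same path sampled twice as fast: distance identical, mean velocity
  # identical (mm/s is grid independent)
  sp <- c(rep(0, 100), rep(8, 50), rep(0, 100))
  t1 <- trajectory_from_speeds(sp, rate = 25)
  t2 <- trajectory_from_speeds(rep(sp, each = 2), rate = 50)
  m1 <- locomotion_metrics(t1)
  m2 <- locomotion_metrics(t2)
  expect_equal(m1$mean_velocity, m2$mean_velocity, tolerance = 1e-9)
  expect_equal(m1$distance, m2$distance, tolerance = 1e-9)
})

test_that("percent change follows its definition and sign convention", {
  mk <- function(v) structure(list(mean_velocity = v, distance = v * 600),
                              class = "locomotion_metrics")
  expect_equal(percent_change(mk(10), mk(5)), -50)
  expect_equal(percent_change(mk(10), mk(10)), 0)
  expect_equal(percent_change(mk(8), mk(12)), 50)
  expect_error(percent_change(mk(0), mk(5)), "undefined")
  # distance-based option agrees for equal epochs
  expect_equal(percent_change(mk(10), mk(5), measure = "distance"), -50)
})

test_that("percent change is invariant to uniform spatial rescaling", {
  set.seed(3)
  sp <- runif(500, 0, 12)
  tr1 <- trajectory_from_speeds(sp, 25)
  tr2 <- trajectory_from_speeds(sp * 0.6, 25)
  scale_traj <- function(tr, c) new_trajectory(tr$time_s, tr$x_mm * c,
                                               tr$y_mm * c)
  pc <- percent_change(locomotion_metrics(tr1), locomotion_metrics(tr2))
  for (c in c(0.1, 3, 25)) {
    pc_scaled <- percent_change(locomotion_metrics(scale_traj(tr1, c)),
                                locomotion_metrics(scale_traj(tr2, c)))
    expect_equal(pc_scaled, pc, tolerance = 1e-9)
  }
})

test_that("stage scoring implements the three-stage scale", {
  # a 1-s bout at 25 mm/s is Stage III
  expect_equal(score_stage(bout_trajectory(25)), 3L)
  # zero movement is Stage 0
  expect_equal(score_stage(bout_trajectory(0)), 0L)
  # brief sub-threshold bouts are Stage I, sustained activity Stage II
  n <- 600 * 25
  brief <- rep(0, n); brief[seq(1, n, by = 10)] <- 8   # 10% active
  expect_equal(score_stage(trajectory_from_speeds(brief, 25)), 1L)
  busy <- rep(8, n)                                     # 100% active
  expect_equal(score_stage(trajectory_from_speeds(busy, 25)), 2L)
  # supra-threshold bout shorter than the minimum does not reach Stage III
  expect_equal(score_stage(bout_trajectory(25, bout_s = 0.2)), 0L)
})

test_that("stage flips to III exactly at the configured velocity threshold", {
  flip <- function(v) score_stage(bout_trajectory(v)) == 3L
  lo <- 5; hi <- 40
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    if (flip(mid)) hi <- mid else lo <- mid
  }
  expect_equal(hi, 20, tolerance = 1e-3)
  # and at a non-default threshold
  cfg <- stage_config(stage3_velocity_threshold = 12)
  expect_equal(score_stage(bout_trajectory(12.01), cfg), 3L)
  expect_lt(score_stage(bout_trajectory(11.99), cfg), 3L)
})

test_that("adding a supra-threshold bout never lowers the stage", {
  set.seed(11)
  for (i in 1:8) {
    sp <- runif(15000, 0, sample(c(1, 5, 10), 1))
    base <- trajectory_from_speeds(sp, 25)
    sp2 <- sp
    at <- sample(1000:13000, 1)
    sp2[at:(at + 30)] <- 25
    with_bout <- trajectory_from_speeds(sp2, 25)
    expect_gte(score_stage(with_bout), score_stage(base))
    expect_equal(score_stage(with_bout), 3L)
  }
})
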