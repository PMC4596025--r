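test_that("control variability is the sample SD of percent changes", {
  # changes -10% and +10% -> SD = sqrt(2)*10
  cp <- data.frame(baseline_velocity = c(10, 10),
                   second_velocity = c(9, 11))
  cs <- control_variability(cp)
  expect_equal(cs$n, 2)
  expect_equal(cs$sd_percent_change, sqrt(200), tolerance = 1e-12)
  expect_equal(cs$mean_percent_change, 0)
  # identical pairs -> SD 0
  same <- data.frame(baseline_velocity = c(5, 8, 12),
                     second_velocity = c(5, 8, 12))
  expect_equal(control_variability(same)$sd_percent_change, 0)
  # n - 1 denominator
  cp3 <- data.frame(baseline_velocity = rep(10, 3),
                    second_velocity = c(8, 10, 12))
  expect_equal(control_variability(cp3)$sd_percent_change, sd(c(-20, 0, 20)))
})

test_that("invalid control input is refused or excluded", {
  expect_error(control_variability(data.frame(baseline_velocity = 1,
                                              second_velocity = 1)),
               "at least two")
  zero <- data.frame(baseline_velocity = c(0, 10, 10),
                     second_velocity = c(5, 9, 11))
  expect_warning(cs <- control_variability(zero), "excluded")
  expect_equal(cs$n, 2)
})

test_that("threshold derivation rounds 2 SDs up to integer percent", {
  expect_identical(derive_threshold(21.8), 44L)
  expect_identical(derive_threshold(10), 20L)
  expect_identical(derive_threshold(21.4), 43L)  # ceil(42.8)
  expect_identical(derive_threshold(21.8, k_sd = 1), 22L)
  cs <- control_variability(data.frame(baseline_velocity = c(10, 10),
                                       second_velocity = c(9, 11)))
  expect_identical(derive_threshold(cs), 29L)    # ceil(2 * 14.14)
})

test_that("classification applies the decision rules with precedence", {
  crit <- hit_criteria()
  # all dead -> toxic
  tox <- classify_compound(compound_trial("a", make_fish(heartbeat = FALSE,
                                                         stimulus = FALSE)),
                           crit)
  expect_equal(tox$label, "toxic")
  expect_equal(tox$n_alive, 0)
  # mean -60%, 4/6 Stage 0 -> hit
  f <- make_fish(baseline = 10, treatment = 4,
                 stage = c(0, 0, 0, 0, 2, 2))
  hit <- classify_compound(compound_trial("b", f), crit)
  expect_equal(hit$label, "hit")
  expect_equal(hit$mean_percent_change, -60)
  expect_equal(hit$n_qualifying_stage, 4)
  # mean +50% -> hyperexcitable
  exc <- classify_compound(compound_trial("c", make_fish(treatment = 15,
                                                         stage = 2L)), crit)
  expect_equal(exc$label, "hyperexcitable")
  # mean -30%, all Stage 0 -> inactive (velocity criterion fails)
  ina <- classify_compound(compound_trial("d", make_fish(treatment = 7)),
                           crit)
  expect_equal(ina$label, "inactive")
  # velocity passes but stages do not -> inactive
  ina2 <- classify_compound(compound_trial("e", make_fish(treatment = 4,
                                                          stage = 2L)), crit)
  expect_equal(ina2$label, "inactive")
})

test_that("toxicity takes precedence over the other labels", {
  # would be a hit on velocity and stage, but half the fish are dead
  f <- make_fish(treatment = 4, stage = 0L,
                 heartbeat = c(rep(FALSE, 3), rep(TRUE, 3)),
                 stimulus = c(rep(FALSE, 3), rep(TRUE, 3)))
  expect_equal(classify_compound(compound_trial("t", f))$label, "toxic")
  # 2 of 6 dead is below the 50% rule -> not toxic
  f2 <- make_fish(treatment = 4, stage = 0L,
                  heartbeat = c(rep(FALSE, 2), rep(TRUE, 4)),
                  stimulus = c(rep(FALSE, 2), rep(TRUE, 4)))
  expect_equal(classify_compound(compound_trial("t2", f2))$label, "hit")
})

test_that("a fish alive by stimulus response alone is not dead", {
  f <- make_fish(treatment = 4, stage = 0L, heartbeat = FALSE,
                 stimulus = TRUE)
  cls <- classify_compound(compound_trial("s", f))
  expect_equal(cls$n_alive, 6)
  expect_equal(cls$label, "hit")
})

test_that("dead fish are excluded from velocity means and stage counts", {
  f <- make_fish(baseline = 10,
                 treatment = c(0.1, 0.1, 4, 4, 4, 4),
                 stage = c(0, 0, 0, 0, 0, 0),
                 heartbeat = c(FALSE, FALSE, rep(TRUE, 4)),
                 stimulus = c(FALSE, FALSE, rep(TRUE, 4)))
  cls <- classify_compound(compound_trial("x", f))
  expect_equal(cls$n_alive, 4)
  expect_equal(cls$mean_percent_change, -60)  # dead -99% fish not counted
  expect_equal(cls$label, "hit")
})

test_that("drug-induced Stage III drives hyperexcitability, baseline Stage III does not", {
  # mutants seize at baseline: treatment Stage III with baseline Stage III
  # is the unperturbed phenotype, not a proconvulsant signal
  f_base3 <- make_fish(treatment = 10, stage = 3L, baseline_stage = 3L)
  expect_equal(classify_compound(compound_trial("m", f_base3))$label,
               "inactive")
  # newly induced Stage III in >= 50% of fish is proconvulsant
  f_new3 <- make_fish(treatment = 10, stage = 3L, baseline_stage = 1L)
  expect_equal(classify_compound(compound_trial("n", f_new3))$label,
               "hyperexcitable")
  # unknown baseline stage counts (conservative)
  f_na <- make_fish(treatment = 10, stage = 3L)
  expect_equal(classify_compound(compound_trial("o", f_na))$label,
               "hyperexcitable")
})

test_that("minimal qualifying fish fraction is 50% (3 of 6)", {
  labels <- vapply(0:6, function(k) {
    f <- make_fish(baseline = 10, treatment = 4,
                   stage = c(rep(0L, k), rep(2L, 6 - k)))
    classify_compound(compound_trial("k", f))$label
  }, character(1))
  expect_equal(labels, c(rep("inactive", 3), rep("hit", 4)))
  k_min <- min(which(labels == "hit")) - 1
  expect_equal(100 * k_min / 6, 50)
})

test_that("per-fish velocity mode requires the threshold fish-wise", {
  crit <- hit_criteria(per_fish_velocity = TRUE)
  # mean is -60% but only 2/6 fish individually pass 44%
  f <- make_fish(baseline = 10, treatment = c(0.5, 0.5, 8, 8, 8, 7.6),
                 stage = 0L)
  expect_equal(classify_compound(compound_trial("p", f), crit)$label,
               "inactive")
  expect_equal(classify_compound(compound_trial("p", f))$label, "hit")
  # 3/6 fish pass individually
  f2 <- make_fish(baseline = 10, treatment = c(0.5, 0.5, 0.5, 8, 8, 8),
                  stage = 0L)
  expect_equal(classify_compound(compound_trial("q", f2), crit)$label, "hit")
})

test_that("fish with zero baseline are excluded with a warning", {
  f <- make_fish(baseline = c(0, rep(10, 5)), treatment = 4, stage = 0L)
  expect_warning(cls <- classify_compound(compound_trial("z", f)),
                 "zero baseline")
  expect_equal(length(cls$per_fish_changes), 5)
  expect_equal(cls$label, "hit")
})

test_that("more suppression never converts a hit to inactive", {
  set.seed(5)
  crit <- hit_criteria()
  for (i in 1:20) {
    tv <- runif(6, 1, 9)
    f <- make_fish(baseline = 10, treatment = tv,
                   stage = sample(0:2, 6, replace = TRUE))
    lab <- classify_compound(compound_trial("m", f), crit)$label
    f2 <- f
    f2$treatment_velocity <- f$treatment_velocity * runif(6, 0.1, 0.9)
    lab2 <- classify_compound(compound_trial("m", f2), crit)$label
    if (lab == "hit") expect_true(lab2 %in% c("hit"))
    if (lab == "inactive") expect_true(lab2 %in% c("inactive", "hit"))
  }
})

test_that("hits are confirmed only by two non-toxic hit trials", {
  mk <- function(label, id = "cpd") {
    structure(list(compound_id = id, label = label), class = "classification")
  }
  expect_true(confirm_hit(mk("hit"), mk("hit")))
  expect_false(confirm_hit(mk("hit"), mk("toxic")))
  expect_false(confirm_hit(mk("hit"), mk("inactive")))
  expect_false(confirm_hit(mk("toxic"), mk("hit")))
  expect_error(confirm_hit(mk("hit", "a"), mk("hit", "b")), "different")
})
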