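test_that("movement variance is gated by the previous outcome", {
  p <- model_params(alpha = 0.4, sigma_m = 0.81, sigma_e = 0.9)
  expect_equal(trial_variance(p, "success"), 0.6561)
  expect_equal(trial_variance(p, "failure"), 1.4661)
  expect_equal(trial_variance(p, "no_feedback"), 0.6561)
  p0 <- model_params(sigma_m = 0.81, sigma_e = 0)
  expect_equal(trial_variance(p0, "success"), trial_variance(p0, "failure"))
  expect_error(model_params(alpha = 1.2), "alpha")
  expect_error(model_params(sigma_m = 0), "sigma_m")
})

test_that("aim updates only after success, by proportion alpha", {
  p <- model_params(alpha = 0.4)
  set.seed(1)
  # certain reward: every step updates the aim toward the executed angle
  st <- model_state(aim = 0)
  res <- step_trial(st, p, flat_landscape(1))
  expect_equal(res$record$reward, 1L)
  expect_equal(res$state$aim, 0.4 * res$record$theta)
  expect_identical(res$state$last_outcome, "success")
  # impossible reward: aim frozen, exploration flagged for the next trial
  res2 <- step_trial(model_state(aim = 2), p, flat_landscape(0))
  expect_equal(res2$state$aim, 2)
  expect_identical(res2$state$last_outcome, "failure")
  # alpha between 0 and 1 puts the new aim strictly between aim and theta
  for (a in c(0.1, 0.5, 0.9)) {
    r3 <- step_trial(model_state(aim = 1), model_params(alpha = a),
                     flat_landscape(1))
    lo <- min(1, r3$record$theta); hi <- max(1, r3$record$theta)
    expect_true(r3$state$aim > lo && r3$state$aim < hi)
  }
})

test_that("a full session respects the schedule and feedback structure", {
  L <- exp1_landscape("steep", "CW")
  s <- simulate_participant(landscape = L, seed = 11)
  expect_equal(nrow(s), 450L)
  expect_equal(s$phase, rep(c("baseline", "experimental", "washout"),
                            c(50, 350, 50)))
  expect_true(all(is.na(s$reward[s$phase != "experimental"])))
  expect_true(all(s$reward[s$phase == "experimental"] %in% 0:1))
  # bit-reproducible under a fixed seed
  expect_identical(s, simulate_participant(landscape = L, seed = 11))
  expect_false(identical(s$theta,
                         simulate_participant(landscape = L, seed = 12)$theta))
})

test_that("with no reward and no exploration the session is pure motor noise", {
  p <- model_params(alpha = 0, sigma_m = 0.81, sigma_e = 0)
  s <- simulate_participant(p, flat_landscape(0), seed = 21)
  expect_equal(mean(s$theta), 0, tolerance = 0.12)
  expect_equal(sd(s$theta), 0.81, tolerance = 0.1)
  # alpha = 0 keeps the aim at 0 whatever the rewards
  s2 <- simulate_participant(model_params(alpha = 0),
                             exp1_landscape("steep", "CW"), seed = 22)
  expect_equal(mean(s2$theta[s2$phase == "experimental"]), 0, tolerance = 0.25)
})

test_that("washout retains the adapted aim", {
  # near-zero noise pins every reach to the aim, exposing the update rule
  p <- model_params(alpha = 0.4, sigma_m = 0.01, sigma_e = 0.01)
  co <- simulate_cohort(p, exp1_landscape("steep", "CW"), n = 1, seed = 31)
  wash <- co$mean_curve$mean[co$mean_curve$phase == "washout"]
  expect_equal(wash, rep(co$final_aim, 50), tolerance = 0.05)
})

test_that("empirical spread matches the variance gate", {
  p <- model_params(alpha = 0, sigma_m = 0.81, sigma_e = 0.9)
  sched <- trial_schedule(0L, 10000L, 0L)
  all_fail <- simulate_cohort(p, flat_landscape(0), sched, n = 1, seed = 41)
  th <- all_fail$theta[1, ]
  expect_equal(sd(th[-1]), sqrt(0.81^2 + 0.9^2), tolerance = 0.05)
  all_succ <- simulate_cohort(p, flat_landscape(1), sched, n = 1, seed = 42)
  expect_equal(sd(all_succ$theta[1, ]), 0.81, tolerance = 0.05)
})

test_that("cohorts summarize their members and stay reproducible", {
  L <- exp1_landscape("steep", "CW")
  one <- simulate_cohort(landscape = L, n = 1, seed = 51)
  s <- simulate_participant(landscape = L, seed = 51)
  expect_equal(one$mean_curve$mean, s$theta)
  co <- simulate_cohort(landscape = L, n = 25, seed = 52)
  expect_equal(colMeans(co$theta), co$mean_curve$mean)
  expect_equal(dim(experimental_matrix(co)), c(25L, 350L))
  co_mean <- simulate_cohort(landscape = L, n = 25, seed = 52, keep = "mean")
  expect_null(co_mean$theta)
  expect_equal(co_mean$mean_curve, co$mean_curve)
  # learners on the steep landscape end on the plateau more often than not
  finals <- rowMeans(experimental_matrix(co)[, 251:350])
  expect_gt(mean(finals > 1), 0.7)
})

test_that("planar reaching rewards the rectangle and updates per axis", {
  tgt <- rect_target(width = 2, length = 10)
  p <- model_params(alpha = 0.4, sigma_m = 0.5, sigma_e = 0.5)
  set.seed(61)
  res <- step_2d(list(aim = c(0, 0), last_outcome = "no_feedback"), p, tgt)
  inside <- abs(res$record$x) <= 1 && abs(res$record$y) <= 5
  expect_equal(res$record$reward, as.integer(inside))
  sim <- simulate_participant_2d(p, tgt, n_trials = 300, seed = 62)
  expect_equal(nrow(sim), 300L)
  hits <- sim$reward == 1L
  expect_true(all(abs(sim$x[hits]) <= 1 & abs(sim$y[hits]) <= 5))
  expect_error(rect_target(0, 5), "positive")
})
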