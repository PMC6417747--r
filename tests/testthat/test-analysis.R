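test_that("exponential fit recovers noiseless parameters exactly", {
  i <- 1:350
  for (truth in list(c(a = 4, lam = 30), c(a = 2.5, lam = 120),
                     c(a = -3, lam = 12))) {
    y <- truth["a"] * (1 - exp(-i / truth["lam"]))
    fit <- fit_exponential(y)
    expect_equal(fit$a, unname(truth["a"]), tolerance = 1e-6)
    expect_equal(fit$lambda, unname(truth["lam"]), tolerance = 1e-6)
    expect_lt(fit$rss, 1e-10)
    expect_true(fit$identifiable)
  }
})

test_that("a flat curve is flagged as unidentifiable", {
  fit <- fit_exponential(rep(0, 350))
  expect_equal(fit$a, 0, tolerance = 1e-6)
  expect_false(fit$identifiable)
})

test_that("bootstrap of two identical groups is symmetric", {
  set.seed(81)
  i <- 1:200
  base <- 3 * (1 - exp(-i / 40))
  grp <- t(replicate(12, base + rnorm(200, 0, 0.4)))
  bl <- bootstrap_lambda(grp, grp, n_resamples = 400)
  expect_equal(bl$p_value, 0.5, tolerance = 0.1)
  expect_true(bl$ci_a[1] <= bl$ci_a[2])
  # a group of identical participants always reproduces the same fit
  same <- rbind(base, base)
  bs <- bootstrap_lambda(same, n_resamples = 25)
  expect_lt(diff(range(bs$lam_a)), 1e-4)
})

test_that("bootstrap interval covers the point fit on simulated cohorts", {
  set.seed(82)
  co <- simulate_cohort(landscape = exp1_landscape("steep", "CW"), n = 30)
  point <- fit_exponential(co)$lambda
  bl <- bootstrap_lambda(co, n_resamples = 300)
  expect_true(point >= bl$ci_a[1] && point <= bl$ci_a[2])
})

test_that("final-reach classification respects cutoffs and pooling", {
  mk <- function(mu) data.frame(participant = 1, trial = 1:350,
                                phase = "experimental",
                                theta = rep(mu, 350),
                                reward = rep(0L, 350))
  expect_identical(classify_final(mk(3.5), 1, "exp1")$label, "learner")
  expect_identical(classify_final(mk(0.2), 1, "exp1")$label, "non_learner")
  expect_identical(classify_final(mk(-2), 1, "exp2")$label, "shallow_learner")
  expect_identical(classify_final(mk(-2), 1, "exp2")$direction, "CCW")
  expect_identical(classify_final(mk(0), 1, "exp2")$label, "non_learner")
  expect_identical(classify_final(mk(1.2), 0.5, "exp2")$label, "steep_learner")
  expect_identical(classify_final(mk(1.2), 1.5, "exp2")$label, "non_learner")
  expect_error(classify_final(mk(0)[1:50, ]), "at least")
  # sign-flip pooling mirrors the label
  s <- mk(2.3)
  flipped <- pool_sign_flip(s, "steepCCW")
  expect_identical(classify_final(s, 1, "exp2")$label, "steep_learner")
  expect_identical(classify_final(flipped, 1, "exp2")$label, "shallow_learner")
})

test_that("Nth-success prediction matches a hand-counted fixture", {
  # three individuals, 6 experimental trials each; steep slope at theta > 0
  theta <- rbind(c(0.5, 2.0, 3.0, 3.5, 3.8, 4.0),    # successes: +,+,+ -> steep final
                 c(-0.5, -2.0, -2.5, -3.0, -3.1, -3.0), # successes: -,-   -> shallow final
                 c(0.6, -0.7, 0.2, -0.1, 0.3, 0.0))  # successes: +,-   -> non-learner
  reward <- rbind(c(1L, 1L, 1L, 0L, 0L, 0L),
                  c(1L, 0L, 1L, 0L, 0L, 0L),
                  c(1L, 1L, 0L, 0L, 0L, 0L))
  res <- nth_success_prediction(theta, reward, max_n = 2, n_last = 5)
  get <- function(N, slope, cls)
    res$prob[res$N == N & res$slope == slope & res$class == cls]
  # N = 1: individuals 1 and 3 succeeded first on the steep side
  expect_equal(get(1, "steep", "steep_learner"), 0.5)
  expect_equal(get(1, "steep", "non_learner"), 0.5)
  expect_equal(get(1, "shallow", "shallow_learner"), 1)
  # N = 2: ind 1 steep (steep final), ind 2 shallow, ind 3 shallow (non)
  expect_equal(get(2, "steep", "steep_learner"), 1)
  expect_equal(get(2, "shallow", "shallow_learner"), 0.5)
  expect_equal(get(2, "shallow", "non_learner"), 0.5)
  expect_equal(res$n_cond[res$N == 2 & res$slope == "shallow"], rep(2L, 3))
  # probabilities are per-slope-and-N distributions
  agg <- aggregate(prob ~ N + slope, res, sum)
  expect_true(all(abs(agg$prob - 1) < 1e-12))
})

test_that("empty conditioning sets are reported as undefined", {
  theta <- rbind(c(1, 2, 3, 4), c(2, 3, 3, 4))
  reward <- rbind(c(1L, 0L, 0L, 0L), c(1L, 1L, 0L, 0L))
  res <- nth_success_prediction(theta, reward, max_n = 3, n_last = 3)
  expect_true(all(is.na(res$prob[res$slope == "shallow"])))
  expect_true(all(res$n_cond[res$slope == "shallow"] == 0L))
  expect_true(all(is.na(res$prob[res$N == 3])))
})

test_that("trial-to-trial variability splits by reinforcement history", {
  set.seed(91)
  sm <- 0.81; se <- 0.9
  # long alternating blocks keep consecutive trials in the same variance
  # regime, so the difference-of-Normals closed forms apply
  rewards <- rep(rep(c(1L, 0L), each = 250L), 20L)
  s <- scripted_series(rewards, sm, se)
  v <- variability_by_history(s)
  sd_s <- v$sd[v$bin == "after_success"]
  sd_f <- v$sd[v$bin == "after_failure"]
  n_s <- v$n[v$bin == "after_success"]
  # 3-SE agreement with sqrt(2)*sigma_m and sqrt(2)*sqrt(sigma_m^2+sigma_e^2)
  expect_lt(abs(sd_s - sqrt(2) * sm), 3 * sd_s / sqrt(2 * n_s))
  expect_lt(abs(sd_f - sqrt(2) * sqrt(sm^2 + se^2)),
            3 * sd_f / sqrt(2 * v$n[v$bin == "after_failure"]))
  expect_gt(sd_f, sd_s)
  # baseline and washout bins reflect motor noise only; each bin holds few
  # trial pairs per participant, so compare the mean over 30 participants
  vb <- replicate(30, {
    si <- scripted_series(rep(c(1L, 0L), 50L), sm, se)
    vi <- variability_by_history(si)
    c(vi$sd[vi$bin == "baseline"], vi$sd[vi$bin == "washout"])
  })
  expect_equal(mean(vb[1, ]), sqrt(2) * sm, tolerance = 0.1)
  expect_equal(mean(vb[2, ]), sqrt(2) * sm, tolerance = 0.1)
  # two-back bins partition the one-back bins
  v2 <- variability_by_history(s, two_back = TRUE)
  expect_equal(sum(v2$n[v2$bin %in% c("after_01", "after_11")]) + 1L,
               v2$n[v2$bin == "after_success"])
})

test_that("exact contingency test matches enumeration and the null", {
  tab <- matrix(c(37, 29, 3, 11), nrow = 2)
  p <- contingency_test(tab)
  expect_equal(p, enumerate_fisher(tab), tolerance = 1e-10)
  expect_lt(abs(p - 0.036), 0.001)
  expect_equal(contingency_test(matrix(5, 2, 2)), 1)
  # random small tables agree with the enumeration oracle
  set.seed(92)
  for (k in 1:20) {
    t2 <- matrix(rpois(4, 6) + 1L, 2, 2)
    expect_equal(contingency_test(t2), enumerate_fisher(t2),
                 tolerance = 1e-10)
  }
  expect_error(contingency_test(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_error(contingency_test(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})
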