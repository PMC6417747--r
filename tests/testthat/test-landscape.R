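test_that("single-gradient landscapes evaluate to the defining values", {
  steep <- exp1_landscape("steep", "CW")
  shallow <- exp1_landscape("shallow", "CW")

  # baseline reward probability and plateau heights
  expect_equal(reward_probability(steep, 0), 1 / 3)
  expect_equal(reward_probability(shallow, 0), 1 / 3)
  expect_equal(reward_probability(steep, 4.5), 1)
  expect_equal(reward_probability(shallow, 4.5), 2 / 3)

  # rising-segment slopes: 2/9 and 1/9 per z-score
  expect_equal(reward_probability(steep, 1.5) - reward_probability(steep, 0.5),
               2 / 9)
  expect_equal(reward_probability(shallow, 2) - reward_probability(shallow, 1),
               1 / 9)
  expect_equal(reward_probability(steep, 1.5), 2 / 3)

  # x-intercepts forced by slope and intercept 1/3
  expect_equal(reward_probability(steep, -1.5), 0)
  expect_equal(reward_probability(shallow, -3), 0)
  expect_gt(reward_probability(steep, -1.4), 0)

  # zero outside the rewarded region
  expect_equal(reward_probability(steep, c(-5, 6.01, 7)), c(0, 0, 0))

  # mirror plateau
  expect_equal(reward_probability(exp1_landscape("steep", "CCW"), -4), 1)
  expect_error(exp1_landscape("medium", "CW"))
})

test_that("valley landscapes have the two-slope structure", {
  stcw <- exp2_landscape("CW")
  expect_equal(reward_probability(stcw, 0), 1 / 3)
  expect_equal(reward_probability(stcw, -3), 2 / 3)   # shallow-arm plateau edge
  expect_equal(reward_probability(stcw, -4.5), 2 / 3)
  expect_equal(reward_probability(stcw, 5), 1)
  expect_equal(reward_probability(stcw, c(-6.5, 6.5)), c(0, 0))
  # slopes on each side of the valley
  expect_equal(reward_probability(stcw, 2) - reward_probability(stcw, 1), 2 / 9)
  expect_equal(reward_probability(stcw, -2) - reward_probability(stcw, -1),
               1 / 9)
})

test_that("mirror identity holds exactly for every landscape family", {
  thetas <- seq(-8, 8, by = 0.01)
  pairs <- list(
    list(exp1_landscape("steep", "CW"), exp1_landscape("steep", "CCW")),
    list(exp1_landscape("shallow", "CW"), exp1_landscape("shallow", "CCW")),
    list(exp2_landscape("CW"), exp2_landscape("CCW")))
  for (pr in pairs) {
    expect_identical(reward_probability(pr[[1]], thetas),
                     reward_probability(pr[[2]], -thetas))
  }
  # double mirror is the identity on values
  L <- exp1_landscape("steep", "CW")
  expect_equal(reward_probability(mirror_landscape(mirror_landscape(L)), thetas),
               reward_probability(L, thetas))
})

test_that("landscapes are valid probability maps, continuous at breakpoints", {
  eps <- 1e-9
  for (L in list(exp1_landscape("steep", "CW"), exp1_landscape("shallow", "CW"),
                 exp1_landscape("steep", "CCW"), exp2_landscape("CW"),
                 exp2_landscape("CCW"), shallow_intercept_landscape(0.2))) {
    p <- reward_probability(L, seq(-10, 10, by = 0.01))
    expect_true(all(p >= 0 & p <= 1))
    # continuity over the nonzero region: breakpoints interior to the support
    seg <- L$segments
    nz <- seg$slope != 0 | seg$intercept != 0
    supp <- range(seg$lower[nz], seg$upper[nz])
    inner <- setdiff(seg$lower[is.finite(seg$lower)], supp)
    for (b in inner) {
      expect_lt(abs(reward_probability(L, b - eps) -
                    reward_probability(L, b + eps)), 1e-6)
    }
  }
})

test_that("sampled rewards match the landscape probabilities", {
  L <- exp1_landscape("steep", "CW")
  set.seed(101)
  expect_true(all(sample_reward(L, rep(4.5, 50)) == 1L))  # p = 1 plateau
  expect_true(all(sample_reward(L, rep(-5, 50)) == 0L))   # outside support
  draws <- sample_reward(L, rep(0, 1e5))
  expect_equal(mean(draws), 1 / 3, tolerance = 0.015)
  chi <- chisq.test(table(factor(draws, levels = 0:1)), p = c(2 / 3, 1 / 3))
  expect_gt(chi$p.value, 1e-3)
})

test_that("z-score conversion round-trips and validates its inputs", {
  b <- baseline_stats(mean_angle = 2.5, sd_angle = 1.8)
  expect_equal(to_zscore(2.5, b), 0)
  expect_equal(to_zscore(2.5 + 1.8, b), 1)
  z <- seq(-4, 4, length.out = 23)
  expect_equal(to_zscore(from_zscore(z, b), b), z)
  expect_error(baseline_stats(0, 0), "positive")
  expect_error(baseline_stats(0, -1), "positive")
})

test_that("sign-flip pooling flips counterclockwise series only, twice = id", {
  s <- data.frame(participant = 1, trial = 1:2, phase = "experimental",
                  theta = c(1, -2), reward = c(1L, 0L))
  flipped <- pool_sign_flip(s, "CCW")
  expect_equal(flipped$theta, c(-1, 2))
  expect_equal(flipped$reward, s$reward)
  expect_equal(pool_sign_flip(s, "CW")$theta, s$theta)
  expect_equal(pool_sign_flip(s, exp2_landscape("CCW"))$theta, c(-1, 2))
  expect_equal(pool_sign_flip(pool_sign_flip(s, "CCW"), "CCW")$theta, s$theta)
})

test_that("intercept-shifted shallow landscape keeps slope, moves plateau", {
  ref <- shallow_intercept_landscape(1 / 3)
  thetas <- seq(-8, 8, by = 0.01)
  expect_equal(reward_probability(ref, thetas),
               reward_probability(exp1_landscape("shallow", "CW"), thetas))
  lo <- shallow_intercept_landscape(0.1)
  expect_equal(reward_probability(lo, 0), 0.1)
  expect_equal(reward_probability(lo, 2) - reward_probability(lo, 1), 1 / 9)
  expect_equal(reward_probability(lo, 4), 0.1 + 1 / 3)
  expect_error(shallow_intercept_landscape(0.8))
})
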