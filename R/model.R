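#' Learning-model parameters
#'
#' The trial-by-trial learner has three free parameters: the aim-update
#' proportion `alpha`, the motor (execution) noise SD `sigma_m`, and the
#' exploration noise SD `sigma_e`. The executed reach angle on trial n is
#' drawn from a Normal centred on the intended aim; its variance is
#' `sigma_m^2` after a rewarded reach and `sigma_m^2 + sigma_e^2` after an
#' unrewarded one. Only rewarded reaches update the intended aim, by a
#' proportion `alpha` of the aim-to-reach difference.
#'
#' The defaults are the package's canonical best-fit set: `alpha = 0.40`
#' with motor variance 0.81 and exploration variance 0.90 in baseline-SD
#' units (i.e. `sigma_m = 0.9`, `sigma_e = sqrt(0.90)`). See the methods
#' vignette for how this parameterization is pinned down by the
#' expected-reward optima and cohort learning rates it reproduces.
#'
#' @param alpha Update proportion, in `[0, 1]`.
#' @param sigma_m Motor noise SD (> 0), z-score units.
#' @param sigma_e Exploration noise SD (>= 0), z-score units.
#' @return An object of class `"model_params"`.
#' @export
model_params <- function(alpha = 0.40, sigma_m = sqrt(0.81),
                         sigma_e = sqrt(0.90)) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("'alpha' must lie in [0, 1]")
  if (!is.numeric(sigma_m) || sigma_m <= 0) stop("'sigma_m' must be > 0")
  if (!is.numeric(sigma_e) || sigma_e < 0) stop("'sigma_e' must be >= 0")
  structure(list(alpha = alpha, sigma_m = sigma_m, sigma_e = sigma_e),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> alpha = %.3g, sigma_m = %.4g (var %.4g), sigma_e = %.4g (var %.4g)\n",
    x$alpha, x$sigma_m, x$sigma_m^2, x$sigma_e, x$sigma_e^2))
  invisible(x)
}

#' Trial schedule
#'
#' The session layout: feedback-free baseline reaches, experimental reaches
#' with binary reinforcement, and feedback-free washout reaches. The
#' reference protocol is 50 / 350 / 50 (450 trials).
#'
#' @param n_baseline,n_experimental,n_washout Nonnegative trial counts.
#' @return An object of class `"trial_schedule"`.
#' @export
trial_schedule <- function(n_baseline = 50L, n_experimental = 350L,
                           n_washout = 50L) {
  counts <- c(n_baseline, n_experimental, n_washout)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("trial counts must be nonnegative integers")
  structure(list(n_baseline = as.integer(n_baseline),
                 n_experimental = as.integer(n_experimental),
                 n_washout = as.integer(n_washout),
                 total = as.integer(sum(counts))),
            class = "trial_schedule")
}

schedule_phases <- function(schedule) {
  rep(c("baseline", "experimental", "washout"),
      c(schedule$n_baseline, schedule$n_experimental, schedule$n_washout))
}

#' Movement variance given the previous outcome
#'
#' Motor variance alone after a rewarded reach; motor plus exploration
#' variance after an unrewarded reach. Trials without feedback (baseline,
#' washout) carry no failure signal, so they behave like rewarded trials:
#' motor variance only.
#'
#' @param params A [model_params()] object.
#' @param last_outcome `"success"`, `"failure"` or `"no_feedback"`.
#' @return The movement variance (z-score squared).
#' @export
trial_variance <- function(params,
                           last_outcome = c("success", "failure", "no_feedback")) {
  stopifnot(inherits(params, "model_params"))
  last_outcome <- match.arg(last_outcome)
  if (last_outcome == "failure") params$sigma_m^2 + params$sigma_e^2
  else params$sigma_m^2
}

#' Learner state
#'
#' @param aim Intended reach aim (z-score); finite.
#' @param last_outcome Outcome of the previous trial, one of `"success"`,
#'   `"failure"`, `"no_feedback"`.
#' @return An object of class `"model_state"`.
#' @export
model_state <- function(aim = 0,
                        last_outcome = c("no_feedback", "success", "failure")) {
  if (!is.finite(aim)) stop("'aim' must be finite")
  structure(list(aim = aim, last_outcome = match.arg(last_outcome)),
            class = "model_state")
}

#' Advance the learner by one reinforced trial
#'
#' Draws the executed reach angle from a Normal centred on the current aim
#' (variance per [trial_variance()]), samples the binary reward from the
#' landscape, and updates the aim toward the executed angle by proportion
#' `alpha` if and only if the reach was rewarded.
#'
#' @param state A [model_state()].
#' @param params A [model_params()].
#' @param landscape A `"reward_landscape"`.
#' @return A list with the updated `state` and a `record` list holding
#'   `theta` (executed angle) and `reward` (0/1).
#' @export
step_trial <- function(state, params, landscape) {
  stopifnot(inherits(state, "model_state"))
  theta <- rnorm(1L, state$aim, sqrt(trial_variance(params, state$last_outcome)))
  r <- sample_reward(landscape, theta)
  if (r == 1L) {
    state$aim <- state$aim + params$alpha * (theta - state$aim)
    state$last_outcome <- "success"
  } else {
    state$last_outcome <- "failure"
  }
  list(state = state, record = list(theta = theta, reward = r))
}

# Vectorized trial loop shared by all 1-D simulations. p_fun(theta, trial)
# returns the reward probability for each of n individuals on that trial;
# trials outside the experimental phase get no feedback and no aim update.
sim_engine <- function(n, params, schedule, p_fun, keep_series = TRUE) {
  phases <- schedule_phases(schedule)
  total <- schedule$total
  aim <- numeric(n)
  explore <- rep(FALSE, n)  # was the previous trial an unrewarded reach?
  s2m <- params$sigma_m^2
  s2f <- s2m + params$sigma_e^2
  theta_mat <- if (keep_series) matrix(NA_real_, n, total)
  reward_mat <- if (keep_series) matrix(NA_integer_, n, total)
  mu <- numeric(total)
  se <- numeric(total)
  for (t in seq_len(total)) {
    if (phases[t] == "experimental") {
      sd_t <- sqrt(ifelse(explore, s2f, s2m))
      th <- rnorm(n, aim, sd_t)
      r <- as.integer(runif(n) < p_fun(th, t))
      aim <- aim + params$alpha * (th - aim) * (r == 1L)
      explore <- r == 0L
      if (keep_series) reward_mat[, t] <- r
    } else {
      th <- rnorm(n, aim, params$sigma_m)
      explore <- rep(FALSE, n)
    }
    if (keep_series) theta_mat[, t] <- th
    mu[t] <- mean(th)
    se[t] <- if (n > 1L) sd(th) / sqrt(n) else NA_real_
  }
  list(theta = theta_mat, reward = reward_mat,
       mean_curve = data.frame(trial = seq_len(total), phase = phases,
                               mean = mu, se = se),
       final_aim = aim)
}

series_from_matrices <- function(theta, reward, phases, participant = 1L) {
  data.frame(participant = participant,
             trial = seq_along(phases),
             phase = phases,
             theta = as.numeric(theta),
             reward = as.integer(reward))
}

#' Simulate a single individual
#'
#' Runs the learning model through a full session. The intended aim starts
#' at 0 (the baseline mean); baseline and washout trials draw reaches with
#' motor variance only and never update the aim, so the adapted aim is
#' retained through washout.
#'
#' @param params A [model_params()].
#' @param landscape A `"reward_landscape"`.
#' @param schedule A [trial_schedule()].
#' @param seed Optional integer seed (sets the global RNG); with a fixed
#'   seed the series is bit-reproducible.
#' @param participant Identifier stored in the output.
#' @return A `trial_series` data frame with columns `participant`, `trial`,
#'   `phase`, `theta` (z-score) and `reward` (0/1, `NA` on feedback-free
#'   trials).
#' @export
simulate_participant <- function(params = model_params(),
                                 landscape,
                                 schedule = trial_schedule(),
                                 seed = NULL,
                                 participant = 1L) {
  stopifnot(inherits(landscape, "reward_landscape"),
            inherits(schedule, "trial_schedule"))
  if (!is.null(seed)) set.seed(seed)
  out <- sim_engine(1L, params, schedule,
                    function(th, t) reward_probability(landscape, th))
  res <- series_from_matrices(out$theta[1L, ], out$reward[1L, ],
                              schedule_phases(schedule), participant)
  class(res) <- c("trial_series", "data.frame")
  res
}

#' Simulate a cohort of individuals
#'
#' Simulates `n` independent individuals with a single vectorized pass over
#' trials, and summarizes the cohort mean reach-angle curve with its
#' standard error. The run is bit-reproducible under `seed`.
#'
#' @inheritParams simulate_participant
#' @param n Number of individuals (>= 1).
#' @param keep `"series"` retains the full angle and reward matrices
#'   (individuals x trials); `"mean"` stores only the mean curve, which
#'   keeps memory flat for very large cohorts.
#' @return An object of class `"cohort_sim"`: a list with `mean_curve`
#'   (data frame `trial`, `phase`, `mean`, `se`), `theta` and `reward`
#'   matrices (or `NULL` under `keep = "mean"`), `final_aim`, and the
#'   generating `params`, `schedule`, `landscape` name and `seed`.
#' @export
simulate_cohort <- function(params = model_params(),
                            landscape,
                            schedule = trial_schedule(),
                            n = 40L,
                            seed = NULL,
                            keep = c("series", "mean")) {
  stopifnot(inherits(landscape, "reward_landscape"),
            inherits(schedule, "trial_schedule"), n >= 1)
  keep <- match.arg(keep)
  if (!is.null(seed)) set.seed(seed)
  out <- sim_engine(as.integer(n), params, schedule,
                    function(th, t) reward_probability(landscape, th),
                    keep_series = keep == "series")
  structure(list(mean_curve = out$mean_curve,
                 theta = out$theta, reward = out$reward,
                 final_aim = out$final_aim,
                 params = params, schedule = schedule,
                 landscape = landscape$name, n = as.integer(n), seed = seed),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d individuals on '%s' (%d trials)\n",
              x$n, x$landscape, x$schedule$total))
  exp_rows <- x$mean_curve$phase == "experimental"
  cat(sprintf("  mean reach angle, last 100 experimental trials: %.3f\n",
              mean(tail(x$mean_curve$mean[exp_rows], 100L))))
  invisible(x)
}

#' Extract the experimental-phase angle matrix of a cohort
#'
#' @param cohort A `"cohort_sim"` simulated with `keep = "series"`.
#' @return Matrix (individuals x experimental trials) of reach angles.
#' @export
experimental_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_sim"))
  if (is.null(cohort$theta))
    stop("cohort was simulated with keep = \"mean\"; no per-individual series")
  cohort$theta[, schedule_phases(cohort$schedule) == "experimental",
               drop = FALSE]
}

#' Rectangular target for planar reaching
#'
#' @param width Extent along the task-relevant axis (x); reward requires
#'   `|x| <= width / 2`.
#' @param length Extent along the task-irrelevant axis (y).
#' @return An object of class `"rect_target"`.
#' @export
rect_target <- function(width, length) {
  if (!is.numeric(width) || width <= 0 || !is.numeric(length) || length <= 0)
    stop("'width' and 'length' must be positive")
  structure(list(width = width, length = length), class = "rect_target")
}

#' Advance the planar learner by one trial
#'
#' Two-dimensional version of [step_trial()]: isotropic Normal noise per axis
#' (shared variance gate from the previous outcome), reward if and only if
#' the endpoint lands inside the rectangle, and a componentwise aim update
#' on success.
#'
#' @param state List with `aim` (length-2 numeric) and `last_outcome`.
#' @param params A [model_params()].
#' @param target A [rect_target()].
#' @return A list with the updated `state` and a `record` list (`x`, `y`,
#'   `reward`).
#' @export
step_2d <- function(state, params, target) {
  stopifnot(inherits(target, "rect_target"), length(state$aim) == 2L)
  sd_t <- sqrt(trial_variance(params, state$last_outcome))
  pt <- rnorm(2L, state$aim, sd_t)
  r <- as.integer(abs(pt[1L]) <= target$width / 2 &&
                  abs(pt[2L]) <= target$length / 2)
  if (r == 1L) {
    state$aim <- state$aim + params$alpha * (pt - state$aim)
    state$last_outcome <- "success"
  } else {
    state$last_outcome <- "failure"
  }
  list(state = state, record = list(x = pt[1L], y = pt[2L], reward = r))
}

#' Simulate planar reaching at a rectangular target
#'
#' Every trial gives binary feedback (hit/miss of the rectangle). The aim
#' starts at the target centre.
#'
#' @inheritParams simulate_participant
#' @param target A [rect_target()].
#' @param n_trials Number of reinforced trials.
#' @return Data frame with columns `trial`, `x`, `y`, `reward`.
#' @export
simulate_participant_2d <- function(params = model_params(),
                                    target,
                                    n_trials = 450L,
                                    seed = NULL) {
  stopifnot(inherits(target, "rect_target"), n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  st <- list(aim = c(0, 0), last_outcome = "no_feedback")
  x <- numeric(n_trials); y <- numeric(n_trials); r <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    res <- step_2d(st, params, target)
    st <- res$state
    x[t] <- res$record$x; y[t] <- res$record$y; r[t] <- res$record$reward
  }
  data.frame(trial = seq_len(n_trials), x = x, y = y, reward = r)
}
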