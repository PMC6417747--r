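#' Gradual target-rotation scenario
#'
#' The learner receives binary feedback only when the reach angle falls
#' inside a reward window whose centre is rotated away from the displayed
#' target in small steps. Units are native degrees; no z-normalization is
#' applied. The rotation schedule holds at 0 for `n_pre` trials, then steps
#' by `step_deg` every `trials_per_step` trials until `total_rotation` is
#' reached, and holds there.
#'
#' @param params A [model_params()] with noise SDs in degrees.
#' @param n_individuals Cohort size.
#' @param n_trials Trials per individual.
#' @param n_pre Unrotated lead-in trials (with feedback).
#' @param step_deg Rotation increment per step (degrees).
#' @param trials_per_step Trials between increments.
#' @param total_rotation Final rotation (degrees).
#' @param window Half-width of the reward window (degrees, > 0).
#' @param seed Optional integer seed.
#' @return List with `rotation` (per-trial window centre), `mean_curve`
#'   (data frame `trial`, `rotation`, `mean`, `se`) and `theta`
#'   (individuals x trials matrix).
#' @export
run_gradual_rotation <- function(params = model_params(),
                                 n_individuals = 18L,
                                 n_trials = 400L,
                                 n_pre = 40L,
                                 step_deg = 1,
                                 trials_per_step = 40L,
                                 total_rotation = 8,
                                 window = 1.5,
                                 seed = NULL) {
  if (window <= 0) stop("'window' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  steps <- pmax(0L, (seq_len(n_trials) - n_pre - 1L) %/% trials_per_step + 1L)
  rotation <- pmin(steps * step_deg, total_rotation) * sign(total_rotation)
  sched <- trial_schedule(0L, n_trials, 0L)
  out <- sim_engine(as.integer(n_individuals), params, sched,
                    function(th, t) as.numeric(abs(th - rotation[t]) <= window))
  list(rotation = rotation,
       mean_curve = data.frame(trial = seq_len(n_trials), rotation = rotation,
                               mean = out$mean_curve$mean,
                               se = out$mean_curve$se),
       theta = out$theta)
}

#' Stochastically shifted-cursor scenario
#'
#' On every trial the feedback cursor is displaced laterally by a random
#' shift drawn from a (possibly skewed) distribution; the learner is
#' rewarded when the shifted position lands inside the target. Units are
#' native millimetres. To maximize hits the learner must compensate by
#' aiming opposite the typical shift; with a skewed shift distribution the
#' hit-maximizing aim does not coincide with minus the mean shift, and the
#' greedy learner typically settles short of it.
#'
#' The shift distribution is a shifted gamma:
#' `shift = shift_location + shift_scale * (G - shape)` with
#' `G ~ Gamma(shape, 1)`, which has mean `shift_location` and skewness
#' `2 / sqrt(shape)`. `shape = Inf` degenerates to a point mass at
#' `shift_location` (a plain target task).
#'
#' @param params A [model_params()] with noise SDs in mm.
#' @param n_individuals Cohort size.
#' @param n_trials Trials per individual.
#' @param target_halfwidth Target half-width (mm, > 0).
#' @param shift_location Mean cursor shift (mm).
#' @param shift_scale Scale of the shift distribution (mm, >= 0).
#' @param shape Gamma shape controlling skewness (> 0, or `Inf` for a
#'   deterministic shift).
#' @param seed Optional integer seed.
#' @return List with `mean_curve` (data frame `trial`, `mean`, `se`),
#'   `theta` (individuals x trials matrix of hand positions) and
#'   `optimal_position` (hit-maximizing hand position found by a fine
#'   scan of the hit probability).
#' @export
run_shifted_cursor <- function(params = model_params(),
                               n_individuals = 30L,
                               n_trials = 400L,
                               target_halfwidth = 5,
                               shift_location = 15,
                               shift_scale = 4,
                               shape = 2,
                               seed = NULL) {
  if (target_halfwidth <= 0) stop("'target_halfwidth' must be > 0")
  if (shift_scale < 0 || (!is.infinite(shape) && shape <= 0))
    stop("invalid shift-distribution parameters")
  if (!is.null(seed)) set.seed(seed)
  draw_shift <- function(k) {
    if (is.infinite(shape) || shift_scale == 0) rep(shift_location, k)
    else shift_location + shift_scale * (rgamma(k, shape = shape) - shape)
  }
  n <- as.integer(n_individuals)
  sched <- trial_schedule(0L, n_trials, 0L)
  out <- sim_engine(n, params, sched, function(th, t) {
    cursor <- th + draw_shift(length(th))
    as.numeric(abs(cursor) <= target_halfwidth)
  })
  # hit probability of each candidate hand position under the shift law
  pos <- seq(-shift_location - 20 * max(shift_scale, 1),
             shift_location + 20 * max(shift_scale, 1), by = 0.05)
  if (is.infinite(shape) || shift_scale == 0) {
    phit <- as.numeric(abs(pos + shift_location) <= target_halfwidth)
  } else {
    lo <- (-target_halfwidth - pos - shift_location) / shift_scale + shape
    hi <- (target_halfwidth - pos - shift_location) / shift_scale + shape
    phit <- pgamma(pmax(hi, 0), shape) - pgamma(pmax(lo, 0), shape)
  }
  best <- pos[phit >= max(phit) - 1e-12]  # centre of a flat-topped optimum
  list(mean_curve = data.frame(trial = seq_len(n_trials),
                               mean = out$mean_curve$mean,
                               se = out$mean_curve$se),
       theta = out$theta,
       optimal_position = mean(range(best)))
}

#' Lag-1 autocorrelation of planar endpoints by axis
#'
#' Simulates reaching at a rectangular target with [simulate_participant_2d()]
#' for several subjects and reports the lag-1 autocorrelation of endpoint
#' position separately for the task-relevant (width, x) and task-irrelevant
#' (length, y) axes. Positive task-irrelevant autocorrelation with
#' near-zero task-relevant autocorrelation is the signature of a random
#' walk along the dimension that does not affect success.
#'
#' @param params A [model_params()].
#' @param target A [rect_target()]; the default is long and thin.
#' @param n_subjects Number of simulated subjects.
#' @param n_trials Trials per subject.
#' @param seed Optional integer seed.
#' @return List with `per_subject` (data frame `subject`, `afc1_relevant`,
#'   `afc1_irrelevant`) and `summary` (means and standard errors per axis).
#' @export
run_rect_target_2d <- function(params = model_params(),
                               target = rect_target(width = 1, length = 12),
                               n_subjects = 6L,
                               n_trials = 450L,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  afc1 <- function(v) {
    a <- acf(v, lag.max = 1L, plot = FALSE, demean = TRUE)
    as.numeric(a$acf[2L])
  }
  per <- data.frame(subject = seq_len(n_subjects),
                    afc1_relevant = NA_real_, afc1_irrelevant = NA_real_)
  for (s in seq_len(n_subjects)) {
    sim <- simulate_participant_2d(params, target, n_trials)
    per$afc1_relevant[s] <- afc1(sim$x)
    per$afc1_irrelevant[s] <- afc1(sim$y)
  }
  summ <- data.frame(
    axis = c("task_relevant", "task_irrelevant"),
    mean_afc1 = c(mean(per$afc1_relevant), mean(per$afc1_irrelevant)),
    se = c(sd(per$afc1_relevant), sd(per$afc1_irrelevant)) / sqrt(n_subjects))
  list(per_subject = per, summary = summ)
}

#' Learning-rate sweep over movement-variability parameters
#'
#' Simulates a cohort and fits the exponential learning curve for every
#' combination of motor SD, exploration SD and landscape, mapping how the
#' two noise sources shape the time constant `lambda`.
#'
#' @param sigma_m_grid,sigma_e_grid Numeric vectors of SD values to cross.
#' @param landscapes Named list of `"reward_landscape"` objects.
#' @param alpha Aim-update proportion used throughout.
#' @param n Individuals per cell.
#' @param schedule A [trial_schedule()].
#' @param seed Optional integer seed; cell c uses `seed + c` so cells are
#'   independent but reproducible.
#' @return Data frame with columns `landscape`, `sigma_m`, `sigma_e`,
#'   `lambda`, `a` and `ok` (`FALSE` where the fit failed).
#' @export
run_variability_sweep <- function(sigma_m_grid = c(0.6, 0.9, 1.2),
                                  sigma_e_grid = c(0.5, 0.95, 1.4),
                                  landscapes = list(
                                    steep = exp1_landscape("steep", "CW"),
                                    shallow = exp1_landscape("shallow", "CW")),
                                  alpha = 0.40,
                                  n = 10000L,
                                  schedule = trial_schedule(),
                                  seed = NULL) {
  cells <- expand.grid(landscape = names(landscapes),
                       sigma_m = sigma_m_grid, sigma_e = sigma_e_grid,
                       stringsAsFactors = FALSE)
  cells$lambda <- NA_real_; cells$a <- NA_real_; cells$ok <- FALSE
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  for (k in seq_len(nrow(cells))) {
    p <- model_params(alpha = alpha, sigma_m = cells$sigma_m[k],
                      sigma_e = cells$sigma_e[k])
    co <- simulate_cohort(p, landscapes[[cells$landscape[k]]], schedule,
                          n = n, keep = "mean",
                          seed = if (is.null(base_seed)) NULL
                                 else base_seed + k)
    fit <- tryCatch(fit_exponential(co), error = function(e) NULL)
    if (!is.null(fit)) {
      cells$lambda[k] <- fit$lambda
      cells$a[k] <- fit$a
      cells$ok[k] <- TRUE
    }
  }
  cells
}

#' Learning-rate sweep over the baseline reward probability
#'
#' Rebuilds the shallow landscape with the rising segment's intercept (the
#' reward probability at baseline, theta = 0) shifted while keeping the
#' slope fixed, and measures the learning rate at each intercept. The
#' reference configuration is `intercept = 1/3`.
#'
#' @param intercepts Numeric vector of baseline reward probabilities,
#'   each in `[0, 2/3]`.
#' @param params A [model_params()].
#' @param n Individuals per intercept.
#' @param schedule A [trial_schedule()].
#' @param seed Optional integer seed (per-cell offsets as in
#'   [run_variability_sweep()]).
#' @return Data frame with columns `intercept`, `lambda`, `a` and `ok`.
#' @export
run_initial_reward_sweep <- function(intercepts = c(0.1, 0.2, 1 / 3, 0.45),
                                     params = model_params(),
                                     n = 10000L,
                                     schedule = trial_schedule(),
                                     seed = NULL) {
  out <- data.frame(intercept = intercepts, lambda = NA_real_,
                    a = NA_real_, ok = FALSE)
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  for (k in seq_along(intercepts)) {
    L <- shallow_intercept_landscape(intercepts[k])
    co <- simulate_cohort(params, L, schedule, n = n, keep = "mean",
                          seed = if (is.null(base_seed)) NULL
                                 else base_seed + k)
    fit <- tryCatch(fit_exponential(co), error = function(e) NULL)
    if (!is.null(fit)) {
      out$lambda[k] <- fit$lambda
      out$a[k] <- fit$a
      out$ok[k] <- TRUE
    }
  }
  out
}
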