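#' Piecewise-linear reinforcement landscapes
#'
#' A reinforcement landscape maps a reach angle (expressed as a z-score
#' relative to baseline reach behaviour) to the probability of receiving
#' binary reward. All landscapes used here are continuous piecewise-linear
#' functions that tile the whole real line: segments outside the rewarded
#' region evaluate to 0.
#'
#' `new_landscape()` is the low-level constructor; most users want
#' [exp1_landscape()] or [exp2_landscape()].
#'
#' @param breaks Increasing numeric vector of interior breakpoints. Segment
#'   `k` covers `[breaks[k-1], breaks[k])` (the first segment is unbounded
#'   below, the last unbounded above).
#' @param slope,intercept Numeric vectors, one entry per segment
#'   (`length(breaks) + 1`), giving the affine coefficients
#'   `p = slope * theta + intercept` on each segment.
#' @param direction Direction label, one of `"CW"`, `"CCW"`, `"steepCW"`,
#'   `"steepCCW"`.
#' @param max_rate Peak reward probability of the landscape, in `[0, 1]`.
#' @param name Human-readable identifier.
#'
#' @return An object of class `"reward_landscape"`: a list with elements
#'   `name`, `direction`, `max_rate` and `segments` (a data frame with
#'   columns `lower`, `upper`, `slope`, `intercept`).
#' @seealso [exp1_landscape()], [exp2_landscape()], [reward_probability()],
#'   [mirror_landscape()]
#' @export
new_landscape <- function(breaks, slope, intercept, direction, max_rate, name) {
  stopifnot(is.numeric(breaks), !is.unsorted(breaks, strictly = TRUE),
            length(slope) == length(breaks) + 1L,
            length(intercept) == length(slope))
  direction <- match.arg(direction, c("CW", "CCW", "steepCW", "steepCCW"))
  if (!is.numeric(max_rate) || max_rate < 0 || max_rate > 1)
    stop("'max_rate' must be a probability in [0, 1]")
  segments <- data.frame(
    lower = c(-Inf, breaks),
    upper = c(breaks, Inf),
    slope = slope,
    intercept = intercept
  )
  structure(
    list(name = name, direction = direction, max_rate = max_rate,
         segments = segments),
    class = "reward_landscape"
  )
}

#' @export
print.reward_landscape <- function(x, ...) {
  cat("<reward_landscape> ", x$name, "\n", sep = "")
  cat("  direction: ", x$direction, ",  peak probability: ",
      format(x$max_rate, digits = 4), "\n", sep = "")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Single-gradient landscapes (steep or shallow)
#'
#' Constructs the one-sided landscapes in which reward probability rises
#' linearly from an x-intercept through the baseline point
#' (theta = 0, p = 1/3) up to a plateau at the peak rate `m` between 3 and 6
#' z-scores, and is 0 elsewhere. The steep landscape has peak rate 1
#' (slope 2/9 per z-score); the shallow landscape has peak rate 2/3
#' (slope 1/9 per z-score). The counterclockwise variants are exact mirror
#' images about theta = 0.
#'
#' The rising segment is `(m/3 - 1/9) * theta + 1/3`, so its x-intercept is
#' `-3 / (3 m - 1)`: -1.5 for the steep landscape and -3 for the shallow one.
#'
#' @param gradient `"steep"` (peak rate 1) or `"shallow"` (peak rate 2/3).
#' @param direction `"CW"` if reward probability rises in the clockwise
#'   (positive z) direction, `"CCW"` for the mirror image.
#' @return A [new_landscape()] object.
#' @examples
#' L <- exp1_landscape("steep", "CW")
#' reward_probability(L, c(0, 1.5, 4.5, 7))
#' @export
exp1_landscape <- function(gradient = c("steep", "shallow"),
                           direction = c("CW", "CCW")) {
  gradient <- match.arg(gradient)
  direction <- match.arg(direction)
  m <- if (gradient == "steep") 1 else 2 / 3
  s <- m / 3 - 1 / 9
  x0 <- -3 / (3 * m - 1)
  cw <- new_landscape(
    breaks    = c(x0, 3, 6),
    slope     = c(0, s, 0, 0),
    intercept = c(0, 1 / 3, m, 0),
    direction = "CW",
    max_rate  = m,
    name      = paste0(gradient, " ", direction)
  )
  if (direction == "CW") cw else {
    out <- mirror_landscape(cw)
    out$name <- paste0(gradient, " CCW")
    out
  }
}

#' Two-sided (valley) landscapes
#'
#' Constructs the complex landscapes in which the learner starts in a valley
#' (p = 1/3 at theta = 0) between a steep slope (2/9 per z-score, plateau 1)
#' rising in one direction and a shallow slope (1/9 per z-score, plateau 2/3)
#' rising in the other. Both plateaus span 3 to 6 z-scores from baseline on
#' their respective sides; the probability is 0 beyond 6 z-scores.
#'
#' @param steep_direction `"CW"` if the steep slope rises clockwise
#'   (positive z), `"CCW"` for the mirror image.
#' @return A [new_landscape()] object with direction `"steepCW"` or
#'   `"steepCCW"`.
#' @examples
#' reward_probability(exp2_landscape("CW"), c(-4.5, -3, 0, 3, 5))
#' @export
exp2_landscape <- function(steep_direction = c("CW", "CCW")) {
  steep_direction <- match.arg(steep_direction)
  stcw <- new_landscape(
    breaks    = c(-6, -3, 0, 3, 6),
    slope     = c(0, 0, -1 / 9, 2 / 9, 0, 0),
    intercept = c(0, 2 / 3, 1 / 3, 1 / 3, 1, 0),
    direction = "steepCW",
    max_rate  = 1,
    name      = "valley steepCW"
  )
  if (steep_direction == "CW") stcw else {
    out <- mirror_landscape(stcw)
    out$direction <- "steepCCW"
    out$name <- "valley steepCCW"
    out
  }
}

#' Mirror a landscape about baseline
#'
#' Returns the landscape reflected about theta = 0, so that
#' `reward_probability(mirror_landscape(L), theta)` equals
#' `reward_probability(L, -theta)` exactly.
#'
#' @param landscape A `"reward_landscape"`.
#' @return The mirrored `"reward_landscape"`.
#' @export
mirror_landscape <- function(landscape) {
  stopifnot(inherits(landscape, "reward_landscape"))
  seg <- landscape$segments
  n <- nrow(seg)
  mirrored <- data.frame(
    lower = rev(-seg$upper),
    upper = rev(-seg$lower),
    slope = rev(-seg$slope),
    intercept = rev(seg$intercept)
  )
  landscape$segments <- mirrored
  flip <- c(CW = "CCW", CCW = "CW", steepCW = "steepCCW", steepCCW = "steepCW")
  landscape$direction <- unname(flip[landscape$direction])
  landscape$name <- paste0("mirror(", landscape$name, ")")
  landscape
}

#' Reward probability at a reach angle
#'
#' Evaluates the piecewise-linear landscape. The landscapes are continuous
#' over their nonzero region, so interior breakpoint ownership is
#' observationally irrelevant there; at a jump discontinuity (the outer
#' plateau edge) the boundary point takes the larger one-sided value,
#' matching plateau intervals that are closed toward the rewarded region
#' on both the clockwise and counterclockwise variants. This keeps the
#' mirror identity `R_mirror(theta) == R(-theta)` exact everywhere.
#'
#' @param landscape A `"reward_landscape"`.
#' @param theta Numeric vector of reach angles (z-score units).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
reward_probability <- function(landscape, theta) {
  stopifnot(inherits(landscape, "reward_landscape"), is.numeric(theta))
  if (any(!is.finite(theta))) stop("'theta' must be finite")
  seg <- landscape$segments
  brk <- seg$lower[-1L]
  idx_r <- findInterval(theta, brk) + 1L                    # [lower, upper)
  idx_l <- findInterval(theta, brk, left.open = TRUE) + 1L  # (lower, upper]
  p <- pmax(seg$slope[idx_r] * theta + seg$intercept[idx_r],
            seg$slope[idx_l] * theta + seg$intercept[idx_l])
  pmin(pmax(p, 0), 1)
}

#' Draw binary rewards from a landscape
#'
#' Bernoulli draws with success probability `reward_probability(landscape,
#' theta)`, using R's global random number stream (seed it with
#' [set.seed()] for reproducibility).
#'
#' @inheritParams reward_probability
#' @return Integer vector of 0/1 outcomes, same length as `theta`.
#' @export
sample_reward <- function(landscape, theta) {
  p <- reward_probability(landscape, theta)
  as.integer(runif(length(p)) < p)
}

#' Baseline reach statistics
#'
#' Summary of a participant's (or simulated individual's) baseline reaches,
#' used to express reach angles as z-scores. In the reference protocol the
#' last 25 baseline trials define the mean and standard deviation.
#'
#' @param mean_angle Mean baseline reach angle (degrees).
#' @param sd_angle Standard deviation of baseline reach angle (degrees);
#'   must be positive.
#' @param n_trials Number of baseline trials summarized (>= 1).
#' @return An object of class `"baseline_stats"`.
#' @export
baseline_stats <- function(mean_angle, sd_angle, n_trials = 25L) {
  if (!is.numeric(sd_angle) || sd_angle <= 0)
    stop("'sd_angle' must be positive")
  if (n_trials < 1) stop("'n_trials' must be >= 1")
  structure(list(mean_angle = mean_angle, sd_angle = sd_angle,
                 n_trials = as.integer(n_trials)),
            class = "baseline_stats")
}

#' Convert reach angles between native degrees and baseline z-scores
#'
#' `to_zscore()` expresses angles relative to the baseline mean, scaled by
#' the baseline standard deviation; `from_zscore()` is its exact inverse.
#'
#' @param angle Reach angle(s) in degrees.
#' @param z Reach angle(s) in z-score units.
#' @param baseline A [baseline_stats()] object.
#' @return Numeric vector.
#' @export
to_zscore <- function(angle, baseline) {
  stopifnot(inherits(baseline, "baseline_stats"))
  (angle - baseline$mean_angle) / baseline$sd_angle
}

#' @rdname to_zscore
#' @export
from_zscore <- function(z, baseline) {
  stopifnot(inherits(baseline, "baseline_stats"))
  z * baseline$sd_angle + baseline$mean_angle
}

#' Pool series across landscape directions by sign-flipping
#'
#' To compare and pool participants irrespective of the direction their
#' landscape rose, normalized reach angles are multiplied by -1 for
#' individuals whose landscape rose counterclockwise (single-gradient
#' `"CCW"` or valley `"steepCCW"`). Rewards are unchanged. Applying the flip
#' twice is the identity.
#'
#' @param series A trial-series data frame (see [simulate_participant()])
#'   with a `theta` column in z-score units.
#' @param landscape_direction Direction label of the landscape the series
#'   was collected under, or a `"reward_landscape"` object.
#' @return The series with `theta` negated when the direction is
#'   counterclockwise-rising.
#' @export
pool_sign_flip <- function(series, landscape_direction) {
  if (inherits(landscape_direction, "reward_landscape"))
    landscape_direction <- landscape_direction$direction
  landscape_direction <- match.arg(landscape_direction,
                                   c("CW", "CCW", "steepCW", "steepCCW"))
  if (landscape_direction %in% c("CCW", "steepCCW"))
    series$theta <- -series$theta
  series
}

#' Shallow landscape with a shifted baseline intercept
#'
#' Rebuilds the shallow clockwise landscape with the rising segment's
#' intercept moved from its reference value 1/3 to `intercept`, keeping the
#' slope fixed at 1/9 per z-score. The plateau (value at theta = 3, i.e.
#' `1/3 + intercept`) and the x-intercept move accordingly. Used to probe
#' how the reward probability at baseline affects the learning rate.
#'
#' @param intercept Reward probability at theta = 0; must keep all segment
#'   values in `[0, 1]` (`0 <= intercept <= 2/3`).
#' @return A [new_landscape()] object.
#' @export
shallow_intercept_landscape <- function(intercept) {
  if (!is.numeric(intercept) || intercept < 0 || intercept > 2 / 3)
    stop("'intercept' must lie in [0, 2/3] to keep probabilities in [0, 1]")
  s <- 1 / 9
  m <- 3 * s + intercept
  x0 <- -intercept / s
  if (x0 >= 3) stop("'intercept' leaves no rising segment")
  new_landscape(
    breaks    = c(x0, 3, 6),
    slope     = c(0, s, 0, 0),
    intercept = c(0, intercept, m, 0),
    direction = "CW",
    max_rate  = m,
    name      = sprintf("shallow CW (intercept %.3f)", intercept)
  )
}
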