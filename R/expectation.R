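#' Movement variance as a function of position on the landscape
#'
#' The exploration component of movement variability scales inversely with
#' the probability of reward: `sigma^2(theta) = sigma_m^2 +
#' (1 - R(theta)) * sigma_e^2`. Where reward is certain only motor variance
#' remains; where reward is impossible the full exploration variance is
#' added.
#'
#' @param landscape A `"reward_landscape"`.
#' @param theta Numeric vector of reach angles (z-score).
#' @param params A [model_params()].
#' @return Numeric vector of variances.
#' @export
position_variance <- function(landscape, theta, params = model_params()) {
  stopifnot(inherits(params, "model_params"))
  params$sigma_m^2 +
    (1 - reward_probability(landscape, theta)) * params$sigma_e^2
}

default_grid <- function() seq(-12, 12, by = 0.005)

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

er_values <- function(landscape, aims, params, grid, variance_at) {
  Rg <- reward_probability(landscape, grid)
  if (variance_at == "integrand") {
    sd_g <- sqrt(params$sigma_m^2 + (1 - Rg) * params$sigma_e^2)
    vapply(aims, function(a) trapz(grid, dnorm(grid, a, sd_g) * Rg),
           numeric(1L))
  } else {
    vapply(aims, function(a) {
      sd_a <- sqrt(position_variance(landscape, a, params))
      trapz(grid, dnorm(grid, a, sd_a) * Rg)
    }, numeric(1L))
  }
}

#' Expected reward given an intended aim
#'
#' Numerically integrates the Normal reach-angle density centred on the
#' intended aim against the reinforcement landscape, giving the probability
#' of reward for a learner who aims at `aim` but executes with motor and
#' exploration noise.
#'
#' The kernel variance follows [position_variance()]. By default it is
#' evaluated at the intended aim, making the integral a true convolution of
#' a fixed Normal kernel with the landscape; `variance_at = "integrand"`
#' instead lets the variance vary with the integration point (the kernel is
#' then no longer a normalized density and no renormalization is applied).
#' The methods vignette discusses why the aim-evaluated form is the default.
#'
#' @param landscape A `"reward_landscape"`.
#' @param aim Intended aim(s), z-score.
#' @param params A [model_params()].
#' @param grid Integration grid; must cover the landscape support with a
#'   margin of at least 4 SDs (checked).
#' @param variance_at `"aim"` (default) or `"integrand"`.
#' @return Numeric vector of expected reward probabilities.
#' @export
expected_reward <- function(landscape, aim, params = model_params(),
                            grid = default_grid(),
                            variance_at = c("aim", "integrand")) {
  stopifnot(inherits(landscape, "reward_landscape"), is.numeric(aim))
  variance_at <- match.arg(variance_at)
  check_grid(landscape, grid, params)
  er_values(landscape, aim, params, grid, variance_at)
}

check_grid <- function(landscape, grid, params) {
  if (length(grid) < 2L || is.unsorted(grid))
    stop("integration grid must be an increasing vector")
  if (max(diff(grid)) > 0.05)
    stop("integration grid too coarse (spacing > 0.05 z-score)")
  seg <- landscape$segments
  nz <- seg$slope != 0 | seg$intercept != 0
  if (any(nz)) {
    support <- range(seg$lower[nz], seg$upper[nz])
    margin <- 4 * sqrt(params$sigma_m^2 + params$sigma_e^2)
    # an unbounded support side cannot be covered; the grid edge then
    # simply truncates the (constant-tail) landscape there
    lo_ok <- !is.finite(support[1L]) || grid[1L] <= support[1L] - margin
    hi_ok <- !is.finite(support[2L]) ||
      grid[length(grid)] >= support[2L] + margin
    if (!lo_ok || !hi_ok)
      stop("integration grid must cover the landscape support with a ",
           "4-SD margin")
  }
  invisible(TRUE)
}

#' Expected-reward curve and reward-maximizing aim
#'
#' `expected_reward_curve()` evaluates [expected_reward()] over a grid of
#' intended aims and locates the maximizing aim; `optimal_aim()` returns
#' only the maximizer, refined by golden-section search around the grid
#' argmax to a resolution finer than the grid spacing. Ties (grid values
#' within `tie_tol` of the maximum forming disjoint neighbourhoods) are
#' broken toward the smallest `|aim|` and reported via a warning.
#'
#' @inheritParams expected_reward
#' @param aims Grid of intended aims to scan.
#' @param tie_tol Tolerance for declaring a non-unique maximum.
#' @return `expected_reward_curve()`: an object of class `"er_curve"` with
#'   elements `aim`, `value`, `theta_opt` and `max_value`.
#'   `optimal_aim()`: the maximizing intended aim (z-score).
#' @examples
#' \donttest{
#' optimal_aim(exp1_landscape("steep", "CW"))
#' }
#' @export
expected_reward_curve <- function(landscape, params = model_params(),
                                  aims = seq(-8, 8, by = 0.005),
                                  grid = default_grid(),
                                  variance_at = c("aim", "integrand"),
                                  tie_tol = 1e-9) {
  stopifnot(inherits(landscape, "reward_landscape"))
  variance_at <- match.arg(variance_at)
  check_grid(landscape, grid, params)
  vals <- er_values(landscape, aims, params, grid, variance_at)
  vmax <- max(vals)
  near <- which(vals >= vmax - tie_tol)
  # disjoint near-maximal plateaus, or one flat top much wider than the
  # resolution of a genuine peak, indicate a non-unique maximum; a short
  # contiguous run is just the grid resolving the peak
  span <- diff(range(aims[near]))
  if (any(diff(near) > 1L) || span > 0.25) {
    warning("non-unique maximum of the expected-reward curve; ",
            "tie broken toward the smallest |aim|")
    best <- near[which.min(abs(aims[near]))]
  } else {
    best <- near[which.max(vals[near])]
  }
  lo <- aims[max(best - 1L, 1L)]
  hi <- aims[min(best + 1L, length(aims))]
  ref <- optimize(function(a) er_values(landscape, a, params, grid, variance_at),
                  interval = c(lo, hi), maximum = TRUE, tol = 1e-4)
  structure(list(aim = aims, value = vals,
                 theta_opt = ref$maximum, max_value = ref$objective),
            class = "er_curve")
}

#' @rdname expected_reward_curve
#' @export
optimal_aim <- function(landscape, params = model_params(),
                        aims = seq(-8, 8, by = 0.005),
                        grid = default_grid(),
                        variance_at = c("aim", "integrand"),
                        tie_tol = 1e-9) {
  expected_reward_curve(landscape, params, aims, grid,
                        variance_at, tie_tol)$theta_opt
}

#' @export
print.er_curve <- function(x, ...) {
  cat(sprintf(
    "<er_curve> %d aims in [%.2f, %.2f]; theta_opt = %.4f (E[U] = %.4f)\n",
    length(x$aim), min(x$aim), max(x$aim), x$theta_opt, x$max_value))
  invisible(x)
}
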