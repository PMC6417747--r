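#' Difference-based initial guesses for the noise parameters
#'
#' Uses the trial-to-trial difference analysis: if consecutive executed
#' angles are independent draws with a common SD `s`, the SD of their
#' difference is `sqrt(2) * s`. The motor SD guess is the after-success
#' `SD(delta) / sqrt(2)`; the exploration SD guess is
#' `sqrt(max(0, SD(delta | failure)^2 / 2 - sigma_m_guess^2))`. The guesses
#' are unbiased when the reinforcement history is locally constant (runs of
#' like outcomes); mixed histories inflate the motor guess slightly, which
#' is why these are starting values for [fit_parameters()], not estimates.
#'
#' @param series A trial-series data frame or a list of them (pooled).
#' @param min_n Minimum number of difference pairs required per bin.
#' @return Named numeric vector with elements `sigma_m` and `sigma_e`.
#' @export
initial_guess_sigmas <- function(series, min_n = 10L) {
  if (is.data.frame(series)) series <- list(series)
  d_succ <- c(); d_fail <- c()
  for (s in series) {
    exp_idx <- which(s$phase == "experimental")
    th <- s$theta[exp_idx]; r <- s$reward[exp_idx]
    d <- diff(th); r_n <- r[-length(r)]
    d_succ <- c(d_succ, d[r_n == 1L])
    d_fail <- c(d_fail, d[r_n == 0L])
  }
  if (length(d_succ) < min_n)
    stop("too few post-success trial pairs (", length(d_succ), ")")
  if (length(d_fail) < min_n)
    stop("too few post-failure trial pairs (", length(d_fail), ")")
  sm <- sd(d_succ) / sqrt(2)
  se2 <- max(0, sd(d_fail)^2 / 2 - sm^2)
  c(sigma_m = sm, sigma_e = sqrt(se2))
}

#' Fit the learning-model parameters to target learning curves
#'
#' Simulation-based least squares: for candidate parameters
#' `(alpha, sigma_m, sigma_e)` the model simulates one cohort per target
#' condition (by default the steep and shallow single-gradient landscapes
#' jointly) and the objective is the summed squared difference between the
#' simulated and target mean experimental curves. Common random numbers -
#' the same seed for every objective evaluation - keep the stochastic
#' objective smooth enough for a simplex search; a coarse grid over the box
#' supplies the simplex start.
#'
#' @param targets Named list of numeric target mean curves (one value per
#'   experimental trial), one entry per landscape in `landscapes`.
#' @param landscapes Named list of `"reward_landscape"` objects matching
#'   `targets`.
#' @param n_sim Individuals simulated per condition per objective
#'   evaluation (>= 100).
#' @param schedule A [trial_schedule()]; its experimental count must match
#'   the target length.
#' @param bounds 2x3 matrix of box constraints (rows lower/upper, columns
#'   alpha, sigma_m, sigma_e).
#' @param seed Seed reused for every objective evaluation (common random
#'   numbers).
#' @param coarse_n Grid points per parameter for the coarse scan.
#' @param maxit Simplex iteration cap.
#' @param n_boot If > 0 and `target_matrices` is supplied, number of
#'   participant-resampled refits used to report the spread of each
#'   parameter.
#' @param target_matrices Optional named list of participant x trial
#'   matrices used for bootstrap refits.
#' @return An object of class `"param_fit"` with `par` (named vector),
#'   `value`, `trace` (data frame of evaluated points), `convergence`, and
#'   `boot` (matrix of bootstrap refits or `NULL`).
#' @export
fit_parameters <- function(targets,
                           landscapes = list(
                             steep = exp1_landscape("steep", "CW"),
                             shallow = exp1_landscape("shallow", "CW")),
                           n_sim = 2000L,
                           schedule = trial_schedule(),
                           bounds = rbind(lower = c(0.05, 0.3, 0.0),
                                          upper = c(0.95, 1.6, 1.8)),
                           seed = 1L,
                           coarse_n = 3L,
                           maxit = 150L,
                           n_boot = 0L,
                           target_matrices = NULL) {
  stopifnot(is.list(targets), length(targets) >= 1L,
            all(names(targets) %in% names(landscapes)), n_sim >= 100L)
  n_exp <- schedule$n_experimental
  for (nm in names(targets))
    if (length(targets[[nm]]) != n_exp)
      stop("target '", nm, "' must have one value per experimental trial")
  flat <- all(vapply(targets, function(y) all(abs(y) < 1e-8), logical(1L)))
  if (flat)
    warning("all target curves are flat at zero; ",
            "'alpha' is unidentifiable from these targets")

  trace <- list()
  objective <- function(par, tg = targets, record = TRUE) {
    if (any(par < bounds["lower", ]) || any(par > bounds["upper", ]))
      return(1e6 + sum(pmax(bounds["lower", ] - par, 0)^2) +
               sum(pmax(par - bounds["upper", ], 0)^2))
    p <- model_params(alpha = par[1L], sigma_m = max(par[2L], 1e-6),
                      sigma_e = par[3L])
    sse <- 0
    for (nm in names(tg)) {
      set.seed(seed)  # common random numbers across evaluations
      sim <- sim_engine(as.integer(n_sim), p, schedule,
                        function(th, t) reward_probability(landscapes[[nm]], th),
                        keep_series = FALSE)
      mc <- sim$mean_curve$mean[sim$mean_curve$phase == "experimental"]
      sse <- sse + sum((mc - tg[[nm]])^2)
    }
    if (record)
      trace[[length(trace) + 1L]] <<- c(par, sse = sse)
    sse
  }

  grid <- expand.grid(
    alpha = seq(bounds["lower", 1L] + 0.1, bounds["upper", 1L] - 0.1,
                length.out = coarse_n),
    sigma_m = seq(max(bounds["lower", 2L], 0.4), min(bounds["upper", 2L], 1.4),
                  length.out = coarse_n),
    sigma_e = seq(max(bounds["lower", 3L], 0.3), min(bounds["upper", 3L], 1.5),
                  length.out = coarse_n))
  gvals <- apply(grid, 1L, objective)
  start <- as.numeric(grid[which.min(gvals), ])

  opt <- optim(start, objective, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-6))
  par <- setNames(opt$par, c("alpha", "sigma_m", "sigma_e"))

  boot <- NULL
  if (n_boot > 0L && !is.null(target_matrices)) {
    boot <- matrix(NA_real_, n_boot, 3L,
                   dimnames = list(NULL, names(par)))
    # resample indices are drawn up front: the objective reseeds the global
    # RNG on every evaluation, so in-loop draws would repeat
    set.seed(seed + 1L)
    idx <- replicate(n_boot, lapply(target_matrices, function(m)
      sample.int(nrow(m), replace = TRUE)), simplify = FALSE)
    for (b in seq_len(n_boot)) {
      bt <- Map(function(m, i) colMeans(m[i, , drop = FALSE]),
                target_matrices, idx[[b]])
      refit <- optim(par, objective, tg = bt, record = FALSE,
                     method = "Nelder-Mead", control = list(maxit = 60L))
      boot[b, ] <- refit$par
    }
  }

  tr <- as.data.frame(do.call(rbind, trace))
  names(tr) <- c("alpha", "sigma_m", "sigma_e", "sse")
  structure(list(par = par, value = opt$value, trace = tr,
                 convergence = opt$convergence, boot = boot,
                 unidentifiable = flat, n_sim = as.integer(n_sim),
                 seed = seed),
            class = "param_fit")
}

#' @export
print.param_fit <- function(x, ...) {
  cat(sprintf(
    "<param_fit> alpha = %.3f, sigma_m = %.3f, sigma_e = %.3f (sse = %.4g)\n",
    x$par["alpha"], x$par["sigma_m"], x$par["sigma_e"], x$value))
  if (x$convergence != 0L)
    cat("  optimizer did not report convergence; best-so-far returned\n")
  if (x$unidentifiable) cat("  warning: flat targets, alpha unidentifiable\n")
  if (!is.null(x$boot)) {
    q <- apply(x$boot, 2L, quantile, c(0.025, 0.975), na.rm = TRUE)
    cat(sprintf("  bootstrap 95%%: alpha [%.2f, %.2f], sigma_m [%.2f, %.2f], sigma_e [%.2f, %.2f]\n",
                q[1, 1], q[2, 1], q[1, 2], q[2, 2], q[1, 3], q[2, 3]))
  }
  invisible(x)
}
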