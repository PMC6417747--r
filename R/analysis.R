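#' Exponential fit to a learning curve
#'
#' Fits `theta_i = a * (1 - exp(-i / lambda))` by nonlinear least squares to
#' a mean reach-angle curve over the experimental trials, with `i = 1` on
#' the first experimental trial so that `lambda` is in units of
#' experimental trials. A multi-start over `lambda` in
#' `c(5, 20, 50, 100, 200)` guards against local minima; the lowest
#' residual sum of squares wins.
#'
#' A flat curve leaves `lambda` unidentifiable: when the fitted asymptote is
#' negligible relative to the curve's scale the fit is flagged via
#' `identifiable = FALSE`.
#'
#' @param y Numeric vector: mean reach angle per experimental trial, or a
#'   `"cohort_sim"` object (its experimental mean curve is used).
#' @param starts Initial values of `lambda` for the multi-start.
#' @return An object of class `"exp_fit"` with elements `a`, `lambda`,
#'   `rss`, `fitted` and `identifiable`.
#' @export
fit_exponential <- function(y, starts = c(5, 20, 50, 100, 200)) {
  if (inherits(y, "cohort_sim"))
    y <- y$mean_curve$mean[y$mean_curve$phase == "experimental"]
  stopifnot(is.numeric(y), length(y) >= 10L)
  i <- seq_along(y)
  dat <- data.frame(i = i, y = y)
  best <- NULL
  a0 <- if (max(abs(y)) > 0) y[which.max(abs(y))] else 1
  for (l0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * (1 - exp(-i / lambda)),
                        data = dat, start = list(a = a0, lambda = l0),
                        lower = c(-Inf, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, coef = coef(fit), fitted = fitted(fit))
  }
  if (is.null(best)) stop("exponential fit failed from every start")
  a <- unname(best$coef["a"])
  lam <- unname(best$coef["lambda"])
  scale <- max(abs(y), 1e-12)
  structure(list(a = a, lambda = lam, rss = best$rss,
                 fitted = as.numeric(best$fitted),
                 identifiable = abs(a) > 0.05 * scale && scale > 1e-8),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> a = %.4f, lambda = %.2f trials, rss = %.4g%s\n",
              x$a, x$lambda, x$rss,
              if (x$identifiable) "" else "  [lambda unidentifiable]"))
  invisible(x)
}

resample_fit <- function(mat, idx, starts) {
  curve <- colMeans(mat[idx, , drop = FALSE])
  tryCatch(fit_exponential(curve, starts = starts)$lambda,
           error = function(e) NA_real_)
}

#' Bootstrap posterior of the learning-rate time constant
#'
#' Resamples participants with replacement, averages each resample's
#' experimental curves, and refits the exponential, yielding the posterior
#' distribution of `lambda` for each group. With two groups the difference
#' distribution `lambda_b - lambda_a` gives a one-tailed probability that
#' group `a` did *not* learn faster: the fraction of difference samples
#' at or below zero.
#'
#' @param group_a,group_b Matrices (participants x experimental trials) of
#'   reach angles, or `"cohort_sim"` objects. `group_b` may be `NULL` for a
#'   single-group posterior.
#' @param n_resamples Number of bootstrap resamples.
#' @param starts Multi-start grid passed to [fit_exponential()].
#' @return An object of class `"bootstrap_lambda"` with `lam_a`, `lam_b`,
#'   `diff` (each with failed resamples dropped and counted in
#'   `n_dropped`), `p_value`, and 2.5-97.5 percentile intervals `ci_a`,
#'   `ci_b`.
#' @export
bootstrap_lambda <- function(group_a, group_b = NULL, n_resamples = 2000L,
                             starts = c(5, 20, 50, 100, 200)) {
  as_mat <- function(g) {
    if (inherits(g, "cohort_sim")) experimental_matrix(g) else as.matrix(g)
  }
  a <- as_mat(group_a)
  if (nrow(a) < 2L) stop("need at least 2 participants per group")
  lam_a <- vapply(seq_len(n_resamples), function(k)
    resample_fit(a, sample.int(nrow(a), replace = TRUE), starts), numeric(1L))
  lam_b <- NULL; dd <- NULL; p <- NA_real_; ci_b <- NULL
  if (!is.null(group_b)) {
    b <- as_mat(group_b)
    if (nrow(b) < 2L) stop("need at least 2 participants per group")
    lam_b <- vapply(seq_len(n_resamples), function(k)
      resample_fit(b, sample.int(nrow(b), replace = TRUE), starts), numeric(1L))
    keep <- !is.na(lam_a) & !is.na(lam_b)
    dd <- lam_b[keep] - lam_a[keep]
    p <- mean(dd <= 0)
    ci_b <- unname(quantile(lam_b[!is.na(lam_b)], c(0.025, 0.975)))
  }
  n_dropped <- sum(is.na(lam_a)) + if (is.null(lam_b)) 0L else sum(is.na(lam_b))
  structure(list(lam_a = lam_a[!is.na(lam_a)],
                 lam_b = if (is.null(lam_b)) NULL else lam_b[!is.na(lam_b)],
                 diff = dd, p_value = p,
                 ci_a = unname(quantile(lam_a[!is.na(lam_a)], c(0.025, 0.975))),
                 ci_b = ci_b, n_dropped = n_dropped,
                 n_resamples = n_resamples),
            class = "bootstrap_lambda")
}

#' @export
print.bootstrap_lambda <- function(x, ...) {
  cat(sprintf("<bootstrap_lambda> %d resamples (%d dropped)\n",
              x$n_resamples, x$n_dropped))
  cat(sprintf("  lambda_a: median %.1f, 95%% CI [%.1f, %.1f]\n",
              median(x$lam_a), x$ci_a[1], x$ci_a[2]))
  if (!is.null(x$lam_b)) {
    cat(sprintf("  lambda_b: median %.1f, 95%% CI [%.1f, %.1f]\n",
                median(x$lam_b), x$ci_b[1], x$ci_b[2]))
    cat(sprintf("  one-tailed P(lambda_b - lambda_a <= 0) = %.4f\n",
                x$p_value))
  }
  invisible(x)
}

final_mean_of <- function(series, n_last = 100L) {
  if (inherits(series, "data.frame")) {
    th <- series$theta[series$phase == "experimental"]
  } else th <- as.numeric(series)
  if (length(th) < n_last)
    stop("need at least ", n_last, " experimental trials")
  mean(tail(th, n_last))
}

#' Classify final reach behaviour
#'
#' Averages the last `n_last` experimental trials and compares against the
#' cutoff. For a single-gradient landscape (`scheme = "exp1"`) the labels
#' are learner (mean >= cutoff) and non-learner. For the valley landscapes
#' (`scheme = "exp2"`, sign-flip-pooled so the steep slope lies at positive
#' z) the labels are steep learner (mean >= cutoff), shallow learner
#' (mean <= -cutoff) and non-learner, with the matching reach direction
#' (clockwise / center / counterclockwise).
#'
#' @param series A trial-series data frame, or a numeric vector of
#'   experimental-phase reach angles.
#' @param cutoff Positive z-score threshold (default 1; robustness checks
#'   use 0.5 and 1.5).
#' @param scheme `"exp1"` or `"exp2"`.
#' @param n_last Number of trailing experimental trials to average.
#' @return An object of class `"final_classification"` with `label`,
#'   `direction`, `final_mean` and `cutoff`.
#' @export
classify_final <- function(series, cutoff = 1.0,
                           scheme = c("exp1", "exp2"), n_last = 100L) {
  scheme <- match.arg(scheme)
  if (cutoff <= 0) stop("'cutoff' must be positive")
  fm <- final_mean_of(series, n_last)
  if (scheme == "exp1") {
    label <- if (fm >= cutoff) "learner" else "non_learner"
  } else {
    label <- if (fm >= cutoff) "steep_learner"
             else if (fm <= -cutoff) "shallow_learner"
             else "non_learner"
  }
  direction <- if (fm >= cutoff) "CW" else if (fm <= -cutoff) "CCW" else "center"
  structure(list(label = label, direction = direction,
                 final_mean = fm, cutoff = cutoff),
            class = "final_classification")
}

#' @export
print.final_classification <- function(x, ...) {
  cat(sprintf("<final_classification> %s (%s); final mean %.3f, cutoff %.2f\n",
              x$label, x$direction, x$final_mean, x$cutoff))
  invisible(x)
}

#' How the Nth success predicts final classification
#'
#' For a cohort on a valley landscape (sign-flip pooled so the steep slope
#' is at positive z), assigns each individual's k-th rewarded reach to the
#' steep slope (`theta > 0`) or shallow slope (`theta < 0`) - a reach at
#' exactly 0 belongs to neither and is skipped - and tabulates, for each
#' success rank N and slope, the conditional frequency of each final
#' classification among individuals whose Nth success lay on that slope.
#'
#' @param theta Matrix (individuals x experimental trials) of reach angles,
#'   or a `"cohort_sim"` (its reward matrix is then taken from the object).
#' @param reward Matching 0/1 reward matrix (ignored when `theta` is a
#'   cohort).
#' @param max_n Largest success rank N to tabulate.
#' @param cutoff,n_last Passed to [classify_final()] (`scheme = "exp2"`).
#' @return Data frame with columns `N`, `slope`, `class`, `prob` and
#'   `n_cond` (size of the conditioning set). Rows with an empty
#'   conditioning set carry `prob = NA`.
#' @export
nth_success_prediction <- function(theta, reward = NULL, max_n = 30L,
                                   cutoff = 1.0, n_last = 100L) {
  if (inherits(theta, "cohort_sim")) {
    reward <- theta$reward[, schedule_phases(theta$schedule) == "experimental",
                           drop = FALSE]
    theta <- experimental_matrix(theta)
  }
  stopifnot(is.matrix(theta), is.matrix(reward),
            all(dim(theta) == dim(reward)))
  n_ind <- nrow(theta)
  labels <- vapply(seq_len(n_ind), function(i)
    classify_final(theta[i, ], cutoff = cutoff, scheme = "exp2",
                   n_last = n_last)$label, character(1L))
  # slope of the Nth success per individual: +1 steep, -1 shallow, NA if
  # fewer than N successes (theta == 0 exactly is dropped from the ranks)
  slope_of <- function(i) {
    idx <- which(reward[i, ] == 1L & theta[i, ] != 0)
    sign(theta[i, idx])
  }
  slopes <- lapply(seq_len(n_ind), slope_of)
  classes <- c("steep_learner", "shallow_learner", "non_learner")
  out <- expand.grid(N = seq_len(max_n), slope = c("steep", "shallow"),
                     class = classes, stringsAsFactors = FALSE)
  out$prob <- NA_real_
  out$n_cond <- 0L
  for (N in seq_len(max_n)) {
    nth <- vapply(slopes, function(s)
      if (length(s) >= N) s[N] else NA_real_, numeric(1L))
    for (sl in c(1, -1)) {
      cond <- which(!is.na(nth) & nth == sl)
      sl_name <- if (sl > 0) "steep" else "shallow"
      rows <- out$N == N & out$slope == sl_name
      out$n_cond[rows] <- length(cond)
      if (length(cond) > 0L) {
        tab <- table(factor(labels[cond], levels = classes))
        out$prob[rows] <- as.numeric(tab[out$class[rows]]) / length(cond)
      }
    }
  }
  out[order(out$N, out$slope, out$class), ]
}

#' Trial-to-trial variability by reinforcement history
#'
#' Standard deviation of the change in reach angle between consecutive
#' trials, `delta = theta[n + 1] - theta[n]`, conditioned on the
#' reinforcement history: after a rewarded experimental reach, after an
#' unrewarded one, and within the feedback-free baseline (trials 25-50 of
#' the reference schedule) and washout windows. Optionally splits the
#' experimental bins by the two-trial history `(r[n-1], r[n])`.
#'
#' @param series A trial-series data frame ([simulate_participant()]
#'   format).
#' @param two_back Also tabulate two-trial history bins.
#' @param min_n Bins with fewer than `min_n` differences get `sd = NA`.
#' @return Data frame with columns `bin`, `sd` and `n`.
#' @export
variability_by_history <- function(series, two_back = FALSE, min_n = 2L) {
  stopifnot(is.data.frame(series),
            all(c("phase", "theta", "reward") %in% names(series)))
  exp_idx <- which(series$phase == "experimental")
  if (length(exp_idx) < 2L) stop("no experimental trial pairs")
  th <- series$theta[exp_idx]
  r <- series$reward[exp_idx]
  d <- diff(th)
  r_n <- r[-length(r)]
  bin_sd <- function(x) if (length(x) >= min_n) sd(x) else NA_real_
  bins <- list(after_success = d[r_n == 1L], after_failure = d[r_n == 0L])
  if (two_back) {
    r_prev <- c(NA_integer_, r_n[-length(r_n)])
    for (a in 0:1) for (b in 0:1) {
      nm <- sprintf("after_%d%d", a, b)
      bins[[nm]] <- d[!is.na(r_prev) & r_prev == a & r_n == b]
    }
  }
  bl <- which(series$phase == "baseline")
  if (length(bl) >= 26L) bl <- tail(bl, 26L)  # trials 25-50 of the default
  bins$baseline <- diff(series$theta[bl])
  bins$washout <- diff(series$theta[series$phase == "washout"])
  data.frame(bin = names(bins),
             sd = vapply(bins, bin_sd, numeric(1L)),
             n = vapply(bins, length, integer(1L)),
             row.names = NULL)
}

#' Exact test of a 2x2 frequency table
#'
#' Two-sided Fisher exact test: the probability, under fixed margins, of
#' all tables whose hypergeometric probability does not exceed the observed
#' table's.
#'
#' @param table A 2x2 matrix of nonnegative integer counts.
#' @return The two-tailed exact p-value.
#' @examples
#' contingency_test(matrix(c(37, 29, 3, 11), nrow = 2))
#' @export
contingency_test <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) ||
      any(table != round(table)))
    stop("'table' must be a 2x2 matrix of nonnegative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("'table' has an empty margin")
  fisher.test(table, alternative = "two.sided")$p.value
}
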