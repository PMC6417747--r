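# Fixtures built in code: degenerate landscapes and scripted-reward series.

# landscape with constant reward probability p everywhere
flat_landscape <- function(p) {
  new_landscape(breaks = 0, slope = c(0, 0), intercept = c(p, p),
                direction = "CW", max_rate = p,
                name = sprintf("flat p=%.2f", p))
}

# alpha = 0 model with a prescribed experimental reward sequence: theta[n]
# is drawn with variance sigma_m^2 after a scripted success (or with no
# preceding feedback) and sigma_m^2 + sigma_e^2 after a scripted failure
scripted_series <- function(rewards, sigma_m = 0.81, sigma_e = 0.9,
                            n_baseline = 50L, n_washout = 50L) {
  n_exp <- length(rewards)
  explore <- c(FALSE, rewards[-n_exp] == 0L)
  sds <- ifelse(explore, sqrt(sigma_m^2 + sigma_e^2), sigma_m)
  data.frame(
    participant = 1L,
    trial = seq_len(n_baseline + n_exp + n_washout),
    phase = rep(c("baseline", "experimental", "washout"),
                c(n_baseline, n_exp, n_washout)),
    theta = c(rnorm(n_baseline, 0, sigma_m),
              rnorm(n_exp, 0, sds),
              rnorm(n_washout, 0, sigma_m)),
    reward = c(rep(NA_integer_, n_baseline), as.integer(rewards),
               rep(NA_integer_, n_washout)))
}

# brute-force two-sided Fisher probability: enumerate all 2x2 tables with
# the observed margins and sum the hypergeometric probabilities that do
# not exceed the observed table's
enumerate_fisher <- function(tab) {
  r <- rowSums(tab); c1 <- colSums(tab)[1L]; n <- sum(tab)
  a_vals <- max(0L, c1 - r[2L]):min(r[1L], c1)
  pr <- dhyper(a_vals, r[1L], r[2L], c1)
  p_obs <- dhyper(tab[1L, 1L], r[1L], r[2L], c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
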