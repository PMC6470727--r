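# Hand-written partial likelihood for untied left-truncated data; used as
# an independent oracle for the Cox engine (grid maximisation, no
# Newton-Raphson, no shared code with cox_lt).
brute_partial_loglik <- function(beta, entry, exit, status, x) {
  ll <- 0
  for (i in which(status == 1)) {
    t <- exit[i]
    risk <- which(entry < t & t <= exit)
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# small untied survival data set with left truncation
make_lt_data <- function(n, seed, truncation = TRUE, beta = 0.6,
                         binary = FALSE) {
  set.seed(seed)
  entry <- if (truncation) runif(n, 40, 60) else rep(0, n)
  x <- if (binary) rbinom(n, 1, 0.5) else rnorm(n)
  z <- rbinom(n, 1, 0.4)
  death <- entry + rexp(n, 0.04 * exp(beta * x - 0.3 * z))
  cens <- entry + runif(n, 2, 30)
  d <- data.frame(entry = entry, exit = pmin(death, cens),
                  status = as.integer(death <= cens), x = x, z = z)
  # jitter to guarantee no ties
  d$exit <- d$exit + seq_len(n) * 1e-9
  d
}

# null-effect cohort used by the calibration checks of the test batteries
null_sim_config <- function(n, seed) {
  sim_config(
    n_subjects = n, seed = seed,
    true_log_hr = c(red = 0, processed = 0, sex_M = 0, bmi = 0),
    missing_rates = numeric(0))
}
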