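# Independent numeric oracles: deliberately naive implementations used to
# cross-check the closed forms in the package.

# Time to exhaustion by brute-force root finding on the fatigue integral
# (quadrature over the constant-power profile), independent of pd_tte().
oracle_tte <- function(params, p, upper = 1e7) {
  rate <- switch(class(params)[1],
    hyperbolic_params = (p - params$cp) / params$w_prime,
    powerlaw_params = (p / params$s)^(1 / (1 - params$e))
  )
  stats::uniroot(function(t) t * rate - 1, c(1e-12, upper), tol = 1e-12)$root
}

# Fatigue after a piecewise profile via fine Riemann summation.
oracle_fatigue <- function(durations, powers, params, n_steps = 2e5) {
  total <- sum(durations)
  ts <- seq(0, total, length.out = n_steps + 1)
  mid <- (ts[-1] + ts[-length(ts)]) / 2
  seg <- findInterval(mid, cumsum(durations), left.open = TRUE) + 1
  p <- powers[seg]
  rate <- switch(class(params)[1],
    hyperbolic_params = (p - params$cp) / params$w_prime,
    powerlaw_params = (p / params$s)^(1 / (1 - params$e))
  )
  sum(rate * diff(ts))
}

# Finish time of a two-phase plan by simulating phase 2 over a dense power
# grid and picking the fastest feasible constant phase-2 power; independent
# of the closed forms in two_phase_finish_time().
oracle_two_phase <- function(total_work, w1, p1, params) {
  t1 <- w1 / p1
  rate1 <- switch(class(params)[1],
    hyperbolic_params = max(0, (p1 - params$cp)) / params$w_prime,
    powerlaw_params = (p1 / params$s)^(1 / (1 - params$e))
  )
  balance <- 1 - t1 * rate1
  if (balance <= 0) return(NA_real_)
  w2 <- total_work - w1
  # p2 must satisfy (w2/p2) * rate(p2) = balance; solve numerically
  g <- function(p2) {
    r2 <- switch(class(params)[1],
      hyperbolic_params = max(0, (p2 - params$cp)) / params$w_prime,
      powerlaw_params = (p2 / params$s)^(1 / (1 - params$e))
    )
    (w2 / p2) * r2 - balance
  }
  lo <- if (inherits(params, "hyperbolic_params")) params$cp + 1e-9 else 1e-9
  hi <- 1e6
  if (g(hi) < 0) return(NA_real_)       # even huge power cannot exhaust: degenerate
  p2 <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  t1 + w2 / p2
}

rand_powerlaw <- function(mode = "velocity") {
  powerlaw_params(runif(1, 5, 800), runif(1, 0.8, 0.97), mode = mode)
}

rand_hyperbolic <- function(mode = "power") {
  hyperbolic_params(runif(1, 150, 450), runif(1, 8000, 35000), mode = mode)
}
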