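test_that("exertion rates match their closed forms at landmark powers", {
  hyp <- hyperbolic_params(400, 25500)
  expect_equal(exertion_rate(hyp, 400), 0)
  expect_equal(exertion_rate(hyp, 407), 7 / 25500)
  expect_equal(exertion_rate(hyp, 400 + 25500), 1)
  expect_error(exertion_rate(hyp, 399), class = "endurofit_error_below_cp")

  pow <- powerlaw_params(9.57, 0.94, mode = "velocity")
  expect_equal(exertion_rate(pow, 9.57), 1)
  expect_equal(exertion_rate(pow, 0), 0)
  # rate at the even 5-km velocity implies exhaustion exactly at the 5-km time
  v5k <- 5000 / pd_time_for_work(pow, 5000)
  expect_equal(1 / exertion_rate(pow, v5k), pd_time_for_work(pow, 5000),
               tolerance = 1e-12)
  expect_error(exertion_rate(pow, -1), class = "endurofit_error_domain")
})

test_that("rate_pow is strictly increasing and convex in power", {
  pow <- powerlaw_params(300, 0.9)
  p <- seq(10, 600, length.out = 200)
  r <- exertion_rate(pow, p)
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(diff(r)) > 0))
})

test_that("fatigue accumulation is exact on constant and multi-segment profiles", {
  pow <- powerlaw_params(9.57, 0.94, mode = "velocity")
  # constant power held for exactly its time to exhaustion -> fatigue 1
  tte <- pd_tte(pow, 7.0)
  st <- accumulate_fatigue(power_profile(tte, 7.0), pow)
  expect_true(st$exhausted)
  expect_equal(st$time_of_exhaustion, tte, tolerance = 1e-12)

  # over-paced first km of a 5-km race, then the exact salvage velocity:
  # exhaustion coincides with 5000 m covered
  res <- two_phase_finish_time(two_phase_plan(5000, 1000, 7.0), pow)
  prof <- power_profile(c(res$t1, res$t2 * 2), c(res$p1, res$p2))
  st2 <- accumulate_fatigue(prof, pow)
  expect_true(st2$exhausted)
  dist_at_exh <- res$t1 * res$p1 + (st2$time_of_exhaustion - res$t1) * res$p2
  expect_equal(dist_at_exh, 5000, tolerance = 1e-9)
  expect_equal(st2$time_of_exhaustion, 819.34, tolerance = 1e-4)

  # hyperbolic: 45 min at 407 W drains 18900 J of the 25500 J capacity
  hyp <- hyperbolic_params(400, 25500)
  st3 <- accumulate_fatigue(power_profile(2700, 407), hyp)
  expect_false(st3$exhausted)
  end <- st3$trajectory[nrow(st3$trajectory), ]
  expect_equal(end$fatigue, 18900 / 25500)
  expect_equal(end$balance, 1 - 18900 / 25500)
  expect_error(accumulate_fatigue(power_profile(c(10, 10), c(420, 350)), hyp),
               class = "endurofit_error_below_cp")
})

test_that("fatigue agrees with brute-force quadrature and is re-segmentation invariant", {
  set.seed(7)
  for (i in 1:5) {
    pow <- rand_powerlaw()
    dur <- runif(3, 50, 400)
    p <- runif(3, 0.2, 0.9) * pow$s
    st <- accumulate_fatigue(power_profile(dur, p), pow)
    fat_end <- st$trajectory$fatigue[nrow(st$trajectory)]
    expect_equal(fat_end, oracle_fatigue(dur, p, pow), tolerance = 1e-4)
    # splitting a constant stretch in two changes nothing
    st2 <- accumulate_fatigue(
      power_profile(c(dur[1] / 2, dur[1] / 2, dur[2:3]), c(p[1], p[1], p[2:3])),
      pow
    )
    expect_equal(st2$trajectory$fatigue[nrow(st2$trajectory)], fat_end,
                 tolerance = 1e-12)
    # fatigue is non-decreasing along the trajectory
    expect_true(all(diff(st$trajectory$fatigue) >= 0))
    # balance + fatigue is identically 1
    expect_equal(st$trajectory$balance + st$trajectory$fatigue,
                 rep(1, nrow(st$trajectory)))
  }
})

test_that("quadrature fallback reproduces the analytic result on a ramped profile", {
  pow <- powerlaw_params(400, 0.9)
  # continuous ramp: P(s) = 200 + s/10
  st <- accumulate_fatigue_fn(function(s) 200 + s / 10, pow, t_end = 1500)
  # piecewise approximation with fine constant steps
  n <- 3000
  edges <- seq(0, 1500, length.out = n + 1)
  mids <- (edges[-1] + edges[-(n + 1)]) / 2
  st2 <- accumulate_fatigue(power_profile(rep(1500 / n, n), 200 + mids / 10), pow)
  expect_equal(st$time_of_exhaustion, st2$time_of_exhaustion, tolerance = 1e-5)
})

test_that("fatigued parameters follow the capacity-depletion closed forms", {
  hyp <- hyperbolic_params(400, 25500)
  f45 <- fatigued_params(hyp, p = 407, t = 2700)
  expect_identical(f45$cp, 400)            # CP never changes with fatigue
  expect_equal(f45$w_prime, 6600)          # W' - t(P - CP), exact
  expect_identical(fatigued_params(hyp, 407, 0), hyp)
  expect_error(fatigued_params(hyp, 407, 3700), class = "endurofit_error_exhausted")

  # power law calibrated so that TTE(407) matches the hyperbolic scenario
  tte <- pd_tte(hyp, 407)
  e <- 1 / 1.05
  s <- 407 * tte^(1 - e)                   # S chosen to equate TTE at 407 W
  pow <- powerlaw_params(s, e)
  expect_equal(s, 601.43, tolerance = 1e-4)
  expect_equal(pd_tte(pow, 407), tte, tolerance = 1e-10)
  f45p <- fatigued_params(pow, p = 407, t = 2700)
  expect_identical(f45p$e, e)              # E never changes with fatigue
  expect_equal(f45p$s, (s^(1 / (1 - e)) - 2700 * 407^(1 / (1 - e)))^(1 - e),
               tolerance = 1e-10)
  expect_lt(f45p$s, s)
})

test_that("fatigued curves are consistent with residual-capacity bookkeeping", {
  # TTE at power q for the fatigued athlete equals the residual time t_res
  # with t * rate(p) + t_res * rate(q) = 1  (the two formulations agree)
  set.seed(13)
  for (i in 1:20) {
    pow <- rand_powerlaw()
    p <- runif(1, 0.3, 0.8) * pow$s
    t <- runif(1, 0.1, 0.9) / exertion_rate(pow, p)
    q <- runif(1, 0.5, 1.2) * p
    faded <- fatigued_params(pow, p, t)
    t_res <- (1 - t * exertion_rate(pow, p)) / exertion_rate(pow, q)
    expect_equal(pd_tte(faded, q), t_res, tolerance = 1e-9)

    hyp <- rand_hyperbolic()
    ph <- hyp$cp + runif(1, 0.1, 1) * hyp$w_prime / 100
    th <- runif(1, 0.1, 0.9) / exertion_rate(hyp, ph)
    qh <- hyp$cp + runif(1, 0.5, 2) * (ph - hyp$cp)
    fadedh <- fatigued_params(hyp, ph, th)
    t_resh <- (1 - th * exertion_rate(hyp, ph)) / exertion_rate(hyp, qh)
    expect_equal(pd_tte(fadedh, qh), t_resh, tolerance = 1e-9)
  }
})

test_that("fatigued power-duration curves shift down (power law) or pivot on CP (hyperbolic)", {
  pow <- powerlaw_params(601.43, 1 / 1.05)
  hyp <- hyperbolic_params(400, 25500)
  grid <- c(10, 60, 300, 1800, 7200)
  faded_pow <- fatigued_params(pow, 407, 2700)
  faded_hyp <- fatigued_params(hyp, 407, 2700)
  # power law: entire curve strictly below the fresh curve
  expect_true(all(pd_power(faded_pow, grid) < pd_power(pow, grid)))
  # hyperbolic: curve drops but still asymptotes to the *same* CP
  expect_true(all(pd_power(faded_hyp, grid) < pd_power(hyp, grid)))
  expect_equal(pd_power(faded_hyp, 1e12), pd_power(hyp, 1e12), tolerance = 1e-9)
  expect_identical(faded_hyp$cp, hyp$cp)
})
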