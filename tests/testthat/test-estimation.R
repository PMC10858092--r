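test_that("noiseless data generated by a model is recovered at machine precision", {
  hyp <- hyperbolic_params(4.5, 180, mode = "velocity")
  x <- generate_effort_grid(hyp, durations = c(150, 400, 700, 880))
  fit <- fit_hyperbolic(x)
  expect_equal(fit$params$cp, 4.5, tolerance = 1e-10)
  expect_equal(fit$params$w_prime, 180, tolerance = 1e-10)
  expect_equal(fit$n_used, 4L)

  pow <- powerlaw_params(8.8, 0.91, mode = "velocity")
  y <- generate_effort_grid(pow, distances = c(1500, 5000, 21097.5))
  fitp <- fit_powerlaw(y)
  expect_equal(fitp$params$s, 8.8, tolerance = 1e-10)
  expect_equal(fitp$params$e, 0.91, tolerance = 1e-10)
  # two points determine the fit exactly
  fit2 <- fit_powerlaw(y[1:2, ])
  expect_equal(fit2$params$s, 8.8, tolerance = 1e-10)
})

test_that("hyperbolic fit uses only in-window efforts; power law is unrestricted", {
  hyp <- hyperbolic_params(4.5, 180, mode = "velocity")
  base <- generate_effort_grid(hyp, durations = c(150, 400, 700, 880))
  # out-of-window rows from a very different athlete must not move the fit
  junk <- efforts(duration = c(30, 5000, 20000), work = c(400, 22000, 70000))
  fit1 <- fit_hyperbolic(base)
  fit2 <- fit_hyperbolic(dplyr::bind_rows(base, junk))
  expect_identical(fit1$params$cp, fit2$params$cp)
  expect_identical(fit1$params$w_prime, fit2$params$w_prime)
  expect_error(fit_hyperbolic(junk), class = "endurofit_error_insufficient_data")
})

test_that("power-law fit is scale-equivariant in intensity", {
  set.seed(3)
  d <- c(120, 300, 700, 1800, 5000)
  x <- efforts(duration = d,
               work = 8.8 * d^0.92 * exp(rnorm(5, 0, 0.02)))
  f1 <- fit_powerlaw(x)
  x2 <- x
  x2$work <- x2$work * 3.7
  x2$intensity <- x2$work / x2$duration
  f2 <- fit_powerlaw(x2)
  expect_equal(f2$params$s, 3.7 * f1$params$s, tolerance = 1e-12)
  expect_equal(f2$params$e, f1$params$e, tolerance = 1e-12)
})

test_that("duration ties keep the better effort before fitting", {
  pow <- powerlaw_params(9, 0.92, mode = "velocity")
  x <- generate_effort_grid(pow, durations = c(200, 500, 800))
  dup <- x[2, ]
  dup$work <- dup$work * 0.9      # slower duplicate at the same duration
  dup$intensity <- dup$work / dup$duration
  fit <- fit_powerlaw(dplyr::bind_rows(x, dup))
  expect_equal(fit$n_used, 3L)
  expect_equal(fit$params$s, 9, tolerance = 1e-10)
})

test_that("elite case-study fits reproduce the published parameter estimates", {
  kh <- fit_hyperbolic(kipchoge_prs())
  expect_equal(kh$params$cp, 6.23, tolerance = 0.01 / 6.23)
  expect_equal(kh$params$w_prime, 176.29, tolerance = 1 / 176.29)
  expect_identical(kh$params$mode, "velocity")
  kp <- fit_powerlaw(kipchoge_prs())
  expect_equal(kp$params$s, 9.57, tolerance = 0.015 / 9.57)
  expect_equal(kp$params$e, 0.94, tolerance = 0.005 / 0.94)
  gp <- fit_powerlaw(gebrselassie_prs())
  expect_gt(gp$params$e, 0.92)    # an even-endurance elite profile
  expect_lt(gp$params$e, 0.96)
})

test_that("fixed-F calibrator reproduces the magazine rule and its limits", {
  # half marathon 59:25 -> marathon prediction
  expect_equal(calibrate_fixed_f(3565, 21097.5, 42195, f = 1.06),
               3565 * 2^1.06, tolerance = 1e-12)   # marathon = exactly 2x half
  expect_equal(calibrate_fixed_f(3565, 21097.5, 42195, f = 1.06),
               7432.78, tolerance = 1e-5)
  expect_equal(calibrate_fixed_f(3565, 21097.5, 21097.5), 3565)
  expect_equal(calibrate_fixed_f(100, 1000, 3000, f = 1), 300)
  expect_error(calibrate_fixed_f(-1, 1000, 3000), class = "endurofit_error_domain")
})

test_that("estimated power-law exponent is unbiased under realistic noise", {
  # 500 seeded replicates of an 8-effort athlete with 2% time noise
  set.seed(202)
  truth <- powerlaw_params(9.57, 0.94, mode = "velocity")
  grid <- c(400, 800, 1500, 3000, 5000, 10000, 21097.5, 42195)
  bias <- replicate(500, {
    x <- generate_effort_grid(truth, distances = grid)
    x$duration <- x$duration * exp(rnorm(nrow(x), 0, 0.02))
    x$intensity <- x$work / x$duration
    fit_powerlaw(x)$params$e - truth$e
  })
  expect_lt(abs(mean(bias)), 0.005)
})

test_that("filtering drops non-maximal efforts, spikes and sparse athletes", {
  # rule (b): 600 s effort slower than a longer one cannot be maximal
  x <- efforts(duration = c(600, 1200), work = c(600 * 400, 1200 * 410),
               kind = "power")
  res <- filter_dataset(x, filter_rules(min_in_window = NULL, mad_multiplier = NULL))
  expect_equal(nrow(res$retained), 1L)
  expect_equal(res$retained$duration, 1200)
  expect_equal(res$excluded$rule, "non_maximal")

  # rule (a): an athlete-season with two in-window efforts is excluded wholesale
  y <- efforts(duration = c(150, 700, 2000), work = c(900, 3500, 8000),
               athlete_id = "sparse", kind = "power")
  res2 <- filter_dataset(y, filter_rules(min_in_window = 3, window = c(120, 1200),
                                         enforce_maximality = FALSE,
                                         mad_multiplier = NULL))
  expect_equal(nrow(res2$retained), 0L)
  expect_equal(res2$report$athletes_excluded, "sparse")

  # rule (c): injected 10x power spikes are removed at MAD multiplier 5
  spec <- population_spec(n_athletes = 20, noise_sigma = 0.02,
                          contamination = 0.05, contamination_type = "spike",
                          seed = 99)
  pop <- generate_population(spec)
  res3 <- filter_dataset(pop$efforts,
                         filter_rules(min_in_window = NULL,
                                      enforce_maximality = FALSE,
                                      mad_multiplier = 5))
  spiked <- pop$efforts$contaminated
  expect_gt(sum(spiked), 0)
  # every spike is flagged as an outlier, and no clean row is lost
  expect_true(all(res3$excluded$contaminated))
  expect_setequal(res3$excluded$rule, "outlier")
  expect_equal(sum(res3$retained$contaminated), 0)

  expect_error(filter_dataset(pop$efforts[0, ]), class = "endurofit_error_domain")
})
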