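#' Instantaneous rate of exertion at a constant power
#'
#' The rate of exertion is the fraction of total capacity consumed per
#' second while holding power `p`; its time integral is accumulated
#' fatigue, and exhaustion occurs when that integral first reaches 1.
#'
#' Hyperbolic model: rate = (P - CP)/W', linear in P and zero at P = CP.
#' Powers below CP are an error -- the depletion model is defined only at
#' or above CP and recovery is deliberately out of scope. Power-law model:
#' rate = (P/S)^(1/(1-E)), defined for any P >= 0, zero at P = 0, equal to
#' 1/s at P = S, and super-linear (strictly convex) in P -- the reason the
#' power law punishes over-pacing.
#'
#' @inheritParams pd_power
#' @param p Power(s), vectorised. Hyperbolic: must be >= CP; power law:
#'   must be >= 0.
#' @return Rate(s) in 1/s.
#' @examples
#' exertion_rate(hyperbolic_params(400, 25500), 407)  # 7/25500
#' @export
exertion_rate <- function(model, p) UseMethod("exertion_rate")

#' @export
exertion_rate.hyperbolic_params <- function(model, p) {
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p))) abort_domain("`p` must be finite.")
  if (any(p < model$cp)) {
    rlang::abort(
      sprintf("Power below CP = %g: the hyperbolic exertion rate is defined only at or above CP (recovery is not modelled).",
              model$cp),
      class = "endurofit_error_below_cp"
    )
  }
  (p - model$cp) / model$w_prime
}

#' @export
exertion_rate.powerlaw_params <- function(model, p) {
  check_nonnegative_vector(p, "p")
  (p / model$s)^(1 / (1 - model$e))
}

#' Piecewise-constant intensity profile
#'
#' An ordered sequence of (duration, power) segments describing the
#' instantaneous power output P<s>; evaluation is right-continuous
#' piecewise-constant.
#'
#' @param duration Segment lengths in seconds, all > 0.
#' @param power Segment powers (velocities), all >= 0.
#' @return A tibble of class `power_profile` with a `total_duration`
#'   attribute.
#' @export
power_profile <- function(duration, power) {
  check_positive_vector(duration, "duration")
  check_nonnegative_vector(power, "power")
  if (length(duration) != length(power)) {
    abort_domain("`duration` and `power` must have the same length.")
  }
  out <- tibble::tibble(duration = as.numeric(duration), power = as.numeric(power))
  class(out) <- c("power_profile", class(out))
  attr(out, "total_duration") <- sum(out$duration)
  out
}

#' Accumulate fatigue along an intensity profile
#'
#' Integrates the exertion rate over a [power_profile()]. Because the rate
#' is constant within each segment the integral is an exact sum, and the
#' exhaustion time (the first t with fatigue = 1) is located analytically
#' inside the breaching segment -- no time stepping. The athlete starts
#' rested (fatigue 0, balance 1).
#'
#' @param profile A [power_profile()].
#' @param model A `pd_params` object. For the hyperbolic model every
#'   segment power must be >= CP.
#' @return A list of class `fatigue_state`: `trajectory` -- tibble
#'   `(t, fatigue, balance)` at segment boundaries plus the exhaustion
#'   instant; `exhausted`; `time_of_exhaustion` (NA if the profile ends
#'   before exhaustion). Fatigue values beyond 1 are retained in the
#'   trajectory as a diagnostic; the exhaustion event itself is always at
#'   exactly 1.
#' @examples
#' prof <- power_profile(c(142.857, 700), c(7.0, 5.913))
#' accumulate_fatigue(prof, powerlaw_params(9.57, 0.94, "velocity"))
#' @export
accumulate_fatigue <- function(profile, model) {
  stopifnot(inherits(profile, "power_profile"))
  rates <- exertion_rate(model, profile$power)  # errors if hyperbolic below CP
  t_end <- cumsum(profile$duration)
  fat <- cumsum(profile$duration * rates)
  traj <- tibble::tibble(t = c(0, t_end), fatigue = c(0, fat))

  t_exh <- NA_real_
  if (any(fat >= 1)) {
    i <- which(fat >= 1)[1]
    fat_before <- if (i == 1L) 0 else fat[i - 1L]
    t_before <- if (i == 1L) 0 else t_end[i - 1L]
    t_exh <- t_before + (1 - fat_before) / rates[i]
    traj <- dplyr::bind_rows(traj, tibble::tibble(t = t_exh, fatigue = 1))
    traj <- dplyr::arrange(traj, .data$t)
  }
  traj$balance <- 1 - traj$fatigue
  structure(
    list(trajectory = traj, exhausted = !is.na(t_exh), time_of_exhaustion = t_exh),
    class = "fatigue_state"
  )
}

#' @export
print.fatigue_state <- function(x, ...) {
  end <- x$trajectory[nrow(x$trajectory), ]
  if (x$exhausted) {
    cat(sprintf("Exhaustion at t = %.6g s\n", x$time_of_exhaustion))
  } else {
    cat(sprintf("Not exhausted; fatigue %.4g (balance %.4g) at t = %.6g s\n",
                end$fatigue, end$balance, end$t))
  }
  invisible(x)
}

#' Accumulate fatigue for an arbitrary (non-piecewise) intensity function
#'
#' Quadrature fallback for user-supplied continuous profiles: integrates
#' `exertion_rate(model, p_fun(s))` numerically and locates the
#' exhaustion time by root finding. For piecewise-constant profiles use
#' [accumulate_fatigue()], which is exact.
#'
#' @param p_fun Function of time returning instantaneous power, vectorised.
#' @param model A `pd_params` object.
#' @param t_end End of the exercise bout, s.
#' @param tol Relative tolerance for the quadrature and root search.
#' @return As [accumulate_fatigue()] (trajectory at the endpoints and the
#'   exhaustion instant only).
#' @export
accumulate_fatigue_fn <- function(p_fun, model, t_end, tol = 1e-10) {
  stopifnot(is.function(p_fun))
  check_positive_scalar(t_end, "t_end")
  fat_at <- function(t) {
    if (t == 0) return(0)
    stats::integrate(function(s) exertion_rate(model, p_fun(s)),
                     0, t, rel.tol = tol, abs.tol = tol)$value
  }
  fat_end <- fat_at(t_end)
  t_exh <- NA_real_
  if (fat_end >= 1) {
    t_exh <- stats::uniroot(function(t) fat_at(t) - 1, c(0, t_end),
                            tol = tol * t_end)$root
  }
  traj <- tibble::tibble(
    t = c(0, if (!is.na(t_exh)) t_exh, t_end),
    fatigue = c(0, if (!is.na(t_exh)) 1, fat_end)
  )
  traj$balance <- 1 - traj$fatigue
  structure(
    list(trajectory = traj, exhausted = !is.na(t_exh), time_of_exhaustion = t_exh),
    class = "fatigue_state"
  )
}

#' Power-duration parameters of a partially fatigued athlete
#'
#' After exercising for `t` seconds at constant power `p` without reaching
#' exhaustion, the athlete's remaining power-duration relationship stays in
#' the same model family with one parameter reduced:
#'
#' * hyperbolic: W' is replaced by W' - t(P - CP); CP is unchanged, so the
#'   fatigued curve still asymptotes to the same critical power no matter
#'   how fatigued the athlete is;
#' * power law: S is replaced by (S^(1/(1-E)) - t P^(1/(1-E)))^(1-E); E is
#'   unchanged, so the whole curve scales downwards with fatigue.
#'
#' The power-law update is evaluated in log space, so it is stable for the
#' large exponents 1/(1-E) that realistic E close to 1 produce.
#'
#' @inheritParams pd_power
#' @param p Constant power held so far (hyperbolic: must be >= CP).
#' @param t Time already exercised, s (>= 0); must be strictly less than
#'   the time to exhaustion at `p`, else an `endurofit_error_exhausted`
#'   condition is signalled. `t = 0` returns the input parameters.
#' @return A `pd_params` object of the same family.
#' @examples
#' fatigued_params(hyperbolic_params(400, 25500), p = 407, t = 2700)  # W' = 6600
#' @export
fatigued_params <- function(model, p, t) UseMethod("fatigued_params")

#' @export
fatigued_params.hyperbolic_params <- function(model, p, t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    abort_domain("`t` must be a single non-negative number.")
  }
  if (t == 0) return(model)
  rate <- exertion_rate(model, p)  # errors below CP
  if (t * rate >= 1) {
    rlang::abort(
      sprintf("Athlete is exhausted at or before t = %g s at power %g.", t, p),
      class = "endurofit_error_exhausted"
    )
  }
  hyperbolic_params(model$cp, model$w_prime - t * (p - model$cp),
                    mode = model$mode)
}

#' @export
fatigued_params.powerlaw_params <- function(model, p, t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    abort_domain("`t` must be a single non-negative number.")
  }
  if (t == 0) return(model)
  check_positive_vector(p, "p")
  rate <- exertion_rate(model, p)
  if (t * rate >= 1) {
    rlang::abort(
      sprintf("Athlete is exhausted at or before t = %g s at power %g.", t, p),
      class = "endurofit_error_exhausted"
    )
  }
  inv <- 1 / (1 - model$e)
  # log(S^inv - t * p^inv), computed stably
  log_rem <- log_diff_exp(inv * log(model$s), log(t) + inv * log(p))
  powerlaw_params(exp((1 - model$e) * log_rem), model$e, mode = model$mode)
}
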