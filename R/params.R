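#' Hyperbolic (critical-power) model parameters
#'
#' The hyperbolic model asserts P(T) = W'/T + CP: power decays towards a
#' strictly positive asymptote CP ("critical power"), and W' is the finite
#' amount of work that can be generated above CP before exhaustion. In
#' velocity mode (running) the same parameters are conventionally called
#' critical velocity CV (m/s) and D' (m); the arithmetic is identical, the
#' mode is a unit label only.
#'
#' @param cp Critical power in J/s (critical velocity in m/s in velocity
#'   mode). Must be > 0.
#' @param w_prime Work capacity above `cp`, in J (distance capacity D' in m
#'   in velocity mode). Must be > 0.
#' @param mode Either `"power"` or `"velocity"`. Purely a label used for
#'   printing; never affects computation.
#' @return An object of class `c("hyperbolic_params", "pd_params")`.
#' @examples
#' hyperbolic_params(cp = 400, w_prime = 25500)
#' hyperbolic_params(cp = 6.23, w_prime = 176.29, mode = "velocity")
#' @export
hyperbolic_params <- function(cp, w_prime, mode = c("power", "velocity")) {
  mode <- match.arg(mode)
  check_positive_scalar(cp, "cp")
  check_positive_scalar(w_prime, "w_prime")
  structure(
    list(cp = as.numeric(cp), w_prime = as.numeric(w_prime), mode = mode),
    class = c("hyperbolic_params", "pd_params")
  )
}

#' Power-law (Riegel) model parameters
#'
#' The power-law model asserts P(T) = S * T^(E-1): `s` is the power (or
#' velocity) sustainable for exactly one second and the endurance exponent
#' `e` in (0, 1) governs how quickly the curve decays (smaller `e`, faster
#' decay). Riegel's fatigue factor F = 1/E > 1 is exposed as a derived view
#' via [fatigue_factor()]; E is the single canonical stored form.
#'
#' @param s One-second power in J/s (velocity in m/s in velocity mode);
#'   must be > 0.
#' @param e Endurance exponent, strictly inside (0, 1).
#' @inheritParams hyperbolic_params
#' @return An object of class `c("powerlaw_params", "pd_params")`.
#' @examples
#' powerlaw_params(s = 9.57, e = 0.94, mode = "velocity")
#' fatigue_factor(powerlaw_params(s = 9.57, e = 0.94))
#' @export
powerlaw_params <- function(s, e, mode = c("power", "velocity")) {
  mode <- match.arg(mode)
  check_positive_scalar(s, "s")
  if (!is.numeric(e) || length(e) != 1L || !is.finite(e) || e <= 0 || e >= 1) {
    abort_domain("`e` must be a single number strictly inside (0, 1).")
  }
  structure(
    list(s = as.numeric(s), e = as.numeric(e), mode = mode),
    class = c("powerlaw_params", "pd_params")
  )
}

#' @export
print.hyperbolic_params <- function(x, ...) {
  units <- if (x$mode == "velocity") c("m/s", "m") else c("J/s", "J")
  lab <- if (x$mode == "velocity") c("CV", "D'") else c("CP", "W'")
  cat(sprintf("Hyperbolic power-duration model: %s = %g %s, %s = %g %s\n",
              lab[1], x$cp, units[1], lab[2], x$w_prime, units[2]))
  invisible(x)
}

#' @export
print.powerlaw_params <- function(x, ...) {
  units <- if (x$mode == "velocity") "m/s" else "J/s"
  cat(sprintf("Power-law power-duration model: S = %g %s, E = %g (F = %g)\n",
              x$s, units, x$e, 1 / x$e))
  invisible(x)
}

#' Riegel fatigue factor F = 1/E
#'
#' @param model A [powerlaw_params()] object.
#' @return The fatigue factor, a number > 1.
#' @export
fatigue_factor <- function(model) {
  stopifnot(inherits(model, "powerlaw_params"))
  1 / model$e
}

#' Maximal sustainable power for a given duration
#'
#' Evaluates the model's power-duration curve P(T). Hyperbolic:
#' P = W'/T + CP, strictly decreasing towards CP. Power law: P = S*T^(E-1),
#' strictly decreasing towards 0, with P(1) = S exactly.
#'
#' @param model A `pd_params` object.
#' @param t Duration(s) in seconds, all > 0. Vectorised.
#' @return Power (or velocity) at each duration.
#' @examples
#' kip <- powerlaw_params(9.57, 0.94, mode = "velocity")
#' pd_power(kip, c(1, 10, 791))
#' @export
pd_power <- function(model, t) UseMethod("pd_power")

#' @export
pd_power.hyperbolic_params <- function(model, t) {
  check_positive_vector(t, "t")
  model$w_prime / t + model$cp
}

#' @export
pd_power.powerlaw_params <- function(model, t) {
  check_positive_vector(t, "t")
  model$s * t^(model$e - 1)
}

#' Time to exhaustion at a constant power
#'
#' Exact closed-form inverse of [pd_power()]. Hyperbolic: T = W'/(P - CP),
#' defined only for P > CP -- at or below CP the model predicts no exhaustion
#' ever, which is signalled as a distinct, inspectable condition of class
#' `endurofit_error_no_exhaustion` rather than returned as an infinity, so
#' that downstream pacing code can tell "never exhausts" from overflow.
#' Power law: T = (S/P)^(1/(1-E)), defined for any P > 0.
#'
#' @inheritParams pd_power
#' @param p Constant power (velocity), vectorised.
#' @return Duration(s) in seconds.
#' @examples
#' pd_tte(hyperbolic_params(400, 25500), 407)   # 3642.857 s
#' @export
pd_tte <- function(model, p) UseMethod("pd_tte")

#' @export
pd_tte.hyperbolic_params <- function(model, p) {
  check_positive_vector(p, "p")
  if (any(p <= model$cp)) {
    rlang::abort(
      sprintf(
        "Power %s does not exceed CP = %g: the hyperbolic model predicts no exhaustion at this intensity.",
        format(min(p)), model$cp
      ),
      class = "endurofit_error_no_exhaustion"
    )
  }
  model$w_prime / (p - model$cp)
}

#' @export
pd_tte.powerlaw_params <- function(model, p) {
  check_positive_vector(p, "p")
  (model$s / p)^(1 / (1 - model$e))
}

#' Maximal work achievable over a given duration
#'
#' The work-duration view of each model. Hyperbolic: W(T) = W' + CP*T, an
#' affine line whose intercept W' > 0 as T -> 0+ is the model's "teleport"
#' artefact (a rested athlete can cover D' metres instantaneously). Power
#' law: W(T) = S*T^E, which has zero intercept.
#'
#' @inheritParams pd_power
#' @return Work in J (distance in m), vectorised over `t`.
#' @export
pd_work <- function(model, t) UseMethod("pd_work")

#' @export
pd_work.hyperbolic_params <- function(model, t) {
  check_positive_vector(t, "t")
  model$w_prime + model$cp * t
}

#' @export
pd_work.powerlaw_params <- function(model, t) {
  check_positive_vector(t, "t")
  model$s * t^model$e
}

#' Fastest time over a fixed amount of work (distance)
#'
#' Inverse of [pd_work()]: the best finish time for a race of a given length
#' when paced optimally (evenly; see [even_pace()]). Hyperbolic:
#' T = (W - W')/CP, defined only for W > W' (any shorter "race" is
#' instantaneous under the model). Power law: T = (W/S)^(1/E) for any W > 0.
#'
#' @inheritParams pd_power
#' @param w Work in J (distance in m), all > 0. Vectorised.
#' @return Duration(s) in seconds.
#' @examples
#' pd_time_for_work(powerlaw_params(9.57, 0.94, "velocity"), 42195)  # ~7541 s
#' @export
pd_time_for_work <- function(model, w) UseMethod("pd_time_for_work")

#' @export
pd_time_for_work.hyperbolic_params <- function(model, w) {
  check_positive_vector(w, "w")
  if (any(w <= model$w_prime)) {
    abort_domain(sprintf(
      "Work must exceed W' = %g: below it the hyperbolic model completes any amount of work instantaneously.",
      model$w_prime
    ))
  }
  (w - model$w_prime) / model$cp
}

#' @export
pd_time_for_work.powerlaw_params <- function(model, w) {
  check_positive_vector(w, "w")
  (w / model$s)^(1 / model$e)
}
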