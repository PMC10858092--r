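#' Even-pacing finish time over a fixed amount of work
#'
#' The constant-power strategy: hold the unique power P such that
#' exhaustion coincides with completing work W, finishing in T = W/P.
#' Power law: T = (W/S)^(1/E). Hyperbolic: T = (W - W')/CP, which requires
#' W > W' -- below W' the model completes the work instantaneously and no
#' even pace exists.
#'
#' @param total_work Work in J (distance in m), > 0.
#' @param model A `pd_params` object.
#' @return List with `time` (s) and `power` (J/s or m/s).
#' @examples
#' even_pace(5000, powerlaw_params(9.57, 0.94, "velocity"))  # ~779 s at 6.42 m/s
#' @export
even_pace <- function(total_work, model) {
  check_positive_scalar(total_work, "total_work")
  t <- pd_time_for_work(model, total_work)  # hyperbolic errors if W <= W'
  list(time = t, power = total_work / t)
}

#' Two-phase pacing plan
#'
#' Phase 1: hold power `p1` until work `w1` is done (duration t1 = w1/p1).
#' Phase 2: hold the highest power p2 that makes exhaustion coincide with
#' completing the remaining work w2 = total_work - w1.
#'
#' @param total_work Total work (distance), > 0.
#' @param w1 Work done in phase 1; 0 < w1 < total_work.
#' @param p1 Phase-1 power (velocity), > 0.
#' @return A list of class `two_phase_plan`.
#' @export
two_phase_plan <- function(total_work, w1, p1) {
  check_positive_scalar(total_work, "total_work")
  check_positive_scalar(w1, "w1")
  check_positive_scalar(p1, "p1")
  if (w1 >= total_work) abort_domain("`w1` must be strictly less than `total_work`.")
  structure(list(total_work = total_work, w1 = w1, p1 = p1),
            class = "two_phase_plan")
}

#' Finish time of a two-phase pacing plan
#'
#' Closed-form evaluation of the two-phase strategy under either model,
#' with the outcome reported as a structured result rather than an error
#' so that whole pacing curves (including infeasible paces) can be
#' tabulated:
#'
#' * `status = "ok"` -- finish time, phase powers/durations and the penalty
#'   relative to even pacing;
#' * `status = "dnf_phase1"` -- the athlete exhausts before completing the
#'   phase-1 work (over-pacing DNF); the exhaustion time and the work
#'   completed at that point are reported;
#' * `status = "degenerate_underpacing"` (hyperbolic only) -- so much
#'   capacity remains at the start of phase 2 (w2 <= remaining W') that the
#'   model says the remaining work takes no time at any finite power: the
#'   finish time is then t1 + 0, flagged separately because no finite
#'   phase-2 power attains it.
#'
#' Under the hyperbolic model a phase-1 power below CP consumes no
#' capacity (recovery is not modelled, so balance simply stays full); this
#' is what makes starting slower than CP strictly costly, while any
#' start at or above CP finishes in exactly the even-pace time.
#'
#' @param plan A [two_phase_plan()].
#' @param model A `pd_params` object.
#' @return A list of class `pacing_result` with elements `status`,
#'   `finish_time`, `t1`, `p1`, `t2`, `p2`, `penalty`, `even_time`, and for
#'   DNFs `exhaustion_time` and `work_at_exhaustion`.
#' @examples
#' kip <- powerlaw_params(9.57, 0.94, mode = "velocity")
#' two_phase_finish_time(two_phase_plan(5000, 1000, 7.0), kip)  # ~819 s
#' @export
two_phase_finish_time <- function(plan, model) UseMethod("two_phase_finish_time", model)

#' @export
two_phase_finish_time.powerlaw_params <- function(plan, model) {
  stopifnot(inherits(plan, "two_phase_plan"))
  w2 <- plan$total_work - plan$w1
  t1 <- plan$w1 / plan$p1
  even <- even_pace(plan$total_work, model)
  fat1 <- t1 * exertion_rate(model, plan$p1)
  if (fat1 >= 1) {
    t_exh <- 1 / exertion_rate(model, plan$p1)
    return(pacing_result("dnf_phase1", even,
                         t1 = t1, p1 = plan$p1,
                         exhaustion_time = t_exh,
                         work_at_exhaustion = t_exh * plan$p1))
  }
  balance <- 1 - fat1
  inv <- 1 / (1 - model$e)
  # p2 solves (w2/p2) * (p2/S)^inv = balance
  log_p2 <- (log(balance) + inv * log(model$s) - log(w2)) * (1 - model$e) / model$e
  p2 <- exp(log_p2)
  t2 <- w2 / p2
  pacing_result("ok", even, t1 = t1, p1 = plan$p1, t2 = t2, p2 = p2)
}

#' @export
two_phase_finish_time.hyperbolic_params <- function(plan, model) {
  stopifnot(inherits(plan, "two_phase_plan"))
  w2 <- plan$total_work - plan$w1
  t1 <- plan$w1 / plan$p1
  even <- even_pace(plan$total_work, model)  # errors if total_work <= W'
  # Below CP nothing is consumed (no recovery model: balance stays full)
  depletion <- if (plan$p1 >= model$cp) t1 * (plan$p1 - model$cp) else 0
  if (depletion >= model$w_prime) {
    t_exh <- model$w_prime / (plan$p1 - model$cp)
    return(pacing_result("dnf_phase1", even,
                         t1 = t1, p1 = plan$p1,
                         exhaustion_time = t_exh,
                         work_at_exhaustion = t_exh * plan$p1))
  }
  r <- model$w_prime - depletion  # residual capacity entering phase 2
  if (w2 <= r) {
    return(pacing_result("degenerate_underpacing", even,
                         t1 = t1, p1 = plan$p1, t2 = 0, p2 = Inf))
  }
  t2 <- (w2 - r) / model$cp
  p2 <- w2 / t2
  pacing_result("ok", even, t1 = t1, p1 = plan$p1, t2 = t2, p2 = p2)
}

pacing_result <- function(status, even, t1, p1, t2 = NA_real_, p2 = NA_real_,
                          exhaustion_time = NA_real_,
                          work_at_exhaustion = NA_real_) {
  finish <- if (status %in% c("ok", "degenerate_underpacing")) t1 + t2 else NA_real_
  structure(
    list(
      status = status,
      finish_time = finish,
      t1 = t1, p1 = p1, t2 = t2, p2 = p2,
      even_time = even$time, even_power = even$power,
      penalty = finish - even$time,
      exhaustion_time = exhaustion_time,
      work_at_exhaustion = work_at_exhaustion
    ),
    class = "pacing_result"
  )
}

#' @export
print.pacing_result <- function(x, ...) {
  cat(sprintf("Two-phase pacing [%s]: ", x$status))
  if (x$status == "ok") {
    cat(sprintf("finish %.4f s (even %.4f s, penalty %+.4f s)\n",
                x$finish_time, x$even_time, x$penalty))
    cat(sprintf("  phase 1: %.4g @ %.4g; phase 2: %.4g s @ %.4g\n",
                x$t1, x$p1, x$t2, x$p2))
  } else if (x$status == "dnf_phase1") {
    cat(sprintf("exhausted at %.4f s with %.4g work done\n",
                x$exhaustion_time, x$work_at_exhaustion))
  } else {
    cat(sprintf("phase-2 work within residual capacity; finish %.4f s at unbounded phase-2 power\n",
                x$finish_time))
  }
  invisible(x)
}

#' Pacing curve: finish time as a function of the phase-1 intensity
#'
#' Evaluates [two_phase_finish_time()] over a grid of phase-1 powers, the
#' numerical analogue of the classic "what if the first kilometre is run at
#' velocity v" figure. Under the power law the curve is U-shaped with its
#' minimum exactly at the even pace; under the hyperbolic model it is flat
#' at the even time for p1 >= CP and increases below CP.
#'
#' @param total_work Total work (distance), > 0.
#' @param model A `pd_params` object.
#' @param p1_grid Phase-1 powers to evaluate (non-empty).
#' @param w1 Phase-1 work, 0 < w1 < total_work.
#' @return Tibble `(p1, finish_time, status, penalty)`; infeasible points
#'   carry `NA` finish time and their status label.
#' @export
pacing_curve <- function(total_work, model, p1_grid, w1) {
  check_positive_vector(p1_grid, "p1_grid")
  rows <- lapply(p1_grid, function(p1) {
    res <- two_phase_finish_time(two_phase_plan(total_work, w1, p1), model)
    tibble::tibble(p1 = p1, finish_time = res$finish_time,
                   status = res$status, penalty = res$penalty)
  })
  dplyr::bind_rows(rows)
}
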