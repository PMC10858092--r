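#' Fit the hyperbolic (critical-power) model by linear regression
#'
#' Exploits the fact that under the hyperbolic model the mean intensity is
#' affine-linear in reciprocal duration: P = CP + W'/T. Ordinary least
#' squares of intensity on 1/T gives CP (CV) as the intercept and W' (D')
#' as the slope. Only efforts whose duration lies inside the validity
#' window are used -- the model is conventionally trusted for efforts of
#' roughly 2-15 minutes -- and window boundaries are inclusive.
#'
#' If two efforts share a duration, only the higher-intensity one is kept
#' before fitting (both cannot be maximal).
#'
#' @param x An effort tibble ([efforts()]).
#' @param window Closed duration window in seconds, default `c(120, 900)`.
#'   Use `c(0, Inf)` to fit on everything.
#' @param min_points Minimum number of in-window efforts required (>= 2).
#' @return A `pd_fit` object: list with `params` ([hyperbolic_params()]),
#'   `n_used`, `residuals` (tibble of per-effort relative residuals on the
#'   intensity scale) and `transform = "reciprocal_duration"`.
#' @examples
#' fit_hyperbolic(kipchoge_prs())$params   # CV ~ 6.23 m/s, D' ~ 176 m
#' @export
fit_hyperbolic <- function(x, window = c(120, 900), min_points = 2L) {
  x <- dedupe_durations(x)
  inw <- x$duration >= window[1] & x$duration <= window[2]
  used <- x[inw, , drop = FALSE]
  if (nrow(used) < max(2L, min_points)) {
    rlang::abort(
      sprintf("Need at least %d efforts with durations in [%g, %g] s; got %d.",
              max(2L, min_points), window[1], window[2], nrow(used)),
      class = "endurofit_error_insufficient_data"
    )
  }
  fit <- stats::lm(intensity ~ I(1 / duration), data = used)
  cp <- unname(stats::coef(fit)[1])
  w_prime <- unname(stats::coef(fit)[2])
  if (!is.finite(cp) || !is.finite(w_prime) || cp <= 0 || w_prime <= 0) {
    rlang::abort(
      sprintf("Hyperbolic fit produced invalid parameters (CP = %g, W' = %g).",
              cp, w_prime),
      class = "endurofit_error_invalid_fit",
      cp = cp, w_prime = w_prime
    )
  }
  mode <- if (all(used$kind == "power")) "power" else "velocity"
  params <- hyperbolic_params(cp, w_prime, mode = mode)
  new_pd_fit(params, used, transform = "reciprocal_duration")
}

#' Fit the power-law (Riegel) model by log-log regression
#'
#' Under the power law, log intensity is affine-linear in log duration:
#' log P = log S + (E - 1) log T. OLS on the log-log scale gives
#' S = exp(intercept) and E = slope + 1. Unlike the hyperbolic model the
#' power law is not restricted to a duration window, so by default all
#' efforts are used.
#'
#' @inheritParams fit_hyperbolic
#' @return A `pd_fit` object with `params` a [powerlaw_params()] and
#'   `transform = "log_log"`.
#' @examples
#' fit_powerlaw(kipchoge_prs())$params   # S ~ 9.57 m/s, E ~ 0.94
#' @export
fit_powerlaw <- function(x, min_points = 2L) {
  used <- dedupe_durations(x)
  if (nrow(used) < max(2L, min_points)) {
    rlang::abort(
      sprintf("Need at least %d efforts with distinct durations; got %d.",
              max(2L, min_points), nrow(used)),
      class = "endurofit_error_insufficient_data"
    )
  }
  fit <- stats::lm(log(intensity) ~ log(duration), data = used)
  s <- exp(unname(stats::coef(fit)[1]))
  e <- unname(stats::coef(fit)[2]) + 1
  if (!is.finite(s) || !is.finite(e) || s <= 0 || e <= 0 || e >= 1) {
    rlang::abort(
      sprintf("Power-law fit produced invalid parameters (S = %g, E = %g).", s, e),
      class = "endurofit_error_invalid_fit",
      s = s, e = e
    )
  }
  mode <- if (all(used$kind == "power")) "power" else "velocity"
  params <- powerlaw_params(s, e, mode = mode)
  new_pd_fit(params, used, transform = "log_log")
}

new_pd_fit <- function(params, used, transform) {
  pred <- pd_power(params, used$duration)
  structure(
    list(
      params = params,
      n_used = nrow(used),
      residuals = tibble::tibble(
        duration = used$duration,
        observed = used$intensity,
        fitted = pred,
        rel_residual = (used$intensity - pred) / used$intensity
      ),
      transform = transform
    ),
    class = "pd_fit"
  )
}

#' @export
print.pd_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  fitted to %d efforts (%s transform); max |rel. residual| = %.3g\n",
              x$n_used, x$transform, max(abs(x$residuals$rel_residual))))
  invisible(x)
}

# Keep the better (higher-intensity) of any efforts tied on duration:
# two efforts over the same duration cannot both be maximal.
dedupe_durations <- function(x) {
  stopifnot(is.data.frame(x), all(c("duration", "intensity") %in% names(x)))
  x <- dplyr::arrange(x, .data$duration, dplyr::desc(.data$intensity))
  x[!duplicated(x$duration), , drop = FALSE]
}

#' Fixed-fatigue-factor race-time calibrator
#'
#' The popular single-race predictor T = T0 * (D/D0)^f: given one previous
#' race (distance `d0`, finish time `t0`) it predicts the finish time over
#' `d` by fixing the fatigue factor (Riegel exponent) at `f` -- i.e. a
#' power-law model in which only the speed parameter S is estimated (from
#' the single race) and E = 1/f is held fixed. The magazine-calculator
#' default is f = 1.06.
#'
#' @param t0 Finish time of the reference race, s.
#' @param d0 Distance of the reference race, m.
#' @param d Target distance(s), m. Vectorised.
#' @param f Fatigue factor, > 0 (1.06 by default; f = 1 gives proportional
#'   scaling).
#' @return Predicted finish time(s) in seconds.
#' @examples
#' calibrate_fixed_f(t0 = 3565, d0 = 21097.5, d = 42195)  # ~7433 s marathon
#' @export
calibrate_fixed_f <- function(t0, d0, d, f = 1.06) {
  check_positive_scalar(t0, "t0")
  check_positive_scalar(d0, "d0")
  check_positive_vector(d, "d")
  check_positive_scalar(f, "f")
  t0 * (d / d0)^f
}

#' Dataset filtering rules
#'
#' Configurable screens applied before large-scale fitting, mirroring the
#' usual hygiene applied to self-reported or training-derived effort data:
#' (a) drop athletes with too few efforts in the validity window; (b)
#' enforce maximality -- the mean-maximal curve must be non-increasing, so
#' any effort whose mean intensity does not exceed that of every strictly
#' longer effort cannot have been maximal and is dropped; (c) drop outliers
#' whose log-residual from a preliminary power-law fit exceeds a multiple
#' of the median absolute deviation (power-meter spikes and similar). The
#' preliminary fit in (c) is a Theil-Sen line on the log-log scale so that
#' the spikes being screened cannot themselves drag the reference line.
#'
#' @param min_in_window Minimum number of in-window efforts per athlete
#'   (NULL disables the rule).
#' @param window Duration window in seconds used by rule (a).
#' @param enforce_maximality Apply rule (b)?
#' @param mad_multiplier Rule (c) threshold; NULL disables the rule.
#' @return A list of class `filter_rules`.
#' @export
filter_rules <- function(min_in_window = 3L, window = c(120, 1200),
                         enforce_maximality = TRUE, mad_multiplier = 5) {
  structure(
    list(min_in_window = min_in_window, window = window,
         enforce_maximality = enforce_maximality,
         mad_multiplier = mad_multiplier),
    class = "filter_rules"
  )
}

#' Filter an effort dataset and report exclusions
#'
#' Applies [filter_rules()] per athlete. Rules that would exclude every
#' effort yield an empty retained table plus the report -- never an error.
#'
#' @param x An effort tibble, possibly with several athletes.
#' @param rules A [filter_rules()] object.
#' @return List with `retained` (effort tibble), `excluded` (the dropped
#'   rows with a `rule` label), and `report` (per-rule exclusion counts,
#'   including athletes dropped wholesale by the minimum-count rule).
#' @export
filter_dataset <- function(x, rules = filter_rules()) {
  if (!is.data.frame(x) || nrow(x) == 0L) {
    abort_domain("`x` must be a non-empty effort table.")
  }
  excluded <- x[0, , drop = FALSE]
  excluded$rule <- character(0)

  drop_rows <- function(rows, rule) {
    if (nrow(rows) == 0L) return()
    rows$rule <- rule
    excluded <<- dplyr::bind_rows(excluded, rows)
  }

  # (b) maximality: an effort is kept only if its intensity is above that of
  # every strictly longer effort by the same athlete
  if (isTRUE(rules$enforce_maximality)) {
    keep <- unlist(lapply(split(seq_len(nrow(x)), x$athlete_id), function(idx) {
      d <- x$duration[idx]; v <- x$intensity[idx]
      ok <- vapply(seq_along(idx), function(i) {
        longer <- d > d[i]
        !any(longer & v >= v[i])
      }, logical(1))
      idx[ok]
    }), use.names = FALSE)
    dropped <- setdiff(seq_len(nrow(x)), sort(keep))
    drop_rows(x[dropped, , drop = FALSE], "non_maximal")
    x <- x[sort(keep), , drop = FALSE]
  }

  # (c) outliers against a preliminary power-law fit, per athlete
  if (!is.null(rules$mad_multiplier) && nrow(x) > 0L) {
    keep <- unlist(lapply(split(seq_len(nrow(x)), x$athlete_id), function(idx) {
      if (length(idx) < 3L) return(idx)
      lt <- log(x$duration[idx]); lv <- log(x$intensity[idx])
      # Theil-Sen preliminary power-law line: robust to the spikes themselves
      pairs <- utils::combn(length(idx), 2)
      slopes <- (lv[pairs[2, ]] - lv[pairs[1, ]]) / (lt[pairs[2, ]] - lt[pairs[1, ]])
      b <- stats::median(slopes, na.rm = TRUE)
      a <- stats::median(lv - b * lt)
      r <- lv - (a + b * lt)
      m <- stats::mad(r)
      if (m == 0) return(idx)
      idx[abs(r) <= rules$mad_multiplier * m]
    }), use.names = FALSE)
    dropped <- setdiff(seq_len(nrow(x)), sort(keep))
    drop_rows(x[dropped, , drop = FALSE], "outlier")
    x <- x[sort(keep), , drop = FALSE]
  }

  # (a) minimum in-window effort count per athlete
  athletes_dropped <- character(0)
  if (!is.null(rules$min_in_window) && nrow(x) > 0L) {
    inw <- x$duration >= rules$window[1] & x$duration <= rules$window[2]
    counts <- tapply(inw, x$athlete_id, sum)
    bad <- names(counts)[counts < rules$min_in_window]
    athletes_dropped <- bad
    drop_rows(x[x$athlete_id %in% bad, , drop = FALSE], "too_few_in_window")
    x <- x[!x$athlete_id %in% bad, , drop = FALSE]
  }

  report <- table(factor(excluded$rule,
                         levels = c("non_maximal", "outlier", "too_few_in_window")))
  list(
    retained = x,
    excluded = excluded,
    report = list(
      efforts_excluded = as.list(report),
      athletes_excluded = athletes_dropped
    )
  )
}
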