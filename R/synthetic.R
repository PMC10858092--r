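#' Specification of a synthetic athlete population
#'
#' Describes the statistical structure of a simulated cohort of athletes:
#' per-athlete ground-truth power-duration parameters drawn from stated
#' distributions, a menu of maximal efforts (race distances and/or fixed
#' durations), multiplicative log-normal observation noise on the recorded
#' time, and optional contamination (power-meter-style intensity spikes or
#' non-maximal efforts) for exercising the filtering rules.
#'
#' Defaults emulate a cohort of club-level runners: one-second speed
#' S ~ lognormal(log 8.5, 0.08) m/s, endurance exponent E ~ U(0.88, 0.96)
#' (a bracket that contains both the elite case-study estimate 0.94 and the
#' classic road-running fatigue factor F = 1.06, i.e. E = 0.943), racing
#' the standard distance menu, with sigma = 0.02 multiplicative time noise
#' (roughly a 1-2 min spread on a marathon).
#'
#' @param n_athletes Number of athletes, >= 1.
#' @param truth_model `"power_law"` or `"hyperbolic"`.
#' @param s_meanlog,s_sdlog Log-scale location/spread of S (power law) in
#'   m/s or J/s.
#' @param e_range Range of the uniform draw for E; must lie inside (0, 1).
#' @param cv_meanlog,cv_sdlog Log-scale location/spread of CP (CV) for
#'   hyperbolic truth.
#' @param d_prime_range Range of the uniform draw for W' (D').
#' @param distances Race distances (m) in the effort menu; NULL for none.
#' @param durations Fixed-duration efforts (s) in the menu; NULL for none.
#' @param noise_sigma SD of the log-normal multiplicative noise on the
#'   recorded time, >= 0.
#' @param contamination Fraction of efforts contaminated, in [0, 1).
#' @param contamination_type `"spike"` (intensity multiplied by 10, the
#'   power-meter malfunction) or `"non_maximal"` (time inflated by a
#'   U(1.10, 1.40) factor).
#' @param mode `"velocity"` or `"power"` unit label.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n_athletes = 200L,
                            truth_model = c("power_law", "hyperbolic"),
                            s_meanlog = log(8.5), s_sdlog = 0.08,
                            e_range = c(0.88, 0.96),
                            cv_meanlog = log(4.3), cv_sdlog = 0.08,
                            d_prime_range = c(100, 250),
                            distances = runner_distances(),
                            durations = NULL,
                            noise_sigma = 0.02,
                            contamination = 0,
                            contamination_type = c("spike", "non_maximal"),
                            mode = c("velocity", "power"),
                            seed = 1L) {
  truth_model <- match.arg(truth_model)
  contamination_type <- match.arg(contamination_type)
  mode <- match.arg(mode)
  problems <- character(0)
  if (!is.numeric(n_athletes) || n_athletes < 1) problems <- c(problems, "n_athletes")
  if (!is.numeric(noise_sigma) || noise_sigma < 0) problems <- c(problems, "noise_sigma")
  if (!is.numeric(contamination) || contamination < 0 || contamination >= 1) {
    problems <- c(problems, "contamination")
  }
  if (e_range[1] <= 0 || e_range[2] >= 1 || e_range[1] > e_range[2]) {
    problems <- c(problems, "e_range")
  }
  if (is.null(distances) && is.null(durations)) problems <- c(problems, "distances/durations")
  if (length(problems) > 0L) {
    rlang::abort(
      sprintf("Invalid population spec field(s): %s", paste(problems, collapse = ", ")),
      class = "endurofit_error_spec"
    )
  }
  structure(
    list(n_athletes = as.integer(n_athletes), truth_model = truth_model,
         s_meanlog = s_meanlog, s_sdlog = s_sdlog, e_range = e_range,
         cv_meanlog = cv_meanlog, cv_sdlog = cv_sdlog,
         d_prime_range = d_prime_range,
         distances = distances, durations = durations,
         noise_sigma = noise_sigma, contamination = contamination,
         contamination_type = contamination_type, mode = mode,
         seed = as.integer(seed)),
    class = "population_spec"
  )
}

#' Standard effort menus
#'
#' `runner_distances()`: the common track/road race distances from 800 m to
#' the marathon. `rower_distances()` / `rower_durations()`: the
#' rowing-ergometer seasons-best menu -- fixed distances plus the 30- and
#' 60-minute fixed-duration efforts.
#'
#' @return Numeric vector of metres (or seconds for durations).
#' @export
runner_distances <- function() c(800, 1500, 3000, 5000, 10000, 21097.5, 42195)

#' @rdname runner_distances
#' @export
rower_distances <- function() c(500, 1000, 5000, 6000, 10000, 21097.5, 42195)

#' @rdname runner_distances
#' @export
rower_durations <- function() c(1800, 3600)

#' Noiseless model-implied efforts over a menu
#'
#' The exact kernel used by [generate_population()] and by oracle tests:
#' for each distance, the model-implied finish time ([pd_time_for_work()]);
#' for each fixed duration, the model-implied work ([pd_work()]).
#'
#' @param params A `pd_params` object.
#' @param distances Race distances in m (work in J), or NULL.
#' @param durations Fixed durations in s, or NULL.
#' @param athlete_id Identifier for the resulting rows.
#' @return An effort tibble ([efforts()]).
#' @export
generate_effort_grid <- function(params, distances = NULL, durations = NULL,
                                 athlete_id = "athlete") {
  if (is.null(distances) && is.null(durations)) {
    abort_domain("Provide at least one of `distances`, `durations`.")
  }
  kind <- if (params$mode == "power") "power" else "distance"
  dur <- work <- numeric(0)
  if (!is.null(distances)) {
    check_positive_vector(distances, "distances")
    dur <- c(dur, pd_time_for_work(params, distances))
    work <- c(work, distances)
  }
  if (!is.null(durations)) {
    check_positive_vector(durations, "durations")
    dur <- c(dur, durations)
    work <- c(work, pd_work(params, durations))
  }
  efforts(duration = dur, work = work, athlete_id = athlete_id, kind = kind)
}

draw_truth <- function(spec, ids) {
  n <- length(ids)
  if (spec$truth_model == "power_law") {
    tibble::tibble(
      athlete_id = ids,
      s = stats::rlnorm(n, spec$s_meanlog, spec$s_sdlog),
      e = stats::runif(n, spec$e_range[1], spec$e_range[2])
    )
  } else {
    tibble::tibble(
      athlete_id = ids,
      cp = stats::rlnorm(n, spec$cv_meanlog, spec$cv_sdlog),
      w_prime = stats::runif(n, spec$d_prime_range[1], spec$d_prime_range[2])
    )
  }
}

truth_params <- function(spec, truth_row) {
  if (spec$truth_model == "power_law") {
    powerlaw_params(truth_row$s, truth_row$e, mode = spec$mode)
  } else {
    hyperbolic_params(truth_row$cp, truth_row$w_prime, mode = spec$mode)
  }
}

#' Generate a synthetic athlete population
#'
#' For each athlete: draws ground-truth parameters from the distributions
#' in the spec, computes the exact model-implied effort over each menu
#' entry, multiplies the recorded time by exp(sigma * z) with z standard
#' normal (work is kept fixed, so intensity wobbles accordingly), and then
#' contaminates the configured fraction of rows. Fully reproducible from
#' `spec$seed`; the global RNG state is left untouched.
#'
#' @param spec A [population_spec()].
#' @return List with `efforts` (tibble in the [efforts()] layout plus a
#'   `contaminated` flag), `truth` (per-athlete ground-truth parameters)
#'   and `spec`.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  withr::with_seed(spec$seed, {
    ids <- sprintf("athlete_%03d", seq_len(spec$n_athletes))
    truth <- draw_truth(spec, ids)
    rows <- lapply(seq_len(spec$n_athletes), function(i) {
      gen <- generate_effort_grid(truth_params(spec, truth[i, ]),
                                  distances = spec$distances,
                                  durations = spec$durations,
                                  athlete_id = ids[i])
      gen$duration <- gen$duration *
        exp(stats::rnorm(nrow(gen), 0, spec$noise_sigma))
      gen$contaminated <- FALSE
      if (spec$contamination > 0) {
        hit <- stats::runif(nrow(gen)) < spec$contamination
        if (spec$contamination_type == "spike") {
          gen$work[hit] <- gen$work[hit] * 10
        } else {
          gen$duration[hit] <- gen$duration[hit] * stats::runif(sum(hit), 1.10, 1.40)
        }
        gen$contaminated <- hit
      }
      gen$intensity <- gen$work / gen$duration
      gen
    })
    list(efforts = dplyr::bind_rows(rows), truth = truth, spec = spec)
  })
}

#' Elite-runner personal-record fixtures
#'
#' Career personal records (World Athletics) of two elite marathon
#' runners, as effort tables in velocity/distance units. These are the
#' in-package case-study datasets: the hyperbolic model fitted to the
#' records with finish times of 2-15 minutes gives CV of about 6.23 m/s
#' and D' of about 176 m for Kipchoge, and the power law fitted to all
#' records up to the marathon gives S of about 9.57 m/s and E of about
#' 0.94. Road-race times are in whole seconds (13:11 for 5 km road,
#' 59:25 half marathon, 2:01:39 marathon; 12:39 / 58:55 / 2:03:59 for
#' Gebrselassie); track times keep their official hundredths.
#'
#' @return An effort tibble with an `event` column.
#' @examples
#' fit_powerlaw(kipchoge_prs())$params
#' @export
kipchoge_prs <- function() {
  pr <- tibble::tribble(
    ~event,          ~distance, ~time,
    "1500m",          1500,     "3:33.20",
    "mile",           1609.344, "3:50.40",
    "3000m",          3000,     "7:27.66",
    "5000m",          5000,     "12:46.53",
    "5km_road",       5000,     "13:11",
    "10km_road",      10000,    "28:11",
    "half_marathon",  21097.5,  "59:25",
    "marathon",       42195,    "2:01:39"
  )
  out <- efforts(duration = parse_hms(pr$time), work = pr$distance,
                 athlete_id = "kipchoge", kind = "distance")
  out$event <- pr$event
  out
}

#' @rdname kipchoge_prs
#' @export
gebrselassie_prs <- function() {
  pr <- tibble::tribble(
    ~event,          ~distance, ~time,
    "1500m",          1500,     "3:33.73",
    "mile",           1609.344, "3:52.39",
    "2000m",          2000,     "4:52.86",
    "3000m",          3000,     "7:25.09",
    "two_miles",      3218.688, "8:01.08",
    "5000m",          5000,     "12:39",
    "10000m",         10000,    "26:22.75",
    "10km_road",      10000,    "27:02",
    "half_marathon",  21097.5,  "58:55",
    "marathon",       42195,    "2:03:59"
  )
  out <- efforts(duration = parse_hms(pr$time), work = pr$distance,
                 athlete_id = "gebrselassie", kind = "distance")
  out$event <- pr$event
  out
}
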