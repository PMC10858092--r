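#' Per-effort relative prediction error
#'
#' The comparison statistic used throughout the model-comparison analyses:
#' the relative difference between the model-predicted and observed mean
#' intensity at each observed duration, (v_pred - v_obs)/v_obs. Signed by
#' default; set `absolute = TRUE` for |error|.
#'
#' @param x An effort tibble ([efforts()]).
#' @param params A `pd_params` object.
#' @param absolute Return absolute errors?
#' @return Numeric vector, one value per effort.
#' @export
relative_error <- function(x, params, absolute = FALSE) {
  stopifnot(is.data.frame(x), all(c("duration", "intensity") %in% names(x)))
  check_positive_vector(x$intensity, "intensity")
  err <- (pd_power(params, x$duration) - x$intensity) / x$intensity
  if (absolute) abs(err) else err
}

#' Default duration bins for model comparison
#'
#' Half-open bins `[lo, hi)` in seconds with edges at 0.5, 1, 2, 15, 20,
#' 45, 90 and 360 minutes -- fine around the 2-15 min validity window of
#' the hyperbolic model, coarser far outside it.
#'
#' @return Numeric vector of bin edges in seconds.
#' @export
default_duration_bins <- function() {
  c(0.5, 1, 2, 15, 20, 45, 90, 360) * 60
}

fit_both_models <- function(x, window) {
  hyp <- tryCatch(fit_hyperbolic(x, window = window), error = function(e) NULL)
  pow <- tryCatch(fit_powerlaw(x), error = function(e) NULL)
  if (is.null(hyp) || is.null(pow)) return(NULL)
  list(hyperbolic = hyp$params, power_law = pow$params)
}

#' Duration-binned model-comparison summary
#'
#' For every athlete, fits each model by its own protocol -- the hyperbolic
#' model on efforts inside the validity `window`, the power law on all
#' efforts -- then scores every effort with [relative_error()], averages
#' within athlete per duration bin, and finally averages across athletes
#' per bin with a standard error (SD across athletes / sqrt(n)). Athletes
#' for whom either model cannot be fitted are excluded from both models'
#' summaries, so each bin compares the two models on exactly the same
#' athletes. Empty bins are omitted; a bin containing a single athlete
#' reports `NA` standard error.
#'
#' @param population Effort tibble for one or more athletes (column
#'   `athlete_id`).
#' @param bin_edges Half-open bin edges `[lo, hi)` in seconds.
#' @param window Validity window for the hyperbolic fit, s.
#' @param absolute Average |error| (default) or signed error.
#' @return Tibble `(bin_lo, bin_hi, model, mean_error, se, n_athletes)`.
#' @export
binned_errors <- function(population, bin_edges = default_duration_bins(),
                          window = c(120, 900), absolute = TRUE) {
  per_athlete <- lapply(split(population, population$athlete_id), function(x) {
    fits <- fit_both_models(x, window)
    if (is.null(fits)) return(NULL)
    bin <- findInterval(x$duration, bin_edges, rightmost.closed = FALSE)
    ok <- bin >= 1L & bin < length(bin_edges)
    if (!any(ok)) return(NULL)
    dplyr::bind_rows(lapply(names(fits), function(m) {
      tibble::tibble(
        athlete_id = x$athlete_id[1],
        model = m,
        bin = bin[ok],
        err = relative_error(x[ok, ], fits[[m]], absolute = absolute)
      )
    }))
  })
  scores <- dplyr::bind_rows(per_athlete)
  if (nrow(scores) == 0L) {
    abort_domain("No athlete could be fitted by both models.")
  }
  scores |>
    dplyr::group_by(.data$athlete_id, .data$model, .data$bin) |>
    dplyr::summarise(err = mean(.data$err), .groups = "drop") |>
    dplyr::group_by(.data$model, .data$bin) |>
    dplyr::summarise(
      mean_error = mean(.data$err),
      se = if (dplyr::n() > 1L) stats::sd(.data$err) / sqrt(dplyr::n()) else NA_real_,
      n_athletes = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bin_lo = bin_edges[.data$bin],
      bin_hi = bin_edges[.data$bin + 1L]
    ) |>
    dplyr::select("bin_lo", "bin_hi", "model", "mean_error", "se", "n_athletes") |>
    dplyr::arrange(.data$bin_lo, .data$model)
}

#' Out-of-sample predictive comparison
#'
#' For each athlete with more than `n_train` efforts: draw `n_train`
#' efforts at random (without replacement, seeded, identical subset for
#' both models), fit each model to the training subset, and score the
#' held-out efforts with absolute [relative_error()]. Athletes for whom
#' either model cannot be fitted on the training draw -- or who have too
#' few efforts -- are excluded from both models' summaries and listed in
#' the exclusion report. Held-out errors are averaged within athlete per
#' duration bin, then across athletes.
#'
#' @inheritParams binned_errors
#' @param n_train Number of training efforts per athlete.
#' @param seed Integer seed; the resampling is bit-reproducible and leaves
#'   the global RNG state untouched.
#' @return List with `summary` -- tibble `(bin_lo, bin_hi, model,
#'   mean_abs_error, se, n_athletes)` -- and `excluded` -- tibble
#'   `(athlete_id, reason)`.
#' @export
out_of_sample <- function(population, n_train = 6L, seed = 1L,
                          bin_edges = default_duration_bins(),
                          window = c(120, 900)) {
  withr::with_seed(seed, {
    excluded <- list()
    per_athlete <- lapply(split(population, population$athlete_id), function(x) {
      id <- x$athlete_id[1]
      if (nrow(x) <= n_train) {
        excluded[[id]] <<- "too_few_efforts"
        return(NULL)
      }
      train_idx <- sample(nrow(x), n_train)
      fits <- fit_both_models(x[train_idx, ], window)
      if (is.null(fits)) {
        excluded[[id]] <<- "unfittable_training_draw"
        return(NULL)
      }
      held <- x[-train_idx, , drop = FALSE]
      bin <- findInterval(held$duration, bin_edges, rightmost.closed = FALSE)
      ok <- bin >= 1L & bin < length(bin_edges)
      if (!any(ok)) return(NULL)
      dplyr::bind_rows(lapply(names(fits), function(m) {
        tibble::tibble(
          athlete_id = id, model = m, bin = bin[ok],
          err = relative_error(held[ok, ], fits[[m]], absolute = TRUE)
        )
      }))
    })
    scores <- dplyr::bind_rows(per_athlete)
    if (nrow(scores) == 0L) abort_domain("No athlete usable for the out-of-sample protocol.")
    summary <- scores |>
      dplyr::group_by(.data$athlete_id, .data$model, .data$bin) |>
      dplyr::summarise(err = mean(.data$err), .groups = "drop") |>
      dplyr::group_by(.data$model, .data$bin) |>
      dplyr::summarise(
        mean_abs_error = mean(.data$err),
        se = if (dplyr::n() > 1L) stats::sd(.data$err) / sqrt(dplyr::n()) else NA_real_,
        n_athletes = dplyr::n(),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        bin_lo = bin_edges[.data$bin],
        bin_hi = bin_edges[.data$bin + 1L]
      ) |>
      dplyr::select("bin_lo", "bin_hi", "model", "mean_abs_error", "se", "n_athletes") |>
      dplyr::arrange(.data$bin_lo, .data$model)
    excl <- if (length(excluded) > 0L) {
      tibble::tibble(athlete_id = names(excluded),
                     reason = unlist(excluded, use.names = FALSE))
    } else {
      tibble::tibble(athlete_id = character(0), reason = character(0))
    }
    list(summary = summary, excluded = excl)
  })
}
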