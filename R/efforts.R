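#' Build a table of maximal efforts
#'
#' The atomic observation throughout the package is a maximal effort: a best
#' performance recorded either as (duration, work) -- cycling and rowing,
#' where work = mean power x duration -- or as (distance, finish time) --
#' running, where distance stands in for work and velocity for power.
#' Internally both are stored in the same SI columns.
#'
#' @param duration Positive durations in seconds.
#' @param work Positive work in J (power mode) or distance in m
#'   (velocity/distance mode).
#' @param athlete_id Optional athlete identifier(s), recycled.
#' @param kind `"power"` or `"distance"`; recorded so that CSV round trips
#'   are lossless ([write_efforts()]).
#' @return A tibble with columns `athlete_id`, `kind`, `duration`, `work`
#'   and the derived `intensity` (= work / duration: mean power in J/s or
#'   mean velocity in m/s).
#' @examples
#' efforts(duration = c(766.53, 3565), work = c(5000, 21097.5),
#'         kind = "distance")
#' @export
efforts <- function(duration, work, athlete_id = "athlete",
                    kind = c("distance", "power")) {
  kind <- match.arg(kind)
  check_positive_vector(duration, "duration")
  check_positive_vector(work, "work")
  if (length(duration) != length(work)) {
    abort_domain("`duration` and `work` must have the same length.")
  }
  tibble::tibble(
    athlete_id = rep_len(as.character(athlete_id), length(duration)),
    kind = kind,
    duration = as.numeric(duration),
    work = as.numeric(work),
    intensity = as.numeric(work) / as.numeric(duration)
  )
}

#' Parse hh:mm:ss (or mm:ss, or plain seconds) to seconds
#'
#' @param x Character or numeric vector. `"02:01:39"` -> 7299; `"13:11"` ->
#'   791; `"766.53"` -> 766.53. Fractional seconds are preserved.
#' @return Numeric seconds; `NA` for unparseable entries.
#' @export
parse_hms <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  vapply(x, function(s) {
    if (is.na(s) || s == "") return(NA_real_)
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    if (length(parts) > 3L) return(NA_real_)
    nums <- suppressWarnings(as.numeric(parts))
    if (anyNA(nums)) return(NA_real_)
    sum(nums * 60^(rev(seq_along(nums)) - 1))
  }, numeric(1), USE.NAMES = FALSE)
}

format_hms <- function(seconds) {
  h <- floor(seconds / 3600)
  m <- floor((seconds - 3600 * h) / 60)
  s <- seconds - 3600 * h - 60 * m
  sprintf("%02d:%02d:%05.2f", h, m, s)
}

#' Read / write maximal-effort tables in the effort CSV dialect
#'
#' The dialect has header `athlete_id,kind,duration_s,quantity` with
#' `kind` in `{power, distance}`. For `kind = "distance"`, `quantity` is the
#' race distance in metres and `duration_s` the finish time; for
#' `kind = "power"`, `quantity` is the mean power in J/s. `duration_s`
#' accepts hh:mm:ss and is normalised to seconds on read. Malformed rows
#' (missing columns, non-positive quantities, unparseable times) fail fast
#' with the offending line numbers.
#'
#' @param path File path.
#' @return `read_efforts()`: a tibble in the layout of [efforts()];
#'   `write_efforts()`: `path`, invisibly.
#' @export
read_efforts <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("athlete_id", "kind", "duration_s", "quantity")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    abort_domain(sprintf("Missing column(s) in effort CSV: %s",
                         paste(missing_cols, collapse = ", ")))
  }
  dur <- parse_hms(raw$duration_s)
  qty <- suppressWarnings(as.numeric(raw$quantity))
  bad_kind <- !raw$kind %in% c("power", "distance")
  bad <- is.na(dur) | is.na(qty) | dur <= 0 | qty <= 0 | bad_kind
  if (any(bad)) {
    rlang::abort(
      sprintf("Malformed effort row(s) at line(s): %s",
              paste(which(bad) + 1L, collapse = ", ")),
      class = "endurofit_error_malformed_row"
    )
  }
  work <- ifelse(raw$kind == "power", qty * dur, qty)
  tibble::tibble(
    athlete_id = raw$athlete_id,
    kind = raw$kind,
    duration = dur,
    work = work,
    intensity = work / dur
  )
}

#' @param x An effort tibble as produced by [efforts()] or [read_efforts()].
#' @rdname read_efforts
#' @export
write_efforts <- function(x, path) {
  stopifnot(is.data.frame(x), all(c("athlete_id", "kind", "duration", "work") %in% names(x)))
  out <- data.frame(
    athlete_id = x$athlete_id,
    kind = x$kind,
    duration_s = format(x$duration, digits = 15, scientific = FALSE, trim = TRUE),
    quantity = format(ifelse(x$kind == "power", x$work / x$duration, x$work),
                      digits = 15, scientific = FALSE, trim = TRUE)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
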