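# Aggregation kinetics from hydrodynamic-size time series: consecutive
# interval slopes dD/dt, the maximum rate, and plateau detection.

validate_size_series <- function(series) {
  series <- as_tibble(series)
  if (!all(c("time_min", "size_nm") %in% names(series))) {
    abort("series needs columns time_min and size_nm")
  }
  if (nrow(series) < 2) abort("need at least 2 time points")
  if (anyDuplicated(series$time_min)) abort("duplicate times in series")
  if (is.unsorted(series$time_min, strictly = TRUE)) {
    abort("times must be strictly increasing")
  }
  if (any(series$size_nm <= 0)) abort("sizes must be > 0")
  series
}

#' Aggregation rates from a size time series
#'
#' The aggregation rate is the slope dD/dt over consecutive measurement
#' intervals: `rate[i] = (D[i+1] - D[i]) / (t[i+1] - t[i])` in nm/min. The
#' maximum interval rate (with its midpoint time) characterises the fastest
#' growth phase; a plateau is declared when a run of at least two
#' consecutive intervals with |rate| below `plateau_tol` persists to the end
#' of the series, and the plateau size is the mean size over that tail.
#'
#' @param series Data frame with columns `time_min`, `size_nm` (and
#'   optionally `sd_nm`, ignored here).
#' @param plateau_tol Absolute rate threshold (nm/min) below which the
#'   series counts as stabilised (default 1).
#' @return An object of class `nf_rates`; [tidy()] returns the per-interval
#'   table, [glance()] the one-row summary (`max_rate_nm_min`,
#'   `max_rate_time_min`, `plateau_size_nm`, `plateau_onset_min`).
#' @export
#' @examples
#' s <- tibble::tibble(time_min = 0:5, size_nm = 20 + 3 * (0:5))
#' glance(aggregation_rates(s))
aggregation_rates <- function(series, plateau_tol = 1) {
  series <- validate_size_series(series)
  t <- series$time_min
  d <- series$size_nm
  n <- length(t)
  rates <- diff(d) / diff(t)
  mid <- (t[-1] + t[-n]) / 2
  intervals <- tibble(t_start_min = t[-n], t_end_min = t[-1],
                      t_mid_min = mid, rate_nm_min = rates)
  imax <- which.max(rates)

  # stabilised = a run of >= 2 calm intervals that persists to the end of
  # the series (a slow sigmoidal start can also have small rates; it is not
  # a plateau)
  calm <- abs(rates) < plateau_tol
  onset_idx <- NA_integer_
  run <- rle(calm)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  nr <- length(run$lengths)
  if (run$values[nr] && run$lengths[nr] >= 2) onset_idx <- starts[nr]
  if (!is.na(onset_idx)) {
    plateau_onset <- t[onset_idx]
    plateau_size <- mean(d[onset_idx:n])
  } else {
    plateau_onset <- NA_real_
    plateau_size <- NA_real_
  }

  structure(
    list(intervals = intervals,
         summary = tibble(max_rate_nm_min = rates[imax],
                          max_rate_time_min = mid[imax],
                          plateau_size_nm = plateau_size,
                          plateau_onset_min = plateau_onset,
                          n_points = n),
         plateau_tol = plateau_tol,
         series = series),
    class = "nf_rates")
}

#' @export
print.nf_rates <- function(x, ...) {
  s <- x$summary
  cat("<aggregation rates> ", nrow(x$intervals), " intervals; max ",
      signif(s$max_rate_nm_min, 4), " nm/min at t = ",
      signif(s$max_rate_time_min, 4), " min; plateau ",
      if (is.na(s$plateau_onset_min)) "none" else
        paste0(signif(s$plateau_size_nm, 4), " nm from t = ",
               s$plateau_onset_min, " min"),
      "\n", sep = "")
  invisible(x)
}

#' @method tidy nf_rates
#' @export
tidy.nf_rates <- function(x, ...) x$intervals

#' @method glance nf_rates
#' @export
glance.nf_rates <- function(x, ...) x$summary

#' Centered moving-average smoothing of a size series
#'
#' Window 1 is the identity; endpoints use truncated (shorter) windows.
#'
#' @param series Data frame with `time_min`, `size_nm`.
#' @param window Odd window length >= 1, at most the series length.
#' @return The smoothed series (same columns).
#' @export
smooth_series <- function(series, window = 1) {
  series <- validate_size_series(series)
  if (window < 1 || window %% 2 == 0) abort("window must be odd and >= 1")
  n <- nrow(series)
  if (window > n) abort("window larger than series")
  if (window == 1) return(series)
  half <- (window - 1) / 2
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    mean(series$size_nm[lo:hi])
  }, numeric(1))
  series$size_nm <- sm
  series
}
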