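# Data containers and file formats: size-distribution counts, PAR series,
# bulk measurements, and the scatter-to-carbon conversion. All files are
# plain comma-separated text with a header row, '.' decimal, times in hours.

#' Construct a size-distribution observation set
#'
#' @param times strictly increasing observation times (hours).
#' @param counts K x m matrix of nonnegative integer cell counts
#'   (rows = times, columns = size classes).
#' @return An object of class \code{"obs_set"} with \code{times},
#'   \code{counts}, \code{totals} (row sums) and \code{proportions}.
#' @export
obs_set <- function(times, counts) {
  counts <- as.matrix(counts)
  if (length(times) != nrow(counts)) {
    stop("one row of counts per observation time is required", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("observation times must be strictly increasing", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0) || any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (max(counts) < .Machine$integer.max) {
    counts <- round(counts)
    storage.mode(counts) <- "integer"
  }
  totals <- rowSums(counts)
  if (any(totals <= 0)) {
    stop("every observation time must have a positive total count", call. = FALSE)
  }
  structure(
    list(
      times = as.numeric(times), counts = counts, totals = totals,
      proportions = counts / totals
    ),
    class = "obs_set"
  )
}

#' @export
print.obs_set <- function(x, ...) {
  cat(sprintf(
    "Size-distribution observations: K = %d times over %g h, m = %d classes, N = %s cells/time\n",
    length(x$times), max(x$times) - min(x$times), ncol(x$counts),
    paste(range(x$totals), collapse = "-")
  ))
  invisible(x)
}

#' Read a size-distribution CSV
#'
#' Expects columns \code{time_h}, \code{class_index}, \code{count} forming a
#' complete times x classes grid; rejects missing cells, duplicates and
#' negative counts, naming the offending rows.
#'
#' @param path CSV file path.
#' @return An \code{\link{obs_set}}.
#' @examples
#' # small synthetic example shipped with the package
#' obs <- read_size_distribution(
#'   system.file("extdata", "example_counts.csv", package = "sizempm")
#' )
#' obs$totals
#' @export
read_size_distribution <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_h", "class_index", "count")
  if (!all(need %in% names(df))) {
    stop(sprintf(
      "size-distribution file must have columns %s",
      paste(need, collapse = ", ")
    ), call. = FALSE)
  }
  if (any(df$count < 0)) {
    stop(sprintf(
      "negative counts at row(s) %s",
      paste(utils::head(which(df$count < 0), 5L), collapse = ", ")
    ), call. = FALSE)
  }
  key <- paste(df$time_h, df$class_index)
  if (anyDuplicated(key)) {
    stop(sprintf(
      "duplicated (time, class) pair at row(s) %s",
      paste(utils::head(which(duplicated(key)), 5L), collapse = ", ")
    ), call. = FALSE)
  }
  times <- sort(unique(df$time_h))
  classes <- sort(unique(df$class_index))
  if (!identical(as.integer(classes), seq_along(classes))) {
    stop("class_index must cover 1..m without gaps", call. = FALSE)
  }
  if (nrow(df) != length(times) * length(classes)) {
    have <- split(df$class_index, df$time_h)
    gaps <- names(have)[vapply(have, length, 0L) != length(classes)]
    stop(sprintf(
      "incomplete grid: time(s) %s lack some size classes",
      paste(utils::head(gaps, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  counts <- matrix(0, length(times), length(classes))
  counts[cbind(match(df$time_h, times), match(df$class_index, classes))] <- df$count
  obs_set(times, counts)
}

#' Write a size-distribution CSV
#' @param obs an \code{\link{obs_set}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_size_distribution <- function(obs, path) {
  m <- ncol(obs$counts)
  df <- data.frame(
    time_h = rep(obs$times, each = m),
    class_index = rep(seq_len(m), length(obs$times)),
    count = as.integer(t(obs$counts))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a light (PAR) series on the dt lattice
#' @param times lattice times (hours): \code{0, dt, ..., T}.
#' @param values PAR values (umol photons m^-2 s^-1), nonnegative.
#' @return An object of class \code{"light_series"}.
#' @export
light_series <- function(times, values) {
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (any(values < 0)) stop("PAR values must be nonnegative", call. = FALSE)
  dts <- diff(times)
  if (length(dts) && (any(dts <= 0) || max(abs(dts - dts[1])) > 1e-8)) {
    stop("light series times must be an evenly spaced increasing lattice", call. = FALSE)
  }
  structure(
    list(times = as.numeric(times), values = as.numeric(values),
         dt = if (length(dts)) dts[1] else NA_real_),
    class = "light_series"
  )
}

# PAR at given lattice times (must be present in the series).
light_at <- function(light, t) {
  idx <- match(round(t / light$dt), round(light$times / light$dt))
  if (anyNA(idx)) {
    stop("light series does not cover all requested lattice times", call. = FALSE)
  }
  light$values[idx]
}

#' Interpolate raw PAR measurements onto the model's dt lattice
#'
#' Linear interpolation onto \code{\{0, dt, ..., T\}}; values are clipped at
#' zero. Unless \code{extrapolate = TRUE}, the raw series must cover the full
#' lattice (no extrapolation beyond its range); with it, end values are held
#' constant.
#'
#' @param raw_times raw measurement times (hours).
#' @param raw_values raw PAR values.
#' @param dt lattice spacing (hours).
#' @param T_end last lattice time (hours).
#' @param extrapolate allow constant extrapolation beyond the raw range.
#' @return A \code{\link{light_series}}.
#' @export
interpolate_par <- function(raw_times, raw_values, dt, T_end, extrapolate = FALSE) {
  lattice <- seq(0, T_end, by = dt)
  if (!extrapolate && (min(raw_times) > 0 + 1e-9 || max(raw_times) < T_end - 1e-9)) {
    stop(sprintf(
      "raw PAR covers [%g, %g] h but the lattice needs [0, %g]; pass extrapolate = TRUE to hold end values",
      min(raw_times), max(raw_times), T_end
    ), call. = FALSE)
  }
  v <- stats::approx(raw_times, raw_values, xout = lattice, rule = 2)$y
  light_series(lattice, pmax(v, 0))
}

#' Read a PAR CSV (columns time_h, par) and interpolate onto the lattice
#' @param path CSV path with columns \code{time_h}, \code{par}.
#' @inheritParams interpolate_par
#' @return A \code{\link{light_series}}.
#' @export
read_par_series <- function(path, dt, T_end, extrapolate = FALSE) {
  df <- utils::read.csv(path)
  if (!all(c("time_h", "par") %in% names(df))) {
    stop("PAR file must have columns time_h, par", call. = FALSE)
  }
  interpolate_par(df$time_h, df$par, dt, T_end, extrapolate = extrapolate)
}

#' Convert forward-angle light scatter to carbon quotas
#'
#' Normalized scatter is mapped to a mass proxy \eqn{M = FALS^{1/1.74}} and
#' rescaled by a single multiplicative constant so the population mean equals
#' the calibration mean carbon quota. Both the exponent and the calibration
#' mean are dataset-specific calibrations, configurable here.
#'
#' @param fals positive normalized scatter values.
#' @param calibration_mean target mean carbon quota (fg C; default 53).
#' @param exponent scatter-to-mass exponent (default 1.74).
#' @return cell sizes in fg C with mean \code{calibration_mean}.
#' @export
fals_to_carbon <- function(fals, calibration_mean = 53, exponent = 1.74) {
  if (any(fals <= 0)) stop("scatter values must be positive", call. = FALSE)
  if (calibration_mean <= 0) stop("calibration mean must be positive", call. = FALSE)
  M <- fals^(1 / exponent)
  M * (calibration_mean / mean(M))
}

#' Construct bulk measurements (abundance, mean size, fixation)
#' @param times measurement times (hours), evenly spaced.
#' @param abundance cell abundance \eqn{a_t} (cells per volume), positive.
#' @param mean_size mean cell size \eqn{s_t} (fg C).
#' @param fixation per-cell carbon fixation rate \eqn{f_t} (fg C cell^-1 h^-1).
#' @return An object of class \code{"bulk_measurements"}.
#' @export
bulk_measurements <- function(times, abundance, mean_size, fixation) {
  if (any(abundance <= 0)) stop("abundance must be positive", call. = FALSE)
  n <- length(times)
  stopifnot(length(abundance) == n, length(mean_size) == n, length(fixation) == n)
  structure(
    list(
      times = as.numeric(times), abundance = abundance,
      mean_size = mean_size, fixation = fixation,
      dt_meas = if (n > 1L) times[2] - times[1] else NA_real_
    ),
    class = "bulk_measurements"
  )
}

#' Empirical carbon-loss series from bulk measurements
#'
#' Inverts the per-cell carbon balance
#' \eqn{s_{t+1} = s_t a_t / a_{t+1} + dt (f_t - l_t)}
#' for the loss rate: \eqn{l_t = f_t - (s_{t+1} - s_t a_t/a_{t+1}) / dt}.
#' The abundance ratio accounts for the dilution of per-cell carbon by
#' division between measurements.
#'
#' @param bulk a \code{\link{bulk_measurements}}.
#' @return data frame with \code{time_h} (interval start) and \code{loss}
#'   (fg C cell^-1 h^-1), one row per consecutive measurement pair.
#' @export
empirical_carbon_loss <- function(bulk) {
  n <- length(bulk$times)
  if (n < 2L) stop("need at least two measurement times", call. = FALSE)
  i <- seq_len(n - 1L)
  dtm <- diff(bulk$times)
  loss <- bulk$fixation[i] -
    (bulk$mean_size[i + 1L] - bulk$mean_size[i] * bulk$abundance[i] / bulk$abundance[i + 1L]) / dtm
  data.frame(time_h = bulk$times[i], loss = loss)
}
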