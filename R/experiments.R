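# Observation-sensitivity machinery: periodic extension of a record,
# sliding-window refits, equally spaced holdout validation, and the
# cross-model comparison table.

#' Extend an observation record by appending it to itself
#'
#' The normalized size-distribution series is repeated with times shifted by
#' the record length per copy; a 46-h record observed every 2 h abuts its
#' next copy at 48 h, preserving the observation lattice.
#'
#' @param obs an \code{\link{obs_set}} with evenly spaced times.
#' @param copies total number of record copies (1 = unchanged).
#' @return an \code{\link{obs_set}} spanning \code{copies} records.
#' @export
extend_periodic <- function(obs, copies = 2L) {
  if (copies < 1L) stop("copies must be at least 1", call. = FALSE)
  spacing <- obs$times[2] - obs$times[1]
  period <- max(obs$times) - min(obs$times) + spacing
  times <- as.vector(outer(obs$times, (seq_len(copies) - 1L) * period, "+"))
  counts <- do.call(rbind, replicate(copies, obs$counts, simplify = FALSE))
  obs_set(times, counts)
}

#' Extend a light series periodically (24-h cycle)
#' @param light a \code{\link{light_series}} covering at least one day.
#' @param T_end new last lattice time (hours).
#' @return a \code{\link{light_series}} on \code{[0, T_end]}.
#' @export
extend_light <- function(light, T_end) {
  dt <- light$dt
  times <- seq(0, T_end, by = dt)
  idx <- match(round((times %% 24) / dt), round(light$times / dt))
  if (anyNA(idx)) {
    stop("light series must cover a full 24-h cycle on the dt lattice", call. = FALSE)
  }
  light_series(times, light$values[idx])
}

#' Sliding-window plan
#'
#' @param total_T extended record length (hours).
#' @param window window length (hours, default 48).
#' @param increment start-time increment (hours, default 4).
#' @return list of class \code{"window_plan"} with \code{starts},
#'   \code{window}, \code{increment}.
#' @examples
#' length(window_plan(96)$starts) # 13 windows: starts 0, 4, ..., 48
#' @export
window_plan <- function(total_T, window = 48, increment = 4) {
  if (window > total_T) {
    stop("window does not fit inside the extended record", call. = FALSE)
  }
  starts <- seq(0, total_T - window, by = increment)
  structure(
    list(starts = starts, window = window, increment = increment, total_T = total_T),
    class = "window_plan"
  )
}

#' Equally spaced holdout plan
#'
#' Splits K observation indices into kept (training) and held-out (testing)
#' sets with the held-out points equally spaced, so the daily cycle stays
#' well sampled. For removal fractions up to 1/2, every
#' \code{round(1/fraction)}-th point is removed; above 1/2, every
#' \code{round(1/(1-fraction))}-th point is kept.
#'
#' @param K number of observation times.
#' @param fraction fraction of points to remove (0 <= fraction < 1).
#' @return list of class \code{"holdout_plan"} with \code{kept},
#'   \code{held_out}, \code{fraction}.
#' @examples
#' holdout_plan(24, 1 / 2) # 12 kept, 12 held out
#' @export
holdout_plan <- function(K, fraction) {
  if (fraction < 0 || fraction >= 1) {
    stop("removal fraction must be in [0, 1)", call. = FALSE)
  }
  idx <- seq_len(K)
  if (fraction == 0) {
    held <- integer(0)
  } else if (fraction <= 0.5) {
    step <- round(1 / fraction)
    held <- as.integer(seq(step, K, by = step))
  } else {
    step <- round(1 / (1 - fraction))
    kept <- as.integer(seq(1L, K, by = step))
    held <- setdiff(idx, kept)
  }
  structure(
    list(kept = setdiff(idx, held), held_out = held, fraction = fraction, K = K),
    class = "holdout_plan"
  )
}

#' Sliding-window refits of a model
#'
#' Fits the model independently inside each window of the plan (initial
#' distribution re-estimated per window) and reports per-window posterior
#' summaries of the daily division rate together with a stability measure:
#' the maximum absolute deviation of the posterior-median rate across
#' windows.
#'
#' @param obs an (extended) \code{\link{obs_set}}.
#' @param light a \code{\link{light_series}} covering the extended record.
#' @param plan a \code{\link{window_plan}}.
#' @param keep_fits keep the full per-window \code{"mpm_fit"} objects.
#' @param ... passed to \code{\link{fit_mpm}} (model, grid, priors, sampler
#'   configuration).
#' @return list of class \code{"sliding_window_result"} with \code{table}
#'   (per-window start, median, quartiles, Rhat flag), \code{stability}
#'   (max |median - grand median|), and optionally \code{fits}.
#' @export
sliding_window_fit <- function(obs, light, plan, keep_fits = FALSE, ...) {
  rows <- vector("list", length(plan$starts))
  fits <- if (keep_fits) vector("list", length(plan$starts)) else NULL
  for (w in seq_along(plan$starts)) {
    s0 <- plan$starts[w]
    sel <- obs$times >= s0 - 1e-9 & obs$times <= s0 + plan$window + 1e-9
    sub <- obs_set(obs$times[sel], obs$counts[sel, , drop = FALSE])
    fit <- fit_mpm(sub, light, ...)
    q <- stats::quantile(fit$derived$mu_daily, c(0.25, 0.5, 0.75))
    rows[[w]] <- data.frame(
      start = s0, mu_q25 = q[1], mu_median = q[2], mu_q75 = q[3],
      divergent = is_divergent_fit(fit)
    )
    if (keep_fits) fits[[w]] <- fit
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(
    list(
      table = table,
      stability = max(abs(table$mu_median - stats::median(table$mu_median))),
      fits = fits, plan = plan
    ),
    class = "sliding_window_result"
  )
}

#' Holdout validation fit
#'
#' Fits the model using only the kept observation times, then reports the
#' size-distribution mean squared error separately on the kept (training)
#' and held-out (testing) partitions, both computed from the
#' posterior-median trajectory over the full time set.
#'
#' @param obs an \code{\link{obs_set}}.
#' @param light a \code{\link{light_series}}.
#' @param plan a \code{\link{holdout_plan}} over the observation indices.
#' @param ... passed to \code{\link{fit_mpm}}.
#' @return list of class \code{"holdout_result"} with \code{fit},
#'   \code{train_mse}, \code{test_mse} (NA when nothing is held out) and
#'   \code{plan}.
#' @export
holdout_fit <- function(obs, light, plan, ...) {
  kept <- plan$kept
  sub <- obs_set(obs$times[kept], obs$counts[kept, , drop = FALSE])
  fit <- fit_mpm(sub, light, ...)
  traj <- simulate_trajectory(
    median_theta(fit), fit$spec, fit$grid, light, obs$times
  )
  errs <- (traj$omegas - obs$proportions)^2
  structure(
    list(
      fit = fit,
      train_mse = mean(errs[kept, ]),
      test_mse = if (length(plan$held_out)) mean(errs[plan$held_out, ]) else NA_real_,
      plan = plan
    ),
    class = "holdout_result"
  )
}

#' Cross-model comparison table
#'
#' One row per fitted model: size-distribution MSE at the posterior-median
#' parameters, posterior median and quartiles of the daily division rate,
#' daily carbon fixation and loss, the photosynthetic saturation parameter
#' and P_max — and, when generating values are supplied (synthetic data),
#' absolute and relative errors of the posterior medians.
#'
#' @param fits named list of \code{"mpm_fit"} objects sharing \code{obs}.
#' @param truth optional named numeric vector with any of
#'   \code{mu_daily}, \code{daily_fixation}, \code{daily_loss},
#'   \code{p_max}, \code{e_k}.
#' @return data frame, one row per model.
#' @export
model_comparison_report <- function(fits, truth = NULL) {
  quantities <- c("mu_daily", "daily_fixation", "daily_loss", "e_k", "p_max")
  rows <- lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    traj <- stats::predict(fit)
    row <- data.frame(
      model = nm,
      psd_mse = psd_mse(
        simulate_trajectory(
          median_theta(fit), fit$spec, fit$grid, fit$light, fit$obs$times
        ),
        fit$obs
      ),
      divergent = is_divergent_fit(fit)
    )
    for (qn in quantities) {
      q <- stats::quantile(fit$derived[[qn]], c(0.25, 0.5, 0.75))
      row[[paste0(qn, "_q25")]] <- q[1]
      row[[paste0(qn, "_median")]] <- q[2]
      row[[paste0(qn, "_q75")]] <- q[3]
      if (!is.null(truth) && qn %in% names(truth)) {
        row[[paste0(qn, "_abs_err")]] <- abs(q[2] - truth[[qn]])
        row[[paste0(qn, "_rel_err")]] <- abs(q[2] - truth[[qn]]) / abs(truth[[qn]])
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
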