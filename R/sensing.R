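# CGM sensor and point-of-care blood glucose meter models.
#
# The sensor applies a per-sensor gain, linear drift since the last
# calibration and multiplicative log-normal noise to the interstitial
# glucose, quantised to the 0.1 mmol/L displayed clinically. Calibration
# against a meter blood glucose rescales the gain so the post-calibration
# reading reproduces the reference exactly.

#' Create a CGM sensor state
#'
#' With the default arguments the per-sensor gain is drawn around 1
#' (log-normal, 5% SD) and the drift rate uniformly in +/-2% per hour;
#' these are typical figures for the sensor generation, not values reported
#' by any study.
#'
#' @param t insertion / calibration time, min.
#' @param gain fixed gain, or NULL to draw one.
#' @param drift_rate fixed fractional drift per hour, or NULL to draw one.
#' @param gain_sd SD of log-gain when drawing.
#' @param drift_max drift-rate bound when drawing, fraction per hour.
#' @return list with class `sensor_state` (`gain`, `drift_rate`,
#'   `last_calibration`, `clamped` flag).
#' @export
sensor_new <- function(t = 0, gain = NULL, drift_rate = NULL,
                       gain_sd = 0.05, drift_max = 0.02) {
  if (is.null(gain)) gain <- exp(stats::rnorm(1, 0, gain_sd))
  if (is.null(drift_rate)) drift_rate <- stats::runif(1, -drift_max, drift_max)
  gain <- min(max(gain, 0.5), 2.0)
  structure(list(gain = gain, drift_rate = drift_rate,
                 last_calibration = t, clamped = FALSE),
            class = "sensor_state")
}

.quantise <- function(x) round(pmax(x, 0) * 10) / 10

# Effective multiplicative gain at time t (stored gain plus accrued drift).
.sensor_gain_at <- function(sensor, t) {
  sensor$gain * (1 + sensor$drift_rate * (t - sensor$last_calibration) / 60)
}

#' Read the CGM sensor
#'
#' Reading = interstitial glucose x gain x (1 + drift since calibration) x
#' multiplicative log-normal noise (mean 1, CV `noise_cv`), quantised to
#' 0.1 mmol/L. Returns NULL when `t` falls inside a dropout window.
#'
#' @param g_isf true interstitial glucose, mmol/L.
#' @param sensor a `sensor_state`.
#' @param t time, min.
#' @param noise_cv multiplicative noise CV (default 7%).
#' @param dropouts optional data.frame of dropout windows from
#'   [schedule_dropouts()].
#' @return list(time, value, source = "sg") or NULL if unavailable.
#' @export
cgm_read <- function(g_isf, sensor, t, noise_cv = 0.07, dropouts = NULL) {
  if (t < 0) stop("t must be >= 0")
  if (!is.null(dropouts) && nrow(dropouts) > 0 &&
      any(t >= dropouts$start & t < dropouts$end)) {
    return(NULL)
  }
  mult <- 1
  if (noise_cv > 0) {
    s2 <- log(1 + noise_cv^2)
    mult <- exp(stats::rnorm(1, -s2 / 2, sqrt(s2)))
  }
  value <- .quantise(g_isf * .sensor_gain_at(sensor, t) * mult)
  list(time = t, value = value, source = "sg")
}

#' Calibrate the sensor against a reference blood glucose
#'
#' Rescales the gain so that an immediate noiseless re-read returns exactly
#' `bg_ref`; accrued drift is folded into the new gain and the drift clock
#' restarts. Gains outside [0.5, 2] are clamped and flagged.
#'
#' @param sensor a `sensor_state`.
#' @param bg_ref reference blood glucose, mmol/L (> 0).
#' @param raw_sg the sensor reading at calibration time, mmol/L (> 0).
#' @param t calibration time, min.
#' @return updated `sensor_state`.
#' @export
calibrate <- function(sensor, bg_ref, raw_sg, t) {
  if (bg_ref <= 0 || raw_sg <= 0) stop("bg_ref and raw_sg must be > 0")
  new_gain <- .sensor_gain_at(sensor, t) * bg_ref / raw_sg
  clamped <- new_gain < 0.5 || new_gain > 2.0
  sensor$gain <- min(max(new_gain, 0.5), 2.0)
  sensor$clamped <- clamped
  sensor$last_calibration <- t
  sensor
}

#' Read the point-of-care blood glucose meter
#'
#' Unbiased Gaussian measurement error (default SD 0.3 mmol/L), quantised
#' to 0.1 mmol/L and floored at zero.
#'
#' @param plasma_glucose true plasma glucose, mmol/L (>= 0).
#' @param t time, min (recorded in the reading).
#' @param sd meter error SD, mmol/L.
#' @return list(time, value, source = "bg").
#' @export
bg_meter_read <- function(plasma_glucose, t = NA_real_, sd = 0.3) {
  if (plasma_glucose < 0) stop("plasma glucose must be >= 0")
  value <- .quantise(plasma_glucose + stats::rnorm(1, 0, sd))
  list(time = t, value = value, source = "bg")
}

#' Schedule sensor dropout windows
#'
#' Episodes arrive as a Poisson process (default one per 72 h) with lengths
#' uniform up to `max_episode` (default 210 min, the longest signal loss
#' such a trial reports). Windows are sorted, non-overlapping and clipped
#' to the monitoring duration.
#'
#' @param duration monitoring duration, min.
#' @param rate episode arrival rate, per min.
#' @param max_episode maximum episode length, min (<= duration).
#' @return data.frame with columns `start`, `end` (min).
#' @export
schedule_dropouts <- function(duration, rate = 1 / (72 * 60),
                              max_episode = 210) {
  if (max_episode > duration) stop("max_episode must be <= duration")
  starts <- numeric(0)
  if (rate > 0) {
    t <- stats::rexp(1, rate)
    while (t < duration) {
      starts <- c(starts, t)
      t <- t + stats::rexp(1, rate)
    }
  }
  if (length(starts) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  lens <- stats::runif(length(starts), 0, max_episode)
  out <- data.frame(start = starts, end = pmin(starts + lens, duration))
  keep <- logical(nrow(out))
  last_end <- -Inf
  for (i in seq_len(nrow(out))) {
    if (out$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- out$end[i]
    }
  }
  out[keep, , drop = FALSE]
}
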