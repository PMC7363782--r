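# Comparator arm: nurse-executed titration from the absolute sensor glucose
# value and its trend, evaluated hourly with sparse blood-glucose checks.
#
# The rule table shipped here is an explicit reconstruction of a typical
# neonatal sliding-scale guideline (start 0.02 U/kg/h above 10 mmol/L,
# +/-50% steps, stop below 4, dextrose review below 3.5); it is editable
# and its quantitative behaviour is not asserted against any clinical
# control-arm numbers.

#' Default guideline rule table
#'
#' Ordered rows over (sensor-glucose band) x (trend band, mmol/L per h);
#' the first matching row wins. Actions: `none`, `start_insulin` (start at
#' `magnitude` if off, else +50%), `increase` (+50% if on), `decrease`
#' (-50%), `stop_insulin`, `start_dextrose_review` (stop insulin and flag a
#' dextrose review). Bands jointly cover (0, Inf) x (-Inf, Inf).
#'
#' @return data.frame of rules.
#' @export
default_guideline_rules <- function() {
  rules <- rbind(
    data.frame(sg_lo = 0,    sg_hi = 3.5, trend_lo = -Inf, trend_hi = Inf,
               action = "start_dextrose_review", magnitude = 0),
    data.frame(sg_lo = 3.5,  sg_hi = 4.0, trend_lo = -Inf, trend_hi = Inf,
               action = "stop_insulin", magnitude = 0),
    data.frame(sg_lo = 4.0,  sg_hi = 8.0, trend_lo = -Inf, trend_hi = -1.5,
               action = "decrease", magnitude = 0),
    data.frame(sg_lo = 4.0,  sg_hi = 8.0, trend_lo = -1.5, trend_hi = Inf,
               action = "none", magnitude = 0),
    data.frame(sg_lo = 8.0,  sg_hi = 10.0, trend_lo = 0.5, trend_hi = Inf,
               action = "increase", magnitude = 0),
    data.frame(sg_lo = 8.0,  sg_hi = 10.0, trend_lo = -Inf, trend_hi = 0.5,
               action = "none", magnitude = 0),
    data.frame(sg_lo = 10.0, sg_hi = Inf, trend_lo = -Inf, trend_hi = -1.0,
               action = "none", magnitude = 0),
    data.frame(sg_lo = 10.0, sg_hi = Inf, trend_lo = -1.0, trend_hi = Inf,
               action = "start_insulin", magnitude = 0.02)
  )
  rules$action <- as.character(rules$action)
  rules
}

#' Validate a guideline rule table
#'
#' Checks that the sensor-glucose and trend bands jointly cover
#' (0, Inf) x (-Inf, Inf) on a probe grid and that actions are known.
#'
#' @param rules rule data.frame.
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_rules <- function(rules) {
  known <- c("none", "start_insulin", "increase", "decrease",
             "stop_insulin", "start_dextrose_review")
  if (!all(rules$action %in% known)) stop("unknown rule action")
  probe_sg <- c(0.1, seq(0.5, 25, by = 0.5))
  probe_tr <- c(-10, -2, -1.2, -0.5, 0, 0.6, 2, 10)
  for (sg in probe_sg) for (tr in probe_tr) {
    hit <- rules$sg_lo <= sg & sg < rules$sg_hi &
      rules$trend_lo <= tr & tr < rules$trend_hi
    if (!any(hit)) stop(sprintf("no rule covers sg=%.1f trend=%.1f", sg, tr))
  }
  invisible(TRUE)
}

#' Least-squares glucose trend over a trailing window
#'
#' @param readings data.frame with columns `time` (min) and `value`
#'   (mmol/L).
#' @param window trailing window, min (default 60).
#' @param t_now window end; defaults to the newest reading time.
#' @return slope in mmol/L per hour; 0 when fewer than two readings fall in
#'   the window.
#' @export
trend <- function(readings, window = 60, t_now = NULL) {
  if (is.null(t_now)) t_now <- max(readings$time)
  sel <- readings$time >= t_now - window & readings$time <= t_now
  tt <- readings$time[sel]
  vv <- readings$value[sel]
  if (length(tt) < 2) return(0)
  tc <- tt - mean(tt)
  denom <- sum(tc^2)
  if (denom == 0) return(0)
  sum(tc * (vv - mean(vv))) / denom * 60
}

#' Apply the guideline to one evaluation
#'
#' First matching rule wins; insulin never goes below zero; if no rule
#' matches the rate is left unchanged with a warning.
#'
#' @param sg current sensor glucose, mmol/L.
#' @param trend glucose trend, mmol/L per h.
#' @param current_insulin commanded insulin rate, U/kg/h.
#' @param rules rule table, default [default_guideline_rules()].
#' @return list(insulin_rate, dextrose_review).
#' @export
guideline_decide <- function(sg, trend, current_insulin,
                             rules = default_guideline_rules()) {
  hit <- which(rules$sg_lo <= sg & sg < rules$sg_hi &
                 rules$trend_lo <= trend & trend < rules$trend_hi)
  if (length(hit) == 0) {
    warning("no guideline rule matched; insulin unchanged")
    return(list(insulin_rate = current_insulin, dextrose_review = FALSE))
  }
  r <- rules[hit[1], ]
  rate <- switch(r$action,
    none = current_insulin,
    start_insulin = if (current_insulin == 0) r$magnitude
                    else current_insulin * 1.5,
    increase = current_insulin * 1.5,
    decrease = current_insulin * 0.5,
    stop_insulin = 0,
    start_dextrose_review = 0
  )
  list(insulin_rate = max(0, rate),
       dextrose_review = r$action == "start_dextrose_review")
}

#' Ward evaluation and blood-glucose check schedule
#'
#' Guideline evaluations run hourly on sensor glucose (threshold-crossing
#' alarms trigger extra evaluations inside the trial loop); blood-glucose
#' spot checks arrive as a Poisson process (default 5.5/day, the rate such
#' control arms report); calibration checks recur every 12 h.
#'
#' @param duration monitoring duration, min (> 0).
#' @param bg_per_day mean number of spot blood-glucose checks per day.
#' @param cal_period calibration cadence, min.
#' @return list of sorted time vectors `eval_times`, `bg_times`,
#'   `cal_times`, all within (0, duration].
#' @export
evaluation_schedule <- function(duration, bg_per_day = 5.5,
                                cal_period = 720) {
  if (duration <= 0) stop("duration must be > 0")
  eval_times <- seq(60, duration, by = 60)
  bg_times <- numeric(0)
  if (bg_per_day > 0) {
    rate <- bg_per_day / 1440
    t <- stats::rexp(1, rate)
    while (t < duration) {
      bg_times <- c(bg_times, t)
      t <- t + stats::rexp(1, rate)
    }
  }
  cal_times <- seq(cal_period, duration, by = cal_period)
  list(eval_times = eval_times, bg_times = round(bg_times),
       cal_times = cal_times)
}
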