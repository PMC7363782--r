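# Glycaemic endpoints and between-arm statistics.
#
# Band conventions: the target band 4.0-8.0 mmol/L is inclusive at both
# ends, hyperglycaemia is strictly > 10.0 and hypoglycaemia strictly
# < 2.6, matching the printed inequalities of such trials and keeping the
# bands non-overlapping at the edges. Time weighting is sample-hold at the
# CGM grid: each reading stands for one sampling interval.

#' Percentage of readings inside a glucose band
#'
#' @param series numeric vector of sensor glucose values, mmol/L (NAs are
#'   dropped).
#' @param lo,hi band edges, mmol/L, inclusive at both ends.
#' @return percent of readings with `lo <= value <= hi`.
#' @export
time_in_range <- function(series, lo = 4.0, hi = 8.0) {
  series <- series[!is.na(series)]
  if (length(series) == 0) stop("empty series")
  mean(series >= lo & series <= hi) * 100
}

#' Percentage of readings strictly above / below a threshold
#'
#' @param series sensor glucose values, mmol/L.
#' @param threshold mmol/L.
#' @return percent of readings.
#' @export
time_above <- function(series, threshold = 10.0) {
  series <- series[!is.na(series)]
  if (length(series) == 0) stop("empty series")
  mean(series > threshold) * 100
}

#' @rdname time_above
#' @export
time_below <- function(series, threshold = 2.6) {
  series <- series[!is.na(series)]
  if (length(series) == 0) stop("empty series")
  mean(series < threshold) * 100
}

#' Convert a percentage of a window to hours
#'
#' @param pct percent, in \[0, 100\].
#' @param window_h window length, hours.
#' @return named vector: `hours` (exact) and `hours_rounded` (nearest
#'   hour, the form such trials print).
#' @export
percent_to_hours <- function(pct, window_h) {
  if (pct < 0 || pct > 100) stop("pct must be in [0, 100]")
  h <- pct / 100 * window_h
  c(hours = h, hours_rounded = round(h))
}

#' Hypoglycaemia episodes in a glucose trace
#'
#' Maximal runs of consecutive readings strictly below `threshold` lasting
#' at least `min_duration` minutes. The duration of a run of n readings is
#' n times the sampling interval (sample-hold), so a 205-min sensor episode
#' at a 5-min grid is a run of 41 readings.
#'
#' @param series data.frame with columns `time` (min, sorted) and `value`
#'   (mmol/L); NA values break runs.
#' @param threshold mmol/L (default 2.6).
#' @param min_duration minimum episode duration, min (default 10, i.e. two
#'   consecutive readings at a 5-min grid).
#' @return data.frame with columns `start`, `end`, `duration`, `nadir`.
#' @export
episodes_below <- function(series, threshold = 2.6, min_duration = 10) {
  t <- series$time
  v <- series$value
  if (is.unsorted(t)) stop("series must be time-sorted")
  interval <- if (length(t) > 1) stats::median(diff(t)) else 1
  below <- !is.na(v) & v < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (i in which(r$values)) {
    dur <- r$lengths[i] * interval
    if (dur >= min_duration) {
      idx <- starts[i]:ends[i]
      out[[length(out) + 1]] <- data.frame(
        start = t[starts[i]], end = t[ends[i]],
        duration = dur, nadir = min(v[idx]))
    }
  }
  if (length(out) == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), nadir = numeric(0)))
  do.call(rbind, out)
}

#' Mean and SD of a glucose series
#'
#' @param series numeric vector (NAs dropped).
#' @return named vector `mean`, `sd` (n-1 denominator; SD is NA for a
#'   single reading).
#' @export
summary_stats <- function(series) {
  series <- series[!is.na(series)]
  if (length(series) == 0) stop("empty series")
  c(mean = mean(series), sd = stats::sd(series))
}

#' Median and interquartile range
#'
#' Linear-interpolation (type-7) quartiles.
#'
#' @param values numeric vector (NAs dropped, must leave >= 1 value).
#' @return named vector `median`, `q1`, `q3`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("empty input")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Mann-Whitney U test
#'
#' Exact two-sided p by enumeration when min(n) <= 8 and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction. U is the number of (x, y) pairs with x > y (plus half the
#' ties).
#'
#' @param x,y numeric samples (non-empty).
#' @return list(U, p, method).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  ties <- any(duplicated(c(x, y)))
  exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Pooled-variance unpaired t test
#'
#' @param x,y numeric samples, each n >= 2. When both variances are zero
#'   and the means equal, returns t = 0, p = 1.
#' @return list(t, df, p).
#' @export
unpaired_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Per-infant glycaemic summary over a period
#'
#' @param record a `trial_record`.
#' @param period_h two-element vector, hours, half-open \[lo, hi).
#' @return one-row data.frame of the summary fields.
#' @export
glycaemic_summary <- function(record, period_h) {
  rows <- record$rows
  sel <- rows$time_min >= period_h[1] * 60 & rows$time_min < period_h[2] * 60
  rows <- rows[sel, ]
  sg <- rows$sg[!is.na(rows$sg)]
  if (length(sg) == 0) stop("no sensor glucose in the requested period")
  st <- summary_stats(sg)
  eps <- episodes_below(data.frame(time = rows$time_min[!is.na(rows$sg)],
                                   value = sg))
  rescue_flux <- dextrose_to_flux(rows$dextrose20_ml_kg_h, 20)
  data.frame(
    id = record$id, arm = record$arm,
    pct_4_8 = time_in_range(sg, 4, 8),
    pct_2p6_10 = time_in_range(sg, 2.6, 10),
    pct_gt10 = time_above(sg, 10),
    pct_lt2p6 = time_below(sg, 2.6),
    mean_sg = st[["mean"]], sd_sg = st[["sd"]],
    hypo_episodes = nrow(eps),
    insulin_mean = mean(rows$insulin_u_kg_h, na.rm = TRUE),
    dextrose_mean = mean(rows$maintenance_dextrose + rescue_flux,
                         na.rm = TRUE),
    stringsAsFactors = FALSE
  )
}

.period_bounds <- function(dataset, period) {
  rng <- range(dataset$records[[1]]$rows$time_min) / 60
  switch(period,
         intervention = c(48, 72),
         post = c(72, rng[2]),
         stop("period must be 'intervention' or 'post'"))
}

#' Between-arm outcome table
#'
#' Per-infant summaries over the period, arm medians (IQR), and a
#' Mann-Whitney p value per row (significance threshold 0.05, no
#' multiplicity adjustment, matching the trial analyses this mirrors).
#'
#' @param dataset a `trial_dataset` containing both arms.
#' @param period `"intervention"` (48-72 h) or `"post"` (72 h to end).
#' @return data.frame: one row per outcome with formatted per-arm
#'   median (IQR) strings, the numeric medians, and p.
#' @export
outcome_table <- function(dataset, period = "intervention") {
  bounds <- .period_bounds(dataset, period)
  per <- do.call(rbind, lapply(dataset$records, glycaemic_summary,
                               period_h = bounds))
  arms <- split(per, per$arm)
  if (length(arms) < 2) stop("dataset must contain both arms")
  metrics <- c(pct_4_8 = "Time 4.0-8.0 mmol/L (%)",
               pct_2p6_10 = "Time 2.6-10.0 mmol/L (%)",
               pct_gt10 = "Time >10.0 mmol/L (%)",
               pct_lt2p6 = "Time <2.6 mmol/L (%)",
               mean_sg = "Mean sensor glucose (mmol/L)",
               sd_sg = "SD of sensor glucose (mmol/L)",
               hypo_episodes = "Episodes of BG <2.6 mmol/L",
               insulin_mean = "Insulin (U/kg/hour)",
               dextrose_mean = "Dextrose (mg/kg/min)")
  fmt <- function(v) {
    m <- median_iqr(v)
    d <- if (max(abs(m)) < 1) 2 else 1 # small rates keep two decimals
    sprintf("%2$.*1$f (%3$.*1$f-%4$.*1$f)", d, m[1], m[2], m[3])
  }
  out <- lapply(names(metrics), function(k) {
    cl <- arms$closed_loop[[k]]
    ct <- arms$control[[k]]
    if (k == "hypo_episodes") { # trials print the arm total
      return(data.frame(outcome = metrics[[k]],
                        closed_loop = sprintf("%d", sum(cl)),
                        control = sprintf("%d", sum(ct)),
                        median_closed_loop = sum(cl),
                        median_control = sum(ct),
                        p = mann_whitney(cl, ct)$p,
                        test = "Mann-Whitney U",
                        stringsAsFactors = FALSE))
    }
    data.frame(outcome = metrics[[k]],
               closed_loop = fmt(cl), control = fmt(ct),
               median_closed_loop = unname(median_iqr(cl)[1]),
               median_control = unname(median_iqr(ct)[1]),
               p = mann_whitney(cl, ct)$p,
               test = "Mann-Whitney U",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- names(metrics)
  attr(tab, "per_infant") <- per
  attr(tab, "period_h") <- bounds
  tab
}
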