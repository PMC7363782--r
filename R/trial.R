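# Orchestration of the full protocol: continuous monitoring from the run
# start to 160 h, guideline control everywhere except the prespecified
# 48-72 h window, where the closed-loop arm switches to the MPC controller
# (5 U/kg per 50 mL insulin, 6-h calibrations) while the control arm stays
# on the guideline (25 U/kg per 50 mL, 12-h calibrations).

#' Trial protocol settings
#'
#' The intervention window is half-open, \[48 h, 72 h): the first MPC
#' action fires at 48:00 and the last at 71:45, giving exactly 96 cycles.
#'
#' @param total_h monitored duration, hours.
#' @param start_h simulation start, hours after birth. Runs starting at
#'   48 h initialise each infant at the steady state matching its baseline
#'   sensor glucose (a proxy for the preceding guideline management).
#' @param window_h intervention window, hours, half-open.
#' @param cgm_period CGM sampling period, min.
#' @param control_period closed-loop cycle period, min.
#' @param cal_ward_min,cal_loop_min calibration cadence outside / inside the
#'   closed loop, min.
#' @param guideline_eval_min guideline evaluation period, min.
#' @param bg_per_day ward spot blood-glucose checks per day.
#' @param noise_cv,gain_sd,drift_max,meter_sd sensor and meter error
#'   settings (see the sensing module).
#' @param dropout_rate,dropout_max sensor dropout process settings.
#' @param conc_ward,conc_loop insulin syringe concentrations, U/kg per
#'   50 mL.
#' @param review_dex_rate 20% dextrose rate started by a guideline dextrose
#'   review, mL/kg/h.
#' @param fluid_change if TRUE, maintenance dextrose is transiently
#'   perturbed for 45 min at each day boundary (emulating fluid changes).
#' @param mpc_cfg controller configuration, [mpc_config()].
#' @param rules guideline rule table.
#' @return list with class `protocol`.
#' @export
protocol <- function(total_h = 160, start_h = 0, window_h = c(48, 72),
                     cgm_period = 5, control_period = 15,
                     cal_ward_min = 720, cal_loop_min = 360,
                     guideline_eval_min = 60, bg_per_day = 5.5,
                     noise_cv = 0.07, gain_sd = 0.05, drift_max = 0.02,
                     meter_sd = 0.3, dropout_rate = 1 / (72 * 60),
                     dropout_max = 210, conc_ward = 25, conc_loop = 5,
                     review_dex_rate = 0.5, fluid_change = FALSE,
                     mpc_cfg = mpc_config(),
                     rules = default_guideline_rules()) {
  if (window_h[1] < start_h || window_h[2] > total_h)
    stop("intervention window must lie within the monitored duration")
  p <- as.list(environment())
  class(p) <- "protocol"
  p
}

# Delivered insulin after pump quantisation at a given syringe
# concentration (U/kg per 50 mL; 0.1 mL/h pump steps).
.delivered_insulin <- function(commanded, concentration) {
  rate_to_pump(commanded, concentration) * concentration / 50
}

#' Run one infant through one arm of the protocol
#'
#' Physiology is stepped at 1-min resolution; the CGM is read every 5 min;
#' the guideline is evaluated hourly (plus threshold-crossing alarms)
#' outside the closed loop, and the MPC controller every 15 min inside it
#' for the closed-loop arm. Deterministic given `seed`.
#'
#' @param profile one-row data.frame from [sample_cohort()].
#' @param arm `"closed_loop"` or `"control"`.
#' @param proto [protocol()].
#' @param seed integer seed.
#' @return `trial_record`: list with `id`, `arm`, `rows` (5-min time grid:
#'   time_min, sg, bg, plasma_glucose, insulin_u_kg_h, dextrose20_ml_kg_h,
#'   maintenance_dextrose, event), `actions` (one row per MPC cycle) and
#'   `events`.
#' @export
run_arm <- function(profile, arm, proto = protocol(), seed = 1L) {
  stopifnot(arm %in% c("closed_loop", "control"))
  set.seed(seed)
  t0 <- proto$start_h * 60
  tend <- proto$total_h * 60
  win <- proto$window_h * 60
  params <- preterm_params(si_base = profile$si_base,
                           egp0 = profile$egp0)
  inputs <- infusion_input(maintenance_dextrose = profile$maintenance_dextrose,
                           enteral_carb = profile$trophic_carb)
  ss <- steady_state(params, profile$baseline_sg, inputs)
  state <- ss$state
  commanded <- ss$basal_insulin           # guideline-commanded insulin
  s_mult <- 1
  sensor <- sensor_new(t = t0, gain_sd = proto$gain_sd,
                       drift_max = proto$drift_max)
  dropouts <- schedule_dropouts(tend - t0, proto$dropout_rate,
                                min(proto$dropout_max, tend - t0))
  if (nrow(dropouts) > 0) {
    dropouts$start <- dropouts$start + t0
    dropouts$end <- dropouts$end + t0
  }
  spot_bg <- numeric(0)
  if (proto$bg_per_day > 0) {
    tt <- t0 + stats::rexp(1, proto$bg_per_day / 1440)
    while (tt < tend) {
      spot_bg <- c(spot_bg, round(tt))
      tt <- tt + stats::rexp(1, proto$bg_per_day / 1440)
    }
  }
  n5 <- (tend - t0) / proto$cgm_period + 1
  rows <- data.frame(time_min = seq(t0, tend, by = proto$cgm_period),
                     sg = NA_real_, bg = NA_real_,
                     plasma_glucose = NA_real_, insulin_u_kg_h = NA_real_,
                     dextrose20_ml_kg_h = NA_real_,
                     maintenance_dextrose = NA_real_,
                     event = "", stringsAsFactors = FALSE)
  actions <- vector("list", 96)
  n_act <- 0
  events <- list()
  add_event <- function(t, type) events[[length(events) + 1]] <<-
      data.frame(time_min = t, type = type, stringsAsFactors = FALSE)
  # reading history ring for trend / alarms
  hist_t <- numeric(0); hist_v <- numeric(0)
  mst <- NULL
  delivered <- .delivered_insulin(commanded,
                                  if (arm == "closed_loop" &&
                                      t0 >= win[1] && t0 < win[2])
                                    proto$conc_loop else proto$conc_ward)
  dex_rate <- 0          # controller / review 20% dextrose, mL/kg/h
  review_active <- FALSE
  maint_factor <- 1
  maint_until <- -Inf
  vol <- profile$si_volatility
  rev_min <- profile$si_reversion_h * 60
  for (t in seq(t0, tend, by = 1)) {
    in_window <- t >= win[1] && t < win[2]
    mpc_active <- arm == "closed_loop" && in_window
    row_i <- if ((t - t0) %% proto$cgm_period == 0)
      (t - t0) / proto$cgm_period + 1 else NA
    reading <- NULL
    if (!is.na(row_i)) {
      reading <- cgm_read(state[["gisf"]], sensor, t,
                          noise_cv = proto$noise_cv, dropouts = dropouts)
      if (!is.null(reading)) {
        rows$sg[row_i] <- reading$value
        hist_t <- c(utils::tail(hist_t, 23), t)
        hist_v <- c(utils::tail(hist_v, 23), reading$value)
      } else if (identical(rows$event[row_i], "")) {
        rows$event[row_i] <- "dropout"
      }
    }
    # calibration (needs a live sensor reading as the raw value)
    cal_period <- if (mpc_active) proto$cal_loop_min else proto$cal_ward_min
    if (t > t0 && (t - t0) %% cal_period == 0 && !is.null(reading)) {
      bgr <- bg_meter_read(plasma_glucose(state, params), t, proto$meter_sd)
      if (bgr$value > 0 && reading$value > 0) {
        sensor <- calibrate(sensor, bgr$value, reading$value, t)
        rows$bg[row_i] <- bgr$value
        add_event(t, "calibration")
        if (bgr$value < 2.6) add_event(t, "hypo_bg")
      }
    }
    # ward spot blood-glucose checks
    if (!mpc_active && t %in% spot_bg) {
      bgr <- bg_meter_read(plasma_glucose(state, params), t, proto$meter_sd)
      if (!is.na(row_i)) rows$bg[row_i] <- bgr$value
      if (bgr$value < 2.6) add_event(t, "hypo_bg")
    }
    # --- control ---
    if (mpc_active && (t - win[1]) %% proto$control_period == 0) {
      if (t == win[1]) {
        mst <- mpc_init(profile$bw_g, proto$mpc_cfg)
        mst$last_insulin <- delivered
        add_event(t, "closed_loop_start")
      }
      bg_fb <- NULL
      if (is.null(reading) && t %% 60 == 0) {
        bgr <- bg_meter_read(plasma_glucose(state, params), t, proto$meter_sd)
        bg_fb <- bgr
        if (bgr$value < 2.6) add_event(t, "hypo_bg")
      }
      cyc <- mpc_cycle(mst, t, sg = reading, bg = bg_fb)
      mst <- cyc$state
      delivered <- cyc$action$insulin_rate
      dex_rate <- cyc$action$dextrose20_rate
      n_act <- n_act + 1
      actions[[n_act]] <- data.frame(
        time_min = t, insulin_rate = cyc$action$insulin_rate,
        dextrose20_rate = dex_rate, mode = cyc$action$mode,
        pred_min40 = cyc$action$pred_min40,
        d_fast = mst$d_fast, b_slow = mst$b_slow,
        stringsAsFactors = FALSE)
      if (nzchar(cyc$action$event)) add_event(t, cyc$action$event)
      commanded <- delivered   # guideline resumes from the loop's last rate
    } else if (!mpc_active) {
      if (arm == "closed_loop" && t == win[2]) {
        dex_rate <- 0          # rescue infusion stops with the loop
        add_event(t, "closed_loop_end")
      }
      alarm <- FALSE
      if (!is.null(reading) && length(hist_v) >= 2) {
        prev <- hist_v[length(hist_v) - 1]
        cur <- reading$value
        alarm <- (prev <= 10 && cur > 10) || (prev >= 4 && cur < 4) ||
          cur < 3.5
      }
      if ((t %% proto$guideline_eval_min == 0 || alarm) &&
          !is.null(reading)) {
        tr <- trend(data.frame(time = hist_t, value = hist_v), 60, t)
        dec <- guideline_decide(reading$value, tr, commanded, proto$rules)
        commanded <- dec$insulin_rate
        delivered <- .delivered_insulin(commanded, proto$conc_ward)
        if (dec$dextrose_review && !review_active) {
          review_active <- TRUE
          add_event(t, "dextrose_review")
        }
        if (review_active && reading$value >= 4) review_active <- FALSE
        dex_rate <- if (review_active) proto$review_dex_rate else 0
      }
    }
    if (!is.na(row_i)) {
      rows$plasma_glucose[row_i] <- round(plasma_glucose(state, params), 3)
      rows$insulin_u_kg_h[row_i] <- delivered
      rows$dextrose20_ml_kg_h[row_i] <- dex_rate
      rows$maintenance_dextrose[row_i] <-
        profile$maintenance_dextrose * maint_factor
    }
    if (t == tend) break
    # --- physiology: advance one minute ---
    if (proto$fluid_change && t > t0 && t %% 1440 == 0) {
      maint_factor <- stats::runif(1, 0.3, 1.2)
      maint_until <- t + 45
      add_event(t, "fluid_change")
    }
    if (t >= maint_until) maint_factor <- 1
    s_mult <- evolve_sensitivity(s_mult, 1, vol, rev_min)
    params$s_mult <- s_mult
    inp <- infusion_input(
      insulin_u_kg_h = delivered,
      dextrose20_ml_kg_h = dex_rate,
      maintenance_dextrose = profile$maintenance_dextrose * maint_factor,
      enteral_carb = profile$trophic_carb)
    state <- step(state, params, inp, 1)
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(time_min = numeric(0), type = character(0),
               stringsAsFactors = FALSE)
  structure(list(id = profile$id, arm = arm, rows = rows,
                 actions = if (n_act) do.call(rbind, actions[seq_len(n_act)])
                           else NULL,
                 events = ev, seed = seed),
            class = "trial_record")
}

#' Run a full virtual trial
#'
#' Samples the cohort, assigns arms by minimisation, and runs every infant
#' through its arm. Deterministic given `seed` (per-infant seeds are
#' derived from it).
#'
#' @param spec [cohort_spec()]; its own seed is overridden by `seed`.
#' @param proto [protocol()].
#' @param seed integer master seed.
#' @return `trial_dataset`: list with `cohort`, `assignment`, `records`,
#'   `seed`.
#' @export
run_trial <- function(spec, proto = protocol(), seed = 1L) {
  spec$seed <- seed
  cohort <- sample_cohort(spec)
  assignment <- assign_arms_minimisation(cohort, seed = seed + 7919L)
  records <- lapply(seq_len(nrow(cohort)), function(i) {
    run_arm(cohort[i, ], assignment$arm[i], proto,
            seed = (seed + i * 10007L) %% 2147483647L)
  })
  names(records) <- cohort$id
  structure(list(cohort = cohort, assignment = assignment,
                 records = records, seed = seed),
            class = "trial_dataset")
}

.required_columns <- c("time_min", "sg", "bg", "plasma_glucose",
                       "insulin_u_kg_h", "dextrose20_ml_kg_h",
                       "maintenance_dextrose", "event")

#' Save / load a trial dataset
#'
#' One CSV per infant plus `cohort.csv` and a JSON manifest recording the
#' seed, arms and file list. The loader validates the per-infant schema and
#' reports any missing columns.
#'
#' @param dataset a `trial_dataset`.
#' @param dir output directory (created if needed).
#' @return (`load_dataset`) the reconstructed `trial_dataset`.
#' @export
save_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(dataset$cohort, dataset$assignment,
               file.path(dir, "cohort.csv"))
  files <- character(0)
  for (rec in dataset$records) {
    f <- paste0("record_", rec$id, ".csv")
    utils::write.csv(rec$rows, file.path(dir, f), row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(seed = dataset$seed,
                   n = nrow(dataset$cohort),
                   arms = as.list(stats::setNames(dataset$assignment$arm,
                                                  dataset$assignment$id)),
                   files = as.list(stats::setNames(files,
                                                   dataset$cohort$id)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cohort_full <- read_cohort(file.path(dir, "cohort.csv"))
  assignment <- cohort_full[, c("id", "arm", "stratum_ga", "stratum_bw")]
  cohort <- cohort_full[, setdiff(names(cohort_full),
                                  c("arm", "stratum_ga", "stratum_bw"))]
  records <- lapply(names(manifest$files), function(id) {
    rows <- utils::read.csv(file.path(dir, manifest$files[[id]]),
                            stringsAsFactors = FALSE)
    rows$event <- ifelse(is.na(rows$event), "", as.character(rows$event))
    missing <- setdiff(.required_columns, names(rows))
    if (length(missing) > 0)
      stop("record ", id, " is missing columns: ",
           paste(missing, collapse = ", "))
    for (cc in setdiff(.required_columns, "event"))
      rows[[cc]] <- as.numeric(rows[[cc]])
    structure(list(id = id, arm = manifest$arms[[id]], rows = rows,
                   actions = NULL,
                   events = data.frame(time_min = numeric(0),
                                       type = character(0),
                                       stringsAsFactors = FALSE),
                   seed = manifest$seed),
              class = "trial_record")
  })
  names(records) <- names(manifest$files)
  structure(list(cohort = cohort, assignment = assignment,
                 records = records, seed = manifest$seed),
            class = "trial_dataset")
}
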