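# Adaptive model-predictive controller with low-glucose 20% dextrose
# rescue, on a 15-minute cycle.
#
# The controller carries an internal copy of the compartment model at
# nominal preterm parameters and adapts two quantities to the individual
# baby: d_fast, a rapidly changing glucose-flux correction (mg/kg/min)
# absorbing whatever the internal model cannot explain (nutrition is never
# disclosed to the controller, so d_fast also carries the entire dextrose
# load), and b_slow, a slowly changing estimate of the basal insulin rate
# that would hold normoglycaemia (U/kg/h). Insulin is chosen by exhaustive
# grid search at the pump's dose resolution over a 90-min predicted
# trajectory; 20% dextrose rescue is chosen over a 30-40 min horizon and
# takes priority, with insulin forced to zero while dextrose runs.

#' Controller configuration
#'
#' @param setpoint glucose reference, mmol/L.
#' @param hypo_weight cost multiplier applied below `hypo_thresh`.
#' @param hypo_thresh asymmetric-penalty threshold, mmol/L.
#' @param max_insulin insulin cap, U/kg/h.
#' @param insulin_step insulin grid step, U/kg/h (pump resolution at the
#'   closed-loop 5 U/kg per 50 mL dilution: 0.1 mL/h x 0.1 U/kg/mL).
#' @param horizon_insulin insulin prediction horizon, min.
#' @param dex_window dextrose evaluation window within the prediction, min.
#' @param dex_trigger predicted-minimum trigger for rescue, mmol/L.
#' @param dex_target predicted minimum the rescue must restore, mmol/L.
#' @param dex_max,dex_step dextrose grid cap and step, mL/kg/h.
#' @param tau_fast,tau_slow adaptation time constants, min.
#' @param predict_dt internal prediction resolution, min.
#' @param safety_floor insulin is withheld whenever the 40-min predicted
#'   minimum falls below this, mmol/L.
#' @param b_slow_init initial basal estimate, U/kg/h.
#' @param anchor_gain fraction of the innovation used to re-anchor the
#'   internal glucose state at each ingest.
#' @param fallback_max_min longest period the controller will dose on
#'   hourly blood-glucose values before holding, min.
#' @return list of settings.
#' @export
mpc_config <- function(setpoint = 6.0, hypo_weight = 4, hypo_thresh = 4.0,
                       max_insulin = 0.5, insulin_step = 0.01,
                       horizon_insulin = 90, dex_window = c(30, 40),
                       dex_trigger = 3.5, dex_target = 4.0,
                       dex_max = 1.0, dex_step = 0.01,
                       tau_fast = 30, tau_slow = 360, predict_dt = 5,
                       safety_floor = 4.0, b_slow_init = 0.02,
                       anchor_gain = 0.5, fallback_max_min = 240) {
  as.list(environment())
}

#' Initialise the controller from the baby's weight
#'
#' The internal model starts at nominal preterm parameters at the glucose
#' setpoint, with zero flux correction and the default basal estimate.
#' Identical weights give identical states.
#'
#' @param weight_g birth weight, g (> 0).
#' @param cfg [mpc_config()].
#' @param params_nominal internal-model parameters; default
#'   [preterm_params()] at the population-median sensitivity.
#' @return list with class `mpc_state`.
#' @export
mpc_init <- function(weight_g, cfg = mpc_config(),
                     params_nominal = preterm_params()) {
  if (weight_g <= 0) stop("weight must be > 0")
  p <- params_nominal
  q1 <- cfg$setpoint * MGDL_PER_MMOL * p$v_g
  ip <- cfg$b_slow_init * 1000 / 60 / (p$v_i * p$k_e)
  st <- patient_state(q1 = q1, q2 = p$k12 / p$k21 * q1, ip = ip,
                      x = p$si_base * ip, gisf = cfg$setpoint)
  structure(list(
    weight_g = weight_g, cfg = cfg, params = p,
    model = st, d_fast = 0, b_slow = cfg$b_slow_init,
    history = data.frame(time = numeric(0), value = numeric(0),
                         source = character(0), stringsAsFactors = FALSE),
    mode = "sg", fallback_started = NA_real_,
    t_model = NA_real_, last_insulin = 0, last_dex = 0
  ), class = "mpc_state")
}

# Propagate the internal model under the last applied rates. The internal
# appearance flux is egp (internal) + d_fast + the controller's own
# dextrose command; nutrition is unknown to the controller by design.
.mpc_propagate <- function(mst, to_t) {
  if (is.na(mst$t_model) || to_t <= mst$t_model) {
    mst$t_model <- to_t
    return(mst)
  }
  p <- mst$params
  flux <- mst$d_fast + dextrose_to_flux(mst$last_dex, 20)
  u_mU <- mst$last_insulin * 1000 / 60
  s <- as.list(unname(mst$model))
  remaining <- to_t - mst$t_model
  dt <- mst$cfg$predict_dt
  while (remaining > 1e-9) {
    h <- min(dt, remaining)
    s <- .rk4(s, p, flux, u_mU, h)
    remaining <- remaining - h
  }
  mst$model <- c(q1 = s[[1]], q2 = s[[2]], ip = s[[3]], x = s[[4]],
                 gisf = s[[5]])
  mst$t_model <- to_t
  mst
}

# Basal insulin rate implied by the internal model plus flux correction at
# the setpoint (used to pull b_slow toward the persistent-error estimate).
.mpc_implied_basal <- function(mst) {
  ss <- steady_state(mst$params, mst$cfg$setpoint, infusion_input(),
                     extra_flux = mst$d_fast)
  ss$basal_insulin
}

#' Ingest a glucose reading (observer update)
#'
#' Computes the innovation e = reading - internal-model sensor glucose,
#' then: adds a first-order share of the implied flux error to `d_fast`
#' (time constant `tau_fast`), pulls `b_slow` toward the basal insulin rate
#' implied by the internal model with its current flux correction (time
#' constant `tau_slow`), and re-anchors the internal glucose state toward
#' the reading. A reading equal to the model prediction leaves `d_fast`
#' unchanged and, once `b_slow` has converged to the implied basal, leaves
#' `b_slow` unchanged too. Stale readings are rejected with a warning.
#'
#' @param mst `mpc_state`.
#' @param reading list(time, value, source) from the sensing module.
#' @return updated `mpc_state`.
#' @export
mpc_ingest <- function(mst, reading) {
  hist <- mst$history
  if (nrow(hist) > 0 && reading$time <= hist$time[nrow(hist)]) {
    warning("stale reading rejected")
    return(mst)
  }
  mst <- .mpc_propagate(mst, reading$time)
  cfg <- mst$cfg
  p <- mst$params
  if (nrow(hist) == 0) {
    # First reading: initialise the observer in a stationary configuration
    # at the observed glucose under the currently running insulin rate, so
    # adaptation starts from "the baby is steady where we find it" rather
    # than from the setpoint.
    q1 <- max(reading$value, 0.1) * MGDL_PER_MMOL * p$v_g
    ip <- mst$last_insulin * 1000 / 60 / (p$v_i * p$k_e)
    x <- p$si_base * ip
    egp <- p$egp0 * max(0, 1 - x / p$x_egp)
    mst$model <- patient_state(q1 = q1, q2 = p$k12 / p$k21 * q1, ip = ip,
                               x = x, gisf = reading$value)
    mst$d_fast <- max(0, p$f01 + p$s_mult * x * q1 - egp)
    mst$history <- data.frame(time = reading$time, value = reading$value,
                              source = reading$source,
                              stringsAsFactors = FALSE)
    return(mst)
  }
  dt <- reading$time - hist$time[nrow(hist)]
  dt <- max(dt, 1)
  e <- reading$value - mst$model[["gisf"]]
  e_q1 <- e * MGDL_PER_MMOL * p$v_g
  f_inn <- e_q1 / max(dt, cfg$predict_dt) # flux that explains the error
  lam_f <- min(1, dt / cfg$tau_fast)
  mst$d_fast <- mst$d_fast + lam_f * f_inn
  lam_s <- min(1, dt / cfg$tau_slow)
  mst$b_slow <- max(0, mst$b_slow +
                      lam_s * (.mpc_implied_basal(mst) - mst$b_slow))
  a <- cfg$anchor_gain
  mst$model[["q1"]] <- max(0, mst$model[["q1"]] + a * e_q1)
  mst$model[["gisf"]] <- max(0, mst$model[["gisf"]] + a * e)
  mst$history <- rbind(utils::tail(hist, 47),
                       data.frame(time = reading$time, value = reading$value,
                                  source = reading$source,
                                  stringsAsFactors = FALSE))
  mst
}

#' Predict sensor-glucose trajectories under candidate infusion rates
#'
#' Integrates the internal model forward with the flux correction held
#' constant and a candidate insulin (and optionally dextrose) rate applied,
#' at `predict_dt` resolution. Vectorised over candidates.
#'
#' @param mst `mpc_state`.
#' @param insulin_rate candidate insulin rate(s), U/kg/h.
#' @param horizon prediction horizon, min (> 0, multiple of `predict_dt`;
#'   horizon 0 returns the current model glucose).
#' @param dex_rate candidate 20% dextrose rate(s), mL/kg/h (recycled
#'   against `insulin_rate`).
#' @return matrix of predicted sensor glucose, candidates x time points
#'   (t = 0, predict_dt, ..., horizon), mmol/L.
#' @export
mpc_predict <- function(mst, insulin_rate, horizon, dex_rate = 0) {
  cfg <- mst$cfg
  n <- max(length(insulin_rate), length(dex_rate))
  insulin_rate <- rep_len(insulin_rate, n)
  dex_rate <- rep_len(dex_rate, n)
  steps <- if (horizon <= 0) 0 else ceiling(horizon / cfg$predict_dt)
  out <- matrix(0, n, steps + 1)
  s <- lapply(unname(as.list(mst$model)), rep_len, n)
  out[, 1] <- s[[5]]
  if (steps == 0) return(out)
  flux <- mst$d_fast + dextrose_to_flux(dex_rate, 20)
  u_mU <- insulin_rate * 1000 / 60
  for (k in seq_len(steps)) {
    s <- .rk4(s, mst$params, flux, u_mU, cfg$predict_dt)
    out[, k + 1] <- s[[5]]
  }
  out
}

#' Choose the insulin rate (90-min predictive grid search)
#'
#' Evaluates every deliverable rate in \[0, `max_insulin`\] at the pump
#' resolution; the cost is the sum over the predicted trajectory of the
#' squared deviation from the setpoint, weighted by `hypo_weight` below
#' `hypo_thresh`. Ties go to the lower rate.
#'
#' @param mst `mpc_state`.
#' @return insulin rate, U/kg/h.
#' @export
mpc_insulin <- function(mst) {
  cfg <- mst$cfg
  if (mst$mode == "hold") return(mst$last_insulin)
  cands <- seq(0, cfg$max_insulin, by = cfg$insulin_step)
  traj <- mpc_predict(mst, cands, cfg$horizon_insulin)
  dev <- traj - cfg$setpoint
  w <- ifelse(traj < cfg$hypo_thresh, cfg$hypo_weight, 1)
  cost <- rowSums(w * dev^2)
  cands[which.min(cost)]
}

#' Choose the 20% dextrose rescue rate (30-40 min horizon)
#'
#' If the predicted sensor-glucose minimum over minutes 30-40 under zero
#' insulin falls below `dex_trigger`, returns the smallest grid rate that
#' lifts that minimum above `dex_target` (the cap if none does); otherwise 0.
#'
#' @param mst `mpc_state`.
#' @return dextrose rate, mL/kg/h.
#' @export
mpc_dextrose <- function(mst) {
  cfg <- mst$cfg
  if (mst$mode == "hold") return(mst$last_dex)
  win <- cfg$dex_window
  idx <- (win[1] / cfg$predict_dt):(win[2] / cfg$predict_dt) + 1
  base <- mpc_predict(mst, 0, win[2])
  if (min(base[1, idx]) >= cfg$dex_trigger) return(0)
  cands <- seq(0, cfg$dex_max, by = cfg$dex_step)
  traj <- mpc_predict(mst, 0, win[2], dex_rate = cands)
  winmin <- apply(traj[, idx, drop = FALSE], 1, min)
  ok <- which(winmin > cfg$dex_target)
  if (length(ok) == 0) cfg$dex_max else cands[min(ok)]
}

#' Convert an insulin rate to a pump rate
#'
#' @param rate insulin rate, U/kg/h.
#' @param concentration syringe concentration, U/kg per 50 mL (5 during
#'   closed loop, 25 on the ward).
#' @param resolution pump rate resolution, mL/h.
#' @return pump rate, mL/h, quantised to `resolution`.
#' @export
rate_to_pump <- function(rate, concentration = 5, resolution = 0.1) {
  if (concentration <= 0) stop("concentration must be > 0")
  round(rate / (concentration / 50) / resolution) * resolution
}

#' Run one 15-minute controller cycle
#'
#' Ingests the newest reading (sensor glucose preferred; hourly blood
#' glucose sustains dosing for up to 4 h of sensor loss, after which the
#' controller holds the last rates and raises an alarm). Dextrose rescue
#' takes priority and forces insulin to zero; otherwise insulin is chosen
#' by [mpc_insulin()] and additionally withheld whenever the 40-min
#' predicted minimum under the chosen rate falls below the safety floor, so
#' no emitted action ever has insulin and dextrose simultaneously positive.
#'
#' @param mst `mpc_state`.
#' @param t cycle time, min; must lie on the 15-min grid.
#' @param sg sensor reading (list) or NULL if unavailable.
#' @param bg blood-glucose reading (list) or NULL.
#' @return list(state = updated `mpc_state`, action = list with
#'   `insulin_rate`, `dextrose20_rate` (U/kg/h, mL/kg/h),
#'   `pump_rate_insulin`, `pump_rate_dextrose` (mL/h), `mode`, `event`,
#'   and `pred_min40`, the 40-min predicted minimum under the emitted
#'   insulin rate).
#' @export
mpc_cycle <- function(mst, t, sg = NULL, bg = NULL) {
  if (t %% 15 != 0) stop("cycle times must lie on the 15-min grid")
  cfg <- mst$cfg
  event <- ""
  if (!is.null(sg)) {
    mst$mode <- "sg"
    mst$fallback_started <- NA_real_
    mst <- mpc_ingest(mst, sg)
  } else {
    if (is.na(mst$fallback_started)) mst$fallback_started <- t
    if (t - mst$fallback_started >= cfg$fallback_max_min) {
      if (mst$mode != "hold") event <- "hold_alarm"
      mst$mode <- "hold"
    } else if (!is.null(bg)) {
      mst$mode <- "bg_fallback"
      mst <- mpc_ingest(mst, bg)
      event <- "bg_fallback"
    } else if (mst$mode == "sg") {
      mst$mode <- "bg_fallback"
      event <- "bg_fallback"
    }
  }
  mst <- .mpc_propagate(mst, t)
  if (mst$mode == "hold") {
    ins <- mst$last_insulin
    dex <- mst$last_dex
    pred_min <- NA_real_
  } else {
    dex <- mpc_dextrose(mst)
    if (dex > 0) {
      ins <- 0
      pred_min <- min(mpc_predict(mst, 0, 40, dex_rate = dex))
    } else {
      ins <- mpc_insulin(mst)
      pred_min <- min(mpc_predict(mst, ins, 40))
      if (pred_min < cfg$safety_floor) {
        ins <- 0
        pred_min <- min(mpc_predict(mst, 0, 40))
      }
    }
  }
  pump_i <- rate_to_pump(ins, 5)
  w_kg <- mst$weight_g / 1000
  pump_d <- round(dex * w_kg / 0.1) * 0.1
  dex_eff <- if (dex > 0 && pump_d == 0) 0.1 / w_kg else pump_d / w_kg
  mst$last_insulin <- ins
  mst$last_dex <- dex_eff
  list(state = mst,
       action = list(insulin_rate = ins, dextrose20_rate = dex_eff,
                     pump_rate_insulin = pump_i,
                     pump_rate_dextrose = if (dex > 0) max(pump_d, 0.1) else 0,
                     mode = mst$mode, event = event, pred_min40 = pred_min))
}
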