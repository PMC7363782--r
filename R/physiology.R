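# Glucose-insulin compartment model of one virtual preterm infant.
#
# Two glucose mass compartments (accessible q1, non-accessible q2, mg/kg),
# a single plasma-insulin pool (intravenous infusion, first-order
# elimination), a remote insulin-action compartment driving both glucose
# utilisation and suppression of endogenous glucose production (EGP), and a
# first-order plasma-to-interstitium lag for the sensor-visible glucose.
#
# Unit conventions (package-wide): glucose mmol/L (x 18.016 to mg/dL),
# insulin U/kg/h externally and mU/kg/min internally, time in minutes.

MGDL_PER_MMOL <- 18.016

#' Physiology parameters of a virtual preterm infant
#'
#' Defaults describe an extremely preterm infant (<1200 g). They are
#' configurable population defaults, not measurements from any one study:
#' endogenous glucose production at zero insulin action (`egp0`) 4 mg/kg/min,
#' insulin-independent utilisation (`f01`) 2.5 mg/kg/min, glucose distribution
#' volume 1.6 dL/kg, plasma insulin half-life ~10 min, insulin action
#' activation 1/40 min^-1, plasma-to-interstitial lag 10 min.
#'
#' @param si_base baseline insulin sensitivity: steady-state fractional
#'   glucose clearance per unit plasma insulin, 1/min per mU/L.
#' @param s_mult dimensionless, time-varying multiplier on insulin action
#'   (median 1 at baseline; evolved by [evolve_sensitivity()]).
#' @param v_g glucose distribution volume, dL/kg.
#' @param f01 insulin-independent glucose utilisation, mg/kg/min.
#' @param egp0 endogenous glucose production at zero insulin action, mg/kg/min.
#' @param k12,k21 glucose inter-compartment transfer rates, 1/min.
#' @param k_a insulin-action activation rate, 1/min.
#' @param k_e plasma-insulin elimination rate, 1/min (default t1/2 = 10 min).
#' @param v_i insulin distribution volume, L/kg.
#' @param x_egp insulin action at which EGP is fully suppressed, 1/min.
#' @param tau_isf plasma-to-interstitial glucose lag, min (must be in 5-20).
#' @return list of parameters with class `preterm_params`.
#' @export
preterm_params <- function(si_base = 5e-4, s_mult = 1,
                           v_g = 1.6, f01 = 2.5, egp0 = 4,
                           k12 = 0.066, k21 = 0.033,
                           k_a = 1 / 40, k_e = log(2) / 10, v_i = 0.12,
                           x_egp = 0.05, tau_isf = 10) {
  p <- list(si_base = si_base, s_mult = s_mult, v_g = v_g, f01 = f01,
            egp0 = egp0, k12 = k12, k21 = k21, k_a = k_a, k_e = k_e,
            v_i = v_i, x_egp = x_egp, tau_isf = tau_isf)
  if (any(unlist(p) < 0)) stop("all physiology parameters must be >= 0")
  if (tau_isf < 5 || tau_isf > 20) stop("tau_isf must lie in [5, 20] min")
  class(p) <- "preterm_params"
  p
}

#' Create a patient state vector
#'
#' @param q1 accessible glucose mass, mg/kg.
#' @param q2 non-accessible glucose mass, mg/kg.
#' @param ip plasma insulin, mU/L.
#' @param x remote insulin action, 1/min.
#' @param gisf interstitial glucose, mmol/L.
#' @return named numeric vector.
#' @export
patient_state <- function(q1, q2 = 0, ip = 0, x = 0, gisf = 0) {
  s <- c(q1 = q1, q2 = q2, ip = ip, x = x, gisf = gisf)
  if (any(s < 0)) stop("all state components must be >= 0")
  s
}

#' Infusion and nutrition inputs to the model
#'
#' @param insulin_u_kg_h intravenous insulin rate, U/kg/h.
#' @param dextrose20_ml_kg_h 20% dextrose rescue rate, mL/kg/h.
#' @param maintenance_dextrose parenteral dextrose, mg/kg/min.
#' @param enteral_carb trophic feed carbohydrate, mg/kg/min.
#' @return list of non-negative rates.
#' @export
infusion_input <- function(insulin_u_kg_h = 0, dextrose20_ml_kg_h = 0,
                           maintenance_dextrose = 0, enteral_carb = 0) {
  inp <- list(insulin_u_kg_h = insulin_u_kg_h,
              dextrose20_ml_kg_h = dextrose20_ml_kg_h,
              maintenance_dextrose = maintenance_dextrose,
              enteral_carb = enteral_carb)
  if (any(unlist(inp) < 0)) stop("all infusion rates must be >= 0")
  inp
}

#' Convert a dextrose infusion rate to a carbohydrate flux
#'
#' A `concentration`% w/v solution carries `concentration * 10` mg of
#' glucose per mL, so flux (mg/kg/min) = rate (mL/kg/h) x concentration x
#' 10 / 60.
#'
#' @param rate infusion rate, mL/kg/h.
#' @param concentration dextrose concentration, percent w/v (20 for the
#'   rescue solution used here).
#' @return glucose flux, mg/kg/min.
#' @export
dextrose_to_flux <- function(rate, concentration = 20) {
  if (any(rate < 0)) stop("dextrose rate must be >= 0")
  if (concentration <= 0 || concentration > 100)
    stop("concentration must be in (0, 100]")
  rate * concentration * 10 / 60
}

# Core derivative kernel. Operates element-wise so the controller can
# propagate many candidate trajectories at once; q1..gisf may be vectors.
# flux_in: total exogenous glucose flux mg/kg/min; u_mU: insulin mU/kg/min.
.deriv <- function(q1, q2, ip, x, gisf, p, flux_in, u_mU) {
  egp <- p$egp0 * pmax(0, 1 - x / p$x_egp)
  dq1 <- flux_in + egp - p$f01 - p$s_mult * x * q1 - p$k12 * q1 + p$k21 * q2
  dq2 <- p$k12 * q1 - p$k21 * q2
  dip <- u_mU / p$v_i - p$k_e * ip
  dx <- p$k_a * (p$si_base * ip - x)
  dgisf <- (q1 / (p$v_g * MGDL_PER_MMOL) - gisf) / p$tau_isf
  list(dq1, dq2, dip, dx, dgisf)
}

#' Time derivatives of the patient state
#'
#' Glucose appearance is the sum of maintenance dextrose, 20% dextrose
#' rescue and enteral carbohydrate plus EGP, which is suppressed linearly in
#' insulin action (fully suppressed at `x_egp`). Utilisation is `f01` plus
#' the insulin-mediated term `s_mult * x * q1`. Interstitial glucose relaxes
#' to plasma glucose with time constant `tau_isf`.
#'
#' @param state patient state vector from [patient_state()].
#' @param params [preterm_params()] list.
#' @param inputs [infusion_input()] list.
#' @return named numeric vector of d(state)/dt, per minute.
#' @export
derivatives <- function(state, params, inputs) {
  flux <- inputs$maintenance_dextrose + inputs$enteral_carb +
    dextrose_to_flux(inputs$dextrose20_ml_kg_h, 20)
  u_mU <- inputs$insulin_u_kg_h * 1000 / 60
  d <- .deriv(state[["q1"]], state[["q2"]], state[["ip"]], state[["x"]],
              state[["gisf"]], params, flux, u_mU)
  c(q1 = d[[1]], q2 = d[[2]], ip = d[[3]], x = d[[4]], gisf = d[[5]])
}

# One vectorised RK4 update of the 5 state components (lists of vectors in,
# list of vectors out); clamps negatives to zero.
.rk4 <- function(s, p, flux_in, u_mU, dt) {
  k1 <- .deriv(s[[1]], s[[2]], s[[3]], s[[4]], s[[5]], p, flux_in, u_mU)
  h <- dt / 2
  k2 <- .deriv(s[[1]] + h * k1[[1]], s[[2]] + h * k1[[2]], s[[3]] + h * k1[[3]],
               s[[4]] + h * k1[[4]], s[[5]] + h * k1[[5]], p, flux_in, u_mU)
  k3 <- .deriv(s[[1]] + h * k2[[1]], s[[2]] + h * k2[[2]], s[[3]] + h * k2[[3]],
               s[[4]] + h * k2[[4]], s[[5]] + h * k2[[5]], p, flux_in, u_mU)
  k4 <- .deriv(s[[1]] + dt * k3[[1]], s[[2]] + dt * k3[[2]], s[[3]] + dt * k3[[3]],
               s[[4]] + dt * k3[[4]], s[[5]] + dt * k3[[5]], p, flux_in, u_mU)
  w <- dt / 6
  lapply(1:5, function(i) {
    pmax(0, s[[i]] + w * (k1[[i]] + 2 * k2[[i]] + 2 * k3[[i]] + k4[[i]]))
  })
}

#' Advance the patient state by one time step
#'
#' Classical 4th-order Runge-Kutta with fixed step. Any state component that
#' would become negative is clamped to zero (optionally with a warning), so
#' long simulations never abort on a transient undershoot.
#'
#' @inheritParams derivatives
#' @param dt step, min; must satisfy 0 < dt <= 1.
#' @param warn_clamp warn when a component is clamped to zero.
#' @return updated state vector.
#' @export
step <- function(state, params, inputs, dt, warn_clamp = FALSE) {
  if (dt <= 0 || dt > 1) stop("dt must satisfy 0 < dt <= 1 min")
  flux <- inputs$maintenance_dextrose + inputs$enteral_carb +
    dextrose_to_flux(inputs$dextrose20_ml_kg_h, 20)
  u_mU <- inputs$insulin_u_kg_h * 1000 / 60
  s <- list(state[["q1"]], state[["q2"]], state[["ip"]], state[["x"]],
            state[["gisf"]])
  out <- .rk4(s, params, flux, u_mU, dt)
  if (warn_clamp && any(unlist(out) == 0)) {
    k1 <- .deriv(s[[1]], s[[2]], s[[3]], s[[4]], s[[5]], params, flux, u_mU)
    euler <- unlist(lapply(1:5, function(i) s[[i]] + dt * k1[[i]]))
    if (any(euler < 0)) warning("state component clamped to zero")
  }
  c(q1 = out[[1]], q2 = out[[2]], ip = out[[3]], x = out[[4]], gisf = out[[5]])
}

#' Plasma glucose concentration of a state
#'
#' @inheritParams derivatives
#' @return plasma glucose, mmol/L (`q1 / v_g` mg/dL divided by 18.016).
#' @export
plasma_glucose <- function(state, params) {
  state[["q1"]] / (params$v_g * MGDL_PER_MMOL)
}

#' Solve for the steady state holding plasma glucose at a target
#'
#' Inverts the model's fixed-point equations: given the nutrition inputs
#' (insulin ignored), finds the remote insulin action, plasma insulin and
#' basal insulin rate that keep plasma glucose exactly at `target`. Used as
#' an oracle for controller tests and to initialise mid-protocol runs.
#'
#' @param params [preterm_params()].
#' @param target target plasma glucose, mmol/L.
#' @param inputs [infusion_input()]; its insulin component is ignored.
#' @param extra_flux additional glucose flux added to appearance, mg/kg/min
#'   (the controller uses this for its adaptive flux correction).
#' @return list with `state` (derivatives ~ 0 at the returned basal rate),
#'   `basal_insulin` (U/kg/h) and `reachable` (FALSE when the target would
#'   require negative insulin; then the basal is reported as 0).
#' @export
steady_state <- function(params, target, inputs = infusion_input(),
                         extra_flux = 0) {
  p <- params
  q1 <- target * MGDL_PER_MMOL * p$v_g
  q2 <- if (p$k21 > 0) p$k12 / p$k21 * q1 else 0
  flux <- inputs$maintenance_dextrose + inputs$enteral_carb +
    dextrose_to_flux(inputs$dextrose20_ml_kg_h, 20) + extra_flux
  # EGP active branch: flux + egp0 (1 - x/x_egp) = f01 + s q1 x
  x <- (flux + p$egp0 - p$f01) / (p$s_mult * q1 + p$egp0 / p$x_egp)
  if (x > p$x_egp) x <- (flux - p$f01) / (p$s_mult * q1) # EGP fully off
  reachable <- x >= 0
  if (!reachable) x <- 0
  ip <- if (p$si_base > 0) x / p$si_base else 0
  basal <- ip * p$v_i * p$k_e * 60 / 1000
  list(state = patient_state(q1 = q1, q2 = q2, ip = ip, x = x, gisf = target),
       basal_insulin = if (reachable) basal else 0,
       reachable = reachable)
}

#' Evolve the insulin-sensitivity multiplier (log Ornstein-Uhlenbeck)
#'
#' Insulin sensitivity in extremely preterm infants varies strongly over
#' hours (sepsis, inotropes, maturation). The multiplier follows a
#' mean-reverting log-OU process whose stationary median equals `baseline`.
#' `volatility` is the coefficient of variation the diffusion would
#' accumulate over 24 h without reversion; the stationary CV implied jointly
#' by `volatility` and `reversion_time` is given by
#' [sensitivity_stationary_cv()]. Uses the exact OU transition, so any `dt`
#' is unbiased.
#'
#' @param s_i current multiplier (> 0).
#' @param dt elapsed time, min.
#' @param volatility CV per 24 h of the driving diffusion (0 = frozen).
#' @param reversion_time mean-reversion time constant, min.
#' @param baseline stationary median (default 1).
#' @return updated multiplier.
#' @export
evolve_sensitivity <- function(s_i, dt, volatility, reversion_time,
                               baseline = 1) {
  if (s_i <= 0) stop("s_i must be > 0")
  if (volatility == 0) return(s_i)
  if (reversion_time <= 0) return(baseline)
  sig_day <- sqrt(log(1 + volatility^2)) # SD of log accumulated per 1440 min
  a <- exp(-dt / reversion_time)
  sd_st <- sig_day * sqrt(reversion_time / (2 * 1440))
  m <- log(baseline)
  exp(m + (log(s_i) - m) * a + sd_st * sqrt(1 - a^2) * stats::rnorm(1))
}

#' Stationary CV of the sensitivity multiplier
#'
#' Closed-form stationary coefficient of variation of the log-OU process in
#' [evolve_sensitivity()].
#'
#' @inheritParams evolve_sensitivity
#' @return stationary CV (dimensionless).
#' @export
sensitivity_stationary_cv <- function(volatility, reversion_time) {
  sig_day <- sqrt(log(1 + volatility^2))
  sd_st <- sig_day * sqrt(reversion_time / (2 * 1440))
  sqrt(exp(sd_st^2) - 1)
}
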