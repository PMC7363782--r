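# Shared builders for the test suite. Everything is generated in code; no
# stored fixtures.

# A quiet, deterministic window-only protocol (noiseless sensor and meter,
# no dropouts): the physiology and controller are then exactly observable.
quiet_protocol <- function(total_h = 60, start_h = 48,
                           window_h = c(48, 60), ...) {
  protocol(total_h = total_h, start_h = start_h, window_h = window_h,
           noise_cv = 0, gain_sd = 0, drift_max = 0, meter_sd = 0,
           dropout_rate = 0, ...)
}

# One-row profile with controllable physiology, bypassing cohort sampling.
make_profile <- function(id = "tst01", si_base = 5e-4, si_volatility = 0,
                         maintenance_dextrose = 8.4, baseline_sg = 8,
                         bw_g = 960, trophic_carb = 0) {
  data.frame(id = id, ga_weeks = 27, bw_g = bw_g, sex = "female",
             si_base = si_base, si_volatility = si_volatility,
             si_reversion_h = 6, egp0 = 4,
             maintenance_dextrose = maintenance_dextrose,
             trophic_carb = trophic_carb, protein_g_kg_d = 3.2,
             lipid_g_kg_d = 1.8, baseline_sg = baseline_sg,
             stringsAsFactors = FALSE)
}

# Worst per-category between-arm imbalance for an arbitrary arm vector
# (independent re-implementation of the audit, used as the brute-force
# oracle).
brute_imbalance <- function(coh, arms, ga_cuts = c(26, 28),
                            bw_cuts = c(750, 1000)) {
  worst <- 0
  for (f in list(findInterval(coh$ga_weeks, ga_cuts),
                 findInterval(coh$bw_g, bw_cuts))) {
    for (cat in unique(f)) {
      worst <- max(worst, abs(sum(arms[f == cat] == 1) -
                                sum(arms[f == cat] == 2)))
    }
  }
  worst
}

# Exact two-sided Mann-Whitney p by full enumeration of allocations.
perm_mw_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  m <- nx * length(y) / 2
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  idx <- utils::combn(length(pooled), nx)
  us <- apply(idx, 2, function(ii) {
    a <- pooled[ii]; b <- pooled[-ii]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  })
  mean(abs(us - m) >= abs(u_obs - m) - 1e-12)
}
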