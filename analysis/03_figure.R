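#!/usr/bin/env Rscript
# Summary figure: median (IQR) sensor glucose and insulin infusion over
# time by arm, with the intervention window and the 4-8 mmol/L target band
# marked. Reads results/trial/; writes results/figure_glucose_control.pdf.

suppressMessages(library(neoloop))

ds <- load_dataset(file.path("results", "trial"))

grid_h <- seq(0, 160, by = 1)
arm_series <- function(arm, col) {
  recs <- ds$records[sapply(ds$records, function(r) r$arm == arm)]
  sapply(grid_h, function(h) {
    vals <- unlist(lapply(recs, function(r) {
      sel <- r$rows$time_min >= h * 60 & r$rows$time_min < (h + 1) * 60
      r$rows[[col]][sel]
    }))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) c(NA, NA, NA) else
      stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
  })
}

pdf(file.path("results", "figure_glucose_control.pdf"), width = 8, height = 7)
par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
cols <- c(closed_loop = "#1b6ca8", control = "#c0392b")
plot(NULL, xlim = c(0, 160), ylim = c(2, 14), xlab = "Hours after birth",
     ylab = "Sensor glucose (mmol/L)", main = "Median (IQR) sensor glucose")
rect(0, 4, 160, 8, col = grDevices::adjustcolor("grey80", 0.4), border = NA)
abline(v = c(48, 72), lty = 2)
for (arm in names(cols)) {
  q <- arm_series(arm, "sg")
  polygon(c(grid_h, rev(grid_h)), c(q[1, ], rev(q[3, ])),
          col = grDevices::adjustcolor(cols[arm], 0.25), border = NA)
  lines(grid_h, q[2, ], col = cols[arm], lwd = 2)
}
legend("topright", legend = c("closed loop", "control"),
       col = cols, lwd = 2, bty = "n")
plot(NULL, xlim = c(0, 160), ylim = c(0, 0.2), xlab = "Hours after birth",
     ylab = "Insulin (U/kg/h)", main = "Median (IQR) insulin infusion")
abline(v = c(48, 72), lty = 2)
for (arm in names(cols)) {
  q <- arm_series(arm, "insulin_u_kg_h")
  polygon(c(grid_h, rev(grid_h)), c(q[1, ], rev(q[3, ])),
          col = grDevices::adjustcolor(cols[arm], 0.25), border = NA)
  lines(grid_h, q[2, ], col = cols[arm], lwd = 2)
}
invisible(dev.off())
message("Figure written to results/figure_glucose_control.pdf")
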