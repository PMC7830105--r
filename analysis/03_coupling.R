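#!/usr/bin/env Rscript
# Step 3: the core coupling analysis for one subject. Extracts respiratory
# and cardiac phases from all three channels, runs windowed dynamical
# Bayesian inference (K = 2, 50-s windows) for all 9 directed
# respiration->cardiac pairs, and writes per-window and per-stage tables
# plus the stage-averaged coupling-function grids under results/report/.
# Run analysis/01_simulate.R first.

suppressMessages(library(phasecf))

rec <- read_recording("results/sim/recording.csv")
proto <- read_protocol("results/sim/protocol.csv")
cfg <- run_config()

an <- analyze_recording(rec, proto, cfg)
build_report(an, "results/report")

cat("Directed pair summary (per-stage median of coupling strength sigma\n")
cat("into the cardiac oscillator, and median directionality D):\n")
for (p in names(an$pairs)) {
  s <- an$pairs[[p]]$stage_sigma
  d <- an$pairs[[p]]$stage_D
  cat(sprintf("  %-22s sigma A=%.2f B=%.2f C=%.2f D=%.2f | D(t) median %.2f\n",
              p, s["A"], s["B"], s["C"], s["D"],
              stats::median(an$pairs[[p]]$windows$D, na.rm = TRUE)))
}
neg <- mean(unlist(lapply(an$pairs, function(x) x$windows$D)) < 0,
            na.rm = TRUE)
cat(sprintf("Fraction of windows with D < 0 (respiration drives cardiac): %.3f\n",
            neg))
cat("Report bundle written under results/report/\n")
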