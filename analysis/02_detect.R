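#!/usr/bin/env Rscript
# Step 2: detect and classify events on the simulated recordings.
#
# Runs the discharge detector on both in-vivo channels (2-200 Hz Bessel
# band-pass, spikes at >= 2x the rolling background amplitude, >= 10 s
# rule, LVF back-extension and onset classification) and the three in-vitro
# detectors on the slice trace, then scores everything against the planted
# ground truth.

suppressMessages(library(ictalwave))

sim <- "results/simulated"
out <- "results/detection"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

score <- function(det, gt) {
  hit <- vapply(seq_len(nrow(gt)), function(i)
    any(det$onset_s < gt$termination_s[i] & det$termination_s > gt$onset_s[i]),
    logical(1))
  fp <- vapply(seq_len(nrow(det)), function(i)
    !any(gt$onset_s < det$termination_s[i] & gt$termination_s > det$onset_s[i]),
    logical(1))
  sprintf("recall %.2f, precision %.2f", mean(hit),
          1 - ifelse(nrow(det), mean(fp), 0))
}

cat("== in-vivo discharges ==\n")
for (ch in c("kindled", "unstim")) {
  x <- read_trace(file.path(sim, sprintf("invivo_%s.csv", ch)))
  gt <- read_events(file.path(sim, sprintf("invivo_%s_truth.csv", ch)))
  ev <- detect_discharges(x)
  cat(sprintf("%s: %d detected of %d planted (%s)\n", ch, nrow(ev), nrow(gt),
              score(ev, gt)))
  print(ev[, c("onset_s", "termination_s", "duration_s", "onset_class",
               "lvf_norm_sd_pct", "suppressed")], digits = 4)
  write.csv(ev, file.path(out, sprintf("discharges_%s.csv", ch)),
            row.names = FALSE)
}

cat("\n== LVF quantification on the kindled channel ==\n")
x <- read_trace(file.path(sim, "invivo_kindled.csv"))
ev <- read.csv(file.path(out, "discharges_kindled.csv"))
lvf <- ev[ev$onset_class == "LVF", ]
for (i in seq_len(nrow(lvf))) {
  m <- quantify_lvf(x, NULL, c(lvf$onset_s[i],
                               lvf$first_spike_s[i] - lvf$onset_s[i] - 0.1))
  cat(sprintf("event at %.1f s: LVF window %.1f s, normalized SD %.0f%%\n",
              lvf$onset_s[i], m$lvf_length_s, m$normalized_sd_pct))
}

cat("\n== in-vitro slice events ==\n")
slice <- read_trace(file.path(sim, "slice.csv"))
gt <- read_events(file.path(sim, "slice_truth.csv"))
res <- detect_slice_events(slice)
for (kind in c("SPW", "INTERICTAL", "ICTAL")) {
  det <- switch(kind, SPW = res$spw, INTERICTAL = res$interictal,
                ICTAL = res$ictal)
  cat(sprintf("%s: %d detected of %d planted (%s)\n", kind, nrow(det),
              sum(gt$kind == kind), score(det, gt[gt$kind == kind, ])))
  write_events(det, file.path(out, sprintf("slice_%s.csv", tolower(kind))))
}
cat(sprintf("slice classified ictal-bearing: %s\n", res$ictal_bearing))
cat("\nwrote", out, "\n")
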