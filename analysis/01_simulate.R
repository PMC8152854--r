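#!/usr/bin/env Rscript
# Step 1: build the synthetic study.
#
# Emulates the recording setup the pipeline targets: a two-channel in-vivo
# recording (kindled hippocampus vs an unstimulated structure) carrying
# concurrent spontaneous discharges with LVF/HYP onsets plus a movement
# artifact, and an in-vitro slice recording carrying sharp waves,
# interictal spikes and ictal discharges. Traces and ground truth go to
# results/simulated/ for the later steps.

suppressMessages(library(ictalwave))

out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260922
fs <- 500   # in-vivo analysis rate: the discharge band of interest is < 200 Hz

cat("== simulating the two-channel in-vivo recording ==\n")
onsets <- c(60, 180, 320, 460)
durs <- c(30, 45, 25, 40)
cls <- c("LVF", "LVF", "HYP", "LVF")

mk_channel <- function(ch_seed, label, jitter) {
  x <- generate_background(synth_config(560, fs = fs, seed = ch_seed,
                                        channel = label))
  gt <- list()
  for (i in seq_along(onsets)) {
    r <- inject_discharge(
      x, discharge_spec(onsets[i] + jitter[i], durs[i], cls[i],
                        lvf_attenuation = 0.4 + 0.03 * i),
      seed = ch_seed + i)
    x <- r$trace
    gt[[i]] <- r$event
  }
  list(trace = x, gt = do.call(rbind, gt))
}

a <- mk_channel(seed, "kindled_hippo", jitter = rep(0, 4))
b <- mk_channel(seed + 1, "unstim_site", jitter = c(0.2, 0.15, 0.1, 0.25))
# one discharge decipherable only in the kindled channel
extra <- inject_discharge(a$trace, discharge_spec(530, 15, "HYP"),
                          seed = seed + 9)
a$trace <- extra$trace
a$gt <- rbind(a$gt, extra$event)
# a movement artifact during the second discharge
art <- inject_artifact(a$trace, times = 195, magnitude = 25, width = 0.3)
a$trace <- art$trace

write_trace(a$trace, file.path(out, "invivo_kindled.csv"))
write_trace(b$trace, file.path(out, "invivo_unstim.csv"))
write_edf(list(a$trace, b$trace), file.path(out, "invivo_pair.edf"))
write_events(a$gt, file.path(out, "invivo_kindled_truth.csv"))
write_events(b$gt, file.path(out, "invivo_unstim_truth.csv"))
cat(sprintf("planted %d + %d discharges (one single-channel), artifact at 195 s\n",
            nrow(a$gt), nrow(b$gt)))

cat("\n== simulating the slice recording ==\n")
slice <- generate_slice_trace(
  list(slice_event_spec("SPW", amplitude_rel = 6, base_duration = 0.05,
                        rate = 1, window = c(0, 145)),
       slice_event_spec("INTERICTAL", amplitude_mv = 0.7,
                        base_duration = 0.3, rate = 0.3,
                        window = c(0, 145)),
       slice_event_spec("ICTAL", amplitude_mv = 1.5, base_duration = 40,
                        interevent_interval = 120, window = c(150, 450))),
  synth_config(450, fs = 1000, seed = seed + 2, background_sd = 0.05))
write_trace(slice$trace, file.path(out, "slice.csv"))
write_events(slice$events, file.path(out, "slice_truth.csv"))
cat(sprintf("planted %s\n",
            paste(names(table(slice$events$kind)), table(slice$events$kind),
                  sep = ": ", collapse = ", ")))
cat("\nwrote", out, "\n")
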