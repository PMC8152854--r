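# shared fixtures: small synthetic traces built in code

# background + one discharge, 500 Hz
make_discharge_trace <- function(onset = 40, dur = 30, cls = "LVF",
                                 att = 0.4, lvf_len = 2, seed = 11,
                                 total_s = 120, fs = 500) {
  bgr <- generate_background(synth_config(total_s, fs = fs, seed = seed))
  inject_discharge(bgr,
                   discharge_spec(onset, dur, cls, lvf_attenuation = att,
                                  lvf_length = lvf_len),
                   seed = seed + 1)
}

# steady-state amplitude of a sinusoid-dominated trace (middle third)
mid_amp <- function(tr) {
  n <- length(tr$samples)
  max(abs(tr$samples[floor(n / 3):floor(2 * n / 3)]))
}

# overlap-based precision/recall of detected vs ground-truth intervals
pr_overlap <- function(det_on, det_off, gt_on, gt_off) {
  hit_det <- vapply(seq_along(det_on), function(i)
    any(det_on[i] < gt_off & det_off[i] > gt_on), logical(1))
  hit_gt <- vapply(seq_along(gt_on), function(i)
    any(gt_on[i] < det_off & gt_off[i] > det_on), logical(1))
  c(precision = if (length(det_on)) mean(hit_det) else NA_real_,
    recall = if (length(gt_on)) mean(hit_gt) else NA_real_)
}
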