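# Shared fixtures: compact phantoms that keep the suite fast while using the
# same generator code paths as full-scale runs.

# 5-minute recording, reperfusion at the start of minute 3
quick_spec <- function(...) {
  phantom_spec(duration = 300, injection_frame = 61, reperfusion_frame = 121,
               ...)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# flow stack built directly from per-frame healthy/ischemic values; half the
# field is each hemisphere, no background, no vessels
flat_stack <- function(healthy_vals, ischemic_vals, h = 6, w = 8,
                       injection_frame = 1,
                       reperfusion_frame = length(healthy_vals),
                       signal = "flow") {
  n <- length(healthy_vals)
  frames <- array(0, dim = c(h, w, n))
  for (t in seq_len(n)) {
    frames[, 1:(w / 2), t] <- ischemic_vals[t]
    frames[, (w / 2 + 1):w, t] <- healthy_vals[t]
  }
  perfusion_stack(frames, timestamps = seq_len(n) - 1,
                  injection_frame = injection_frame,
                  reperfusion_frame = reperfusion_frame, signal = signal)
}

flat_geometry <- function(h = 6, w = 8) {
  lab <- matrix(1L, h, w)
  lab[, 1:(w / 2)] <- 2L
  hemisphere_geometry(lab, "left")
}

empty_vessels <- function(h = 6, w = 8) {
  structure(list(mask = matrix(FALSE, h, w), threshold = Inf,
                 method = "none"),
            class = "vessel_mask")
}
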