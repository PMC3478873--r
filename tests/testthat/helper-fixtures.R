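# Shared training fixture: a long record with balanced ectopy and a short
# walking stretch, so every Layer-2 state (including Invalid) sees enough
# of its own observation symbols during supervised estimation.
training_config <- function(seed) {
  synth_config(
    duration_s = 600, pvc_rate = 0.12, apc_rate = 0.12,
    motion_schedule = data.frame(
      activity = c("standing", "walking", "standing"),
      start_s = c(0, 420, 480), end_s = c(420, 480, 600)),
    seed = seed)
}

# feasibility of a decoded path: topology respected, every run at least
# its state's minimum duration
path_is_feasible <- function(path, mask, mind) {
  runs <- rle(path)
  ok_dwell <- all(runs$lengths >= mind[runs$values])
  v <- runs$values
  ok_topo <- length(v) < 2 ||
    all(mask[cbind(v[-length(v)], v[-1])])
  ok_dwell && ok_topo
}
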