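# Shared fixtures: a small synthetic session cached per test run.

small_config <- function(...) {
  sim_config(stage_durations = c(120, 120, 120), n_neurons = 12,
             class_counts = c(SAN = 3, SIN = 2, NewPN = 2, OldPN = 2,
                              null = 3),
             seed = 42L, ...)
}

local({
  cfg <- small_config()
  ses <- simulate_behavior(cfg)
  sim <- simulate_dff(cfg, ses)
  assign("FIX_CFG", cfg, envir = topenv())
  assign("FIX_SESSION", ses, envir = topenv())
  assign("FIX_DFF", sim$dff, envir = topenv())
  assign("FIX_TRUTH", sim$truth, envir = topenv())
})

# hand-built epoch table on the imaging clock
mk_epochs <- function(start_times, end_times, event = "mouse", rate = 9.76) {
  data.frame(event = event, start_time = start_times, end_time = end_times,
             duration = end_times - start_times,
             start_frame = ceiling(start_times * rate - 1e-9),
             end_frame = ceiling(end_times * rate - 1e-9),
             stringsAsFactors = FALSE)
}
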