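# Shared fixtures and cached heavy runs.  Everything is generated in code;
# the cache keeps expensive sweeps from being recomputed across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# small, fast experiment configuration for unit-level checks
small_config <- function(...) {
  experiment_config(N = 16, fig_size = 4, n_seeds = 3, ...)
}

# default-size configuration (the study conditions)
full_config <- function(...) experiment_config(...)

# spike steps of one neuron extracted from a raster
neuron_spike_steps <- function(raster, channel, layer, row, col) {
  sel <- raster$channel == channel & raster$layer == layer &
    raster$row == row & raster$col == col
  sort(raster$step[sel])
}

fg_seg_full <- function() cached("fg_seg_full", run_fg_segregation(full_config()))

pattern_sweep_full <- function() cached("pattern_sweep_full",
  run_fg_masking(full_config(), "pattern"))

uniform_sweep_full <- function() cached("uniform_sweep_full",
  run_fg_masking(full_config(), "uniform"))

meta_accept <- function() cached("meta_accept", {
  cfg <- full_config(soa_meta = seq(-100, 200, by = 25))
  run_metacontrast(cfg, target_durations = 25, mask_durations = c(50, 100))
})

repetition_runs <- function() cached("repetition_runs", {
  cfg <- full_config()
  list(normal = run_repetition(cfg, "normal"),
       high = run_repetition(cfg, "high"))
})
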