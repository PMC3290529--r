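make_fg_raster <- function(N = 8, fig = 2, dur = 100, cfg = NULL) {
  if (is.null(cfg)) cfg <- network_config(N = N)
  fg <- make_fg_texture(N, fig)
  sch <- build_schedule(list(stim_event(1, fg$feat1, 0, Inf, cfg$w_input),
                             stim_event(2, fg$feat2, 0, Inf, cfg$w_input)),
                        duration_ms = dur, dt = cfg$dt)
  run_network(sch, cfg)
}

test_that("assemble_current implements retinotopic excitation plus pooled inhibition", {
  N <- 64
  zero <- matrix(0, N, N)
  expect_equal(assemble_current(list(list(F = zero, w_exc = 400, w_inh = -700)), N),
               zero)
  ones <- matrix(1, N, N)
  I <- assemble_current(list(list(F = ones, w_exc = 400, w_inh = -700)), N)
  expect_true(all(I == -300))
  centre <- unclass(make_fg_texture(N, 16)$feat1)
  I2 <- assemble_current(list(list(F = centre, w_exc = 400, w_inh = -700)), N)
  expect_true(all(I2[centre == 1] == 356.25))
  expect_true(all(I2[centre == 0] == -43.75))
  expect_error(assemble_current(list(list(F = matrix(2, N, N),
                                          w_exc = 1, w_inh = 0)), N), "binary")
  expect_error(assemble_current(list(list(F = matrix(0, 2, 2),
                                          w_exc = 1, w_inh = 0)), N), "shape")
})

test_that("increasing an inhibitory source's activity never increases any current", {
  N <- 8
  F_small <- matrix(0, N, N); F_small[1:2, 1] <- 1
  F_large <- F_small; F_large[1:4, 1:4] <- 1
  I_small <- assemble_current(list(list(F = matrix(0, N, N), w_exc = 400, w_inh = 0),
                                   list(F = F_small, w_exc = 0, w_inh = -700)), N)
  I_large <- assemble_current(list(list(F = matrix(0, N, N), w_exc = 400, w_inh = 0),
                                   list(F = F_large, w_exc = 0, w_inh = -700)), N)
  expect_true(all(I_large <= I_small))
})

test_that("an empty schedule yields an empty raster, reproducibly", {
  cfg <- network_config(N = 8)
  sch <- build_schedule(list(), duration_ms = 20, dt = cfg$dt)
  r <- run_network(sch, cfg)
  expect_equal(nrow(r), 0L)
})

test_that("identical runs give bit-identical rasters", {
  r1 <- make_fg_raster()
  r2 <- make_fg_raster()
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("with inhibition off, layer 2 equals single-neuron simulation of its drive", {
  # 4x4 grid, pooled inhibition disabled: every layer-2 neuron must replicate
  # simulate_neuron() driven by w_exc times its layer-1 twin's spike
  # indicator, delayed by one step
  N <- 4
  cfg <- network_config(N = N, w_inh = 0, w_input = 2.5)
  fg <- make_fg_texture(N, 2)
  dur <- 80
  sch <- build_schedule(list(stim_event(1, fg$feat1, 0, Inf, cfg$w_input),
                             stim_event(2, fg$feat2, 0, Inf, cfg$w_input)),
                        duration_ms = dur, dt = cfg$dt)
  raster <- run_network(sch, cfg)
  n_steps <- attr(raster, "n_steps")
  p <- cfg$params
  for (ch in 1:2) for (row in 1:N) for (col in 1:N) {
    s1 <- neuron_spike_steps(raster, ch, 1, row, col)
    I <- numeric(n_steps)
    s1d <- s1[s1 < n_steps] + 1L  # one-dt transmission delay
    I[s1d] <- cfg$w_exc
    expected <- simulate_neuron(I, p, dt = cfg$dt, v0 = cfg$v0, u0 = cfg$u0,
                                v_floor = cfg$v_floor)
    expect_identical(neuron_spike_steps(raster, ch, 2, row, col),
                     as.integer(expected))
  }
})

test_that("the compiled integrator matches the R reference step-by-step", {
  N <- 4
  cfg <- network_config(N = N, w_input = 2.5)
  fg <- make_fg_texture(N, 2)
  n_steps <- 250
  sch <- build_schedule(list(stim_event(1, fg$feat1, 0, Inf, cfg$w_input),
                             stim_event(2, fg$feat2, 0, Inf, cfg$w_input)),
                        duration_ms = n_steps * cfg$dt, dt = cfg$dt)
  raster <- run_network(sch, cfg)
  state <- init_network_state(cfg)
  frames <- list(cfg$w_input * unclass(fg$feat1), cfg$w_input * unclass(fg$feat2))
  ref <- list()
  for (k in seq_len(n_steps)) {
    state <- step_network(state, frames, cfg)
    for (ch in 1:2) for (layer in 1:2) {
      sp <- which(state$spikes[[ch]][[layer]] == 1, arr.ind = TRUE)
      if (nrow(sp))
        ref[[length(ref) + 1L]] <- data.frame(step = k, channel = ch,
                                              layer = layer,
                                              row = sp[, 1], col = sp[, 2])
    }
  }
  ref <- do.call(rbind, ref)
  got <- as.data.frame(raster)[, c("step", "channel", "layer", "row", "col")]
  o <- function(d) d[order(d$step, d$channel, d$layer, d$row, d$col), ]
  expect_equal(o(got), o(ref), ignore_attr = TRUE)
})

test_that("rasters inherit the 90-degree rotation symmetry of the stimulus", {
  r <- make_fg_raster(N = 8, fig = 2, dur = 80)
  N <- attr(r, "N")
  key <- function(d) sort(paste(d$step, d$channel, d$layer, d$row, d$col))
  rot <- data.frame(step = r$step, channel = r$channel, layer = r$layer,
                    row = r$col, col = N + 1L - r$row)
  expect_identical(key(as.data.frame(r)), key(rot))
})

test_that("permuting channels together with their inputs permutes the outputs", {
  cfg <- network_config(N = 8)
  fg <- make_fg_texture(8, 2)
  mk <- function(f1, f2) {
    sch <- build_schedule(list(stim_event(1, f1, 0, Inf, cfg$w_input),
                               stim_event(2, f2, 0, Inf, cfg$w_input)),
                          duration_ms = 60, dt = cfg$dt)
    run_network(sch, cfg)
  }
  a <- as.data.frame(mk(fg$feat1, fg$feat2))
  b <- as.data.frame(mk(fg$feat2, fg$feat1))
  b$channel <- 3L - b$channel
  o <- function(d) d[order(d$step, d$channel, d$layer, d$row, d$col), ]
  expect_equal(o(a), o(b), ignore_attr = TRUE)
})

test_that("a uniform field drives no early layer-2 spikes", {
  # all-ones input to one channel: every layer-2 neuron of that channel
  # receives 400 - 700 = -300 per active step and stays silent early on
  cfg <- network_config(N = 8)
  sch <- build_schedule(list(stim_event(1, make_uniform_mask(8), 0, Inf,
                                        cfg$w_input)),
                        duration_ms = 50, dt = cfg$dt)
  r <- run_network(sch, cfg)
  expect_equal(sum(r$layer == 2 & r$channel == 1), 0L)
})

test_that("schedule/config mismatches are caught", {
  cfg <- network_config(N = 8)
  sch <- build_schedule(list(), n_channels = 3, duration_ms = 10)
  expect_error(run_network(sch, cfg), "channels")
  sch2 <- build_schedule(list(), duration_ms = 10)
  expect_error(run_network(sch2, cfg, clock = simulation_clock(0.2, 100)),
               "shorter")
})
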