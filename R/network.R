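#' Network configuration
#'
#' Architecture and integration settings for the two-layer grid model.  Two
#' feature channels of N x N Izhikevich neurons are wired in two layers:
#' layer 1 is driven retinotopically by the stimulus (no inhibition), and
#' every layer-2 neuron combines point-to-point excitation from the layer-1
#' neuron at its own grid position with pooled inhibition proportional to the
#' normalized spike count of the whole source layer,
#' \deqn{I_{ij} = w_{exc} F_{ij} + w_{inh} \frac{\sum_{kl} F_{kl}}{N^2},}
#' where `F` is the previous step's layer-1 spike map (one-step transmission
#' delay).
#'
#' Two wirings are supported.  `"within"` (figure-ground experiments): each
#' layer-2 channel reads only its own channel's layer 1.  `"both"`
#' (metacontrast/repetition, the ON/OFF configuration): each layer-2 channel
#' reads both channels' layer 1, excitation and inhibition alike, with the
#' same unscaled weights.
#'
#' @param N grid side (default 64).
#' @param dt Euler step (ms, default 0.20).
#' @param w_input stimulus-to-layer-1 weight (default 2.5; the calibration is
#'   discussed in the package vignette).
#' @param w_exc layer-1 to layer-2 retinotopic excitatory weight (default 400).
#' @param w_inh layer-1 to layer-2 pooled inhibitory weight (default -700;
#'   must be non-positive).
#' @param v0,u0 initial conditions for every neuron; `u0` defaults to
#'   `params$b * v0`, the resting value.
#' @param v_floor lower bound on membrane voltage (mV), the potassium
#'   reversal potential; see [step_neuron()].
#' @param inhibition `"within"` or `"both"`: which layer-1 channels inhibit a
#'   layer-2 channel.
#' @param excitation `"within"` or `"both"`: which layer-1 channels excite a
#'   layer-2 channel.
#' @param n_channels number of feature channels (default 2).
#' @param params an [izhikevich_params()].
#' @return An object of class `network_config`.
#' @export
network_config <- function(N = 64, dt = 0.2, w_input = 2.5, w_exc = 400,
                           w_inh = -700, v0 = -64, u0 = NULL, v_floor = -90,
                           inhibition = c("within", "both"),
                           excitation = c("within", "both"),
                           n_channels = 2, params = izhikevich_params()) {
  inhibition <- match.arg(inhibition)
  excitation <- match.arg(excitation)
  stopifnot(N >= 1, dt > 0, n_channels >= 1)
  if (w_inh > 0)
    stop("inhibition is achieved by a negative weight: w_inh must be <= 0")
  if (is.null(u0)) u0 <- params$b * v0
  structure(list(N = as.integer(N), dt = dt, w_input = w_input,
                 w_exc = w_exc, w_inh = w_inh, v0 = v0, u0 = u0,
                 v_floor = v_floor, inhibition = inhibition,
                 excitation = excitation, n_channels = as.integer(n_channels),
                 params = params),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("network config: %d channels x 2 layers of %dx%d neurons, dt = %g ms\n",
              x$n_channels, x$N, x$N, x$dt))
  cat(sprintf("  weights: input %g, excitation %g, inhibition %g (%s-channel)\n",
              x$w_input, x$w_exc, x$w_inh, x$inhibition))
  cat(sprintf("  init: v0 = %g, u0 = %g; v floor %g mV\n", x$v0, x$u0, x$v_floor))
  invisible(x)
}

#' Per-channel wiring lists
#'
#' Expands a [network_config()] into explicit per-channel source lists for
#' the integrator: which layer-1 channels excite and inhibit each layer-2
#' channel.  Layer 1 never receives inhibition.
#'
#' @param config a [network_config()].
#' @return A list (one element per channel) with `exc_src`, `inh_src`
#'   (integer channel indices), `w_exc`, `w_inh`.
#' @export
channel_wiring <- function(config) {
  all_ch <- seq_len(config$n_channels)
  lapply(all_ch, function(ch) list(
    exc_src = if (config$excitation == "both") all_ch else ch,
    inh_src = if (config$inhibition == "both") all_ch else ch,
    w_exc = config$w_exc, w_inh = config$w_inh))
}

#' Assemble the input current of a layer
#'
#' Sums source contributions of the form
#' `w_exc * F + w_inh * (sum(F) / N^2) * 1`, where `F` is a binary field
#' (stimulus input or spike map), the excitatory part is a point-by-point
#' retinotopic copy of `F`, and the inhibitory part is a spatially constant
#' field proportional to the normalized sum of `F`.
#'
#' @param sources list of sources; each a list with `F` (binary N x N
#'   matrix), `w_exc`, `w_inh`.
#' @param N grid side.
#' @return N x N matrix of input currents.
#' @examples
#' F <- matrix(0, 4, 4); F[2:3, 2:3] <- 1
#' assemble_current(list(list(F = F, w_exc = 400, w_inh = -700)), 4)
#' @export
assemble_current <- function(sources, N) {
  I <- matrix(0, N, N)
  for (s in sources) {
    F <- s$F
    if (!is.matrix(F) || any(dim(F) != c(N, N)))
      stop("source field has wrong shape")
    if (!all(F %in% c(0, 1))) stop("source field must be binary")
    I <- I + s$w_exc * F + s$w_inh * (sum(F) / N^2)
  }
  I
}

#' Advance the whole network by one Euler step (reference path)
#'
#' Pure-R single step used for small-grid verification; [run_network()] is
#' the compiled equivalent for full-size simulations.  Layer-1 currents come
#' from the given stimulus frames; layer-2 currents from the layer-1 spike
#' maps of the previous step stored in `state`.
#'
#' @param state a network state as returned by [init_network_state()] or a
#'   previous `step_network()` call.
#' @param input_frames list of per-channel stimulus drive matrices (already
#'   weighted, e.g. `w_input * frame`).
#' @param config a [network_config()].
#' @return The updated state; `state$spikes[[channel]][[layer]]` holds this
#'   step's binary spike maps.
#' @export
step_network <- function(state, input_frames, config) {
  N <- config$N
  wiring <- channel_wiring(config)
  new_spikes <- state$spikes
  for (ch in seq_len(config$n_channels)) {
    drv <- input_frames[[ch]]
    if (!is.matrix(drv) || any(dim(drv) != c(N, N)))
      stop(sprintf("bad input frame shape for channel %d", ch))
    for (layer in 1:2) {
      I <- if (layer == 1) drv else {
        w <- wiring[[ch]]
        srcs <- lapply(w$exc_src, function(s)
          list(F = state$spikes[[s]][[1]], w_exc = w$w_exc, w_inh = 0))
        srcs <- c(srcs, lapply(w$inh_src, function(s)
          list(F = state$spikes[[s]][[1]], w_exc = 0, w_inh = w$w_inh)))
        assemble_current(srcs, N)
      }
      r <- tryCatch(
        step_neuron(state$layers[[ch]][[layer]], I, config$params, config$dt,
                    v_floor = config$v_floor, step = state$step + 1L),
        error = function(e) stop(sprintf("channel %d, layer %d: %s",
                                         ch, layer, conditionMessage(e))))
      state$layers[[ch]][[layer]] <- r$state
      new_spikes[[ch]][[layer]] <- matrix(as.numeric(r$spiked), N, N)
    }
  }
  state$spikes <- new_spikes
  state$step <- state$step + 1L
  state
}

#' Initialize a network state
#'
#' @param config a [network_config()].
#' @return A list with per-(channel, layer) [neuron_state()]s, empty spike
#'   maps, and a step counter.
#' @export
init_network_state <- function(config) {
  N <- config$N
  zero <- matrix(0, N, N)
  layers <- lapply(seq_len(config$n_channels), function(ch)
    lapply(1:2, function(l)
      neuron_state(matrix(config$v0, N, N), matrix(config$u0, N, N))))
  spikes <- lapply(seq_len(config$n_channels), function(ch) list(zero, zero))
  list(layers = layers, spikes = spikes, step = 0L)
}

#' Run the network over a stimulus schedule
#'
#' Integrates the full network with the compiled forward-Euler kernel and
#' returns the spike raster as an event table.  Deterministic: identical
#' schedule and configuration give bit-identical rasters.
#'
#' @param schedule a [build_schedule()] result.  Event weights in the
#'   schedule are used as-is (build them with `w_input` already applied, as
#'   the experiment drivers do).
#' @param config a [network_config()].
#' @param clock optional [simulation_clock()]; defaults to covering the
#'   schedule duration.
#' @return A `spike_raster`: a data.frame with columns `step` (1-based),
#'   `t_ms` (bin start), `channel`, `layer`, `row`, `col`, plus attributes
#'   `N`, `dt`, `n_steps`, `n_channels`.
#' @export
run_network <- function(schedule, config, clock = NULL) {
  stopifnot(inherits(schedule, "stimulus_schedule"),
            inherits(config, "network_config"))
  if (schedule$n_channels != config$n_channels)
    stop("schedule and config disagree on the number of channels")
  dt <- config$dt
  if (is.null(clock)) {
    n_steps <- as.integer(ceiling(schedule$duration_ms / dt))
    clock <- simulation_clock(dt, n_steps)
  }
  if (clock$dt != dt) stop("clock dt must match config dt")
  if (schedule$duration_ms < clock$n_steps * dt - 1e-9)
    stop("schedule is shorter than the simulation clock")
  ev <- lapply(schedule$events, function(e) {
    off <- if (is.finite(e$duration_ms))
      as.integer(floor((e$onset_ms + e$duration_ms) / dt)) else clock$n_steps
    list(channel = e$channel, frame = as.numeric(unclass(e$frame)),
         on = as.integer(floor(e$onset_ms / dt)), off = off,
         weight = e$weight)
  })
  res <- run_network_cpp(config$N, clock$n_steps, dt,
                         unclass(config$params), config$v0, config$u0,
                         config$v_floor, config$n_channels, ev,
                         channel_wiring(config))
  pop <- res$pop
  idx <- res$idx
  N <- config$N
  out <- data.frame(step = res$step + 1L,
                    t_ms = res$step * dt,
                    channel = pop %% config$n_channels + 1L,
                    layer = pop %/% config$n_channels + 1L,
                    row = idx %% N + 1L,
                    col = idx %/% N + 1L)
  structure(out, N = N, dt = dt, n_steps = clock$n_steps,
            n_channels = config$n_channels,
            class = c("spike_raster", "data.frame"))
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike raster: %d spikes, %dx%d grid, %d channels, %d steps of %g ms\n",
              nrow(x), attr(x, "N"), attr(x, "N"), attr(x, "n_channels"),
              attr(x, "n_steps"), attr(x, "dt")))
  invisible(x)
}
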