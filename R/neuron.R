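#' Izhikevich neuron parameters
#'
#' Parameter set for the two-variable Izhikevich (2003) neuron
#' \deqn{v' = 0.04 v^2 + 5 v + 140 - u + I/C, \qquad u' = a (b v - u),}
#' with the after-spike reset: if \eqn{v \ge v_{peak}} then \eqn{v \leftarrow c},
#' \eqn{u \leftarrow u + d}.  Voltages are read in mV and time in ms.
#'
#' The defaults `a = 0.02, b = 0.25, c = -55, d = 0.05, v_peak = 30` are the
#' phasic-bursting regime: a sustained suprathreshold current step from rest
#' evokes a dense initial burst of spikes rather than regular tonic firing,
#' and release from sustained hyperpolarization can evoke a rebound burst.
#'
#' @param a recovery time scale (1/ms). Must be positive.
#' @param b recovery sensitivity (dimensionless coupling of `u` to `v`).
#' @param c membrane voltage reset value after a spike (mV).
#' @param d recovery-variable jump applied at each spike.
#' @param v_peak spike cutoff (mV); crossing it counts as a spike.
#' @param capacitance scale factor dividing the input current term.
#' @return An object of class `izhikevich_params` (a named list).
#' @examples
#' p <- izhikevich_params()
#' p$a
#' @export
izhikevich_params <- function(a = 0.02, b = 0.25, c = -55, d = 0.05,
                              v_peak = 30, capacitance = 1) {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0,
            is.numeric(b), length(b) == 1L,
            is.numeric(c), length(c) == 1L,
            is.numeric(d), length(d) == 1L,
            is.numeric(v_peak), length(v_peak) == 1L,
            is.numeric(capacitance), length(capacitance) == 1L, capacitance > 0)
  if (v_peak <= c)
    stop("v_peak must exceed the reset value c")
  structure(list(a = a, b = b, c = c, d = d, v_peak = v_peak,
                 capacitance = capacitance),
            class = "izhikevich_params")
}

#' @export
print.izhikevich_params <- function(x, ...) {
  cat("Izhikevich neuron parameters\n")
  cat(sprintf("  a = %g, b = %g, c = %g, d = %g, v_peak = %g, C = %g\n",
              x$a, x$b, x$c, x$d, x$v_peak, x$capacitance))
  invisible(x)
}

#' Neuron state
#'
#' Membrane voltage and recovery variable of a single neuron (or, when `v`
#' and `u` are equal-shaped arrays, of a whole population).
#'
#' @param v membrane voltage (mV).
#' @param u recovery variable; defaults to `b * v`, the resting value on the
#'   `u`-nullcline.
#' @param b recovery sensitivity used for the default `u`.
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(v = -64, u = NULL, b = 0.25) {
  if (is.null(u)) u <- b * v
  stopifnot(is.numeric(v), is.numeric(u), length(v) == length(u))
  structure(list(v = v, u = u), class = "neuron_state")
}

#' Advance a neuron by one Euler step
#'
#' One forward-Euler update of `(v, u)` with simultaneous updates (the `u`
#' update uses the pre-update `v`).  If the updated voltage reaches
#' `params$v_peak`, the after-spike reset is applied and the spike is
#' reported for this step; a spiking neuron leaves the step with `v` equal
#' to `params$c` exactly.  After reset, `v` is clipped from below at
#' `v_floor`.
#'
#' @param state a [neuron_state()]; `v`/`u` may be vectors or matrices.
#' @param I input current (same shape as `state$v`, or scalar).
#' @param params an [izhikevich_params()].
#' @param dt Euler step (ms), positive.
#' @param v_floor lower bound on the membrane voltage (mV); keeps single-step
#'   inhibitory kicks from driving `v` into the regime where the quadratic
#'   term dominates.  Use `-Inf` to disable.
#' @param step step index used in error messages for non-finite states.
#' @return A list with `state` (the updated [neuron_state()]) and `spiked`
#'   (logical, same shape as `v`).
#' @examples
#' st <- neuron_state()
#' step_neuron(st, I = 10, izhikevich_params(), dt = 0.2)$spiked
#' @export
step_neuron <- function(state, I, params = izhikevich_params(), dt = 0.2,
                        v_floor = -90, step = NA_integer_) {
  stopifnot(inherits(state, "neuron_state"), dt > 0)
  v <- state$v
  u <- state$u
  vn <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I / params$capacitance)
  un <- u + dt * params$a * (params$b * v - u)
  if (any(!is.finite(vn)) || any(!is.finite(un)))
    stop(sprintf("numerical blow-up: non-finite membrane state at step %s",
                 ifelse(is.na(step), "?", as.character(step))))
  spiked <- vn >= params$v_peak
  vn[spiked] <- params$c
  un[spiked] <- un[spiked] + params$d
  vn[vn < v_floor] <- v_floor
  list(state = neuron_state(vn, un), spiked = spiked)
}

#' Simulate a single neuron over a current trace
#'
#' Plain R loop over [step_neuron()].  Deterministic for fixed inputs; used
#' both as the user-level single-cell API and as the reference path against
#' which the compiled network integrator is checked.
#'
#' @param I_trace input current per Euler step.
#' @param params an [izhikevich_params()].
#' @param dt Euler step (ms).
#' @param v0,u0 initial conditions; `u0` defaults to `params$b * v0`.
#' @param v_floor lower bound on `v` (mV); see [step_neuron()].
#' @return Integer vector of spike step indices (1-based: a spike at step
#'   `k` occurred in the time bin `[(k-1) dt, k dt)`).
#' @examples
#' p <- izhikevich_params()
#' # a sustained current step from rest evokes a phasic burst
#' steps <- simulate_neuron(rep(2.5, 250), p, dt = 0.2)
#' length(steps)
#' @export
simulate_neuron <- function(I_trace, params = izhikevich_params(), dt = 0.2,
                            v0 = -64, u0 = NULL, v_floor = -90) {
  stopifnot(is.numeric(I_trace), dt > 0)
  if (is.null(u0)) u0 <- params$b * v0
  st <- neuron_state(v0, u0)
  spikes <- integer(0)
  for (k in seq_along(I_trace)) {
    r <- step_neuron(st, I_trace[k], params, dt, v_floor = v_floor, step = k)
    st <- r$state
    if (r$spiked) spikes <- c(spikes, k)
  }
  spikes
}

#' Simulation clock
#'
#' @param dt Euler step (ms); the default 0.20 ms is used throughout.
#' @param n_steps total number of steps.
#' @param t0 start time (ms).
#' @return An object of class `simulation_clock`.
#' @export
simulation_clock <- function(dt = 0.2, n_steps, t0 = 0) {
  stopifnot(dt > 0, n_steps >= 0)
  structure(list(dt = dt, n_steps = as.integer(n_steps), t0 = t0),
            class = "simulation_clock")
}

#' @export
print.simulation_clock <- function(x, ...) {
  cat(sprintf("simulation clock: %d steps of %g ms (%g ms total)\n",
              x$n_steps, x$dt, x$n_steps * x$dt))
  invisible(x)
}
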