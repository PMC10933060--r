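#' Duplex neuron state
#'
#' Holds the instantaneous state of a (possibly gated) Izhikevich neuron:
#' membrane potential `v` (mV), recovery variable `u`, the cached nonlinear
#' terms `alpha = 0.04 v^2 + 140 - u` and `beta = a (b v - u)`, the most
#' recent voltage increment `last_dv`, and the recompute/step counters from
#' which the computation-saving percentage is derived. A fresh state has a
#' cold cache (`last_dv = Inf`), so the first gated step always recomputes.
#'
#' @param v,u initial membrane potential (mV) and recovery variable.
#' @param params a [neuron_params()] object used to fill the cache.
#' @return An object of class `duplex_state`.
#' @export
duplex_state <- function(v, u, params) {
  stopifnot(inherits(params, "neuron_params"))
  if (!is.finite(v) || !is.finite(u)) stop("state must be finite")
  structure(list(v = v, u = u,
                 alpha = 0.04 * v * v + 140 - u,
                 beta = params$a * (params$b * v - u),
                 last_dv = Inf,
                 recompute_count = 0L, step_count = 0L),
            class = "duplex_state")
}

check_step_args <- function(state, I, dt) {
  if (!is.finite(state$v) || !is.finite(state$u))
    stop("non-finite neuron state; aborting")
  if (!is.finite(I)) stop("non-finite input current; aborting")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a positive number")
}

#' One full forward-Euler step of the Izhikevich model
#'
#' Advances `v` and `u` by one step of
#' `v[n+1] = (0.04 v[n]^2 + 5 v[n] + 140 - u[n] + I[n]) dt + v[n]`,
#' `u[n+1] = a (b v[n] - u[n]) dt + u[n]`,
#' with full evaluation of both right-hand sides (the cache is refreshed and
#' `recompute_count` incremented). The after-spike reset is a separate
#' operation, [apply_reset()].
#'
#' @param state a [duplex_state()].
#' @param params a [neuron_params()].
#' @param I input current for this step.
#' @param dt time step (ms), positive.
#' @return The advanced `duplex_state`.
#' @export
step_izhikevich <- function(state, params, I, dt) {
  stopifnot(inherits(state, "duplex_state"), inherits(params, "neuron_params"))
  check_step_args(state, I, dt)
  state$alpha <- 0.04 * state$v * state$v + 140 - state$u
  state$beta <- params$a * (params$b * state$v - state$u)
  state$recompute_count <- state$recompute_count + 1L
  vn <- (state$alpha + 5 * state$v + I) * dt + state$v
  un <- state$beta * dt + state$u
  if (!is.finite(vn) || !is.finite(un)) stop("non-finite neuron state; aborting")
  state$last_dv <- vn - state$v
  state$v <- vn
  state$u <- un
  state$step_count <- state$step_count + 1L
  state
}

#' One duplex (activity-gated) step
#'
#' If the magnitude of the previous step's voltage increment exceeded `delta`
#' (strictly), the cached `alpha` and `beta` terms are recomputed from the
#' current state; otherwise the cached values are reused. The step itself is
#' always `v[n+1] = (alpha + 5 v[n] + I) dt + v[n]`,
#' `u[n+1] = beta dt + u[n]`. Ties (`|dv| == delta`) skip recomputation.
#'
#' @inheritParams step_izhikevich
#' @param delta quasi-static threshold (mV); `delta >= 0`. With `delta = 0`
#'   the trajectory is identical to the full stepper.
#' @return The advanced `duplex_state`.
#' @export
step_duplex <- function(state, params, I, dt, delta) {
  stopifnot(inherits(state, "duplex_state"), inherits(params, "neuron_params"))
  check_step_args(state, I, dt)
  if (!is.finite(delta) || delta < 0) stop("'delta' must be >= 0")
  if (delta == 0 || abs(state$last_dv) > delta) {
    state$alpha <- 0.04 * state$v * state$v + 140 - state$u
    state$beta <- params$a * (params$b * state$v - state$u)
    state$recompute_count <- state$recompute_count + 1L
  }
  vn <- (state$alpha + 5 * state$v + I) * dt + state$v
  un <- state$beta * dt + state$u
  if (!is.finite(vn) || !is.finite(un)) stop("non-finite neuron state; aborting")
  state$last_dv <- vn - state$v
  state$v <- vn
  state$u <- un
  state$step_count <- state$step_count + 1L
  state
}

#' After-spike reset
#'
#' If `v > v_peak` (strict), `v` is reset to `c` and `u` incremented by `d`.
#'
#' @inheritParams step_izhikevich
#' @return A list with elements `state` (possibly reset) and `spiked`.
#' @export
apply_reset <- function(state, params) {
  stopifnot(inherits(state, "duplex_state"), inherits(params, "neuron_params"))
  spiked <- state$v > params$v_peak
  if (spiked) {
    state$v <- params$c
    state$u <- state$u + params$d
  }
  list(state = state, spiked = spiked)
}

#' Simulate a single neuron
#'
#' Runs `duration/dt` forward-Euler steps with either the full stepper
#' (both right-hand sides evaluated every step) or the duplex stepper (cached
#' `alpha`/`beta` reused while the voltage increment stays at or below
#' `delta`). The after-spike reset is applied after every step. Samples are
#' recorded after each step, at times `dt, 2 dt, ..., duration`.
#'
#' @param params a [neuron_params()] object.
#' @param config a [sim_config()] object; `config$delta` is the quasi-static
#'   threshold used by the duplex stepper.
#' @param I the injected current: a single number (constant drive), a numeric
#'   vector with one value per step, or a function of time (ms) evaluated at
#'   the start of each step.
#' @param stepper `"full"` or `"duplex"`.
#' @return An object of class `izh_trace`: a list with `times`, `v`, `u`,
#'   `qs_mask` (TRUE where the cache was *not* recomputed), `spike_mask`,
#'   and the recompute/step counters. Use [as.data.frame()] to flatten.
#' @examples
#' tr <- simulate_neuron(neuron_params(), sim_config(duration = 500), I = 4)
#' sum(tr$spike_mask)
#' @export
simulate_neuron <- function(params, config, I = 0,
                            stepper = c("full", "duplex")) {
  stopifnot(inherits(params, "neuron_params"), inherits(config, "sim_config"))
  stepper <- match.arg(stepper)
  n <- as.integer(round(config$duration / config$dt))
  if (n < 1L) stop("'duration' shorter than one step")
  if (is.function(I)) {
    I <- I((seq_len(n) - 1) * config$dt)
  } else if (length(I) == 1L) {
    I <- rep(as.numeric(I), n)
  }
  if (length(I) < n)
    stop(sprintf("current waveform has %d values but %d steps are required",
                 length(I), n))
  I <- as.numeric(I[seq_len(n)])
  if (anyNA(I) || any(!is.finite(I))) stop("non-finite input current; aborting")
  ic <- resolve_ic(config, params)
  res <- sim_neuron_cpp(ic[["v0"]], ic[["u0"]], params$a, params$b, params$c,
                        params$d, params$v_peak, I, config$dt,
                        config$delta, stepper == "duplex")
  structure(list(times = seq_len(n) * config$dt,
                 v = res$v, u = res$u,
                 qs_mask = res$qs, spike_mask = res$spike,
                 recompute_count = res$recompute_count,
                 step_count = res$step_count,
                 params = params, config = config, stepper = stepper),
            class = "izh_trace")
}

#' @export
print.izh_trace <- function(x, ...) {
  cat(sprintf(
    "izh_trace: %d steps of %g ms (%s stepper%s), %d spikes, CSP %.1f%%\n",
    x$step_count, x$config$dt, x$stepper,
    if (x$stepper == "duplex") sprintf(", delta=%g mV", x$config$delta) else "",
    sum(x$spike_mask), 100 * (x$step_count - x$recompute_count) / x$step_count))
  invisible(x)
}

#' @export
as.data.frame.izh_trace <- function(x, ...) {
  data.frame(time_ms = x$times, v_mV = x$v, u = x$u,
             qs_flag = as.integer(x$qs_mask),
             spike = as.integer(x$spike_mask))
}

#' Extract spike times from a trace
#'
#' A spike is a step at which the after-spike reset fired. Times are the
#' sample times of those steps, strictly increasing.
#'
#' @param trace an `izh_trace` (or fixed-point trace).
#' @return An object of class `spike_train` (numeric vector of times in ms,
#'   with the trace `dt` attached as an attribute).
#' @export
detect_spikes <- function(trace) {
  if (is.null(trace$times) || length(trace$times) == 0L)
    stop("empty trace")
  st <- trace$times[as.logical(trace$spike_mask)]
  structure(st, class = "spike_train", dt = trace$config$dt)
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train: %d spikes", length(x)))
  if (length(x) > 1)
    cat(sprintf(", mean ISI %.2f ms", mean(diff(unclass(x)))))
  cat("\n")
  invisible(x)
}

#' Steady-state inter-spike interval
#'
#' The timing convention used for the spike-period comparison: discard the
#' first spike (transient) and take the last complete inter-spike interval of
#' the run.
#'
#' @param spikes a `spike_train` or numeric vector of spike times (ms).
#' @return The steady-state interval in ms.
#' @export
steady_isi <- function(spikes) {
  s <- as.numeric(spikes)
  if (length(s) < 3L)
    stop("need at least 3 spikes for a steady-state interval")
  isi <- diff(s)[-1]  # drop the interval touching the first (transient) spike
  isi[length(isi)]
}
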