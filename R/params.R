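#' Izhikevich neuron parameters
#'
#' The two-variable Izhikevich model is governed by four dimensionless
#' constants: `a` (time scale of the recovery variable `u`), `b` (sensitivity
#' of `u` to the membrane potential `v`), `c` (after-spike reset value of `v`,
#' in mV) and `d` (after-spike increment of `u`), plus the spike cutoff
#' `v_peak` (mV) above which the reset fires.
#'
#' @param a recovery time scale; must be positive.
#' @param b recovery sensitivity.
#' @param c after-spike reset of `v` (mV); must lie below `v_peak`.
#' @param d after-spike increment of `u`.
#' @param v_peak spike cutoff (mV). The conventional value is 30 and the
#'   reset condition is the strict inequality `v > v_peak`.
#' @return An object of class `neuron_params`.
#' @examples
#' p <- neuron_params()          # tonic spiking
#' p <- izh_preset("bursting")
#' @export
neuron_params <- function(a = 0.02, b = 0.2, c = -65, d = 6, v_peak = 30) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d),
            length(a) == 1L, length(b) == 1L, length(c) == 1L,
            length(d) == 1L, length(v_peak) == 1L)
  if (!is.finite(a) || a <= 0) stop("'a' must be a positive finite number")
  if (!all(is.finite(c(b, c, d, v_peak)))) stop("parameters must be finite")
  if (c >= v_peak) stop("'c' (after-spike reset) must be below 'v_peak'")
  structure(list(a = a, b = b, c = c, d = d, v_peak = v_peak),
            class = "neuron_params")
}

#' Canonical parameter presets
#'
#' `"tonic"` is the regular/tonic-spiking set (a=0.02, b=0.2, c=-65, d=6);
#' `"bursting"` the canonical bursting set (c=-50, d=2).
#'
#' @param name preset name.
#' @return A [neuron_params()] object.
#' @export
izh_preset <- function(name = c("tonic", "bursting")) {
  name <- match.arg(name)
  switch(name,
         tonic    = neuron_params(0.02, 0.2, -65, 6),
         bursting = neuron_params(0.02, 0.2, -50, 2))
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("Izhikevich parameters: a=%g b=%g c=%g d=%g (v_peak=%g mV)\n",
              x$a, x$b, x$c, x$d, x$v_peak))
  invisible(x)
}

#' Simulation configuration
#'
#' @param dt time step in ms (forward Euler); default 1/32 ms.
#' @param duration total simulated time in ms.
#' @param delta quasi-static threshold in mV for the duplex stepper; 0
#'   disables gating (every step recomputes).
#' @param v0,u0 initial conditions. If `NULL`, `v0` defaults to the reset
#'   value `c` of the parameter set and `u0` to `b * v0` (the resting
#'   convention for this model).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 1 / 32, duration = 1000, delta = 0,
                       v0 = NULL, u0 = NULL) {
  stopifnot(length(dt) == 1L, length(duration) == 1L, length(delta) == 1L)
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be positive")
  if (!is.finite(delta) || delta < 0) stop("'delta' must be >= 0")
  if (!is.finite(duration) || duration < dt)
    stop("'duration' must be at least one time step")
  if (!is.null(v0) && !is.finite(v0)) stop("'v0' must be finite")
  if (!is.null(u0) && !is.finite(u0)) stop("'u0' must be finite")
  structure(list(dt = dt, duration = duration, delta = delta,
                 v0 = v0, u0 = u0),
            class = "sim_config")
}

# resolve v0/u0 defaults against a parameter set
resolve_ic <- function(config, params) {
  v0 <- if (is.null(config$v0)) params$c else config$v0
  u0 <- if (is.null(config$u0)) params$b * v0 else config$u0
  c(v0 = v0, u0 = u0)
}
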