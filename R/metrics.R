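#' Computation-saving percentage (CSP)
#'
#' The fraction of integration steps at which the cached `alpha`/`beta`
#' terms were *not* recomputed, as a percentage of all steps.
#'
#' @param x anything carrying `recompute_count` and `step_count`: an
#'   `izh_trace`, a `duplex_state`, or a plain list.
#' @return CSP in percent, in `[0, 100]`.
#' @export
csp <- function(x) {
  if (is.null(x$recompute_count) || is.null(x$step_count))
    stop("'x' must carry recompute_count and step_count")
  n <- x$step_count
  if (any(n <= 0)) stop("no steps taken")
  100 * (n - x$recompute_count) / n
}

#' Quasi-static fraction of a trace
#'
#' Percentage of steps flagged quasi-static (cache reused) in a trace's
#' `qs_mask`. Definitionally equal to [csp()] on the same run.
#'
#' @param trace a trace with a `qs_mask`.
#' @return Percentage in `[0, 100]`.
#' @export
qs_fraction <- function(trace) {
  if (is.null(trace$qs_mask) || length(trace$qs_mask) == 0L)
    stop("trace has no (non-empty) qs_mask")
  100 * mean(as.logical(trace$qs_mask))
}

trace_v <- function(x) if (is.list(x) && !is.null(x$v)) x$v else as.numeric(x)

#' Normalized root-mean-square deviation between two voltage traces
#'
#' `100 * sqrt(mean((v_ref - v_dx)^2)) / (max(v_ref) - min(v_ref))`, with the
#' normalization range taken from the reference (unmodified) trace over the
#' compared window. The traces must be time-aligned samples of equal length.
#' For spiking traces that drift out of phase, see [shape_nrmsd()], which
#' compares period-normalized spike shapes instead.
#'
#' @param v_ref,v_dx numeric vectors or traces of equal length (>= 2).
#' @return NRMSD in percent.
#' @export
nrmsd <- function(v_ref, v_dx) {
  a <- trace_v(v_ref); b <- trace_v(v_dx)
  if (length(a) != length(b)) stop("traces must have equal length")
  if (length(a) < 2L) stop("need at least 2 samples")
  rng <- max(a) - min(a)
  if (rng == 0) stop("flat reference trace: NRMSD undefined")
  100 * sqrt(mean((a - b)^2)) / rng
}

#' Spike-shape NRMSD between an unmodified and a gated run
#'
#' Measures the deviation in the *shape* of the spike waveform, independent
#' of the (separately quantified) spike-timing drift. Each steady-state
#' inter-spike period of the gated trace is linearly resampled onto the
#' duration of the corresponding reference period; the pointwise NRMSD
#' ([nrmsd()]) is computed per period pair and averaged over all complete
#' steady-state periods (the interval touching the first spike is discarded
#' as transient).
#'
#' @param trace_ref reference (full-stepper) `izh_trace`.
#' @param trace_dx duplex `izh_trace` on the same time grid.
#' @return Mean shape NRMSD in percent.
#' @export
shape_nrmsd <- function(trace_ref, trace_dx) {
  if (!isTRUE(all.equal(trace_ref$config$dt, trace_dx$config$dt)))
    stop("traces must share the same dt")
  sr <- which(as.logical(trace_ref$spike_mask))
  sd <- which(as.logical(trace_dx$spike_mask))
  k_max <- min(length(sr), length(sd)) - 1L
  if (k_max < 2L) stop("need at least 3 spikes in each trace")
  vals <- vapply(2:k_max, function(k) {
    wr <- (sr[k] + 1L):sr[k + 1L]
    wd <- (sd[k] + 1L):sd[k + 1L]
    vd <- approx(seq(0, 1, length.out = length(wd)), trace_dx$v[wd],
                 xout = seq(0, 1, length.out = length(wr)))$y
    nrmsd(trace_ref$v[wr], vd)
  }, numeric(1))
  mean(vals)
}

#' Spike timing error
#'
#' Relative difference between the steady-state inter-spike intervals of the
#' unmodified and gated runs:
#' `100 * |isi_ref - isi_dx| / isi_ref`, where each interval is the last
#' complete inter-spike interval after discarding the first spike
#' ([steady_isi()]).
#'
#' @param ref,dx `spike_train`s (or traces, from which spikes are extracted);
#'   each needs at least 3 spikes.
#' @return Timing error in percent.
#' @export
timing_error <- function(ref, dx) {
  if (is.list(ref)) ref <- detect_spikes(ref)
  if (is.list(dx)) dx <- detect_spikes(dx)
  100 * abs(steady_isi(ref) - steady_isi(dx)) / steady_isi(ref)
}

#' Speed-up percentage
#'
#' `100 * (t_ref - t_dx) / t_ref`: positive when the gated run is cheaper.
#' The costs may be measured runtimes or operation-count totals.
#'
#' @param t_ref,t_dx reference and duplex costs; `t_ref` must be positive.
#' @return Speed-up in percent (signed).
#' @export
speedup <- function(t_ref, t_dx) {
  if (!is.finite(t_ref) || t_ref <= 0) stop("reference cost must be positive")
  100 * (t_ref - t_dx) / t_ref
}

#' Error/performance sweep over quasi-static thresholds
#'
#' Simulates the neuron once with the full stepper and once per `delta` with
#' the duplex stepper under a common constant-current protocol, and reports
#' the spike timing error, the spike-shape NRMSD, the computation-saving
#' percentage, and the operation-cost speed-up for each threshold.
#'
#' The speed-up column uses the fixed-point data-path operation-cost model
#' (see [step_op_cost()]): the reference cost is every step at the
#' firing-state cost, the duplex cost mixes firing-state and quasi-static
#' step costs according to the measured gate decisions.
#'
#' @param deltas quasi-static thresholds (mV) to sweep.
#' @param params neuron parameters; tonic-spiking by default.
#' @param I constant input current; default 4.
#' @param dt time step (ms); default 1/32.
#' @param duration run length (ms); default 20000 (20 s).
#' @param weights operation-cost weights, see [op_cost_weights()].
#' @return A data frame with columns `delta_mv`, `te_pct`, `nrmsd_pct`,
#'   `csp_pct`, `speedup_pct`.
#' @examples
#' duplex_sweep(deltas = c(0.01, 0.2), duration = 4000)
#' @export
duplex_sweep <- function(deltas = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.2),
                         params = neuron_params(), I = 4, dt = 1 / 32,
                         duration = 20000, weights = op_cost_weights()) {
  cfg_full <- sim_config(dt = dt, duration = duration, delta = 0)
  ref <- simulate_neuron(params, cfg_full, I = I, stepper = "full")
  cost_fs <- step_op_cost("fs", params = params, dt = dt, weights = weights)
  cost_qs <- step_op_cost("qs", params = params, dt = dt, weights = weights)
  rows <- lapply(deltas, function(del) {
    cfg <- sim_config(dt = dt, duration = duration, delta = del)
    dx <- simulate_neuron(params, cfg, I = I, stepper = "duplex")
    n_fs <- dx$recompute_count
    n_qs <- dx$step_count - n_fs
    data.frame(delta_mv = del,
               te_pct = timing_error(ref, dx),
               nrmsd_pct = shape_nrmsd(ref, dx),
               csp_pct = csp(dx),
               speedup_pct = speedup(dx$step_count * cost_fs,
                                     n_fs * cost_fs + n_qs * cost_qs))
  })
  do.call(rbind, rows)
}
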