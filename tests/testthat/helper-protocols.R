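# Shared protocols: the tonic-spiking constant-current reference run.
tonic <- neuron_params()          # a=0.02 b=0.2 c=-65 d=6

tonic_cfg <- function(duration = 20000, delta = 0, dt = 1 / 32)
  sim_config(dt = dt, duration = duration, delta = delta)

run_tonic <- function(duration = 20000, delta = 0, I = 4,
                      stepper = if (delta > 0) "duplex" else "full")
  simulate_neuron(tonic, tonic_cfg(duration, delta), I = I, stepper = stepper)

# a trace object built from slices of an existing one (for locality checks)
slice_trace <- function(tr, idx) {
  out <- list(times = tr$times[idx], v = tr$v[idx], u = tr$u[idx],
              qs_mask = tr$qs_mask[idx], spike_mask = tr$spike_mask[idx],
              recompute_count = sum(!tr$qs_mask[idx]),
              step_count = length(idx),
              params = tr$params, config = tr$config, stepper = tr$stepper)
  class(out) <- "izh_trace"
  out
}
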