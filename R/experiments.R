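# Registry of canned experiments. Each entry takes (params, seed, dir) and
# returns a named list of headline metrics; file outputs go into dir.
experiment_registry <- function() {
  list(threshold_sweep = exp_threshold_sweep,
       random_net = exp_random_net,
       layer_csp = exp_layer_csp,
       current_sweep = exp_current_sweep,
       pattern_train_test = exp_pattern_train_test,
       fx_single_neuron = exp_fx_single_neuron)
}

#' Validate and normalize a configuration list
#'
#' Fills defaults (tonic parameters, `dt = 1/32` ms, `delta = 0`, full
#' stepper, Q16.14 fixed point) and applies sanity checks; contradictory or
#' unphysical keys are rejected with a message.
#'
#' @param raw a (possibly partial) named list, e.g. parsed from YAML/JSON.
#' @return The normalized configuration list.
#' @export
validate_config <- function(raw = list()) {
  if (!is.list(raw)) stop("config must be a list")
  defaults <- list(a = 0.02, b = 0.2, c = -65, d = 6, v_peak = 30,
                   dt = 1 / 32, duration = 1000, delta = 0, I = 4,
                   stepper = "full", v0 = NULL, u0 = NULL,
                   fx = list(word_bits = 30, frac_bits = 14,
                             cordic_iters = 16, overflow = "saturate"))
  unknown <- setdiff(names(raw), c(names(defaults), "seed"))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw)
  if (!cfg$stepper %in% c("full", "duplex"))
    stop("stepper must be 'full' or 'duplex'")
  if (!is.numeric(cfg$dt) || cfg$dt <= 0) stop("dt must be positive")
  if (!is.numeric(cfg$delta) || cfg$delta < 0) stop("delta must be >= 0")
  if (cfg$duration < cfg$dt) stop("duration must cover at least one step")
  if (cfg$fx$frac_bits >= cfg$fx$word_bits)
    stop("fx.frac_bits must be smaller than fx.word_bits")
  if (!cfg$fx$overflow %in% c("saturate", "raise"))
    stop("fx.overflow must be 'saturate' or 'raise'")
  # exercise the stricter constructors
  neuron_params(cfg$a, cfg$b, cfg$c, cfg$d, cfg$v_peak)
  sim_config(cfg$dt, cfg$duration, cfg$delta, cfg$v0, cfg$u0)
  cfg
}

# deterministic per-component substream: experiments must not perturb each
# other's randomness when one is added or re-run
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

exp_threshold_sweep <- function(params, seed, dir) {
  deltas <- params$deltas %||% c(0.001, 0.005, 0.01, 0.05, 0.1, 0.2)
  duration <- params$duration %||% 20000
  rep_ <- duplex_sweep(deltas = deltas, duration = duration,
                       I = params$I %||% 4, dt = params$dt %||% 1 / 32)
  write_comparison_report(rep_, file.path(dir, "threshold_sweep.csv"))
  list(csp_pct = rep_$csp_pct, te_pct = rep_$te_pct,
       nrmsd_pct = rep_$nrmsd_pct, delta_mv = rep_$delta_mv)
}

exp_random_net <- function(params, seed, dir) {
  net <- random_network(params$n_exc %||% 800, params$n_inh %||% 200,
                        seed = derive_seed(seed, "random_net"))
  sim <- simulate_network(net, duration = params$duration %||% 1000,
                          dt = params$dt %||% 0.5,
                          stepper = params$stepper %||% "full",
                          delta = params$delta %||% 0)
  write_raster_csv(sim, file.path(dir, "raster.csv"))
  write.csv(spike_count_distribution(sim),
            file.path(dir, "spike_count_distribution.csv"),
            row.names = FALSE, quote = FALSE)
  list(band_fraction_6_24 = band_fraction(sim),
       total_spikes = nrow(sim$raster))
}

exp_layer_csp <- function(params, seed, dir) {
  deltas <- params$deltas %||% c(0.005, 0.05, 0.1)
  n_present <- params$n_present %||% 60
  net <- layered_network(seed = derive_seed(seed, "layer_csp"))
  net <- train_network(net, n_present = n_present)
  pats <- rep(list(pattern_stimulus("E"), pattern_stimulus("H")),
              params$n_test %||% 3)
  rows <- do.call(rbind, lapply(deltas, function(del) {
    rep_ <- test_network(net, pats, stepper = "duplex", delta = del)
    do.call(rbind, lapply(names(rep_$csp_by_layer), function(ly)
      data.frame(delta_mv = del, layer = ly,
                 csp_mean = mean(rep_$csp_by_layer[[ly]]),
                 csp_min = min(rep_$csp_by_layer[[ly]]),
                 csp_max = max(rep_$csp_by_layer[[ly]]))))
  }))
  write.csv(rows, file.path(dir, "layer_csp.csv"), row.names = FALSE,
            quote = FALSE)
  list(csp_mean_by_delta = tapply(rows$csp_mean, rows$delta_mv, mean))
}

exp_current_sweep <- function(params, seed, dir) {
  currents <- params$currents %||% seq(2, 20, by = 2)
  delta <- params$delta %||% 1 / 128
  duration <- params$duration %||% 20000
  rows <- do.call(rbind, lapply(currents, function(I) {
    tr <- simulate_neuron(neuron_params(),
                          sim_config(dt = params$dt %||% 1 / 32,
                                     duration = duration, delta = delta),
                          I = I, stepper = "duplex")
    data.frame(I = I, csp_pct = csp(tr), n_spikes = sum(tr$spike_mask))
  }))
  write.csv(rows, file.path(dir, "current_sweep.csv"), row.names = FALSE,
            quote = FALSE)
  list(csp_pct = rows$csp_pct, I = rows$I)
}

exp_pattern_train_test <- function(params, seed, dir) {
  s <- derive_seed(seed, "pattern")
  full <- train_and_test(seed = s, stepper = "full",
                         n_present = params$n_present %||% 60,
                         n_test = params$n_test %||% 5)
  dx <- train_and_test(seed = s, stepper = "duplex",
                       delta = params$delta %||% 1 / 8,
                       n_present = params$n_present %||% 60,
                       n_test = params$n_test %||% 5)
  out <- data.frame(stepper = c(rep("full", length(full$out_counts)),
                                rep("duplex", length(dx$out_counts))),
                    label = c(full$labels, dx$labels),
                    out_spikes = c(full$out_counts, dx$out_counts))
  write.csv(out, file.path(dir, "pattern_test.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(full$net$W12, file.path(dir, "weights_full_W12.csv"),
            row.names = FALSE, quote = FALSE)
  list(full_success = full$success, duplex_success = dx$success)
}

exp_fx_single_neuron <- function(params, seed, dir) {
  cfg <- sim_config(dt = 1 / 32, duration = params$duration %||% 1000,
                    delta = params$delta %||% 1 / 128)
  fxr <- fx_simulate(neuron_params(), cfg, I = params$I %||% 16,
                     stepper = "duplex")
  fl <- fx_float_twin(neuron_params(), cfg, I = params$I %||% 16,
                      stepper = "duplex")
  write_trace_csv(fxr, file.path(dir, "fx_trace.csv"))
  write.csv(fx_constant_report(), file.path(dir, "fx_constants.csv"),
            row.names = FALSE, quote = FALSE)
  spikes <- detect_spikes(fxr)
  list(rmsd_vs_float = sqrt(mean((fxr$v - fl$v)^2)),
       csp_pct = csp(fxr),
       energy_proxy = if (length(spikes)) energy_proxy(fxr, spikes) else NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a registered experiment
#'
#' Executes one of the canned experiments — the threshold sweep, the random
#' network, the layered-network per-layer CSP, the input-current sweep, the
#' pattern train/test, or the fixed-point single neuron — writing its CSV
#' outputs and a `summary.json` (seed, resolved parameters, package version
#' and headline metrics) into `output_dir`. Outputs are deterministic for a
#' fixed seed.
#'
#' @param name experiment name; one of `threshold_sweep`, `random_net`,
#'   `layer_csp`, `current_sweep`, `pattern_train_test`,
#'   `fx_single_neuron`.
#' @param params named list of parameter overrides (experiment-specific).
#' @param seed integer master seed; per-experiment substreams are derived
#'   from it so experiments do not perturb each other.
#' @param output_dir output directory (created if missing).
#' @return The summary list, invisibly.
#' @export
run_experiment <- function(name, params = list(), seed = 1,
                           output_dir = tempfile("experiment")) {
  reg <- experiment_registry()
  if (!name %in% names(reg))
    stop("unknown experiment '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  if (!dir.exists(output_dir) &&
      !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output dir ", output_dir)
  metrics <- reg[[name]](params, seed, output_dir)
  summary <- list(experiment = name, seed = seed, params = params,
                  package_version = as.character(packageVersion("duplexneuron")),
                  metrics = metrics)
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Generate reproducible fixture files
#'
#' Writes plain-text fixtures for tests and demos: the "E"/"H" pattern
#' bitmaps, a (reduced) seeded random-network weight matrix, or constant /
#' step current protocols. Regenerating with the same seed gives identical
#' files.
#'
#' @param kind `"patterns"`, `"random_net_weights"` or `"current_protocols"`.
#' @param seed RNG seed where randomness is involved.
#' @param dir output directory (created if missing).
#' @param ... size overrides (`n_exc`, `n_inh` for the weight fixture;
#'   `duration`, `dt`, `I` for the protocols).
#' @return Character vector of the files written.
#' @export
generate_fixtures <- function(kind = c("patterns", "random_net_weights",
                                       "current_protocols"),
                              seed = 1, dir = tempfile("fixtures"), ...) {
  kind <- match.arg(kind)
  opts <- list(...)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- switch(kind,
    patterns = {
      e <- file.path(dir, "E.txt"); h <- file.path(dir, "H.txt")
      write_pattern(pattern_stimulus("E"), e)
      write_pattern(pattern_stimulus("H"), h)
      c(e, h)
    },
    random_net_weights = {
      net <- random_network(opts$n_exc %||% 16, opts$n_inh %||% 4,
                            seed = seed)
      f <- file.path(dir, "weights.csv")
      write.csv(round(net$S, 6), f, row.names = FALSE, quote = FALSE)
      f
    },
    current_protocols = {
      dt <- opts$dt %||% 1 / 32
      duration <- opts$duration %||% 1000
      t <- seq(0, duration, by = dt)
      const <- data.frame(time_ms = t, I = opts$I %||% 4)
      stepp <- data.frame(time_ms = t,
                          I = ifelse(t < duration / 2, 0, opts$I %||% 4))
      f1 <- file.path(dir, "constant_current.csv")
      f2 <- file.path(dir, "step_current.csv")
      write.csv(const, f1, row.names = FALSE, quote = FALSE)
      write.csv(stepp, f2, row.names = FALSE, quote = FALSE)
      c(f1, f2)
    })
  files
}
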