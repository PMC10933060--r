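# 7x6 glyph bitmaps for the two stimulus patterns ('#' = on pixel).
glyph_rows <- list(
  E = c("#####.",
        "#.....",
        "#.....",
        "####..",
        "#.....",
        "#.....",
        "#####."),
  H = c("#....#",
        "#....#",
        "#....#",
        "######",
        "#....#",
        "#....#",
        "#....#"))

parse_glyph <- function(rows) {
  if (length(rows) != 7L || any(nchar(rows) != 6L))
    stop("a glyph is 7 rows of 6 characters")
  as.integer(unlist(strsplit(rows, "")) == "#")
}

#' Binary pixel-pattern stimulus
#'
#' A 42-element binary grid (7 rows by 6 columns, row-major) mapped to input
#' currents: active pixels drive their input neuron with `i_on`, inactive
#' pixels with `i_off`. The two built-in glyphs are block letters "E" and
#' "H".
#'
#' @param label `"E"` or `"H"` to use a built-in glyph, or any label when
#'   `grid` is supplied.
#' @param grid optional explicit 42-element 0/1 vector (row-major).
#' @param i_on,i_off drive currents for active and inactive pixels.
#' @return An object of class `pattern_stimulus`.
#' @examples
#' p <- pattern_stimulus("E")
#' sum(p$grid)   # number of active pixels
#' @export
pattern_stimulus <- function(label, grid = NULL, i_on = 10, i_off = 0) {
  if (is.null(grid)) {
    if (!label %in% names(glyph_rows)) stop("no built-in glyph for ", label)
    grid <- parse_glyph(glyph_rows[[label]])
  }
  grid <- as.integer(grid)
  if (length(grid) != 42L || !all(grid %in% c(0L, 1L)))
    stop("'grid' must be 42 binary values")
  structure(list(label = label, grid = grid, i_on = i_on, i_off = i_off),
            class = "pattern_stimulus")
}

#' @export
print.pattern_stimulus <- function(x, ...) {
  m <- matrix(c(".", "#")[x$grid + 1L], 7, 6, byrow = TRUE)
  cat(sprintf("pattern '%s' (%d active pixels):\n", x$label, sum(x$grid)))
  apply(m, 1, function(r) cat(" ", paste(r, collapse = ""), "\n"))
  invisible(x)
}

#' Map a pattern to its 42 input currents
#'
#' @param p a [pattern_stimulus()].
#' @return Numeric vector of 42 drive currents.
#' @export
encode_pattern <- function(p) {
  stopifnot(inherits(p, "pattern_stimulus"))
  ifelse(p$grid > 0, p$i_on, p$i_off)
}

#' STDP configuration
#'
#' Pair-based exponential spike-timing-dependent plasticity: a presynaptic
#' spike preceding a postsynaptic spike by `dt` potentiates the synapse by
#' `a_plus * exp(-dt / tau_plus)`; the reverse order depresses by
#' `a_minus * exp(-dt / tau_minus)`. Amplitudes are in weight units for
#' [stdp_update()]; the network trainer scales them by the layer's weight
#' range.
#'
#' @param a_plus,a_minus potentiation/depression amplitudes (> 0).
#' @param tau_plus,tau_minus trace time constants (ms, > 0).
#' @param nearest_neighbor if `TRUE`, only nearest spike pairs interact;
#'   default all-to-all pairing.
#' @return An object of class `stdp_config`.
#' @export
stdp_config <- function(a_plus = 0.05, a_minus = 0.055,
                        tau_plus = 20, tau_minus = 20,
                        nearest_neighbor = FALSE) {
  stopifnot(a_plus > 0, a_minus > 0, tau_plus > 0, tau_minus > 0)
  structure(list(a_plus = a_plus, a_minus = a_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus,
                 nearest_neighbor = isTRUE(nearest_neighbor)),
            class = "stdp_config")
}

#' Pair-based STDP weight update
#'
#' Applies the exponential pair rule to one synapse given its pre- and
#' postsynaptic spike trains, then clips to bounds. Simultaneous spikes
#' (`dt == 0`) leave the weight unchanged.
#'
#' @param w synaptic weight (scalar or vector; trains are shared).
#' @param pre_spikes,post_spikes numeric spike times (ms).
#' @param cfg an [stdp_config()].
#' @param bounds length-2 clipping interval `[w_min, w_max]`.
#' @return Updated weight(s), clipped to `bounds`.
#' @examples
#' stdp_update(0, pre_spikes = 0, post_spikes = 20, cfg = stdp_config(),
#'             bounds = c(0, 1))  # a_plus * exp(-1)
#' @export
stdp_update <- function(w, pre_spikes, post_spikes, cfg = stdp_config(),
                        bounds = c(0, 1)) {
  stopifnot(inherits(cfg, "stdp_config"), length(bounds) == 2L)
  dw <- 0
  if (length(pre_spikes) && length(post_spikes)) {
    if (cfg$nearest_neighbor) {
      # each post pairs with the nearest preceding pre, and vice versa
      for (tp in post_spikes) {
        prec <- pre_spikes[pre_spikes < tp]
        if (length(prec))
          dw <- dw + cfg$a_plus * exp(-(tp - max(prec)) / cfg$tau_plus)
      }
      for (tq in pre_spikes) {
        post_prec <- post_spikes[post_spikes < tq]
        if (length(post_prec))
          dw <- dw - cfg$a_minus * exp(-(tq - max(post_prec)) / cfg$tau_minus)
      }
    } else {
      d <- outer(post_spikes, pre_spikes, "-")  # t_post - t_pre
      dw <- cfg$a_plus * sum(exp(-d[d > 0] / cfg$tau_plus)) -
        cfg$a_minus * sum(exp(d[d < 0] / cfg$tau_minus))
    }
  }
  pmin(pmax(w + dw, bounds[1]), bounds[2])
}

#' Three-layer pattern-recognition network
#'
#' A feed-forward 42-7-1 network of identical regular-spiking Izhikevich
#' neurons: 42 input neurons driven by the pixel currents, a fully connected
#' hidden layer, and one output neuron. Synapses are delta-current (a
#' presynaptic spike adds the weight to the postsynaptic input for the next
#' step). Initial weights are uniform in `init_frac` of each layer's weight
#' range. Weight bounds differ per layer because the hidden layer integrates
#' up to 42 synchronous inputs and the output neuron only 7.
#'
#' @param seed RNG seed for the weight initialization.
#' @param hidden hidden-layer size (default 7).
#' @param w12_bounds,w23_bounds per-layer weight bounds `[min, max]`.
#' @param init_frac range (fractions of the bound interval) for the uniform
#'   weight initialization.
#' @param stdp an [stdp_config()]; amplitudes are interpreted as fractions
#'   of the layer weight range during training.
#' @param dt Euler step (ms).
#' @param present_ms,gap_ms stimulus-on and silent-gap durations per
#'   presentation.
#' @param i_teach teacher current injected into hidden and output neurons
#'   while a pattern is on during training (slightly above the model's
#'   rheobase, so trained-on neurons fire and pair causally with the input
#'   volleys).
#' @return An object of class `layered_network`.
#' @export
layered_network <- function(seed = 1, hidden = 7,
                            w12_bounds = c(0, 36), w23_bounds = c(0, 160),
                            init_frac = c(0.05, 0.25),
                            stdp = stdp_config(), dt = 1 / 32,
                            present_ms = 40, gap_ms = 55, i_teach = 5) {
  set.seed(seed)
  W12 <- matrix(w12_bounds[1] + diff(w12_bounds) *
                  runif(42 * hidden, init_frac[1], init_frac[2]),
                42, hidden)
  W23 <- w23_bounds[1] + diff(w23_bounds) *
    runif(hidden, init_frac[1], init_frac[2])
  structure(list(W12 = W12, W23 = W23, hidden = hidden,
                 w12_bounds = w12_bounds, w23_bounds = w23_bounds,
                 stdp = stdp, dt = dt, present_ms = present_ms,
                 gap_ms = gap_ms, i_teach = i_teach,
                 params = neuron_params(), seed = seed, trained = FALSE),
            class = "layered_network")
}

#' @export
print.layered_network <- function(x, ...) {
  cat(sprintf("layered_network 42-%d-1 (seed %d, %strained)\n",
              x$hidden, x$seed, if (x$trained) "" else "un"))
  invisible(x)
}

run_layered <- function(net, stimuli, train, stepper, delta) {
  gated <- stepper == "duplex"
  pats <- do.call(rbind, lapply(stimuli, function(s) s$grid))
  i_on <- stimuli[[1]]$i_on; i_off <- stimuli[[1]]$i_off
  p <- net$params
  sim_layered_cpp(net$W12, net$W23, pats,
                  p$a, p$b, p$c, p$d, p$v_peak,
                  net$dt, net$present_ms, net$gap_ms,
                  i_on, i_off, net$i_teach,
                  train,
                  net$stdp$a_plus, net$stdp$a_minus,
                  net$stdp$tau_plus, net$stdp$tau_minus,
                  net$w12_bounds[1], net$w12_bounds[2],
                  net$w23_bounds[1], net$w23_bounds[2],
                  delta, gated)
}

#' Train the layered network on one pattern
#'
#' Presents the training pattern `n_present` times (stimulus on for
#' `present_ms`, then a silent gap) with online pair-based STDP on both
#' weight layers and the teacher current active, using either the full or
#' the duplex stepper throughout.
#'
#' @param net a [layered_network()].
#' @param pattern training stimulus (default the "E" glyph).
#' @param n_present number of presentations.
#' @param stepper `"full"` or `"duplex"`.
#' @param delta quasi-static threshold (mV) when `stepper = "duplex"`.
#' @return The network with trained weights (`$trained = TRUE`) and the
#'   training run attached as `$last_run`.
#' @export
train_network <- function(net, pattern = pattern_stimulus("E"),
                          n_present = 60, stepper = c("full", "duplex"),
                          delta = 0) {
  stopifnot(inherits(net, "layered_network"),
            inherits(pattern, "pattern_stimulus"))
  stepper <- match.arg(stepper)
  res <- run_layered(net, rep(list(pattern), n_present), TRUE, stepper, delta)
  net$W12 <- res$W12
  net$W23 <- res$W23
  net$trained <- TRUE
  net$last_run <- res
  net
}

#' Test the layered network on a pattern sequence
#'
#' Presents the test stimuli without plasticity or teacher current and
#' reports per-presentation output spike counts. The discrimination
#' criterion: the output neuron spikes on every "E" presentation and stays
#' silent on every "H" presentation.
#'
#' @inheritParams train_network
#' @param patterns list of [pattern_stimulus()] objects (must include both
#'   labels for a discrimination test).
#' @return A list: `labels`, `out_counts`, `hid_counts`, `success`,
#'   `diverged` (weights saturated without selectivity), per-neuron
#'   recompute/step counters, and the per-layer CSP summary.
#' @export
test_network <- function(net, patterns, stepper = c("full", "duplex"),
                         delta = 0) {
  stopifnot(inherits(net, "layered_network"))
  stepper <- match.arg(stepper)
  res <- run_layered(net, patterns, FALSE, stepper, delta)
  labels <- vapply(patterns, function(p) p$label, character(1))
  is_target <- labels == "E"
  success <- all(res$out_counts[is_target] > 0) &&
    all(res$out_counts[!is_target] == 0)
  on_pix <- pattern_stimulus("E")$grid > 0
  w_hi <- mean(net$W12[on_pix, ]) / net$w12_bounds[2]
  w_lo <- mean(net$W12[!on_pix, ]) / net$w12_bounds[2]
  diverged <- net$trained && w_hi > 0.95 && w_lo > 0.95
  n1 <- 42L; n2 <- net$hidden
  layer <- rep(c("input", "hidden", "output"), c(n1, n2, 1L))
  csp_neuron <- 100 * (res$step_count - res$recompute_count) / res$step_count
  list(labels = labels, out_counts = as.integer(res$out_counts),
       hid_counts = res$hid_counts, success = success, diverged = diverged,
       recompute_count = res$recompute_count, step_count = res$step_count,
       csp_by_layer = split(csp_neuron, layer), out_v = res$out_v,
       stepper = stepper, delta = delta)
}

#' Train on "E", test on "E" and "H"
#'
#' The full pattern-recognition experiment: build (or reuse) a network,
#' train it on the "E" glyph, then present an alternating test sequence of
#' both glyphs and report discrimination.
#'
#' @param seed network/weight seed.
#' @param stepper `"full"` or `"duplex"` (used for both phases: duplex
#'   networks are retrained with the duplex stepper).
#' @param delta quasi-static threshold (mV).
#' @param n_present training presentations.
#' @param n_test test presentations per label.
#' @param net optionally a prebuilt (possibly pre-trained) network; when
#'   supplied with `retrain = FALSE` the stored weights are tested as-is.
#' @param retrain whether to (re)train before testing.
#' @param ... passed to [layered_network()].
#' @return The [test_network()] report, with the trained network attached
#'   as `$net`.
#' @export
train_and_test <- function(seed = 1, stepper = c("full", "duplex"),
                           delta = 0, n_present = 60, n_test = 5,
                           net = NULL, retrain = TRUE, ...) {
  stepper <- match.arg(stepper)
  if (is.null(net)) net <- layered_network(seed = seed, ...)
  if (retrain)
    net <- train_network(net, n_present = n_present, stepper = stepper,
                         delta = delta)
  pats <- rep(list(pattern_stimulus("E"), pattern_stimulus("H")), n_test)
  rep_ <- test_network(net, pats, stepper = stepper, delta = delta)
  rep_$net <- net
  rep_
}
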