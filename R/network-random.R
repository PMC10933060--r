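#' Randomly coupled excitatory/inhibitory network
#'
#' Builds the classic 1,000-neuron random network recipe: `n_exc` excitatory
#' neurons whose parameters are interpolated from regular spiking toward
#' bursting by squared uniform deviates (`c = -65 + 15 r^2`,
#' `d = 8 - 6 r^2`), `n_inh` inhibitory neurons interpolated toward fast
#' spiking (`a = 0.02 + 0.08 r`, `b = 0.25 - 0.05 r`), and a dense random
#' weight matrix with positive weights from excitatory neurons
#' (`0.5 U(0,1)`) and negative from inhibitory (`-U(0,1)`), respecting
#' Dale's principle. Self-connections are not excluded, as in the original
#' recipe.
#'
#' @param n_exc,n_inh population sizes (defaults 800/200).
#' @param seed RNG seed; the build is deterministic given the seed.
#' @param w_exc,w_inh weight scales for the two populations.
#' @return An object of class `random_network` with fields `a`, `b`, `c`,
#'   `d` (per-neuron parameter vectors), `S` (weight matrix, columns =
#'   presynaptic), `n_exc`, `n_inh`, `seed`.
#' @export
random_network <- function(n_exc = 800, n_inh = 200, seed = 1,
                           w_exc = 0.5, w_inh = 1) {
  stopifnot(n_exc >= 1, n_inh >= 1)
  set.seed(seed)
  n <- n_exc + n_inh
  re <- runif(n_exc); ri <- runif(n_inh)
  structure(list(
    a = c(rep(0.02, n_exc), 0.02 + 0.08 * ri),
    b = c(rep(0.2, n_exc), 0.25 - 0.05 * ri),
    c = c(-65 + 15 * re^2, rep(-65, n_inh)),
    d = c(8 - 6 * re^2, rep(2, n_inh)),
    S = cbind(matrix(w_exc * runif(n * n_exc), n, n_exc),
              matrix(-w_inh * runif(n * n_inh), n, n_inh)),
    n_exc = n_exc, n_inh = n_inh, n = n, seed = seed),
    class = "random_network")
}

#' @export
print.random_network <- function(x, ...) {
  cat(sprintf("random_network: %d excitatory + %d inhibitory neurons (seed %d)\n",
              x$n_exc, x$n_inh, x$seed))
  invisible(x)
}

#' Simulate a random network
#'
#' All neurons are stepped synchronously with forward Euler (optionally
#' duplex-gated per neuron). Noisy thalamic drive is drawn once per
#' millisecond (`N(0, noise_exc^2)` for excitatory targets,
#' `N(0, noise_inh^2)` for inhibitory); synaptic input is delta-current: the
#' weights of all neurons that spiked during the previous millisecond are
#' summed into the postsynaptic drive for the next millisecond, the event
#' frame of the original recipe. `dt` must divide 1 ms.
#'
#' @param net a [random_network()].
#' @param duration simulated time (ms), default 1000.
#' @param dt Euler step (ms), default 0.5.
#' @param stepper `"full"` or `"duplex"`.
#' @param delta quasi-static threshold (mV) for the duplex stepper.
#' @param noise_exc,noise_inh thalamic noise amplitudes.
#' @param seed RNG seed for the noise; defaults to the network's seed.
#' @return An object of class `network_sim`: `raster` (data frame `time_ms`,
#'   `neuron`), `counts` (spikes per neuron), `recompute_count` and
#'   `step_count` per neuron, and the call configuration.
#' @export
simulate_network <- function(net, duration = 1000, dt = 0.5,
                             stepper = c("full", "duplex"), delta = 0,
                             noise_exc = 5, noise_inh = 2, seed = NULL) {
  stopifnot(inherits(net, "random_network"))
  stepper <- match.arg(stepper)
  gated <- stepper == "duplex"
  k <- round(1 / dt)
  if (!isTRUE(all.equal(k * dt, 1))) stop("'dt' must divide 1 ms")
  if (is.null(seed)) seed <- net$seed
  set.seed(seed)
  n <- net$n
  v <- rep(-65, n); u <- net$b * v
  alpha <- 0.04 * v^2 + 140 - u
  beta <- net$a * (net$b * v - u)
  last_dv <- rep(Inf, n)
  rec <- integer(n); steps <- 0L
  counts <- integer(n)
  ev_t <- vector("list", duration); ev_i <- vector("list", duration)
  fired_ms <- logical(n)
  for (t in seq_len(duration)) {
    noise <- c(noise_exc * rnorm(net$n_exc), noise_inh * rnorm(net$n_inh))
    syn <- if (any(fired_ms))
      rowSums(net$S[, fired_ms, drop = FALSE]) else numeric(n)
    fired_ms[] <- FALSE
    I <- noise + syn
    ms_t <- numeric(0); ms_i <- integer(0)
    for (s in seq_len(k)) {
      if (gated && delta > 0) {
        r <- abs(last_dv) > delta
        if (any(r)) {
          alpha[r] <- 0.04 * v[r]^2 + 140 - u[r]
          beta[r] <- net$a[r] * (net$b[r] * v[r] - u[r])
          rec[r] <- rec[r] + 1L
        }
      } else {
        alpha <- 0.04 * v^2 + 140 - u
        beta <- net$a * (net$b * v - u)
        rec <- rec + 1L
      }
      vn <- (alpha + 5 * v + I) * dt + v
      un <- beta * dt + u
      if (anyNA(vn) || any(!is.finite(vn)))
        stop(sprintf("non-finite state at %d ms (neuron %d)", t,
                     which(!is.finite(vn))[1]))
      last_dv <- vn - v
      f <- vn > 30
      if (any(f)) {
        vn[f] <- net$c[f]
        un[f] <- un[f] + net$d[f]
        counts[f] <- counts[f] + 1L
        fired_ms <- fired_ms | f
        ms_t <- c(ms_t, rep((t - 1) + s * dt, sum(f)))
        ms_i <- c(ms_i, which(f))
      }
      v <- vn; u <- un
      steps <- steps + 1L
    }
    ev_t[[t]] <- ms_t; ev_i[[t]] <- ms_i
  }
  structure(list(raster = data.frame(time_ms = unlist(ev_t),
                                     neuron = unlist(ev_i)),
                 counts = counts,
                 recompute_count = rec,
                 step_count = rep(steps, n),
                 n_neurons = n, duration = duration, dt = dt,
                 stepper = stepper, delta = delta, seed = seed),
            class = "network_sim")
}

#' @export
print.network_sim <- function(x, ...) {
  cat(sprintf("network_sim: %d neurons, %g ms, %d spikes (%s stepper)\n",
              x$n_neurons, x$duration, nrow(x$raster), x$stepper))
  invisible(x)
}

#' Per-neuron spike-count distribution
#'
#' Histogram of the number of spikes per neuron over a network run. The
#' counts sum to the number of neurons; neurons with no spikes appear in the
#' zero bin.
#'
#' @param x a `network_sim`, a raster data frame (`time_ms`, `neuron`), or a
#'   vector of per-neuron counts.
#' @param n_neurons required when `x` is a raster data frame.
#' @return A data frame with columns `spikes` and `n_neurons`.
#' @export
spike_count_distribution <- function(x, n_neurons = NULL) {
  counts <- if (inherits(x, "network_sim")) {
    x$counts
  } else if (is.data.frame(x)) {
    if (is.null(n_neurons)) stop("'n_neurons' required for a raster")
    tabulate(x$neuron, nbins = n_neurons)
  } else {
    as.integer(x)
  }
  tab <- table(factor(counts, levels = 0:max(counts, 0)))
  data.frame(spikes = as.integer(names(tab)),
             n_neurons = as.integer(tab))
}

#' Fraction of neurons within a spike-count band
#'
#' @param x as in [spike_count_distribution()].
#' @param lo,hi inclusive band bounds (defaults 6 and 24 spikes).
#' @param n_neurons required when `x` is a raster data frame.
#' @return Fraction in `[0, 1]`.
#' @export
band_fraction <- function(x, lo = 6, hi = 24, n_neurons = NULL) {
  counts <- if (inherits(x, "network_sim")) x$counts
  else if (is.data.frame(x)) {
    if (is.null(n_neurons)) stop("'n_neurons' required for a raster")
    tabulate(x$neuron, nbins = n_neurons)
  } else as.integer(x)
  mean(counts >= lo & counts <= hi)
}
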