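#' Fixed-point format descriptor
#'
#' Two's-complement Q-format: `word_bits` total bits of which `frac_bits`
#' are fractional. The default is the 30-bit word with a 14-bit fraction and
#' 16-bit integer part (Q16.14) used by the hardware data path.
#'
#' @param word_bits total word length in bits.
#' @param frac_bits fraction bits; `word_bits > frac_bits >= 0`.
#' @param signed signed flag (only signed arithmetic is implemented).
#' @return An object of class `fx_format`.
#' @export
fx_format <- function(word_bits = 30, frac_bits = 14, signed = TRUE) {
  stopifnot(length(word_bits) == 1L, length(frac_bits) == 1L)
  word_bits <- as.integer(word_bits); frac_bits <- as.integer(frac_bits)
  if (frac_bits < 0 || word_bits <= frac_bits)
    stop("need word_bits > frac_bits >= 0")
  if (!isTRUE(signed)) stop("only signed formats are supported")
  if (word_bits > 48) stop("word lengths above 48 bits are not supported")
  structure(list(word_bits = word_bits, frac_bits = frac_bits, signed = TRUE),
            class = "fx_format")
}

#' @export
print.fx_format <- function(x, ...) {
  cat(sprintf("Q%d.%d fixed point (%d-bit word, ULP = 2^-%d)\n",
              x$word_bits - x$frac_bits, x$frac_bits, x$word_bits,
              x$frac_bits))
  invisible(x)
}

#' Fixed-point values
#'
#' `fx_value()` wraps integral raw payloads in a format; [fx_quantize()]
#' rounds real numbers to the nearest representable value (half away from
#' zero rounds up). On overflow the default policy saturates to the
#' representable range, hardware-style, and flags the result
#' (`attr(x, "overflow")`); `overflow = "raise"` throws instead.
#'
#' @param raw integral raw payloads (two's-complement interpretation).
#' @param fmt an [fx_format()].
#' @return An `fx_value` vector.
#' @export
fx_value <- function(raw, fmt = fx_format()) {
  stopifnot(inherits(fmt, "fx_format"))
  raw <- as.numeric(raw)
  if (any(raw != round(raw))) stop("raw payloads must be integral")
  lim <- 2^(fmt$word_bits - 1)
  if (any(raw >= lim | raw < -lim)) stop("raw payload outside word range")
  structure(raw, fmt = fmt, class = "fx_value")
}

#' @rdname fx_value
#' @param x real numbers to quantize.
#' @param overflow `"saturate"` (flag and clamp) or `"raise"`.
#' @examples
#' fx_quantize(0.04, fx_format())          # raw 655, value 655/16384
#' @export
fx_quantize <- function(x, fmt = fx_format(),
                        overflow = c("saturate", "raise")) {
  stopifnot(inherits(fmt, "fx_format"))
  overflow <- match.arg(overflow)
  res <- fx_quantize_cpp(as.numeric(x), fmt$word_bits, fmt$frac_bits,
                         overflow == "raise")
  out <- fx_value(res$raw, fmt)
  attr(out, "overflow") <- res$overflow
  out
}

#' @export
as.double.fx_value <- function(x, ...) {
  as.vector(unclass(x), mode = "double") * 2^(-attr(x, "fmt")$frac_bits)
}

#' @export
print.fx_value <- function(x, ...) {
  fmt <- attr(x, "fmt")
  v <- as.double(x)
  cat(sprintf("fx_value (Q%d.%d): ", fmt$word_bits - fmt$frac_bits,
              fmt$frac_bits))
  cat(format(utils::head(v, 8)), if (length(v) > 8) "..." else "", "\n")
  invisible(x)
}

fx_raw <- function(x) as.numeric(unclass(x))

#' Shift-add decomposition of a positive constant
#'
#' Approximates `target` as a sum of powers of two `sum(2^-s)` so that
#' multiplication by the constant reduces to arithmetic shifts and adds.
#' Negative shift amounts are left shifts (powers above one). When `shifts`
#' is not given, a greedy binary expansion with at most `max_terms` terms is
#' used; the relative error of the approximation is recorded.
#'
#' @param target positive constant to approximate.
#' @param shifts optional explicit shift list (right-shift amounts).
#' @param max_terms greedy term budget.
#' @return An object of class `shift_add_constant` with fields `target`,
#'   `shifts`, `value` (`sum(2^-s)`) and `rel_error`.
#' @examples
#' shift_add_constant(0.04)   # 2^-5 + 2^-7 + 2^-11 = 0.0395508
#' @export
shift_add_constant <- function(target, shifts = NULL, max_terms = 3) {
  stopifnot(is.numeric(target), length(target) == 1L, is.finite(target),
            target > 0)
  if (is.null(shifts)) {
    shifts <- integer(0)
    r <- target
    while (length(shifts) < max_terms && r > 0) {
      s <- ceiling(-log2(r))      # largest power of two not exceeding r
      if (s > 40) break           # below any practical resolution
      shifts <- c(shifts, as.integer(s))
      r <- r - 2^(-s)
    }
    if (length(shifts) == 0L) stop("no usable decomposition for target")
  } else {
    shifts <- as.integer(shifts)
    if (length(shifts) == 0L) stop("'shifts' must be nonempty")
  }
  value <- sum(2^(-shifts))
  structure(list(target = target, shifts = shifts, value = value,
                 rel_error = abs(value - target) / target),
            class = "shift_add_constant")
}

#' @export
print.shift_add_constant <- function(x, ...) {
  cat(sprintf("shift-add constant: %g ~ %s = %.10g (rel err %.3g)\n",
              x$target,
              paste(sprintf("2^-%d", x$shifts), collapse = " + "),
              x$value, x$rel_error))
  invisible(x)
}

#' Multiply a fixed-point value by a shift-add constant
#'
#' Computes `sum_s arshift(x, s)` over the decomposition's shift list using
#' sign-preserving arithmetic shifts on the raw payload, matching the
#' hardware realization of constant multiplication.
#'
#' @param x an `fx_value`.
#' @param k a [shift_add_constant()].
#' @param overflow overflow policy, see [fx_quantize()].
#' @return An `fx_value` in the same format.
#' @export
fx_mul_shiftadd <- function(x, k, overflow = c("saturate", "raise")) {
  stopifnot(inherits(x, "fx_value"), inherits(k, "shift_add_constant"))
  overflow <- match.arg(overflow)
  fmt <- attr(x, "fmt")
  res <- fx_shiftadd_cpp(fx_raw(x), k$shifts, fmt$word_bits,
                         overflow == "raise")
  out <- fx_value(res$raw, fmt)
  attr(out, "overflow") <- res$overflow
  out
}

#' Linear-mode CORDIC squaring
#'
#' Computes `x^2` by linear-mode (multiplicative) CORDIC: the input value is
#' pre-scaled by a power of two into `[-1, 1]`, z-driven micro-rotations
#' `z <- z - d 2^-i`, `y <- y + d m 2^-i` (`d = sign(z)`) accumulate the
#' product, and the scaling exponent is re-applied squared. Two extra
#' iterations per scaling octave hold the absolute error within
#' `|x| * 2^-n_iter` before output quantization.
#'
#' @param x an `fx_value`.
#' @param n_iter base iteration count (>= 1); default `frac_bits + 2`.
#' @param overflow overflow policy.
#' @return An `fx_value` holding the squared value, with the executed
#'   iteration counts in `attr(, "iters")`.
#' @export
cordic_square <- function(x, n_iter = NULL, overflow = c("saturate", "raise")) {
  stopifnot(inherits(x, "fx_value"))
  overflow <- match.arg(overflow)
  fmt <- attr(x, "fmt")
  if (is.null(n_iter)) n_iter <- fmt$frac_bits + 2L
  if (!is.numeric(n_iter) || length(n_iter) != 1L || n_iter < 1)
    stop("'n_iter' must be a positive integer")
  res <- fx_cordic_square_cpp(fx_raw(x), fmt$word_bits, fmt$frac_bits,
                              as.integer(n_iter), overflow == "raise")
  out <- fx_value(res$raw, fmt)
  attr(out, "iters") <- res$iters
  attr(out, "overflow") <- res$overflow
  out
}

# Shift-add decompositions of the data path's constant multipliers.
fx_decompositions <- function(params, dt, max_terms = 3) {
  list(k_sq = shift_add_constant(0.04, max_terms = max_terms),
       k_lin = shift_add_constant(5, shifts = c(-2L, 0L)),
       b = shift_add_constant(params$b, max_terms = max_terms),
       a = shift_add_constant(params$a, max_terms = max_terms),
       dt = shift_add_constant(dt, max_terms = 1))
}

#' Constant-decomposition report
#'
#' The shift-add decompositions the fixed-point data path uses for its
#' constant multipliers, with approximation values and relative errors.
#'
#' @param params neuron parameters.
#' @param dt time step (ms); must be a power of two so that multiplication by
#'   `dt` is a single arithmetic shift.
#' @param max_terms greedy term budget per constant.
#' @return A data frame with columns `constant`, `target`, `shifts`,
#'   `approx_value`, `rel_error`.
#' @export
fx_constant_report <- function(params = neuron_params(), dt = 1 / 32,
                               max_terms = 3) {
  dec <- fx_decompositions(params, dt, max_terms)
  do.call(rbind, lapply(names(dec), function(nm) {
    k <- dec[[nm]]
    data.frame(constant = nm, target = k$target,
               shifts = paste(k$shifts, collapse = " "),
               approx_value = k$value, rel_error = k$rel_error)
  }))
}

dt_to_shift <- function(dt) {
  s <- round(log2(1 / dt))
  if (!isTRUE(all.equal(2^(-s), dt)))
    stop("fixed-point simulation requires dt to be a power of two")
  as.integer(s)
}

#' Fixed-point duplex/full simulation
#'
#' Runs the whole simulation on the emulated hardware data path: all state
#' and constants quantized to `fmt`, constant multiplications by shift-add
#' decompositions, the square term by linear-mode CORDIC, and the
#' quasi-static comparator gating the `alpha`/`beta` register updates.
#' Operation counts (adds, shifts, CORDIC iterations, compare/mux) are
#' accumulated separately for quasi-static and firing-state steps.
#'
#' @inheritParams simulate_neuron
#' @param fmt an [fx_format()]; Q16.14 by default.
#' @param n_iter CORDIC base iteration count; default `frac_bits + 2`.
#' @param overflow overflow policy, see [fx_quantize()].
#' @param max_terms shift-add term budget for the constant decompositions.
#' @return An `fx_trace` (also an `izh_trace`): dequantized `v`/`u` samples,
#'   `qs_mask`, `spike_mask`, recompute/step counters, the per-mode operation
#'   cost matrix in `$costs`, and the decomposition list in `$decompositions`.
#' @export
fx_simulate <- function(params, config, I = 0,
                        stepper = c("full", "duplex"), fmt = fx_format(),
                        n_iter = NULL, overflow = c("saturate", "raise"),
                        max_terms = 3) {
  stopifnot(inherits(params, "neuron_params"), inherits(config, "sim_config"),
            inherits(fmt, "fx_format"))
  stepper <- match.arg(stepper)
  overflow <- match.arg(overflow)
  if (is.null(n_iter)) n_iter <- fmt$frac_bits + 2L
  n <- as.integer(round(config$duration / config$dt))
  if (is.function(I)) I <- I((seq_len(n) - 1) * config$dt)
  if (length(I) == 1L) I <- rep(as.numeric(I), n)
  if (length(I) < n) stop("current waveform shorter than the run")
  I <- as.numeric(I[seq_len(n)])
  dec <- fx_decompositions(params, config$dt, max_terms)
  ic <- resolve_ic(config, params)
  q <- function(x) fx_raw(fx_quantize(x, fmt, overflow))
  res <- sim_neuron_fx_cpp(q(ic[["v0"]]), q(ic[["u0"]]), q(params$c),
                           q(params$d), q(params$v_peak), q(I), q(140),
                           q(config$delta),
                           dec$k_sq$shifts, dec$b$shifts, dec$a$shifts,
                           dec$k_lin$shifts, dt_to_shift(config$dt),
                           fmt$word_bits, fmt$frac_bits, as.integer(n_iter),
                           overflow == "raise", stepper == "duplex")
  scale <- 2^(-fmt$frac_bits)
  costs <- res$costs
  dimnames(costs) <- list(c("QS", "FS"),
                          c("adds", "shifts", "cordic_iters", "mux_compares"))
  structure(list(times = seq_len(n) * config$dt,
                 v = res$v_raw * scale, u = res$u_raw * scale,
                 v_raw = res$v_raw, u_raw = res$u_raw,
                 qs_mask = res$qs, spike_mask = res$spike,
                 recompute_count = res$recompute_count,
                 step_count = res$step_count,
                 costs = costs, overflow = res$overflow,
                 decompositions = dec, fmt = fmt, n_iter = n_iter,
                 params = params, config = config, stepper = stepper),
            class = c("fx_trace", "izh_trace"))
}

#' Floating-point twin of the fixed-point data path
#'
#' Simulates the same model as [fx_simulate()] — including the shift-add
#' *approximated* constants (e.g. 0.0396 in place of 0.04) — but in double
#' precision with exact squaring. Comparing this twin against the
#' fixed-point run isolates the quantization and CORDIC error of the
#' arithmetic from the (separately reported) constant-approximation error.
#'
#' @inheritParams fx_simulate
#' @return An `izh_trace`.
#' @export
fx_float_twin <- function(params, config, I = 0,
                          stepper = c("full", "duplex"), max_terms = 3) {
  stepper <- match.arg(stepper)
  dec <- fx_decompositions(params, config$dt, max_terms)
  p2 <- params
  p2$a <- dec$a$value
  p2$b <- dec$b$value
  n <- as.integer(round(config$duration / config$dt))
  if (is.function(I)) I <- I((seq_len(n) - 1) * config$dt)
  if (length(I) == 1L) I <- rep(as.numeric(I), n)
  I <- as.numeric(I[seq_len(n)])
  ic <- resolve_ic(config, params)
  res <- sim_neuron_cpp(ic[["v0"]], ic[["u0"]], p2$a, p2$b, p2$c, p2$d,
                        p2$v_peak, I, config$dt, config$delta,
                        stepper == "duplex", k_sq = dec$k_sq$value,
                        k_lin = dec$k_lin$value)
  structure(list(times = seq_len(n) * config$dt, v = res$v, u = res$u,
                 qs_mask = res$qs, spike_mask = res$spike,
                 recompute_count = res$recompute_count,
                 step_count = res$step_count,
                 params = params, config = config, stepper = stepper),
            class = "izh_trace")
}

#' Operation-cost weights
#'
#' Per-operation weights for the data-path cost model. Shifts default to
#' zero (pure routing in hardware); adds, CORDIC iterations and
#' compare/multiplex operations cost one unit each.
#'
#' @param add,shift,cordic,compare nonnegative weights.
#' @return A named numeric vector of class `op_cost_weights`.
#' @export
op_cost_weights <- function(add = 1, shift = 0, cordic = 1, compare = 1) {
  w <- c(add = add, shift = shift, cordic = cordic, compare = compare)
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be >= 0")
  structure(w, class = "op_cost_weights")
}

#' Per-step operation cost of the data path
#'
#' Weighted operation count of one quasi-static (`"qs"`) or firing-state
#' (`"fs"`) step of the fixed-point data path, derived from the shift-add
#' decomposition lengths and the CORDIC iteration count. Quasi-static steps
#' skip the CORDIC square and the `alpha`/`beta` register updates entirely.
#'
#' @param mode `"qs"` or `"fs"`.
#' @param params neuron parameters (their constants fix the decompositions).
#' @param dt time step (power of two).
#' @param fmt fixed-point format.
#' @param n_iter CORDIC base iterations; default `frac_bits + 2`.
#' @param weights an [op_cost_weights()] vector.
#' @param max_terms shift-add term budget.
#' @return A single weighted cost.
#' @export
step_op_cost <- function(mode = c("fs", "qs"), params = neuron_params(),
                         dt = 1 / 32, fmt = fx_format(), n_iter = NULL,
                         weights = op_cost_weights(), max_terms = 3) {
  mode <- match.arg(mode)
  if (is.null(n_iter)) n_iter <- fmt$frac_bits + 2L
  dec <- fx_decompositions(params, dt, max_terms)
  nsh <- function(k) sum(k$shifts != 0L)
  len <- function(k) length(k$shifts)
  # always executed: 5v, alpha+5v+I, *dt, +v, beta*dt+u, dv, two comparators
  adds <- (len(dec$k_lin) - 1) + 2 + 1 + 1 + 1
  shifts <- nsh(dec$k_lin) + 2
  cordic <- 0
  cmp <- 2
  if (mode == "fs") {
    adds <- adds + (len(dec$k_sq) - 1) + 2 + (len(dec$b) - 1) + 1 +
      (len(dec$a) - 1)
    shifts <- shifts + nsh(dec$k_sq) + nsh(dec$b) + nsh(dec$a)
    cordic <- n_iter
  }
  sum(weights * c(adds, shifts, cordic, cmp))
}

#' Energy proxy per spike
#'
#' A software stand-in for dynamic energy per spike: the weighted total
#' operation count of a run divided by its number of spikes. Strictly
#' decreasing in the number of quasi-static steps whenever the firing-state
#' step cost exceeds the quasi-static cost.
#'
#' @param x an `fx_trace`, or a per-mode cost matrix as in `fx_trace$costs`.
#' @param spikes a `spike_train` (or anything `length()`-able); at least one
#'   spike is required.
#' @param weights an [op_cost_weights()] vector.
#' @return Proxy units per spike.
#' @export
energy_proxy <- function(x, spikes, weights = op_cost_weights()) {
  costs <- if (is.matrix(x)) x else x$costs
  if (is.null(costs)) stop("'x' must carry an operation-cost matrix")
  n_sp <- length(spikes)
  if (n_sp < 1) stop("energy per spike undefined for zero spikes")
  total <- sum(colSums(costs) * as.numeric(weights))
  total / n_sp
}
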