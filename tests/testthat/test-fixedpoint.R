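fmt14 <- fx_format()                 # Q16.14, the hardware word

test_that("quantization is round-to-nearest within half an ULP", {
  expect_identical(as.numeric(unclass(fx_quantize(0, fmt14))), 0)
  q <- fx_quantize(0.04, fmt14)
  expect_identical(as.numeric(unclass(q)), 655)       # round(0.04 * 2^14)
  expect_equal(as.double(q), 655 / 16384)
  set.seed(7)
  x <- runif(10000, -3e4, 3e4)
  err <- abs(as.double(fx_quantize(x, fmt14)) - x)
  expect_lte(max(err), 2^-15)          # half ULP
})

test_that("overflow saturates by default and raises in strict mode", {
  big <- 2^15                           # outside Q16.14
  q <- fx_quantize(big, fmt14)
  expect_true(attr(q, "overflow"))
  expect_identical(as.numeric(unclass(q)), 2^29 - 1)  # positive rail
  qn <- fx_quantize(-big - 1, fmt14)
  expect_identical(as.numeric(unclass(qn)), -2^29)    # negative rail
  expect_error(fx_quantize(big, fmt14, overflow = "raise"), "overflow")
  expect_error(fx_format(word_bits = 14, frac_bits = 14), "word_bits")
})

test_that("greedy decomposition reproduces the canonical 0.04 constant", {
  k <- shift_add_constant(0.04)
  expect_identical(k$shifts, c(5L, 7L, 11L))
  expect_identical(k$value, 2^-5 + 2^-7 + 2^-11)
  expect_identical(round(k$value, 4), 0.0396)
  # powers above one decompose with left shifts
  k5 <- shift_add_constant(5)
  expect_identical(sort(k5$shifts), c(-2L, 0L))
  expect_identical(k5$value, 5)
  expect_identical(k5$rel_error, 0)
  expect_error(shift_add_constant(-1), "target")
})

test_that("shift-add multiplication matches the exact product within ULPs", {
  k <- shift_add_constant(0.04)
  one <- fx_quantize(1, fmt14)
  expect_identical(as.double(fx_mul_shiftadd(one, k)), 0.03955078125)
  zero <- fx_quantize(0, fmt14)
  expect_identical(as.double(fx_mul_shiftadd(zero, k)), 0)
  # sign symmetry under arithmetic shifts: within one ULP per term
  set.seed(11)
  x <- runif(1000, 0, 3e4)
  pos <- fx_mul_shiftadd(fx_quantize(x, fmt14), k)
  neg <- fx_mul_shiftadd(fx_quantize(-x, fmt14), k)
  expect_lte(max(abs(unclass(pos) + unclass(neg))), length(k$shifts))
  # exactness: against the exact real product, truncation <= #shifts ULPs
  raws <- unclass(fx_quantize(runif(1000, -3e4, 3e4), fmt14))
  acc <- unclass(fx_mul_shiftadd(fx_value(raws, fmt14), k))
  exact <- raws * k$value
  expect_lte(max(abs(acc - exact)), length(k$shifts))
})

test_that("CORDIC squaring converges to the exact square", {
  expect_identical(as.double(cordic_square(fx_quantize(0, fmt14))), 0)
  q3 <- fx_quantize(3, fmt14)
  r <- cordic_square(q3, n_iter = 16)
  # bound: |x| 2^-16 algorithmic + half-ULP output rounding
  expect_lte(abs(as.double(r) - as.double(q3)^2), 3 * 2^-16 + 2^-15)
  expect_error(cordic_square(q3, n_iter = 0), "n_iter")
  # error at worst halves per added iteration (high-resolution format so
  # output rounding does not mask the algorithmic error)
  hi <- fx_format(44, 22)
  set.seed(3)
  x <- fx_quantize(runif(500, -128, 128), hi)
  exact <- as.double(x)^2
  maxerr <- vapply(6:14, function(n)
    max(abs(as.double(cordic_square(x, n_iter = n)) - exact)), numeric(1))
  expect_true(all(maxerr[-1] <= 0.55 * maxerr[-length(maxerr)]))
})

test_that("the fixed-point duplex path honors the gate and counts its work", {
  cfg <- sim_config(duration = 200, delta = 1 / 8)
  fx <- fx_simulate(tonic, cfg, I = 16, stepper = "duplex")
  expect_identical(unname(fx$costs["QS", "cordic_iters"]), 0)  # QS skips v^2
  expect_gt(fx$costs["FS", "cordic_iters"], 0)
  n_qs <- sum(fx$qs_mask)
  expect_identical(unname(fx$costs["QS", "mux_compares"]), 2 * n_qs)
  # per-step FS cost exceeds QS cost under the default weights
  expect_gt(step_op_cost("fs"), step_op_cost("qs"))
  # analytic per-step costs agree with the counters the run accumulated
  w <- op_cost_weights()
  qs_measured <- sum(fx$costs["QS", ] * as.numeric(w)) / n_qs
  expect_equal(qs_measured, step_op_cost("qs"), tolerance = 1e-12)
})

test_that("gate-off equivalence holds bit-exactly in fixed point", {
  cfg <- sim_config(duration = 2000, delta = 0)
  dup <- fx_simulate(tonic, cfg, I = 16, stepper = "duplex")
  full <- fx_simulate(tonic, cfg, I = 16, stepper = "full")
  expect_identical(dup$v_raw, full$v_raw)
  expect_identical(dup$u_raw, full$u_raw)
})

test_that("Q16.14 trajectory tracks its float twin within 1 mV RMS over a period", {
  # one tonic period at the hardware drive current
  ref <- simulate_neuron(tonic, sim_config(duration = 50), I = 16)
  s <- as.numeric(detect_spikes(ref))
  dur <- ceiling(s[3])                      # covers a full steady period
  for (del in c(0, 1 / 128, 1 / 8)) {
    cfg <- sim_config(duration = dur, delta = del)
    stepper <- if (del > 0) "duplex" else "full"
    fx <- fx_simulate(tonic, cfg, I = 16, stepper = stepper)
    fl <- fx_float_twin(tonic, cfg, I = 16, stepper = stepper)
    expect_lt(sqrt(mean((fx$v - fl$v)^2)), 1)
  }
})

test_that("energy proxy is linear in weights and favors quasi-static runs", {
  cfg <- sim_config(duration = 500, delta = 1 / 8)
  dx <- fx_simulate(tonic, cfg, I = 16, stepper = "duplex")
  full <- fx_simulate(tonic, cfg, I = 16, stepper = "full")
  sp_dx <- detect_spikes(dx); sp_full <- detect_spikes(full)
  expect_gt(length(sp_dx), 0)
  w <- op_cost_weights()
  expect_gt(energy_proxy(full, sp_full, w), energy_proxy(dx, sp_dx, w))
  expect_identical(energy_proxy(dx, sp_dx, op_cost_weights(0, 0, 0, 0)), 0)
  w2 <- op_cost_weights(2, 0, 2, 2)
  expect_equal(energy_proxy(dx, sp_dx, w2), 2 * energy_proxy(dx, sp_dx, w))
  expect_error(energy_proxy(dx, numeric(0)), "zero spikes")
})

test_that("the constant report covers the data path with small errors", {
  rep_ <- fx_constant_report()
  expect_setequal(rep_$constant, c("k_sq", "k_lin", "b", "a", "dt"))
  expect_true(all(rep_$rel_error < 0.03))
  expect_identical(rep_$rel_error[rep_$constant == "dt"], 0)  # exact shift
  expect_error(fx_simulate(tonic, sim_config(dt = 0.3, duration = 3)),
               "power of two")
})
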