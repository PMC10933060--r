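test_that("single Euler step matches the hand-evaluated update", {
  st <- duplex_state(-65, -13, tonic)
  st2 <- step_izhikevich(st, tonic, I = 0, dt = 1 / 32)
  # dv = (0.04*65^2 - 325 + 140 + 13) / 32 = -3/32
  expect_identical(st2$v, -65 - 3 / 32)
  expect_identical(st2$v, -65.09375)
  # u starts on its nullcline (u = b v), so du is exactly zero
  expect_identical(st2$u, -13)
  expect_identical(st2$recompute_count, 1L)
  expect_identical(st2$step_count, 1L)
})

test_that("step preconditions reject bad inputs", {
  st <- duplex_state(-65, -13, tonic)
  expect_error(step_izhikevich(st, tonic, I = 0, dt = 0), "dt")
  expect_error(step_izhikevich(st, tonic, I = NaN, dt = 1 / 32), "non-finite")
  expect_error(step_duplex(st, tonic, I = 0, dt = 1 / 32, delta = -0.1),
               "delta")
  expect_error(duplex_state(Inf, 0, tonic), "finite")
  expect_error(neuron_params(a = -0.01), "positive")
  expect_error(neuron_params(c = 31), "below")
})

test_that("after-spike reset follows the strict v > v_peak rule", {
  st <- duplex_state(31, -13, tonic)
  r <- apply_reset(st, tonic)
  expect_true(r$spiked)
  expect_identical(r$state$v, -65)     # v -> c
  expect_identical(r$state$u, -7)      # u -> u + d
  # below the cutoff: unchanged
  r2 <- apply_reset(duplex_state(29.9, -13, tonic), tonic)
  expect_false(r2$spiked)
  expect_identical(r2$state$v, 29.9)
  # exactly at the cutoff: strict inequality, no reset
  r3 <- apply_reset(duplex_state(30, -13, tonic), tonic)
  expect_false(r3$spiked)
})

test_that("R single-step composition reproduces the compiled loop exactly", {
  n <- 2000
  tr <- run_tonic(duration = n / 32, delta = 0.05)
  st <- duplex_state(-65, -13, tonic)
  v_seq <- numeric(n)
  qs_seq <- logical(n)
  for (i in seq_len(n)) {
    before <- st$recompute_count
    st <- step_duplex(st, tonic, I = 4, dt = 1 / 32, delta = 0.05)
    qs_seq[i] <- st$recompute_count == before
    st <- apply_reset(st, tonic)$state
    v_seq[i] <- st$v
  }
  expect_identical(v_seq, tr$v)
  expect_identical(qs_seq, as.logical(tr$qs_mask))
  expect_identical(st$recompute_count, tr$recompute_count)
})

test_that("gate-off (delta = 0) duplex equals the full stepper exactly", {
  ref <- run_tonic(duration = 2000, delta = 0, stepper = "full")
  dx <- simulate_neuron(tonic, tonic_cfg(2000, delta = 0), I = 4,
                        stepper = "duplex")
  expect_identical(dx$v, ref$v)
  expect_identical(dx$u, ref$u)
  expect_false(any(dx$qs_mask))
})

test_that("an always-closed gate freezes the cache and u grows linearly", {
  # huge threshold: only the cold-start step recomputes (short horizon: the
  # frozen-cache voltage map has slope 1 + 5 dt > 1, so any long run
  # eventually escapes even an enormous gate)
  tr <- simulate_neuron(tonic, sim_config(duration = 20 / 32, delta = 1e9,
                                          v0 = -65, u0 = -10),
                        I = 0, stepper = "duplex")
  expect_identical(tr$recompute_count, 1L)
  expect_true(all(tr$qs_mask[-1]))
  # u is an arithmetic progression with common difference beta * dt
  beta0 <- tonic$a * (tonic$b * -65 - -10)
  expect_equal(diff(tr$u), rep(beta0 * (1 / 32), tr$step_count - 1),
               tolerance = 1e-12)
})

test_that("tonic drive yields periodic spiking with constant steady ISI", {
  tr <- run_tonic(duration = 20000)
  s <- as.numeric(detect_spikes(tr))
  expect_gt(length(s), 10)
  isi <- diff(s)[-1]                       # drop the transient interval
  expect_lt((max(isi) - min(isi)) / mean(isi), 0.01)   # constant to < 1 %
})

test_that("waveform and config validation reject impossible runs", {
  expect_error(simulate_neuron(tonic, tonic_cfg(100), I = numeric(10)),
               "waveform")
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(duration = 0.001, dt = 1 / 32), "duration")
  expect_error(sim_config(delta = -1), "delta")
  # single-step run is legal
  tr <- simulate_neuron(tonic, sim_config(duration = 1 / 32, dt = 1 / 32),
                        I = 0)
  expect_identical(tr$step_count, 1L)
})

test_that("spike detection is local: slicing a trace slices its train", {
  tr <- run_tonic(duration = 4000)
  full_train <- as.numeric(detect_spikes(tr))
  n <- tr$step_count
  first <- slice_trace(tr, 1:(n / 2))
  second <- slice_trace(tr, (n / 2 + 1):n)
  expect_identical(c(as.numeric(detect_spikes(first)),
                     as.numeric(detect_spikes(second))), full_train)
  # flat subthreshold trace has an empty train
  flat <- simulate_neuron(tonic, tonic_cfg(100), I = 0)
  expect_length(detect_spikes(flat), 0)
})

test_that("trajectories stay in the physiological envelope for both steppers", {
  for (I in c(0, 4, 12, 20)) {
    for (del in c(0, 0.1)) {
      tr <- simulate_neuron(tonic, tonic_cfg(2000, delta = del), I = I,
                            stepper = if (del > 0) "duplex" else "full")
      expect_true(all(tr$v >= -90 & tr$v <= 40),
                  info = sprintf("I=%g delta=%g", I, del))
    }
  }
})

test_that("duplex trajectory at a large threshold still spikes tonically", {
  dx <- run_tonic(duration = 20000, delta = 0.2)
  ref <- run_tonic(duration = 20000)
  n_dx <- sum(dx$spike_mask); n_ref <- sum(ref$spike_mask)
  expect_gt(n_dx, 0.5 * n_ref)
  expect_lt(n_dx, 2 * n_ref)
  # waveform stays in a spiking regime: full range still covered
  expect_gt(max(dx$v), 25)
  expect_lt(min(dx$v), -60)
})
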