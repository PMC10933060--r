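test_that("random network build is deterministic and respects Dale's sign rule", {
  n1 <- random_network(seed = 42)
  n2 <- random_network(seed = 42)
  expect_identical(n1$S, n2$S)
  expect_identical(n1$a, n2$a)
  expect_identical(dim(n1$S), c(1000L, 1000L))
  expect_true(all(n1$S[, 1:800] >= 0))       # excitatory columns
  expect_true(all(n1$S[, 801:1000] <= 0))    # inhibitory columns
  # excitatory parameters interpolate toward bursting, inhibitory toward fast
  expect_true(all(n1$c[1:800] >= -65 & n1$c[1:800] <= -50))
  expect_true(all(n1$a[801:1000] >= 0.02 & n1$a[801:1000] <= 0.1))
})

test_that("a silent network stays silent", {
  net <- random_network(n_exc = 40, n_inh = 10, seed = 1)
  net$S[] <- 0
  sim <- simulate_network(net, duration = 200, noise_exc = 0, noise_inh = 0)
  expect_identical(nrow(sim$raster), 0L)
  expect_true(all(sim$counts == 0))
})

test_that("raster, histogram and band fraction agree on spike totals", {
  net <- random_network(seed = 5)
  sim <- simulate_network(net, duration = 1000)
  dist <- spike_count_distribution(sim)
  expect_identical(sum(dist$n_neurons), 1000L)
  expect_identical(sum(dist$spikes * dist$n_neurons), nrow(sim$raster))
  expect_identical(spike_count_distribution(sim$raster, 1000), dist)
  # most neurons spike 6..24 times in a second
  expect_gt(band_fraction(sim), 0.8)
  expect_lt(band_fraction(sim), 0.98)
  # seeded determinism end to end
  sim2 <- simulate_network(net, duration = 1000)
  expect_identical(sim2$raster, sim$raster)
})

test_that("STDP pair rule closed forms and bounded updates", {
  cfg <- stdp_config(a_plus = 0.05, a_minus = 0.055)
  expect_identical(stdp_update(0.3, numeric(0), numeric(0), cfg), 0.3)
  # single pre at 0, post at tau_plus: dw = a_plus * exp(-1)
  expect_equal(stdp_update(0, 0, 20, cfg, bounds = c(-1, 1)),
               0.05 * exp(-1))
  # reversed order depresses
  expect_equal(stdp_update(0, 20, 0, cfg, bounds = c(-1, 1)),
               -0.055 * exp(-1))
  # simultaneous spikes change nothing
  expect_identical(stdp_update(0.5, 5, 5, cfg), 0.5)
  # weights never leave their bounds over random trains
  set.seed(9)
  for (rep in 1:50) {
    w <- stdp_update(runif(1), sort(runif(20, 0, 200)),
                     sort(runif(20, 0, 200)), cfg, bounds = c(0, 1))
    expect_true(w >= 0 && w <= 1)
  }
  # nearest-neighbour pairing uses only adjacent pairs
  nn <- stdp_config(nearest_neighbor = TRUE)
  expect_equal(stdp_update(0, c(0, 10), 30, nn, bounds = c(-1, 1)),
               0.05 * exp(-20 / 20))
})

test_that("pattern encoding maps pixels to drive currents", {
  e <- pattern_stimulus("E"); h <- pattern_stimulus("H")
  expect_identical(length(e$grid), 42L)
  expect_gt(sum(abs(e$grid - h$grid)), 0)            # patterns differ
  blank <- pattern_stimulus("blank", grid = rep(0, 42), i_on = 10, i_off = 1)
  expect_identical(encode_pattern(blank), rep(1, 42))
  Ie <- encode_pattern(e)
  expect_identical(sum(Ie == e$i_on), sum(e$grid))
  expect_identical(sum(Ie == e$i_off), 42L - sum(e$grid))
})

test_that("untrained network output is silent for both patterns", {
  r <- train_and_test(seed = 2, retrain = FALSE)
  expect_true(all(r$out_counts == 0))
  expect_false(r$diverged)
})

test_that("training on E yields full E/H discrimination (full stepper)", {
  r <- train_and_test(seed = 1, stepper = "full")
  expect_true(r$success)
  expect_true(all(r$out_counts[r$labels == "E"] > 0))
  expect_true(all(r$out_counts[r$labels == "H"] == 0))
  expect_false(r$diverged)
  # selectivity: pattern synapses saturated, off-pattern synapses low
  on <- pattern_stimulus("E")$grid > 0
  expect_gt(mean(r$net$W12[on, ]), 0.9 * r$net$w12_bounds[2])
  expect_lt(mean(r$net$W12[!on, ]), 0.3 * r$net$w12_bounds[2])
})

test_that("a retrained duplex network discriminates at least as well as
           transferred full-stepper weights", {
  full <- train_and_test(seed = 1, stepper = "full")
  retrained <- train_and_test(seed = 1, stepper = "duplex", delta = 1 / 8)
  transferred <- train_and_test(net = full$net, stepper = "duplex",
                                delta = 1 / 8, retrain = FALSE)
  expect_true(retrained$success)
  score <- function(r) sum(r$out_counts[r$labels == "E"] > 0) +
    sum(r$out_counts[r$labels == "H"] == 0)
  expect_gte(score(retrained), score(transferred))
})

test_that("per-layer CSP lies in [0,100] and grows with the threshold", {
  net <- train_network(layered_network(seed = 3))
  pats <- rep(list(pattern_stimulus("E"), pattern_stimulus("H")), 2)
  mean_csp <- sapply(c(0.005, 0.05, 0.1), function(del) {
    r <- test_network(net, pats, stepper = "duplex", delta = del)
    all_csp <- unlist(r$csp_by_layer)
    expect_true(all(all_csp >= 0 & all_csp <= 100))
    sapply(r$csp_by_layer, mean)
  })
  for (ly in rownames(mean_csp))
    expect_true(all(diff(mean_csp[ly, ]) >= 0), info = ly)
})
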