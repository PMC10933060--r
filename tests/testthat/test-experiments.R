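test_that("config validation fills defaults and rejects contradictions", {
  cfg <- validate_config()
  expect_identical(cfg$dt, 1 / 32)
  expect_identical(cfg$delta, 0)
  expect_identical(cfg$fx$word_bits, 30)
  expect_identical(cfg$fx$frac_bits, 14)
  expect_identical(cfg$a, 0.02)
  expect_error(validate_config(list(delta = -1)), "delta")
  expect_error(validate_config(list(dt = 0)), "dt")
  expect_error(validate_config(list(fx = list(word_bits = 10, frac_bits = 14,
                                              overflow = "saturate"))),
               "frac_bits")
  expect_error(validate_config(list(nonsense = 1)), "unknown")
  expect_error(validate_config(list(stepper = "rk4")), "stepper")
})

test_that("unknown experiments are rejected, registry names are stable", {
  expect_error(run_experiment("no_such_thing"), "unknown experiment")
})

test_that("experiment outputs are byte-identical across repeated runs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p <- list(duration = 3000, deltas = c(0.01, 0.1))
  run_experiment("threshold_sweep", params = p, seed = 7, output_dir = d1)
  run_experiment("threshold_sweep", params = p, seed = 7, output_dir = d2)
  f1 <- file.path(d1, "threshold_sweep.csv"); f2 <- file.path(d2, "threshold_sweep.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))
  s <- jsonlite::read_json(file.path(d1, "summary.json"))
  expect_identical(s$seed, 7L)
  expect_identical(s$experiment, "threshold_sweep")
})

test_that("current-sweep experiment: CSP within range, declining in drive", {
  d <- withr::local_tempdir()
  s <- run_experiment("current_sweep",
                      params = list(currents = c(2, 8, 16), duration = 3000),
                      seed = 1, output_dir = d)
  cspv <- unlist(s$metrics$csp_pct)
  expect_true(all(cspv >= 0 & cspv <= 100))
  expect_true(all(diff(cspv) <= 0))
  expect_true(file.exists(file.path(d, "current_sweep.csv")))
})

test_that("remaining experiments complete on reduced parameters", {
  d <- withr::local_tempdir()
  s1 <- run_experiment("random_net", params = list(duration = 300),
                       seed = 2, output_dir = d)
  expect_true(file.exists(file.path(d, "raster.csv")))
  s2 <- run_experiment("fx_single_neuron", params = list(duration = 300),
                       seed = 2, output_dir = d)
  expect_true(is.finite(s2$metrics$rmsd_vs_float))
  expect_gt(s2$metrics$csp_pct, 0)
  s3 <- run_experiment("layer_csp",
                       params = list(n_present = 5, n_test = 1,
                                     deltas = c(0.01, 0.1)),
                       seed = 2, output_dir = d)
  expect_true(file.exists(file.path(d, "layer_csp.csv")))
})

test_that("fixtures regenerate identically and match the shipped patterns", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- generate_fixtures("patterns", dir = d1)
  p <- read_pattern(file.path(d1, "E.txt"))
  expect_identical(p$grid, pattern_stimulus("E")$grid)
  shipped <- system.file("extdata", "E.txt", package = "duplexneuron")
  expect_identical(readLines(shipped), readLines(file.path(d1, "E.txt")))
  w1 <- generate_fixtures("random_net_weights", seed = 4, dir = d1)
  w2 <- generate_fixtures("random_net_weights", seed = 4, dir = d2)
  expect_identical(readLines(w1), readLines(w2))
  pr <- generate_fixtures("current_protocols", dir = d1, duration = 100)
  prot <- read.csv(pr[1])
  expect_gte(max(prot$time_ms), 100)      # covers the full duration
})
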