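test_that("amplitude suppression reproduces its endpoint identities", {
  withr::with_seed(1, {
    ref <- matrix(rnorm(140), 20, 7)
    dev <- matrix(rnorm(140, sd = 0.1), 20, 7)
  })
  tre <- ref + dev
  expect_equal(amplitude_suppression(ref, tre, ref, 1:4), 100)
  expect_equal(amplitude_suppression(ref, tre, tre, 1:4), 0)
  expect_equal(amplitude_suppression(ref, tre, ref + 0.5 * dev, 1:4), 50,
               tolerance = 1e-9)
  # no tremor deviation -> undefined, not infinite
  expect_true(is.na(amplitude_suppression(ref, ref, ref, 1:4)))
  # invariant to a uniform time shift of all three trajectories
  sh <- 3L
  idx <- c((sh + 1):20, 1:sh)
  expect_equal(amplitude_suppression(ref[idx, ], tre[idx, ],
                                     (ref + 0.5 * dev)[idx, ], 1:4),
               50, tolerance = 1e-9)
})

test_that("occurrence counts strict per-step improvements within tolerance", {
  n <- 40
  ref <- matrix(0, n, 7)
  dev <- matrix(0, n, 7); dev[, 4] <- 0.2
  tre <- ref + dev
  sup_good <- ref + 0.5 * dev
  expect_equal(occurrence(ref, tre, ref, 4), 100)
  expect_equal(occurrence(ref, tre, tre, 4), 0)       # strict inequality
  expect_equal(occurrence(ref, tre, sup_good, 4), 100)
  # suppresses the affected axis but drags an unaffected one beyond eps
  sup_drag <- sup_good
  sup_drag[1:10, 1] <- 0.5
  expect_equal(occurrence(ref, tre, sup_drag, 4, eps = 0.1), 75)
})

test_that("torque suppression and the windowed curve behave at endpoints", {
  tau_t <- matrix(sin(seq(0, 8 * pi, length.out = 60)), ncol = 1)
  expect_equal(torque_suppression(tau_t * 0, tau_t), 100)
  expect_equal(torque_suppression(tau_t, tau_t), 0)
  expect_equal(torque_suppression(tau_t / 4, tau_t), 75, tolerance = 1e-9)

  ref <- matrix(0, 60, 7)
  dev <- matrix(0, 60, 7); dev[, 4] <- sin(seq(0, 8 * pi, length.out = 60))
  curve <- suppression_curve(ref, ref + dev, ref + 0.1 * dev, 4,
                             dt = 1 / 30, f1 = 5)
  expect_equal(curve[!is.na(curve)],
               rep(90, sum(!is.na(curve))), tolerance = 1e-9)
})

test_that("oracle policy attains the 100 percent upper bound, zero policy does not", {
  env <- fix_env(axes = c(2, 4), profile = "testing")
  res <- simulate_episode(env, oracle_policy(), seed = 5)
  rec <- res$records
  ref <- as.matrix(rec[paste0("ref_q", 1:7)])
  tre <- as.matrix(rec[paste0("tremor_q", 1:7)])
  sup <- as.matrix(rec[paste0("sup_q", 1:7)])
  expect_equal(amplitude_suppression(ref, tre, sup, c(2, 4)), 100,
               tolerance = 1e-9)
  expect_equal(occurrence(ref, tre, sup, c(2, 4)), 100)

  res0 <- simulate_episode(env, zero_policy(), seed = 5)
  rec0 <- res0$records
  expect_equal(amplitude_suppression(as.matrix(rec0[paste0("ref_q", 1:7)]),
                                     as.matrix(rec0[paste0("tremor_q", 1:7)]),
                                     as.matrix(rec0[paste0("sup_q", 1:7)]),
                                     c(2, 4)),
               0, tolerance = 1e-9)
})

test_that("the protocol enumerates 15 combinations x movements deterministically", {
  combos <- tremor_axis_combinations()
  expect_length(combos, 15L)
  expect_setequal(vapply(combos, paste, character(1), collapse = ","),
                  unique(vapply(combos, paste, character(1), collapse = ",")))
  # reduced protocol run: 2 combos x 2 movements x 1 episode
  lib <- movement_library(seed = 1)
  movements <- lib[c(1, 3)]
  rep1 <- run_protocol(zero_policy(), movements, n_episodes = 1L, seed = 4,
                       combos = list(4L, c(1L, 4L)))
  rep2 <- run_protocol(zero_policy(), movements, n_episodes = 1L, seed = 4,
                       combos = list(4L, c(1L, 4L)))
  expect_identical(rep1, rep2)
  expect_equal(nrow(rep1), 4L)
  expect_true(all(abs(rep1$amplitude_mean) < 1e-9))
  expect_true(all(rep1$occurrence_mean == 0))
  expect_true(all(rep1$torque_mean == 0))
})

test_that("protocol reports round-trip to CSV and JSON", {
  lib <- movement_library(seed = 1)
  rep1 <- run_protocol(oracle_policy(), lib[1], n_episodes = 1L, seed = 2,
                       combos = list(4L))
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  save_protocol_report(rep1, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(back$amplitude_mean, rep1$amplitude_mean, tolerance = 1e-6)
  summ <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(summ$amplitude_suppression_mean, 100, tolerance = 1e-6)
  expect_equal(summ$occurrence_mean, 100, tolerance = 1e-6)
})
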