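test_that("principal axis dominates the labelled movement", {
  for (lab in names(movement_labels())) {
    tr <- generate_synthetic_movement(lab, 4, 1 / 30, 1, seed = 1)
    pr <- movement_labels()[[lab]]
    vel <- apply(tr$angles, 2, diff) / tr$dt
    v_pr <- max(abs(vel[, pr]))
    v_other <- max(abs(vel[, -pr]))
    expect_gt(v_pr, 0.3)
    expect_lt(v_other, 0.1 * v_pr)
  }
})

test_that("zero amplitude gives a constant neutral-pose trajectory", {
  tr <- generate_synthetic_movement("elbow_flexion_extension",
                                    amplitude_scale = 0, seed = 5)
  expect_equal(unname(tr$angles),
               matrix(rep(neutral_pose(), each = nrow(tr$angles)), ncol = 7),
               tolerance = 1e-12)
})

test_that("generation is deterministic given the seed", {
  a <- generate_synthetic_movement("shoulder_flexion_extension", seed = 9)
  b <- generate_synthetic_movement("shoulder_flexion_extension", seed = 9)
  c <- generate_synthetic_movement("shoulder_flexion_extension", seed = 10)
  expect_identical(a$angles, b$angles)
  expect_false(identical(a$angles, c$angles))
})

test_that("generated trajectories respect anatomical joint limits", {
  lims <- joint_limits()
  for (seed in 1:3) {
    for (lab in names(movement_labels())) {
      tr <- generate_synthetic_movement(lab, seed = seed)
      for (j in 1:7) {
        expect_true(all(tr$angles[, j] >= lims["lower", j] - 1e-12))
        expect_true(all(tr$angles[, j] <= lims["upper", j] + 1e-12))
      }
    }
  }
})

test_that("voluntary spectral content stays below 2 Hz", {
  tr <- generate_synthetic_movement("shoulder_abduction_adduction",
                                    duration_s = 8, seed = 2)
  for (j in 1:7) {
    x <- tr$angles[, j] - mean(tr$angles[, j])
    if (sd(x) < 1e-9) next
    expect_lt(dominant_freqs(x, tr$dt, 1), 2)
  }
})

test_that("unknown labels and bad dt are rejected", {
  expect_error(generate_synthetic_movement("jumping_jacks"), "unknown")
  expect_error(generate_synthetic_movement("elbow_flexion_extension",
                                           dt = -0.1), "dt")
  expect_error(generate_synthetic_movement("elbow_flexion_extension",
                                           duration_s = 0.03), "3")
})

test_that("save/load round-trips a trajectory", {
  tr <- fix_trajectory(seed = 3)
  path <- tempfile(fileext = ".csv")
  save_trajectory(tr, path)
  tr2 <- load_trajectory(path)
  expect_equal(unname(tr2$angles), unname(tr$angles), tolerance = 1e-9)
  expect_equal(tr2$dt, tr$dt, tolerance = 1e-9)
  expect_identical(tr2$movement_label, tr$movement_label)
})

test_that("malformed trajectory files are rejected with named rows", {
  p <- tempfile(fileext = ".csv")
  writeLines("t,q1,q2,q3,q4,q5,q6", p)        # 6 joint columns
  writeLines(c("t,q1,q2,q3,q4,q5,q6", "0,0,0,0,0,0,0"), p)
  expect_error(load_trajectory(p), "expected 7 joint columns")

  writeLines(c("t,q1,q2,q3,q4,q5,q6,q7",
               "0,0,0,0,0.4,0,0,0",
               "0.1,0,0,0,0.4,0,0,0",
               "0.05,0,0,0,0.4,0,0,0"), p)
  expect_error(load_trajectory(p), "non-monotone.*row 3")

  writeLines("t,q1,q2,q3,q4,q5,q6,q7", p)     # header only
  expect_error(load_trajectory(p), "empty")
})

test_that("resampling preserves identity, constants, and linear midpoints", {
  tr <- fix_trajectory(seed = 4)
  same <- resample_trajectory(tr, tr$dt)
  expect_equal(same$angles, tr$angles, tolerance = 1e-12)

  const <- joint_trajectory(matrix(rep(neutral_pose(), each = 10), ncol = 7),
                            0.1, "elbow_flexion_extension")
  rs <- resample_trajectory(const, 0.037)
  expect_equal(unname(rs$angles),
               matrix(rep(neutral_pose(), each = nrow(rs$angles)), ncol = 7),
               tolerance = 1e-12)

  ramp <- joint_trajectory(outer(0:10, rep(0.05, 7)), 0.1,
                           "elbow_flexion_extension")
  half <- resample_trajectory(ramp, 0.05)
  mids <- half$angles[seq(2, nrow(half$angles) - 1, by = 2), 1]
  expect_equal(mids, (ramp$angles[1:10, 1] + ramp$angles[2:11, 1]) / 2,
               tolerance = 1e-12)

  expect_error(resample_trajectory(ramp, 10), "duration")
})

test_that("movement library has two recordings of each movement", {
  lib <- movement_library(seed = 1)
  expect_length(lib, 8L)
  labs <- vapply(lib, `[[`, character(1), "movement_label")
  expect_equal(unname(table(labs)[names(movement_labels())]),
               rep(2L, 4), ignore_attr = TRUE)
  expect_false(identical(lib[[1]]$angles, lib[[2]]$angles))
})
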