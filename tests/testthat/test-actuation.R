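test_that("as-printed force components reproduce the worked example", {
  f <- force_components(c(0, 0, 0), c(1, 0, 0), 1, mode = "as_printed")
  expect_equal(f, c(1, 0, 1), tolerance = 1e-12)
  # the same geometry in unit-vector mode pulls the endpoint to the anchor
  u <- force_components(c(0, 0, 0), c(1, 0, 0), 1, mode = "unit_vector")
  expect_equal(u, c(-1, 0, 0), tolerance = 1e-12)
  for (mode in c("unit_vector", "as_printed")) {
    expect_equal(force_components(c(0, 0, 0), c(1, 2, 3), 0, mode),
                 c(0, 0, 0))
  }
  expect_error(force_components(c(1, 1, 1), c(1, 1, 1), 5), "coincide")
  expect_error(force_components(c(0, 0, 0), c(1, 0, 0), -1), ">= 0")
})

test_that("unit-vector force magnitude equals F; as-printed does not", {
  withr::with_seed(4, {
    for (i in 1:20) {
      p1 <- rnorm(3); p2 <- rnorm(3); F <- runif(1, 0.1, 50)
      u <- force_components(p1, p2, F, "unit_vector")
      expect_equal(sqrt(sum(u^2)), F, tolerance = 1e-9)
    }
  })
  # generic-geometry discrepancy pins the printed construction
  a <- force_components(c(0, 0, 0), c(1, 1, 1), 1, "as_printed")
  expect_gt(abs(sqrt(sum(a^2)) - 1), 0.1)
})

test_that("actuator torque follows the right-hand rule and bilinearity", {
  expect_equal(actuator_torque(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1)),
               c(0, 1, 0), tolerance = 1e-12)
  expect_equal(actuator_torque(c(2, 0, 0), c(0, 0, 0), c(0, 0, 2)),
               c(0, 4, 0), tolerance = 1e-12)
  # parallel force and lever arm -> no torque
  expect_equal(actuator_torque(c(0, 0, 3), c(0, 0, 0), c(0, 0, 1)),
               c(0, 0, 0), tolerance = 1e-12)
  # doubling the lever arm doubles every component
  f <- c(0.3, -1, 2)
  t1 <- actuator_torque(f, c(0, 0, 0), c(1, 2, 3))
  t2 <- actuator_torque(f, c(0, 0, 0), c(2, 4, 6))
  expect_equal(t2, 2 * t1, tolerance = 1e-12)
})

test_that("total joint torques: zeros, attribution, and additivity", {
  lay <- default_exo_layout()
  ang <- neutral_pose()
  expect_equal(as.numeric(total_joint_torques(lay, numeric(7), ang)),
               numeric(7))
  # single elbow actuator affects only the elbow coordinate
  f <- numeric(7); f[6] <- 20
  tq <- as.numeric(total_joint_torques(lay, f, ang))
  expect_gt(abs(tq[4]), 0.1)
  expect_equal(tq[-4], numeric(6), tolerance = 1e-12)
  expect_equal(tq[5:7], numeric(3))          # no wrist actuators ever
  # both elbow actuators give opposite-sign elbow torques
  f2 <- numeric(7); f2[7] <- 20
  tq2 <- as.numeric(total_joint_torques(lay, f2, ang))
  expect_lt(tq2[4] * tq[4], 0)
  # additivity over actuators
  withr::with_seed(5, {
    forces <- runif(7, 0, lay$F_max)
    total <- as.numeric(total_joint_torques(lay, forces, ang))
    parts <- matrix(0, 7, 7)
    for (i in 1:7) {
      fi <- numeric(7); fi[i] <- forces[i]
      parts[i, ] <- as.numeric(total_joint_torques(lay, fi, ang))
    }
    expect_equal(total, colSums(parts), tolerance = 1e-9)
  })
})

test_that("out-of-range forces clamp with warning or error in strict mode", {
  lay <- default_exo_layout()
  f <- numeric(7); f[1] <- lay$F_max[1] * 2
  expect_warning(total_joint_torques(lay, f, neutral_pose()), "clamp")
  expect_error(total_joint_torques(lay, f, neutral_pose(), strict = TRUE),
               "F_max")
})

test_that("endpoint shift changes torques continuously", {
  lay <- default_exo_layout()
  ang <- neutral_pose()
  f <- rep(10, 7)
  base <- as.numeric(total_joint_torques(lay, f, ang))
  shifts <- c(0.02, 0.005, 1e-4, 0)
  errs <- vapply(shifts, function(s) {
    sh <- matrix(0, 7, 3); sh[, 1] <- s
    max(abs(as.numeric(total_joint_torques(lay, f, ang,
                                           endpoint_shift = sh)) - base))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_equal(errs[4], 0)
  expect_gt(errs[1], 0)
})

test_that("layout round-trips through YAML and validates", {
  lay <- default_exo_layout()
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(actuators = lay$actuators), path)
  lay2 <- read_exo_layout(path)
  expect_equal(lay2$Fs, lay$Fs)
  expect_equal(lay2$Fe, lay$Fe)
  expect_equal(lay2$actuators[[3]]$anchor, lay$actuators[[3]]$anchor)
  expect_error(exo_layout(lay$actuators[1:5]), "exactly 7")
})
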