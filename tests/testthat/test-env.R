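test_that("observation is length 80, bounded, with zero force history at reset", {
  env <- fix_env()
  obs <- env_reset(env, 1)
  expect_length(obs, 80L)
  expect_equal(obs_dim(env), 80L)
  expect_equal(action_dim(env), 7L)
  expect_true(all(is.finite(obs)))
  expect_true(all(obs >= -1 & obs <= 1))
  expect_equal(obs[1:14], numeric(14))        # force-history slots
})

test_that("resets are deterministic and the episode is Markov in the seed", {
  env <- fix_env()
  o1 <- env_reset(env, 7)
  o2 <- env_reset(env, 7)
  expect_identical(o1, o2)
  o3 <- env_reset(env, 8)
  expect_false(identical(o1, o3))
  # identical seed + action sequence -> identical trajectories
  run <- function() {
    env_reset(env, 12)
    withr::with_seed(5, {
      replicate(10, env_step(env, runif(7, -1, 1))$reward)
    })
  }
  expect_identical(run(), run())
})

test_that("randomization draws respect their profile ranges and nesting", {
  for (profile in c("training", "testing")) {
    cfg <- randomization_config(profile)
    withr::with_seed(2, {
      for (i in 1:300) {
        d <- sample_randomization(cfg)
        expect_true(all(d$matrix_scales >= cfg$matrix_scale[1] &
                          d$matrix_scales <= cfg$matrix_scale[2]))
        expect_true(all(d$precision >= cfg$actuator_precision[1] &
                          d$precision <= cfg$actuator_precision[2]))
        expect_true(all(d$endpoint_shift_cm >= cfg$endpoint_shift_cm[1] &
                          d$endpoint_shift_cm <= cfg$endpoint_shift_cm[2]))
        expect_equal(rowSums(d$endpoint_shift != 0) <= 1, rep(TRUE, 7))
      }
    })
  }
  tr_cfg <- randomization_config("training")
  te_cfg <- randomization_config("testing")
  for (p in c("matrix_scale", "actuator_precision", "endpoint_shift_cm")) {
    expect_gte(tr_cfg[[p]][1], te_cfg[[p]][1])
    expect_lte(tr_cfg[[p]][2], te_cfg[[p]][2])
  }
})

test_that("zero action leaves the tremor unsuppressed; cancellation restores the reference", {
  env <- fix_env()
  env_reset(env, 3)
  repeat {
    st <- env_step(env, rep(-1, 7))
    if (st$done) break
  }
  rec <- env_records(env)
  sup <- unname(as.matrix(rec[paste0("sup_q", 1:7)]))
  tre <- unname(as.matrix(rec[paste0("tremor_q", 1:7)]))
  expect_equal(sup, tre, tolerance = 1e-12)

  env_reset(env, 3)
  repeat {
    st <- env_step(env, rep(-1, 7),
                   override_torque = -env_tremor_torque(env))
    if (st$done) break
  }
  rec <- env_records(env)
  expect_equal(unname(as.matrix(rec[paste0("sup_q", 1:7)])),
               unname(as.matrix(rec[paste0("ref_q", 1:7)])),
               tolerance = 1e-12)
})

test_that("episode length equals trajectory length minus history warm-up", {
  env <- fix_env()
  env_reset(env, 1)
  n_steps <- 0L
  repeat {
    st <- env_step(env, rep(-1, 7))
    n_steps <- n_steps + 1L
    if (st$done) break
  }
  expect_equal(n_steps, env$n - 2L)
  expect_error(env_step(env, rep(-1, 7)), "done")
})

test_that("reward decomposition identity holds at every logged step", {
  env <- fix_env(axes = c(1, 4))
  env_reset(env, 9)
  w <- reward_weights()
  withr::with_seed(1, {
    for (i in 1:30) {
      st <- env_step(env, runif(7, -1, 1))
      r <- st$record
      recomposed <- w[["axes"]] * r$r_axes + w[["torque"]] * r$r_torque +
        w[["force"]] * r$r_force + w[["smoothness"]] * r$r_smoothness +
        w[["unwanted"]] * r$r_unwanted
      expect_equal(st$reward, recomposed, tolerance = 1e-12)
    }
  })
})

test_that("invalid construction and actions are rejected", {
  tr <- fix_trajectory()
  expect_error(tremor_env(tr, integer(0)), "non-empty")
  expect_error(tremor_env(tr, 5L), "subset of 1..4")
  env <- fix_env()
  expect_error(env_step(env, rep(0, 7)), "reset")
  env_reset(env, 1)
  expect_error(env_step(env, c(NA, rep(0, 6))), "finite")
  expect_error(env_step(env, rep(0, 6)), "length-7")
})

test_that("tremor torque history slots track the generated series", {
  env <- fix_env(axes = 4L)
  obs <- env_reset(env, 21)
  tau_blk <- obs[15:26]
  tab <- env$cfg$torque_scale[1:4]
  expected <- as.numeric(t(env$tremor$torques[1:3, 1:4]) / tab)
  expect_equal(tau_blk, pmin(pmax(expected, -1), 1), tolerance = 1e-12)
  # only q4 rows are nonzero for an elbow-only tremor
  expect_true(all(tau_blk[-seq(4, 12, by = 4)] == 0))
})
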