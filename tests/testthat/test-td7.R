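small_cfg <- function(...) {
  args <- utils::modifyList(
    list(zs_dim = 8L, hidden = 24L, batch_size = 32L,
         buffer_capacity = 5000L, start_timesteps = 50L,
         eval_freq = 10000L, target_update_freq = 25L),
    list(...))
  do.call(td7_config, args)
}

test_that("LAP priority clamps at 1 and is monotone in |delta|", {
  expect_equal(lap_priority(0.5, 0.4), 1)
  expect_equal(lap_priority(-0.99, 2), 1)
  expect_equal(lap_priority(2, 1), 2)
  expect_equal(lap_priority(3, 0.4), 3^0.4)
  d <- seq(0, 10, by = 0.25)
  expect_true(all(diff(lap_priority(d, 0.7)) >= 0))
})

test_that("clipped double Q target uses the smaller critic and respects done", {
  expect_equal(clipped_double_q_target(1, 3, 5, 0.99, 0), 1 + 0.99 * 3)
  expect_equal(clipped_double_q_target(1, 5, 3, 0.99, 0), 1 + 0.99 * 3)
  expect_equal(clipped_double_q_target(2.5, 3, 5, 0.99, 1), 2.5)
  expect_equal(clipped_double_q_target(2.5, 3, 5, 0, 0), 2.5)
  # bootstrap never exceeds either single critic's estimate
  withr::with_seed(1, {
    q1 <- rnorm(50); q2 <- rnorm(50)
    y <- clipped_double_q_target(0, q1, q2, 1, 0)
    expect_true(all(y <= q1 & y <= q2))
  })
})

test_that("agent critic target is r at terminals and with zero discount", {
  ag <- td7_agent("m", small_cfg(gamma = 0.99), seed = 1)
  s2 <- runif(80, -1, 1)
  expect_equal(td7_critic_target(ag, 3.2, s2, done = 1), 3.2)
  ag0 <- td7_agent("m", small_cfg(gamma = 0), seed = 1)
  expect_equal(td7_critic_target(ag0, -1.7, s2, done = 0), -1.7)
})

test_that("batches split equally across movement sub-buffers", {
  rp <- replay_create(c("a", "b", "c", "d"), capacity = 1000,
                      s_dim = 4, a_dim = 2)
  withr::with_seed(1, {
    for (id in c("a", "b", "c", "d")) {
      for (i in 1:(50 * match(id, c("a", "b", "c", "d")))) {
        replay_add(rp, id, runif(4), runif(2), 0, runif(4), 0)
      }
    }
    batch <- replay_sample(rp, 256L)
  })
  expect_equal(unname(table(batch$movement)), rep(64L, 4),
               ignore_attr = TRUE)
  expect_equal(unname(replay_sizes(rp)), c(50L, 100L, 150L, 200L))
})

test_that("within-buffer sampling follows the LAP law", {
  rp <- replay_create("m", capacity = 100, s_dim = 2, a_dim = 1, alpha = 1)
  for (i in 1:10) replay_add(rp, "m", runif(2), 0.5, 0, runif(2), 0)
  # all priorities equal -> uniform sampling
  withr::with_seed(7, {
    counts <- table(factor(replicate(200, replay_sample(rp, 500L)$index),
                           levels = 1:10))
  })
  chi <- stats::chisq.test(as.numeric(counts))
  expect_gt(chi$p.value, 0.01)
  # one transition with 10x priority dominates proportionally
  replay_update_priority(rp, rep("m", 10), 1:10, c(10, rep(1, 9)))
  expect_equal(rp$buf$m$prio[1:10], c(10, rep(1, 9)))
  withr::with_seed(8, {
    idx <- replicate(100, replay_sample(rp, 1000L)$index)
  })
  frac <- mean(idx == 1)
  expect_equal(frac, 10 / 19, tolerance = 0.05)
})

test_that("pink noise has a 1/f spectral slope and unit variance", {
  x <- pink_noise(2^14, 2, seed = 1)
  expect_equal(apply(x, 2, sd), c(1, 1), tolerance = 1e-9)
  sl <- psd_slope(x[, 1])
  expect_gt(sl, -1.5)
  expect_lt(sl, -0.5)
  # white noise slope is near zero, clearly distinct
  w <- withr::with_seed(1, rnorm(2^14))
  expect_gt(psd_slope(w), -0.2)
  # pink noise is more autocorrelated at lag 1 than equal-variance white
  ac_p <- stats::acf(x[, 1], lag.max = 1, plot = FALSE)$acf[2]
  ac_w <- stats::acf(w, lag.max = 1, plot = FALSE)$acf[2]
  expect_gt(ac_p, ac_w + 0.2)
})

test_that("exploration respects scale and clipping", {
  a <- c(0.9, -0.9, 0, 0.5, -0.5, 1, -1)
  expect_identical(explore_action(a, rnorm(7), 0), a)
  withr::with_seed(2, {
    for (i in 1:50) {
      out <- explore_action(a, rnorm(7, sd = 3), 1)
      expect_true(all(out >= -1 & out <= 1))
    }
  })
})

test_that("zero training steps returns initialized networks and empty log", {
  env <- fix_env()
  out <- td7_train(list(elbow = env), small_cfg(), total_steps = 0L, seed = 1)
  expect_s3_class(out$agent, "td7_agent")
  expect_equal(nrow(out$log), 0L)
  expect_length(out$episode_returns, 0L)
  a <- agent_action(out$agent, runif(80, -1, 1))
  expect_length(a, 7L)
  expect_true(all(abs(a) <= 1))
})

test_that("a short training run updates networks and checkpoints monotonically", {
  env <- fix_env()
  cfg <- small_cfg(eval_freq = 150L)
  out <- td7_train(list(elbow = env), cfg, total_steps = 450L, seed = 2)
  expect_gte(nrow(out$log), 2L)
  expect_true(all(diff(out$log$best_return) >= 0))
  expect_true(all(is.finite(out$log$eval_return)))
  # replay never mixes movement tags (single sub-buffer here)
  expect_equal(names(replay_sizes(out$agent$replay)), "elbow")
  expect_equal(sum(replay_sizes(out$agent$replay)), 450L)
})

test_that("checkpoints round-trip through the JSON format", {
  ag <- td7_agent("m", small_cfg(), seed = 3)
  obs <- runif(80, -1, 1)
  a0 <- agent_action(ag, obs, use_checkpoint = TRUE)
  path <- tempfile(fileext = ".json")
  save_checkpoint(ag, path)
  ag2 <- load_checkpoint(path)
  expect_equal(agent_action(ag2, obs, use_checkpoint = TRUE), a0,
               tolerance = 1e-12)
})
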