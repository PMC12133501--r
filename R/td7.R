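#' TD7 agent configuration
#'
#' Hyperparameters default to the published TD7 reference values (network
#' width 256, embedding 256, Adam 3e-4, batch 256, discount 0.99, LAP
#' alpha 0.4, delayed policy updates every 2 critic steps, hard target
#' updates every 250 steps), with one tremor-specific modification: the
#' exploration and target-policy noise scales are multiplied by
#' \code{noise_reduction} (default 0.5) because small force changes map to
#' large joint torques, and exploration uses pink instead of white noise.
#'
#' @param obs_dim,act_dim Observation/action dimensions.
#' @param zs_dim Embedding width.
#' @param hidden Hidden layer width.
#' @param lr Adam learning rate (all networks).
#' @param gamma Discount factor.
#' @param alpha LAP prioritization exponent.
#' @param batch_size Replay batch size (split equally over sub-buffers).
#' @param buffer_capacity Per-movement sub-buffer capacity.
#' @param start_timesteps Uniform-random warm-up transitions before the
#'   policy acts and updates begin.
#' @param exploration_noise Base exploration noise scale.
#' @param target_policy_noise,noise_clip TD3-style target smoothing.
#' @param noise_reduction Multiplier applied to both noise scales.
#' @param policy_freq Critic steps per delayed actor step.
#' @param target_update_freq Steps between hard target-network updates.
#' @param eval_freq,eval_episodes Checkpoint evaluation cadence and size.
#' @param loss_ceiling Divergence guard: abort if the critic loss exceeds
#'   this for \code{loss_patience} consecutive updates.
#' @param loss_patience See \code{loss_ceiling}.
#' @return List of class \code{td7_config}.
#' @export
td7_config <- function(obs_dim = 80L, act_dim = 7L, zs_dim = 256L,
                       hidden = 256L, lr = 3e-4, gamma = 0.99, alpha = 0.4,
                       batch_size = 256L, buffer_capacity = 1e6,
                       start_timesteps = 1000L,
                       exploration_noise = 0.1,
                       target_policy_noise = 0.2, noise_clip = 0.5,
                       noise_reduction = 0.5,
                       policy_freq = 2L, target_update_freq = 250L,
                       eval_freq = 2500L, eval_episodes = 1L,
                       loss_ceiling = 1e4, loss_patience = 200L) {
  structure(as.list(environment()), class = "td7_config")
}

#' Create a TD7 agent
#'
#' Builds the encoder pair (state encoder f with average-L1-normalized
#' output, state-action encoder g), the actor, the twin critics, their
#' target copies, the checkpoint slot and the per-movement LAP replay.
#'
#' @param movement_ids Character vector naming the reference movements
#'   (one replay sub-buffer each).
#' @param config A \code{\link{td7_config}}.
#' @param seed Integer seed for weight initialization.
#' @return An agent object (environment) of class \code{td7_agent}.
#' @export
td7_agent <- function(movement_ids, config = td7_config(), seed = 1L) {
  cfg <- config
  ag <- new.env(parent = emptyenv())
  ag$cfg <- cfg
  with_seed(seed, {
    ag$f <- mlp_init(c(cfg$obs_dim, cfg$hidden, cfg$zs_dim), out_act = "avgl1")
    ag$g <- mlp_init(c(cfg$zs_dim + cfg$act_dim, cfg$hidden, cfg$zs_dim))
    ag$actor <- mlp_init(c(cfg$zs_dim + cfg$obs_dim, cfg$hidden, cfg$hidden,
                           cfg$act_dim), out_act = "tanh")
    cdim <- cfg$zs_dim * 2 + cfg$obs_dim + cfg$act_dim
    ag$q1 <- mlp_init(c(cdim, cfg$hidden, cfg$hidden, 1L))
    ag$q2 <- mlp_init(c(cdim, cfg$hidden, cfg$hidden, 1L))
  })
  for (nm in c("f", "g", "actor", "q1", "q2")) {
    ag[[paste0(nm, "_t")]] <- ag[[nm]]
    ag[[paste0("opt_", nm)]] <- adam_init(ag[[nm]])
  }
  ag$f_cp <- ag$f
  ag$actor_cp <- ag$actor
  ag$best_eval <- -Inf
  ag$replay <- replay_create(movement_ids, cfg$buffer_capacity,
                             cfg$obs_dim, cfg$act_dim, cfg$alpha)
  ag$n_updates <- 0L
  ag$loss_bad_streak <- 0L
  class(ag) <- "td7_agent"
  ag
}

critic_input <- function(zsa, zs, S, A) cbind(zsa, zs, S, A)

#' Deterministic policy action
#'
#' @param agent A \code{\link{td7_agent}}.
#' @param obs Observation vector or batch matrix.
#' @param use_checkpoint Use the checkpointed (best-evaluated) actor and
#'   encoder instead of the current ones.
#' @return Action vector (or matrix) in [-1, 1].
#' @export
agent_action <- function(agent, obs, use_checkpoint = FALSE) {
  f <- if (use_checkpoint) agent$f_cp else agent$f
  actor <- if (use_checkpoint) agent$actor_cp else agent$actor
  S <- if (is.matrix(obs)) obs else matrix(obs, nrow = 1)
  zs <- mlp_forward(f, S)
  out <- mlp_forward(actor, cbind(zs, S))
  if (is.matrix(obs)) out else as.numeric(out)
}

#' Clipped double Q bootstrap target
#'
#' \eqn{y = r + \gamma (1 - d) \min(Q_1', Q_2')}: bootstrapping from the
#' minimum of the two target critics curbs overestimation; terminal
#' transitions do not bootstrap.
#'
#' @param r Reward(s).
#' @param q1p,q2p Target critic estimates at the target action.
#' @param gamma Discount.
#' @param done Terminal flag(s), 0/1.
#' @return Target value(s).
#' @export
clipped_double_q_target <- function(r, q1p, q2p, gamma, done) {
  r + gamma * (1 - done) * pmin(q1p, q2p)
}

#' TD7 critic target for a batch of next states
#'
#' Embeds the next states with the target encoder, takes the target
#' actor's action (optionally with clipped smoothing noise), evaluates
#' both target critics and applies \code{\link{clipped_double_q_target}}.
#'
#' @param agent A \code{\link{td7_agent}}.
#' @param r Rewards.
#' @param S2 Next-observation batch (rows) or single observation.
#' @param done Terminal flags.
#' @param smoothing Add TD3-style clipped target-policy noise.
#' @return Numeric target vector.
#' @export
td7_critic_target <- function(agent, r, S2, done, smoothing = FALSE) {
  cfg <- agent$cfg
  if (!is.matrix(S2)) S2 <- matrix(S2, nrow = 1)
  zs2 <- mlp_forward(agent$f_t, S2)
  a2 <- mlp_forward(agent$actor_t, cbind(zs2, S2))
  if (smoothing) {
    eps <- matrix(rnorm(length(a2),
                        sd = cfg$target_policy_noise * cfg$noise_reduction),
                  nrow(a2), ncol(a2))
    a2 <- clip(a2 + clip(eps, -cfg$noise_clip, cfg$noise_clip), -1, 1)
  }
  zsa2 <- mlp_forward(agent$g_t, cbind(zs2, a2))
  X2 <- critic_input(zsa2, zs2, S2, a2)
  q1p <- as.numeric(mlp_forward(agent$q1_t, X2))
  q2p <- as.numeric(mlp_forward(agent$q2_t, X2))
  as.numeric(clipped_double_q_target(r, q1p, q2p, cfg$gamma, done))
}

# One TD7 gradient step on a sampled batch: encoder dynamics-prediction
# update, twin-critic Huber update with LAP priority refresh, delayed
# deterministic-policy-gradient actor update.  Returns the critic loss.
td7_update <- function(agent, batch) {
  cfg <- agent$cfg
  nb <- length(batch$r)

  # --- encoders: predict the (target-encoded) next-state embedding
  fw_f <- mlp_forward(agent$f, batch$S, cache = TRUE)
  fw_g <- mlp_forward(agent$g, cbind(fw_f$out, batch$A), cache = TRUE)
  zs2_tgt <- mlp_forward(agent$f_t, batch$S2)
  diff <- fw_g$out - zs2_tgt
  dG <- 2 * diff / length(diff)
  gr_g <- mlp_backward(agent$g, fw_g, dG)
  gr_f <- mlp_backward(agent$f, fw_f,
                       gr_g$dX[, seq_len(cfg$zs_dim), drop = FALSE])
  st <- adam_step(agent$g, gr_g, agent$opt_g, cfg$lr)
  agent$g <- st$net; agent$opt_g <- st$state
  st <- adam_step(agent$f, gr_f, agent$opt_f, cfg$lr)
  agent$f <- st$net; agent$opt_f <- st$state

  # --- critics (encoders held fixed: no gradient flows back into them)
  zs <- mlp_forward(agent$f, batch$S)
  zsa <- mlp_forward(agent$g, cbind(zs, batch$A))
  X <- critic_input(zsa, zs, batch$S, batch$A)
  y <- td7_critic_target(agent, batch$r, batch$S2, batch$done,
                         smoothing = TRUE)
  deltas <- matrix(0, nb, 2)
  for (k in 1:2) {
    qn <- if (k == 1) "q1" else "q2"
    fw <- mlp_forward(agent[[qn]], X, cache = TRUE)
    d <- as.numeric(fw$out) - y
    deltas[, k] <- d
    dY <- matrix(clip(d, -1, 1) / nb, ncol = 1)    # Huber (kappa = 1)
    gr <- mlp_backward(agent[[qn]], fw, dY)
    st <- adam_step(agent[[qn]], gr, agent[[paste0("opt_", qn)]], cfg$lr)
    agent[[qn]] <- st$net; agent[[paste0("opt_", qn)]] <- st$state
  }
  replay_update_priority(agent$replay, batch$movement, batch$index,
                         pmax(abs(deltas[, 1]), abs(deltas[, 2])))
  closs <- mean(pmin(0.5 * deltas[, 1]^2, abs(deltas[, 1]) - 0.5))

  # --- delayed actor update (deterministic policy gradient through q1)
  agent$n_updates <- agent$n_updates + 1L
  if (agent$n_updates %% cfg$policy_freq == 0L) {
    fw_a <- mlp_forward(agent$actor, cbind(zs, batch$S), cache = TRUE)
    A_pi <- fw_a$out
    fw_g2 <- mlp_forward(agent$g, cbind(zs, A_pi), cache = TRUE)
    Xp <- critic_input(fw_g2$out, zs, batch$S, A_pi)
    fw_q <- mlp_forward(agent$q1, Xp, cache = TRUE)
    dY <- matrix(-1 / nb, nb, 1)
    gr_q <- mlp_backward(agent$q1, fw_q, dY)
    zd <- cfg$zs_dim; od <- cfg$obs_dim; ad <- cfg$act_dim
    d_zsa <- gr_q$dX[, seq_len(zd), drop = FALSE]
    d_a_direct <- gr_q$dX[, (2 * zd + od + 1):(2 * zd + od + ad),
                          drop = FALSE]
    gr_g2 <- mlp_backward(agent$g, fw_g2, d_zsa)
    d_a_embed <- gr_g2$dX[, (zd + 1):(zd + ad), drop = FALSE]
    gr_a <- mlp_backward(agent$actor, fw_a, d_a_direct + d_a_embed)
    st <- adam_step(agent$actor, gr_a, agent$opt_actor, cfg$lr)
    agent$actor <- st$net; agent$opt_actor <- st$state
  }

  # --- hard target updates at fixed cadence
  if (agent$n_updates %% cfg$target_update_freq == 0L) {
    for (nm in c("f", "g", "actor", "q1", "q2")) {
      agent[[paste0(nm, "_t")]] <- agent[[nm]]
    }
  }
  closs
}

#' Evaluate the current (or checkpointed) policy
#'
#' Runs deterministic episodes in each environment and returns the mean
#' episode return.
#'
#' @param agent A \code{\link{td7_agent}}.
#' @param envs Named list of \code{\link{tremor_env}}s.
#' @param seeds Episode seeds (one evaluation episode per seed per env).
#' @param use_checkpoint Evaluate the checkpointed networks.
#' @return Mean episode return.
#' @export
td7_evaluate <- function(agent, envs, seeds = 1L, use_checkpoint = FALSE) {
  rets <- c()
  for (env in envs) {
    for (sd in seeds) {
      obs <- env_reset(env, sd)
      total <- 0
      repeat {
        st <- env_step(env, agent_action(agent, obs, use_checkpoint))
        total <- total + st$reward
        if (st$done) break
        obs <- st$observation
      }
      rets <- c(rets, total)
    }
  }
  mean(rets)
}

#' Train the TD7 agent
#'
#' One set of parallel environments, one per reference movement, each with
#' its own tremor draw; per-step transitions go to the movement's replay
#' sub-buffer; pink-noise exploration; one gradient step per collected
#' transition after warm-up; periodic checkpoint evaluation retaining the
#' best-performing networks.
#'
#' @param envs Named list of \code{\link{tremor_env}} (names are the
#'   movement ids used for the replay split).
#' @param config A \code{\link{td7_config}}.
#' @param total_steps Total environment transitions to collect.
#' @param seed Master seed (weights, exploration, episode seeds).
#' @param agent Optional existing \code{\link{td7_agent}} to continue
#'   training (e.g. a fine-tuning phase with lowered learning rate and
#'   exploration noise); its replay buffer is kept.  The \code{config}
#'   passed here governs the continued run.
#' @return List: \code{agent}, \code{log} (per-evaluation data frame),
#'   \code{episode_returns} (training episode returns in order).
#' @export
td7_train <- function(envs, config = td7_config(), total_steps = 10000L,
                      seed = 1L, agent = NULL) {
  stopifnot(length(envs) >= 1L, !is.null(names(envs)))
  if (is.null(agent)) {
    agent <- td7_agent(names(envs), config, seed = derive_seed(seed, 0L))
  } else {
    stopifnot(inherits(agent, "td7_agent"))
    agent$cfg <- config
    # evaluation episode seeds differ between phases, so scores are not
    # comparable across them: re-baseline the checkpoint criterion
    agent$best_eval <- -Inf
  }
  cfg <- config
  if (total_steps == 0L) {
    return(list(agent = agent,
                log = data.frame(step = integer(), eval_return = numeric(),
                                 best_return = numeric(),
                                 critic_loss = numeric()),
                episode_returns = numeric()))
  }
  state <- lapply(envs, function(e) list(obs = NULL, pink = NULL, k = 0L,
                                         ret = 0, ep = 0L))
  names(state) <- names(envs)
  eval_seeds <- derive_seed(seed, 900L) + seq_len(cfg$eval_episodes)
  log_rows <- list()
  ep_returns <- c()
  steps <- 0L
  last_loss <- NA_real_
  with_seed(derive_seed(seed, 1L), {
    while (steps < total_steps) {
      for (id in names(envs)) {
        if (steps >= total_steps) break
        env <- envs[[id]]
        stt <- state[[id]]
        if (is.null(stt$obs)) {
          stt$ep <- stt$ep + 1L
          ep_seed <- derive_seed(seed, 1000L + stt$ep * 17L +
                                   match(id, names(envs)))
          stt$obs <- env_reset(env, ep_seed)
          stt$pink <- pink_noise(env$n, cfg$act_dim)
          stt$k <- 0L
          stt$ret <- 0
        }
        a <- if (steps < cfg$start_timesteps) {
          runif(cfg$act_dim, -1, 1)
        } else {
          stt$k_noise <- stt$k %% nrow(stt$pink) + 1L
          explore_action(agent_action(agent, stt$obs),
                         stt$pink[stt$k_noise, ],
                         cfg$exploration_noise * cfg$noise_reduction)
        }
        res <- env_step(env, a)
        replay_add(agent$replay, id, stt$obs, a, res$reward,
                   res$observation, res$done)
        stt$ret <- stt$ret + res$reward
        stt$k <- stt$k + 1L
        steps <- steps + 1L
        if (res$done) {
          ep_returns <- c(ep_returns, stt$ret)
          stt$obs <- NULL
        } else {
          stt$obs <- res$observation
        }
        state[[id]] <- stt

        if (steps >= cfg$start_timesteps) {
          batch <- replay_sample(agent$replay, cfg$batch_size)
          last_loss <- td7_update(agent, batch)
          if (!is.finite(last_loss) || last_loss > cfg$loss_ceiling) {
            agent$loss_bad_streak <- agent$loss_bad_streak + 1L
            if (agent$loss_bad_streak >= cfg$loss_patience) {
              stop("training diverged: critic loss above ceiling for ",
                   cfg$loss_patience, " consecutive updates")
            }
          } else {
            agent$loss_bad_streak <- 0L
          }
        }

        if (steps %% cfg$eval_freq == 0L) {
          ev <- td7_evaluate(agent, envs, eval_seeds)
          if (ev > agent$best_eval) {
            agent$best_eval <- ev
            agent$actor_cp <- agent$actor
            agent$f_cp <- agent$f
          }
          log_rows[[length(log_rows) + 1L]] <-
            data.frame(step = steps, eval_return = ev,
                       best_return = agent$best_eval,
                       critic_loss = last_loss)
          # evaluation reset the shared envs: restart training episodes
          for (id2 in names(envs)) state[[id2]]$obs <- NULL
        }
      }
    }
    # final checkpoint evaluation if the last step missed the cadence
    if (steps %% cfg$eval_freq != 0L) {
      ev <- td7_evaluate(agent, envs, eval_seeds)
      if (ev > agent$best_eval) {
        agent$best_eval <- ev
        agent$actor_cp <- agent$actor
        agent$f_cp <- agent$f
      }
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(step = steps, eval_return = ev,
                   best_return = agent$best_eval, critic_loss = last_loss)
    }
  })
  # restore training-state observations: evaluation reset shared envs
  list(agent = agent,
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(step = integer(), eval_return = numeric(),
                    best_return = numeric(), critic_loss = numeric()),
       episode_returns = ep_returns)
}

#' Wrap an agent as a policy function
#'
#' @param agent A \code{\link{td7_agent}}.
#' @param use_checkpoint Use the best-evaluated checkpoint networks.
#' @return \code{function(obs)} returning a length-7 action.
#' @export
td7_policy <- function(agent, use_checkpoint = TRUE) {
  force(agent); force(use_checkpoint)
  function(obs) agent_action(agent, obs, use_checkpoint)
}

#' Save / load checkpoint networks as JSON (text, versioned)
#'
#' Stores the checkpointed actor and state encoder plus the configuration
#' and a content hash, sufficient to deploy the policy.
#'
#' @param agent A \code{\link{td7_agent}}.
#' @param path Output JSON path.
#' @return \code{path} (saver) or a minimal agent-like object with
#'   \code{f_cp}, \code{actor_cp}, usable with
#'   \code{agent_action(use_checkpoint = TRUE)}.
#' @export
save_checkpoint <- function(agent, path) {
  ser_net <- function(net) list(W = lapply(net$W, as.vector),
                                b = net$b, sizes = net$sizes,
                                act = net$act, out_act = net$out_act)
  payload <- list(version = 1L,
                  config = agent$cfg[c("obs_dim", "act_dim", "zs_dim",
                                       "hidden")],
                  best_eval = agent$best_eval,
                  f = ser_net(agent$f_cp), actor = ser_net(agent$actor_cp))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_net <- function(x) {
    sizes <- as.integer(x$sizes)
    W <- vector("list", length(sizes) - 1L)
    for (l in seq_along(W)) {
      W[[l]] <- matrix(x$W[[l]], sizes[l], sizes[l + 1])
    }
    list(W = W, b = lapply(x$b, as.numeric), sizes = sizes,
         act = x$act, out_act = x$out_act)
  }
  ag <- new.env(parent = emptyenv())
  ag$f_cp <- de_net(p$f)
  ag$actor_cp <- de_net(p$actor)
  ag$best_eval <- p$best_eval
  class(ag) <- "td7_agent"
  ag
}
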