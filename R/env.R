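#' Environment configuration
#'
#' Bundles every tunable piece of the simulation: control rate, integrator
#' substeps, anatomical matrices, arm geometry, actuator layout, tremor
#' torque scale table, reward weights and the reward-form flags.
#'
#' @param dt Control step, seconds (default 1/30: the 30--40 Hz actuation
#'   rate typical of soft actuators).
#' @param n_substeps Integrator substeps per control step.
#' @param matrices An \code{\link{anatomical_matrices}}.
#' @param geometry An \code{\link{arm_geometry}}.
#' @param layout An \code{\link{exo_layout}}.
#' @param torque_scale Per-axis max tremor torque table.
#' @param weights Reward weights (\code{\link{reward_weights}}).
#' @param noise_sigma Tremor Gaussian noise level.
#' @param single_weight_axes,smoothness_as_printed Reward-form flags, see
#'   \code{\link{reward_axes}} and \code{\link{reward_smoothness}}.
#' @param carry_state If \code{TRUE}, carry displacement velocity across
#'   control steps instead of re-initializing from the reference (ablation).
#' @param force_mode Actuator force model (\code{\link{force_components}}).
#' @return List of class \code{env_config}.
#' @export
env_config <- function(dt = 1 / 30, n_substeps = 40L,
                       matrices = default_anatomical_matrices(),
                       geometry = arm_geometry(),
                       layout = default_exo_layout(),
                       torque_scale = torque_scale_table(),
                       weights = reward_weights(),
                       noise_sigma = 0.1,
                       single_weight_axes = FALSE,
                       smoothness_as_printed = FALSE,
                       carry_state = FALSE,
                       force_mode = "unit_vector") {
  structure(list(dt = dt, n_substeps = as.integer(n_substeps),
                 matrices = matrices, geometry = geometry, layout = layout,
                 torque_scale = torque_scale, weights = weights,
                 noise_sigma = noise_sigma,
                 single_weight_axes = single_weight_axes,
                 smoothness_as_printed = smoothness_as_printed,
                 carry_state = carry_state, force_mode = force_mode),
            class = "env_config")
}

#' Tremor-suppression reinforcement learning environment
#'
#' A gym-style environment.  Each episode follows one reference movement;
#' a two-harmonic tremor torque drives a fixed set of affected axes at
#' every step; the action is the commanded tension of the 7 actuators
#' (in [-1, 1], mapped affinely to [0, F_max]); the observation is the
#' 80-dimensional normalized vector of recent forces, tremor torques,
#' actuator endpoint positions and joint positions; the reward is the
#' five-term shaped reward.  Episode randomization (anatomical matrix
#' scales, actuator precision, endpoint shifts, tremor parameters) is
#' sampled at reset from the selected profile.
#'
#' @param trajectory A \code{\link{joint_trajectory}} (resampled to the
#'   control rate if needed).
#' @param tremor_axes Integer subset of 1..4 (shoulder axes and elbow
#'   flexion/extension, the trained combinations).
#' @param profile Randomization profile, \code{"training"} or
#'   \code{"testing"}.
#' @param config An \code{\link{env_config}}.
#' @return An environment object of class \code{tremor_env}; use
#'   \code{\link{env_reset}} and \code{\link{env_step}}.
#' @export
tremor_env <- function(trajectory, tremor_axes, profile = "training",
                       config = env_config()) {
  stopifnot(inherits(trajectory, "joint_trajectory"))
  tremor_axes <- sort(unique(as.integer(tremor_axes)))
  if (length(tremor_axes) == 0L || any(!tremor_axes %in% 1:4)) {
    stop_validation("tremor_axes must be a non-empty subset of 1..4 ",
                    "(shoulder axes and elbow flexion/extension)")
  }
  if (abs(trajectory$dt - config$dt) > 1e-12) {
    trajectory <- resample_trajectory(trajectory, config$dt)
  }
  e <- new.env(parent = emptyenv())
  e$traj <- trajectory
  e$axes <- tremor_axes
  e$profile <- profile
  e$cfg <- config
  e$rand_cfg <- randomization_config(profile)
  e$n <- nrow(trajectory$angles)
  e$ready <- FALSE
  class(e) <- "tremor_env"
  e
}

#' @export
print.tremor_env <- function(x, ...) {
  cat(sprintf("<tremor_env> %s, tremor axes {%s}, %s profile, %d steps\n",
              x$traj$movement_label,
              paste0("q", x$axes, collapse = ","), x$profile, x$n))
  invisible(x)
}

#' Observation and action dimensions
#'
#' @param env A \code{tremor_env}.
#' @return Integer dimension.
#' @export
obs_dim <- function(env) 80L

#' @rdname obs_dim
#' @export
action_dim <- function(env) 7L

#' Reset the environment
#'
#' Samples the episode's dynamics randomization and tremor specification,
#' zeroes all actuator forces, generates the tremor torque series for the
#' episode and returns the initial observation.  Deterministic given
#' \code{seed}.
#'
#' @param env A \code{\link{tremor_env}}.
#' @param seed Integer episode seed.
#' @return The initial observation (length-80 numeric in [-1, 1]).
#' @export
env_reset <- function(env, seed = 1L) {
  stopifnot(inherits(env, "tremor_env"))
  cfg <- env$cfg
  with_seed(seed, {
    env$rand <- sample_randomization(env$rand_cfg)
    env$spec <- sample_tremor_spec(env$rand_cfg$tremor, env$axes,
                                   noise_sigma = cfg$noise_sigma)
    accel <- synthesize_acceleration(env$spec, env$n, cfg$dt)
  })
  env$tremor <- acceleration_to_torque(accel, env$spec, cfg$torque_scale,
                                       cfg$dt)
  env$mat_ep <- precompute_propagator(
    scale_matrices(cfg$matrices, env$rand$matrix_scales),
    cfg$dt, cfg$n_substeps)
  env$sim_angles <- env$traj$angles        # overwritten as steps complete
  env$tremor_angles <- env$traj$angles
  env$f_prev1 <- numeric(7)                # force applied at t-1
  env$f_prev2 <- numeric(7)                # force applied at t-2
  env$carry <- NULL
  env$t <- 3L
  env$records <- vector("list", env$n - 2L)
  env$seed <- seed
  env$ready <- TRUE
  build_observation(env)
}

# Normalized length-80 observation at the environment's current step.
build_observation <- function(env) {
  cfg <- env$cfg
  t <- min(env$t, env$n)
  reach <- arm_reach(cfg$geometry)
  origin <- cfg$geometry$shoulder_origin

  # actuator force history (t-2, t-1), normalized per-actuator: 7 x 2
  f_blk <- c(env$f_prev2 / cfg$layout$F_max, env$f_prev1 / cfg$layout$F_max)

  # tremor torque history (t-2 : t) on the four trainable axes: 4 x 3
  scale4 <- cfg$torque_scale[1:4]
  tau_blk <- as.numeric(t(env$tremor$torques[(t - 2):t, 1:4]) / scale4)

  # actuator endpoint and joint position history (t-2, t-1): 7x3x2 + 2x3x2
  pos_blk <- numeric(0)
  joint_blk <- numeric(0)
  for (row in c(t - 2L, t - 1L)) {
    pos <- actuator_positions(cfg$layout, env$sim_angles[row, ],
                              cfg$geometry, env$rand$endpoint_shift)
    pos_blk <- c(pos_blk,
                 as.numeric(t(sweep(pos$ends, 2, origin))) / reach)
    joint_blk <- c(joint_blk, (pos$fk$elbow - origin) / reach,
                   (pos$fk$wrist - origin) / reach)
  }
  clip(c(f_blk, tau_blk, pos_blk, joint_blk), -1, 1)
}

#' Advance the environment by one control step
#'
#' Maps the action to actuator tensions (scaled by the episode's sampled
#' precision factors, clamped to the physical range), computes the
#' exoskeleton joint torques, advances the coupled displacement dynamics
#' from the reference pose under tremor + exoskeleton torque (and, for the
#' logged comparison, under tremor alone), computes the five-term reward
#' and returns the next observation.  The episode terminates at the end of
#' the reference trajectory; there is no early termination.
#'
#' @param env A reset \code{\link{tremor_env}}.
#' @param action Length-7 numeric in [-1, 1].
#' @param override_torque Optional length-7 joint torque that replaces the
#'   actuator-model torque (diagnostic hook for oracle policies that
#'   command a joint torque directly; forces are logged as zero).
#' @return List: \code{observation}, \code{reward}, \code{done},
#'   \code{record} (the step log row as a one-row data frame).
#' @export
env_step <- function(env, action, override_torque = NULL) {
  stopifnot(inherits(env, "tremor_env"))
  if (!isTRUE(env$ready)) stop_validation("call env_reset() before env_step()")
  if (length(action) != 7L || any(is.na(action)) || any(!is.finite(action))) {
    stop_validation("action must be a finite length-7 vector")
  }
  cfg <- env$cfg
  t <- env$t
  if (t > env$n) stop_validation("episode is done; reset the environment")
  ref_t <- env$traj$angles[t, ]
  tau_t <- env$tremor$torques[t, ]

  if (is.null(override_torque)) {
    cmd <- (clip(action, -1, 1) + 1) / 2 * cfg$layout$F_max
    actual <- clip(cmd * env$rand$precision, 0, cfg$layout$F_max)
    tau_o <- as.numeric(total_joint_torques(
      cfg$layout, actual, ref_t, cfg$geometry, cfg$force_mode,
      endpoint_shift = env$rand$endpoint_shift))
  } else {
    if (length(override_torque) != 7L) {
      stop_validation("override_torque must be length 7")
    }
    actual <- numeric(7)
    tau_o <- as.numeric(override_torque)
  }

  sup <- step_from_reference(ref_t, tau_t, tau_o, env$mat_ep, cfg$dt,
                             carry_state = if (cfg$carry_state) env$carry,
                             n_substeps = cfg$n_substeps)
  tre <- step_from_reference(ref_t, tau_t, numeric(7), env$mat_ep, cfg$dt,
                             n_substeps = cfg$n_substeps)
  if (cfg$carry_state) env$carry <- sup$displacement

  aff <- env$axes
  comp <- list(
    axes = reward_axes(length(aff), single_weight = cfg$single_weight_axes),
    torque = reward_torque(tau_t[aff] + tau_o[aff], tau_t[aff]),
    force = reward_force(actual, cfg$layout$Fe, cfg$layout$Fs),
    smoothness = reward_smoothness(rbind(env$f_prev2, env$f_prev1, actual),
                                   cfg$layout$Fe, cfg$layout$Fs,
                                   as_printed = cfg$smoothness_as_printed),
    unwanted = reward_unwanted(tau_o[setdiff(1:7, aff)],
                               cfg$layout$Fe, cfg$layout$Fs))
  reward <- total_reward(comp, cfg$weights)

  env$sim_angles[t, ] <- sup$angles
  env$tremor_angles[t, ] <- tre$angles
  row <- c(t = t, time_s = (t - 1) * cfg$dt, reward = reward,
           r_axes = comp$axes, r_torque = comp$torque,
           r_force = comp$force, r_smoothness = comp$smoothness,
           r_unwanted = comp$unwanted, clamped = as.numeric(sup$clamped),
           stats::setNames(ref_t, paste0("ref_q", 1:7)),
           stats::setNames(tre$angles, paste0("tremor_q", 1:7)),
           stats::setNames(sup$angles, paste0("sup_q", 1:7)),
           stats::setNames(tau_t, paste0("tau_t", 1:7)),
           stats::setNames(tau_t + tau_o, paste0("tau_e", 1:7)),
           stats::setNames(tau_o, paste0("tau_o", 1:7)),
           stats::setNames(actual, paste0("force", 1:7)))
  # stored as a named numeric row; env_records() assembles the data frame
  rec <- structure(as.list(row), class = "data.frame", row.names = 1L)
  env$records[[t - 2L]] <- row

  env$f_prev2 <- env$f_prev1
  env$f_prev1 <- actual
  env$t <- t + 1L
  done <- env$t > env$n
  list(observation = build_observation(env), reward = reward, done = done,
       record = rec)
}

#' Tremor torque at the environment's current step
#'
#' Simulator introspection used by the perfect-cancellation oracle policy.
#'
#' @param env A reset \code{\link{tremor_env}}.
#' @return Length-7 tremor torque vector, N.m.
#' @export
env_tremor_torque <- function(env) {
  stopifnot(inherits(env, "tremor_env"), isTRUE(env$ready))
  env$tremor$torques[min(env$t, env$n), ]
}

#' Episode step records
#'
#' @param env A \code{\link{tremor_env}} after stepping.
#' @return Data frame of per-step logs (one row per completed step).
#' @export
env_records <- function(env) {
  stopifnot(inherits(env, "tremor_env"))
  recs <- Filter(Negate(is.null), env$records)
  as.data.frame(do.call(rbind, recs))
}

#' Write episode records to CSV
#'
#' @param env A \code{\link{tremor_env}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
save_records <- function(env, path) {
  utils::write.csv(env_records(env), path, row.names = FALSE)
  invisible(path)
}

#' Remaining episode length
#'
#' @param env A reset \code{\link{tremor_env}}.
#' @return Number of steps left in the episode.
#' @export
env_steps_remaining <- function(env) {
  max(0L, env$n - env$t + 1L)
}
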