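#' Baseline and oracle policies
#'
#' \code{zero_policy} commands zero tension on every actuator (action -1
#' maps to force 0).  \code{oracle_policy} is the perfect-cancellation
#' upper bound: it reads the simulator's current tremor torque and
#' commands the exact opposite joint torque, bypassing the actuator model;
#' it is a diagnostic anchor, not a realizable controller.
#'
#' @return A policy object usable with \code{\link{simulate_episode}}.
#' @export
zero_policy <- function() {
  structure(list(kind = "zero"), class = "exo_policy")
}

#' @rdname zero_policy
#' @export
oracle_policy <- function() {
  structure(list(kind = "oracle"), class = "exo_policy")
}

#' Wrap a plain function as a policy
#'
#' @param fn \code{function(obs)} returning a length-7 action in [-1, 1].
#' @return A policy object.
#' @export
function_policy <- function(fn) {
  structure(list(kind = "fn", fn = fn), class = "exo_policy")
}

#' Run one episode under a policy
#'
#' @param env A \code{\link{tremor_env}}.
#' @param policy A policy object (\code{\link{zero_policy}},
#'   \code{\link{oracle_policy}}, \code{\link{function_policy}}) or a bare
#'   \code{function(obs)}.
#' @param seed Episode seed passed to \code{\link{env_reset}}.
#' @return List: \code{records} (per-step data frame), \code{total_reward},
#'   \code{env} (the stepped environment, for metric extraction).
#' @export
simulate_episode <- function(env, policy, seed = 1L) {
  if (is.function(policy)) policy <- function_policy(policy)
  stopifnot(inherits(policy, "exo_policy"))
  obs <- env_reset(env, seed)
  total <- 0
  repeat {
    st <- switch(policy$kind,
      zero = env_step(env, rep(-1, 7)),
      oracle = env_step(env, rep(-1, 7),
                        override_torque = -env_tremor_torque(env)),
      fn = env_step(env, policy$fn(obs)))
    total <- total + st$reward
    if (st$done) break
    obs <- st$observation
  }
  list(records = env_records(env), total_reward = total, env = env)
}

rms <- function(x) sqrt(mean(x^2))

#' Tremor amplitude suppression
#'
#' The percentage reduction in RMS angular deviation from the reference
#' trajectory achieved by the exoskeleton on the tremor-affected axes:
#' \deqn{100 \left(1 - \frac{\mathrm{RMS}(q^{sup} - q^{ref})}
#'   {\mathrm{RMS}(q^{trem} - q^{ref})}\right)}
#' 100 means the suppressed trajectory coincides with the reference; 0
#' means no improvement over the unsuppressed tremor; negative values mean
#' amplification.
#'
#' @param ref,tremor_only,suppressed n x 7 angle matrices.
#' @param affected_axes Integer axes over which the RMS is taken.
#' @return Percentage (scalar).
#' @export
amplitude_suppression <- function(ref, tremor_only, suppressed,
                                  affected_axes) {
  dev_s <- (suppressed - ref)[, affected_axes, drop = FALSE]
  dev_t <- (tremor_only - ref)[, affected_axes, drop = FALSE]
  denom <- rms(dev_t)
  if (denom == 0) return(NA_real_)
  100 * (1 - rms(dev_s) / denom)
}

#' Time-resolved amplitude suppression curve
#'
#' Windowed version of \code{\link{amplitude_suppression}}: RMS ratio over
#' a sliding window of one tremor period at the first-harmonic frequency,
#' giving the per-time-step suppression profile across the movement.
#'
#' @inheritParams amplitude_suppression
#' @param dt Step duration, seconds.
#' @param f1 First-harmonic frequency, Hz (sets the window to one period).
#' @return Numeric vector (percentage per step; NA where the window's
#'   tremor deviation is zero).
#' @export
suppression_curve <- function(ref, tremor_only, suppressed, affected_axes,
                              dt, f1) {
  n <- nrow(ref)
  w <- max(3L, round(1 / (f1 * dt)))
  dev_s <- (suppressed - ref)[, affected_axes, drop = FALSE]^2
  dev_t <- (tremor_only - ref)[, affected_axes, drop = FALSE]^2
  out <- rep(NA_real_, n)
  half <- w %/% 2L
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    s <- sqrt(mean(dev_s[lo:hi, ])); t_ <- sqrt(mean(dev_t[lo:hi, ]))
    if (t_ > 0) out[i] <- 100 * (1 - s / t_)
  }
  out
}

#' Tremor suppression occurrence
#'
#' Percentage of time steps where the tremor was reduced without
#' disrupting the voluntary trajectory: the suppressed deviation on the
#' affected axes is strictly smaller than the unsuppressed deviation, and
#' the largest deviation induced on the unaffected axes stays below the
#' tolerance \code{eps} (default 5 percent of the movement's angular
#' range).
#'
#' @inheritParams amplitude_suppression
#' @param eps Unaffected-axis tolerance, radians; \code{NULL} for the
#'   default.
#' @return Percentage of steps (scalar in [0, 100]).
#' @export
occurrence <- function(ref, tremor_only, suppressed, affected_axes,
                       eps = NULL) {
  if (is.null(eps)) {
    rng <- max(apply(ref, 2, function(col) diff(range(col))))
    eps <- 0.05 * max(rng, 0.1)
  }
  dev_s <- (suppressed - ref)[, affected_axes, drop = FALSE]
  dev_t <- (tremor_only - ref)[, affected_axes, drop = FALSE]
  reduced <- sqrt(rowMeans(dev_s^2)) < sqrt(rowMeans(dev_t^2))
  other <- setdiff(1:7, affected_axes)
  ok_other <- if (length(other)) {
    apply(abs((suppressed - ref)[, other, drop = FALSE]), 1, max) < eps
  } else {
    rep(TRUE, nrow(ref))
  }
  100 * mean(reduced & ok_other)
}

#' Torque suppression percentage
#'
#' \eqn{100 (1 - \sum|\tau^e| / \sum|\tau^t|)} over the affected axes.
#'
#' @param tau_e,tau_t Matrices (steps x axes) of post-exoskeleton and
#'   tremor-only torques on the affected axes.
#' @return Percentage.
#' @export
torque_suppression <- function(tau_e, tau_t) {
  denom <- sum(abs(tau_t))
  if (denom == 0) return(NA_real_)
  100 * (1 - sum(abs(tau_e)) / denom)
}

episode_metrics <- function(records, affected_axes, dt, f1) {
  ref <- as.matrix(records[paste0("ref_q", 1:7)])
  tre <- as.matrix(records[paste0("tremor_q", 1:7)])
  sup <- as.matrix(records[paste0("sup_q", 1:7)])
  tau_t <- as.matrix(records[paste0("tau_t", 1:7)])[, affected_axes,
                                                    drop = FALSE]
  tau_e <- as.matrix(records[paste0("tau_e", 1:7)])[, affected_axes,
                                                    drop = FALSE]
  curve <- suppression_curve(ref, tre, sup, affected_axes, dt, f1)
  list(amplitude = amplitude_suppression(ref, tre, sup, affected_axes),
       occurrence = occurrence(ref, tre, sup, affected_axes),
       torque = torque_suppression(tau_e, tau_t),
       peak = if (all(is.na(curve))) NA_real_ else max(curve, na.rm = TRUE),
       mean_reward = mean(records$reward))
}

#' All trainable tremor-axis combinations
#'
#' @return List of the 15 non-empty subsets of \{q1, q2, q3, q4\}.
#' @export
tremor_axis_combinations <- function() {
  out <- list()
  for (m in 1:15) out[[m]] <- which(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L)
  out
}

#' Run the full evaluation protocol
#'
#' Iterates every non-empty tremor-axis combination of the shoulder axes
#' and elbow flexion/extension (15 subsets) crossed with the reference
#' movements, running \code{n_episodes} episodes each under testing-range
#' (out-of-distribution) dynamics randomization, and aggregates amplitude
#' suppression, occurrence and torque suppression per combination and
#' movement.
#'
#' @param policy A policy object or function.
#' @param movements Named list of \code{\link{joint_trajectory}}s (default:
#'   one recording of each of the four reference movements).
#' @param n_episodes Episodes per (combination x movement) cell.
#' @param profile Randomization profile (default \code{"testing"}).
#' @param seed Master seed.
#' @param config An \code{\link{env_config}}.
#' @param combos Subsets of axes to evaluate (default all 15).
#' @return Data frame, one row per combination x movement: mean/median/max
#'   amplitude suppression, mean occurrence, mean torque suppression, mean
#'   peak windowed suppression, mean reward.
#' @export
run_protocol <- function(policy, movements = NULL, n_episodes = 3L,
                         profile = "testing", seed = 1L,
                         config = env_config(),
                         combos = tremor_axis_combinations()) {
  if (is.null(movements)) {
    lib <- movement_library(seed = seed)
    movements <- lib[seq(1, 8, by = 2)]      # one recording per movement
  }
  rows <- list()
  ci <- 0L
  for (axes in combos) {
    ci <- ci + 1L
    for (mi in seq_along(movements)) {
      amp <- occ <- trq <- pk <- rwd <- numeric(n_episodes)
      env <- tremor_env(movements[[mi]], axes, profile, config)
      for (ep in seq_len(n_episodes)) {
        sd <- derive_seed(seed, ci * 1000L + mi * 100L + ep)
        res <- simulate_episode(env, policy, sd)
        m <- episode_metrics(res$records, axes, config$dt, env$spec$f1)
        amp[ep] <- m$amplitude; occ[ep] <- m$occurrence
        trq[ep] <- m$torque; pk[ep] <- m$peak; rwd[ep] <- m$mean_reward
      }
      rows[[length(rows) + 1L]] <- data.frame(
        combination = paste0("q", axes, collapse = "+"),
        movement = movements[[mi]]$movement_label,
        n_episodes = n_episodes,
        amplitude_mean = mean(amp), amplitude_median = median(amp),
        amplitude_max = max(amp),
        occurrence_mean = mean(occ),
        torque_mean = mean(trq),
        peak_mean = mean(pk),
        reward_mean = mean(rwd))
    }
  }
  do.call(rbind, rows)
}

#' Write a protocol report
#'
#' CSV table plus a JSON summary (grand means over all cells).
#'
#' @param report Data frame from \code{\link{run_protocol}}.
#' @param csv_path,json_path Output paths.
#' @return \code{csv_path}, invisibly.
#' @export
save_protocol_report <- function(report, csv_path, json_path = NULL) {
  utils::write.csv(report, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      n_cells = nrow(report),
      amplitude_suppression_mean = mean(report$amplitude_mean),
      occurrence_mean = mean(report$occurrence_mean),
      torque_suppression_mean = mean(report$torque_mean)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
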