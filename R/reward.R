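#' Reward weights of the five-term shaped reward
#'
#' @return Named numeric vector: \code{axes} (0.5), \code{torque} (0.9),
#'   \code{force} (0.05), \code{smoothness} (0.05), \code{unwanted} (0.5).
#' @export
reward_weights <- function() {
  c(axes = 0.5, torque = 0.9, force = 0.05, smoothness = 0.05, unwanted = 0.5)
}

#' Tremor-axis sub-reward
#'
#' Constant per-step bonus proportional to the number of tremor-affected
#' axes, encouraging strategies that engage every involved axis:
#' \eqn{r^a = w_a n_a} with \eqn{w_a = 0.5}.  Note the total reward weights
#' this term by \eqn{w_a} again, so the effective contribution is
#' \eqn{w_a^2 n_a}; set \code{single_weight = TRUE} for the alternative
#' single-weighting reading.
#'
#' @param n_axes Number of axes with generated tremor torque.
#' @param w_a Axis weight (default 0.5).
#' @param single_weight If \code{TRUE}, return \code{n_axes} so only the
#'   total-reward weight applies.
#' @return Scalar sub-reward.
#' @export
reward_axes <- function(n_axes, w_a = 0.5, single_weight = FALSE) {
  if (single_weight) n_axes else w_a * n_axes
}

#' Torque-suppression sub-reward
#'
#' \deqn{r^\tau = \exp\left(-\frac{1}{n}\sum_{i=1}^n
#'   \frac{|\tau^e_i| - |\tau^t_i|}{|\tau^t_i| + 1}\right)}
#' where \eqn{\tau^t} are the unmitigated tremor torques on the affected
#' axes and \eqn{\tau^e} the torques after the exoskeleton has applied its
#' forces.  Equals 1 when nothing changes, exceeds 1 under net suppression
#' and drops below 1 under amplification.
#'
#' @param tau_e,tau_t Numeric vectors of equal length (affected axes).
#' @return Scalar sub-reward.
#' @export
reward_torque <- function(tau_e, tau_t) {
  n <- length(tau_t)
  if (n < 1L || length(tau_e) != n) {
    stop_validation("tau_e and tau_t must be non-empty vectors of equal length")
  }
  exp(-sum((abs(tau_e) - abs(tau_t)) / (abs(tau_t) + 1)) / n)
}

#' Minimal-force sub-reward
#'
#' \deqn{r^F = \exp\left(-\frac{\sum_i F_i}{F_e + F_s}\right)}
#' with \eqn{F_s, F_e} the summed maximum shoulder and elbow actuator
#' forces.  Equals 1 at zero force and decreases strictly in every force.
#'
#' @param forces Length-7 actuator forces, N.
#' @param Fe,Fs Maximum elbow/shoulder force sums, N.
#' @return Scalar sub-reward.
#' @export
reward_force <- function(forces, Fe, Fs) {
  exp(-sum(forces) / (Fe + Fs))
}

#' Action-smoothness sub-reward
#'
#' Penalizes the discrete second derivative of the actuator forces:
#' \deqn{r^{as} = -\frac{1}{N (F_e + F_s)^2}
#'   \sum_{i=1}^{N} (F_{i,t} - 2 F_{i,t-1} + F_{i,t-2})^2}
#' The value is the negated normalized squared second difference, so
#' constant (or linearly ramping) force histories score 0 and jerky ones
#' are penalized; \code{as_printed = TRUE} restores the unnegated form.
#'
#' @param force_history 3 x 7 matrix of forces at steps t-2, t-1, t (rows).
#' @param Fe,Fs Maximum elbow/shoulder force sums, N.
#' @param as_printed Return the positive (unnegated) quantity.
#' @return Scalar sub-reward (<= 0 by default).
#' @export
reward_smoothness <- function(force_history, Fe, Fs, as_printed = FALSE) {
  if (!is.matrix(force_history) || nrow(force_history) != 3L) {
    stop_validation("force_history must be a 3 x N matrix (t-2, t-1, t)")
  }
  n_act <- ncol(force_history)
  d2 <- force_history[3, ] - 2 * force_history[2, ] + force_history[1, ]
  val <- sum(d2^2) / (n_act * (Fe + Fs)^2)
  if (as_printed) val else -val
}

#' Unwanted-torque sub-reward
#'
#' \deqn{r^u = \exp\left(-\frac{\sum_i |\tau^u_i|}{(F_e + F_s)^2}\right)}
#' where \eqn{\tau^u} are the exoskeleton torques created on the
#' non-tremor-affected axes.  The absolute value keeps the reward at most 1
#' (no credit for sign cancellation); it equals 1 exactly when untouched
#' axes stay untouched.
#'
#' @param tau_u Torques on non-affected axes, N.m.
#' @param Fe,Fs Maximum elbow/shoulder force sums, N.
#' @return Scalar sub-reward in (0, 1].
#' @export
reward_unwanted <- function(tau_u, Fe, Fs) {
  exp(-sum(abs(tau_u)) / (Fe + Fs)^2)
}

#' Total shaped reward
#'
#' Weighted sum of the five sub-rewards:
#' \deqn{r = w_a r^a + w_\tau r^\tau + w_F r^F + w_{as} r^{as} + w_u r^u}
#'
#' @param components Named list/vector with elements \code{axes},
#'   \code{torque}, \code{force}, \code{smoothness}, \code{unwanted}.
#' @param weights Named weights (\code{\link{reward_weights}}).
#' @return Scalar total reward.
#' @export
total_reward <- function(components, weights = reward_weights()) {
  need <- names(reward_weights())
  if (!all(need %in% names(components))) {
    stop_validation("components must name: ", paste(need, collapse = ", "))
  }
  sum(vapply(need, function(k) weights[[k]] * components[[k]], numeric(1)))
}
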