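#' Joint trajectory container
#'
#' A \code{joint_trajectory} holds a time-indexed series of 7-DoF arm joint
#' angles: the reference (voluntary) movement onto which tremor and
#' exoskeleton displacements are superimposed.
#'
#' @param angles n x 7 numeric matrix of joint angles, radians.
#' @param dt Seconds per time step (constant sampling).
#' @param movement_label One of \code{names(movement_labels())}.
#' @param recording_id Free-form identifier for the recording.
#' @return An object of class \code{joint_trajectory} with fields
#'   \code{angles}, \code{dt}, \code{movement_label}, \code{recording_id}.
#' @export
joint_trajectory <- function(angles, dt, movement_label, recording_id = "r1") {
  angles <- as.matrix(angles)
  if (ncol(angles) != 7L) {
    stop_validation("expected 7 joint columns, got ", ncol(angles))
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop_validation("dt must be a single positive number")
  }
  if (nrow(angles) < 3L) {
    stop_validation("trajectory needs at least 3 samples (observation history)")
  }
  if (any(!is.finite(angles))) {
    bad <- which(!is.finite(angles), arr.ind = TRUE)[1, ]
    stop_validation("non-finite angle at row ", bad[1], ", column ", bad[2])
  }
  if (!movement_label %in% names(movement_labels())) {
    stop_validation("unknown movement label: ", movement_label)
  }
  colnames(angles) <- paste0("q", 1:7)
  structure(list(angles = angles, dt = dt,
                 movement_label = movement_label,
                 recording_id = as.character(recording_id)),
            class = "joint_trajectory")
}

#' @export
print.joint_trajectory <- function(x, ...) {
  cat(sprintf("<joint_trajectory> %s [%s], %d steps @ %.4f s (%.2f s)\n",
              x$movement_label, x$recording_id, nrow(x$angles), x$dt,
              (nrow(x$angles) - 1) * x$dt))
  invisible(x)
}

# Minimum-jerk position profile on [0, 1].
min_jerk <- function(u) 10 * u^3 - 15 * u^4 + 6 * u^5

#' Generate a synthetic reference movement
#'
#' Synthesizes a smooth voluntary arm movement: the labelled movement's
#' principal joint sweeps a large arc with an out-and-back minimum-jerk
#' angular profile while the remaining joints hold small, slowly varying
#' values around the neutral pose.  The minimum-jerk profile is the standard
#' model of voluntary reaching and keeps the voluntary spectrum well below
#' the 4--12 Hz tremor band, so voluntary and tremorous motion remain
#' spectrally separable.
#'
#' @param movement_label One of \code{names(movement_labels())}.
#' @param duration_s Total movement duration in seconds (default 4).
#' @param dt Seconds per step (default 1/30, the typical soft-actuator
#'   control rate).
#' @param amplitude_scale Scales the principal sweep and the secondary
#'   wiggle; 0 yields a constant neutral pose.
#' @param seed Integer seed; the trajectory is deterministic given the seed.
#' @return A \code{\link{joint_trajectory}}.
#' @examples
#' tr <- generate_synthetic_movement("elbow_flexion_extension", seed = 1)
#' range(tr$angles[, 4])
#' @export
generate_synthetic_movement <- function(movement_label,
                                        duration_s = 4,
                                        dt = 1 / 30,
                                        amplitude_scale = 1,
                                        seed = 1L) {
  if (!movement_label %in% names(movement_labels())) {
    stop_validation("unknown movement label: ", movement_label)
  }
  if (!is.finite(dt) || dt <= 0) stop_validation("dt must be positive")
  n <- floor(duration_s / dt) + 1L
  if (n < 3L) stop_validation("duration_s/dt must allow at least 3 samples")
  if (amplitude_scale < 0) stop_validation("amplitude_scale must be >= 0")

  principal <- movement_labels()[[movement_label]]
  lims <- joint_limits()
  neutral <- neutral_pose()
  tt <- (seq_len(n) - 1) * dt

  # principal sweep: 60% of the joint range, clipped to stay inside limits.
  # The elbow sweep is additionally capped to the functional flexion range
  # used in daily-activity movements, within which the straight-line cable
  # routing of the exosuit retains extension authority.
  sweep_cap <- c(Inf, Inf, Inf, 0.8, Inf, Inf, Inf)
  base_span <- 0.6 * (lims["upper", principal] - lims["lower", principal])
  span <- min(base_span, sweep_cap[principal],
              lims["upper", principal] - neutral[principal] - 0.02)
  span <- span * min(amplitude_scale, 1)

  u <- tt / max(tt)
  prof <- ifelse(u < 0.5, min_jerk(2 * u), min_jerk(2 * (1 - u)))

  angles <- matrix(rep(neutral, each = n), nrow = n)
  angles[, principal] <- neutral[principal] + span * prof

  with_seed(seed, {
    for (j in setdiff(1:7, principal)) {
      amp <- amplitude_scale * runif(1, 0.005, 0.02)
      f <- runif(1, 0.1, 0.4)           # Hz, well under the tremor band
      ph <- runif(1, 0, 2 * pi)
      angles[, j] <- neutral[j] + amp * sin(2 * pi * f * tt + ph)
    }
  })
  angles <- clip(angles, rep(lims["lower", ], each = n),
                 rep(lims["upper", ], each = n))
  joint_trajectory(angles, dt, movement_label,
                   recording_id = paste0("synthetic-seed", seed))
}

#' Save a trajectory to CSV (with JSON sidecar)
#'
#' Writes the documented CSV dialect: header \code{t,q1,...,q7}, time in
#' seconds, angles in radians, plus a JSON sidecar (same path with
#' \code{.json} extension) holding \code{movement_label},
#' \code{recording_id} and \code{dt}.
#'
#' @param traj A \code{\link{joint_trajectory}}.
#' @param path Output CSV path.
#' @return The CSV path, invisibly.
#' @export
save_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "joint_trajectory"))
  n <- nrow(traj$angles)
  df <- data.frame(t = (seq_len(n) - 1) * traj$dt, traj$angles)
  utils::write.csv(df, path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(list(movement_label = traj$movement_label,
                            recording_id = traj$recording_id,
                            dt = traj$dt),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a trajectory from CSV
#'
#' Inverse of \code{\link{save_trajectory}}; save-then-load round-trips the
#' angle matrix to floating-point precision.  If the JSON sidecar is
#' missing, the label defaults to \code{elbow_flexion_extension} with a
#' warning.
#'
#' @param path CSV path in the documented dialect.
#' @return A \code{\link{joint_trajectory}}.
#' @export
load_trajectory <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: ", path)
  df <- tryCatch(utils::read.csv(path), error = function(e) {
    stop_validation("cannot parse trajectory CSV: ", conditionMessage(e))
  })
  if (nrow(df) == 0L) stop_validation("empty trajectory file: ", path)
  if (ncol(df) != 8L) {
    stop_validation("expected 7 joint columns (t,q1..q7), got ",
                    ncol(df) - 1L, " joint columns")
  }
  tcol <- df[[1]]
  if (any(!is.finite(tcol))) {
    stop_validation("non-finite time value at row ", which(!is.finite(tcol))[1])
  }
  dts <- diff(tcol)
  if (length(dts) && any(dts <= 0)) {
    stop_validation("non-monotone time column at row ", which(dts <= 0)[1] + 1L)
  }
  if (length(dts) && (max(dts) - min(dts)) > 1e-6 * max(dts)) {
    stop_validation("time column is not uniformly sampled")
  }
  ang <- as.matrix(df[, -1, drop = FALSE])
  if (any(!is.finite(ang))) {
    bad <- which(!is.finite(ang), arr.ind = TRUE)[1, ]
    stop_validation("NaN/non-finite angle at row ", bad[1])
  }
  side <- sub("\\.csv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    label <- meta$movement_label
    rec <- meta$recording_id %||% basename(path)
    dt <- meta$dt %||% dts[1]
  } else {
    warning("sidecar ", side, " missing; defaulting movement label")
    label <- "elbow_flexion_extension"
    rec <- basename(path)
    dt <- dts[1]
  }
  joint_trajectory(ang, dt, label, rec)
}

#' Resample a trajectory onto a new time grid
#'
#' Linear interpolation of every joint channel onto a grid with spacing
#' \code{new_dt}; the start point is always preserved and the end point is
#' preserved whenever the total duration is a multiple of \code{new_dt}.
#'
#' @param traj A \code{\link{joint_trajectory}}.
#' @param new_dt New sampling interval, seconds.
#' @return A resampled \code{\link{joint_trajectory}}.
#' @export
resample_trajectory <- function(traj, new_dt) {
  stopifnot(inherits(traj, "joint_trajectory"))
  if (!is.finite(new_dt) || new_dt <= 0) stop_validation("new_dt must be positive")
  n <- nrow(traj$angles)
  t_end <- (n - 1) * traj$dt
  if (new_dt > t_end) {
    stop_validation("new_dt (", new_dt, " s) exceeds trajectory duration (",
                    t_end, " s)")
  }
  old_t <- (seq_len(n) - 1) * traj$dt
  n_new <- floor(t_end / new_dt + 1e-9) + 1L
  new_t <- (seq_len(n_new) - 1) * new_dt
  ang <- vapply(1:7, function(j) {
    stats::approx(old_t, traj$angles[, j], xout = new_t, rule = 2)$y
  }, numeric(n_new))
  joint_trajectory(ang, new_dt, traj$movement_label, traj$recording_id)
}

#' Build the standard reference movement library
#'
#' Two seed-varied recordings for each of the four reference movements,
#' emulating two distinct recordings per movement pattern.
#'
#' @param duration_s,dt Passed to \code{\link{generate_synthetic_movement}}.
#' @param seed Base seed; per-recording seeds are derived from it.
#' @return Named list of 8 \code{joint_trajectory} objects.
#' @export
movement_library <- function(duration_s = 4, dt = 1 / 30, seed = 1L) {
  out <- list()
  k <- 0L
  for (lab in names(movement_labels())) {
    for (rec in 1:2) {
      k <- k + 1L
      tr <- generate_synthetic_movement(lab, duration_s, dt,
                                        amplitude_scale = 1,
                                        seed = derive_seed(seed, k))
      tr$recording_id <- paste0(lab, "-rec", rec)
      out[[tr$recording_id]] <- tr
    }
  }
  out
}
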