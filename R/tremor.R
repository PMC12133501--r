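#' Tremor parameter sampling ranges
#'
#' Uniform ranges for the two tremor harmonics and the amplitude fraction.
#' The training profile draws the first harmonic from 4--6 Hz, the second
#' from 8--12 Hz and the amplitude from 0.1--1 of the per-axis maximum; the
#' testing profile widens these to 3.75--6.25 Hz, 7.5--12.5 Hz and
#' 0.05--1.05 to probe out-of-distribution generalization.
#'
#' @param profile \code{"training"} or \code{"testing"}.
#' @return List with elements \code{f1}, \code{f2}, \code{amplitude}, each a
#'   length-2 numeric range.
#' @export
tremor_ranges <- function(profile = c("training", "testing")) {
  profile <- match.arg(profile)
  if (profile == "training") {
    list(f1 = c(4, 6), f2 = c(8, 12), amplitude = c(0.1, 1))
  } else {
    list(f1 = c(3.75, 6.25), f2 = c(7.5, 12.5), amplitude = c(0.05, 1.05))
  }
}

#' Sample a tremor specification
#'
#' Draws first- and second-harmonic frequencies independently and uniformly
#' from their ranges, an amplitude fraction, and harmonic phases.  A single
#' (f1, f2) pair is shared by all affected axes, so multi-axis tremors are
#' frequency-coupled; phases are likewise shared across axes by default.
#'
#' @param ranges Either a profile name (\code{"training"}/\code{"testing"})
#'   or an explicit list as returned by \code{\link{tremor_ranges}}.
#' @param affected_axes Non-empty integer subset of 1..7.
#' @param noise_sigma Standard deviation of the per-step Gaussian noise
#'   added to the harmonic sum before normalization (default 0.1).
#' @param seed Optional integer seed controlling the draw (and later the
#'   noise realization).
#' @return An object of class \code{tremor_spec}.
#' @export
sample_tremor_spec <- function(ranges = "training", affected_axes,
                               noise_sigma = 0.1, seed = NULL) {
  if (is.character(ranges)) ranges <- tremor_ranges(ranges)
  affected_axes <- sort(unique(as.integer(affected_axes)))
  if (length(affected_axes) == 0L) {
    stop_validation("affected_axes must be non-empty")
  }
  if (any(affected_axes < 1L | affected_axes > 7L)) {
    stop_validation("affected_axes must be within 1..7")
  }
  draw <- function() {
    list(f1 = runif(1, ranges$f1[1], ranges$f1[2]),
         f2 = runif(1, ranges$f2[1], ranges$f2[2]),
         amplitude_scale = runif(1, ranges$amplitude[1], ranges$amplitude[2]),
         phase1 = runif(1, 0, 2 * pi),
         phase2 = runif(1, 0, 2 * pi))
  }
  d <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(c(d, list(affected_axes = affected_axes,
                      noise_sigma = noise_sigma,
                      seed = seed)),
            class = "tremor_spec")
}

#' @export
print.tremor_spec <- function(x, ...) {
  cat(sprintf(
    "<tremor_spec> f1=%.2f Hz f2=%.2f Hz amp=%.2f axes={%s} sigma=%.2f\n",
    x$f1, x$f2, x$amplitude_scale,
    paste0("q", x$affected_axes, collapse = ","), x$noise_sigma))
  invisible(x)
}

#' Synthesize the unit-normalized tremor acceleration waveform
#'
#' The Parkinsonian tremor is modelled as the superposition of two sine
#' waves (first and second harmonic) plus i.i.d. Gaussian noise, then
#' normalized to unit peak magnitude:
#' \deqn{s(t) = \sin(2\pi f_1 t + \phi_1) + \sin(2\pi f_2 t + \phi_2) +
#'   \epsilon_t, \quad \epsilon_t \sim N(0, \sigma^2)}
#' The same waveform is applied on every affected axis (shared frequencies
#' and phases), which realizes the frequency coupling of multi-axis tremor.
#'
#' @param spec A \code{\link{sample_tremor_spec}} result.
#' @param n_steps Number of samples (>= 2).
#' @param dt Sampling interval, seconds; must satisfy the Nyquist bound for
#'   the second harmonic (\code{dt <= 1/(2 f2)}).
#' @return Numeric vector of length \code{n_steps} with \code{max(abs(.)) == 1}.
#' @export
synthesize_acceleration <- function(spec, n_steps, dt) {
  stopifnot(inherits(spec, "tremor_spec"))
  if (n_steps < 2L) stop_validation("n_steps must be >= 2")
  if (dt > 1 / (2 * spec$f2)) {
    stop_validation("dt = ", dt, " s violates the Nyquist bound 1/(2 f2) = ",
                    signif(1 / (2 * spec$f2), 4), " s for f2 = ", spec$f2, " Hz")
  }
  tt <- (seq_len(n_steps) - 1) * dt
  s <- sin(2 * pi * spec$f1 * tt + spec$phase1) +
       sin(2 * pi * spec$f2 * tt + spec$phase2)
  if (spec$noise_sigma > 0) {
    eps <- if (is.null(spec$seed)) {
      rnorm(n_steps, 0, spec$noise_sigma)
    } else {
      with_seed(derive_seed(spec$seed, 1L), rnorm(n_steps, 0, spec$noise_sigma))
    }
    s <- s + eps
  }
  s / max(abs(s))
}

#' Convert tremor acceleration to per-axis joint torques
#'
#' Per-axis torque is the unit-normalized acceleration waveform scaled by
#' the sampled amplitude fraction and the per-axis maximum tremor torque;
#' axes not affected by the tremor receive exactly zero.
#'
#' @param accel Unit-normalized acceleration vector
#'   (\code{\link{synthesize_acceleration}}).
#' @param spec The \code{tremor_spec} that generated it.
#' @param scale_table Named per-axis maximum tremor torque, N.m
#'   (\code{\link{torque_scale_table}}).
#' @param dt Sampling interval (carried into the result).
#' @return An object of class \code{tremor_series}: list with \code{dt} and
#'   \code{torques}, an n x 7 matrix in N.m.
#' @export
acceleration_to_torque <- function(accel, spec,
                                   scale_table = torque_scale_table(),
                                   dt) {
  stopifnot(inherits(spec, "tremor_spec"))
  keys <- paste0("q", spec$affected_axes)
  missing <- setdiff(keys, names(scale_table))
  if (length(missing)) {
    stop_validation("torque scale table has no entry for: ",
                    paste(missing, collapse = ", "))
  }
  n <- length(accel)
  torques <- matrix(0, nrow = n, ncol = 7,
                    dimnames = list(NULL, paste0("q", 1:7)))
  for (a in spec$affected_axes) {
    torques[, a] <- accel * spec$amplitude_scale * scale_table[[paste0("q", a)]]
  }
  structure(list(dt = dt, torques = torques, spec = spec),
            class = "tremor_series")
}

#' Generate a complete tremor torque series
#'
#' Convenience wrapper: synthesize the acceleration waveform and convert it
#' to torques in one call.
#'
#' @inheritParams acceleration_to_torque
#' @inheritParams synthesize_acceleration
#' @return A \code{tremor_series}.
#' @export
tremor_series <- function(spec, n_steps, dt,
                          scale_table = torque_scale_table()) {
  accel <- synthesize_acceleration(spec, n_steps, dt)
  acceleration_to_torque(accel, spec, scale_table, dt)
}

#' Export a tremor torque series to CSV
#'
#' Columns \code{t,tau1..tau7}, the torque analogue of the trajectory CSV
#' dialect.
#'
#' @param series A \code{tremor_series}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
save_tremor_series <- function(series, path) {
  stopifnot(inherits(series, "tremor_series"))
  n <- nrow(series$torques)
  df <- data.frame(t = (seq_len(n) - 1) * series$dt, series$torques)
  names(df) <- c("t", paste0("tau", 1:7))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
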