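#' Dynamics randomization profiles
#'
#' Per-episode uniform sampling ranges for the simulator parameters.  The
#' training profile is a strict subset of the testing profile for every
#' parameter, so evaluation under the testing profile probes
#' out-of-distribution generalization:
#' \tabular{lll}{
#'   parameter \tab training \tab testing \cr
#'   anatomical matrix scale \tab [0.9, 1.1] \tab [0.875, 1.125] \cr
#'   actuator precision scale \tab [0.97, 1.03] \tab [0.96, 1.04] \cr
#'   actuator end-point shift (one axis) \tab [0, 2] cm \tab [0, 2.5] cm \cr
#'   tremor first harmonic \tab [4, 6] Hz \tab [3.75, 6.25] Hz \cr
#'   tremor second harmonic \tab [8, 12] Hz \tab [7.5, 12.5] Hz \cr
#'   tremor amplitude fraction \tab [0.1, 1] \tab [0.05, 1.05] \cr
#' }
#'
#' @param profile \code{"training"} or \code{"testing"}.
#' @return An object of class \code{randomization_config}: list of named
#'   length-2 ranges plus the tremor ranges and the profile name.
#' @export
randomization_config <- function(profile = c("training", "testing")) {
  profile <- match.arg(profile)
  if (profile == "training") {
    cfg <- list(matrix_scale = c(0.9, 1.1),
                actuator_precision = c(0.97, 1.03),
                endpoint_shift_cm = c(0, 2))
  } else {
    cfg <- list(matrix_scale = c(0.875, 1.125),
                actuator_precision = c(0.96, 1.04),
                endpoint_shift_cm = c(0, 2.5))
  }
  cfg$tremor <- tremor_ranges(profile)
  cfg$profile <- profile
  structure(cfg, class = "randomization_config")
}

#' Sample one episode's randomization draw
#'
#' Draws, uniformly from the profile ranges: one scale per anatomical
#' matrix (I, D, K), a precision factor per actuator, and per actuator an
#' end-point shift magnitude applied along one randomly chosen local axis.
#' Uses the current RNG stream; seed it (or wrap in the environment reset)
#' for reproducibility.
#'
#' @param config A \code{\link{randomization_config}}.
#' @return List with \code{matrix_scales} (length 3), \code{precision}
#'   (length 7), \code{endpoint_shift} (7 x 3 matrix, metres),
#'   \code{endpoint_shift_cm} (the drawn magnitudes).
#' @export
sample_randomization <- function(config = randomization_config("training")) {
  stopifnot(inherits(config, "randomization_config"))
  ms <- runif(3, config$matrix_scale[1], config$matrix_scale[2])
  prec <- runif(7, config$actuator_precision[1], config$actuator_precision[2])
  mag_cm <- runif(7, config$endpoint_shift_cm[1], config$endpoint_shift_cm[2])
  axis <- sample.int(3, 7, replace = TRUE)
  shift <- matrix(0, 7, 3)
  shift[cbind(1:7, axis)] <- mag_cm / 100
  list(matrix_scales = ms, precision = prec,
       endpoint_shift = shift, endpoint_shift_cm = mag_cm)
}
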