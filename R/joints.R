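#' Joint conventions of the seven degree-of-freedom arm model
#'
#' The arm model uses seven generalized coordinates, ordered
#' \code{q1..q7}: shoulder flexion/extension (SFE), shoulder
#' abduction/adduction (SAA), shoulder external/internal rotation (SEIR),
#' elbow flexion/extension (EFE), forearm pronation/supination (FPS),
#' wrist flexion/extension (WFE) and wrist radial/ulnar deviation (WRUD).
#' All angles are in radians.
#'
#' @return Character vector of the seven joint axis short names.
#' @export
joint_names <- function() {
  c("SFE", "SAA", "SEIR", "EFE", "FPS", "WFE", "WRUD")
}

#' Reference movement labels
#'
#' The four dynamic reference movements the controller is trained on, each
#' sweeping one principal joint axis.
#'
#' @return Named integer vector mapping movement label to its principal
#'   joint axis index (1-based into \code{q1..q7}).
#' @export
movement_labels <- function() {
  c(shoulder_flexion_extension  = 1L,
    shoulder_abduction_adduction = 2L,
    elbow_flexion_extension      = 4L,
    shoulder_external_rotation   = 3L)
}

#' Anatomical joint angle limits
#'
#' Default per-joint range of motion, radians.  Values are standard adult
#' ranges from the physiotherapy literature; they are configuration, not a
#' measured quantity of this package.
#'
#' @return 2 x 7 matrix with rows \code{lower}, \code{upper}.
#' @export
joint_limits <- function() {
  lims <- rbind(
    lower = c(-1.047, -0.524, -1.222, 0.000, -1.571, -1.222, -0.349),
    upper = c( 3.142,  3.142,  1.571, 2.531,  1.396,  1.396,  0.524))
  colnames(lims) <- joint_names()
  lims
}

#' Neutral (resting) arm pose
#'
#' Slightly flexed elbow and near-vertical upper arm; the pose around which
#' synthetic reference movements are generated.
#'
#' @return Length-7 numeric vector, radians.
#' @export
neutral_pose <- function() {
  c(0.20, 0.15, 0.00, 0.40, 0.00, 0.00, 0.00)
}

#' Per-axis maximum tremor torque scale table
#'
#' Maximum tremor-driving torque per joint axis in Newton-metres, used to
#' convert unit-normalized tremor acceleration waveforms into torques and to
#' normalize torque observations.  The shipped values are documented
#' placeholders of plausible magnitude (largest at the shoulder, smallest at
#' the wrist); override via the YAML interface for patient-specific scales.
#'
#' @param path Optional path to a YAML mapping \code{q1..q7} to N.m.
#' @return Named length-7 numeric vector (names \code{q1..q7}).
#' @export
torque_scale_table <- function(path = NULL) {
  if (is.null(path)) {
    tab <- c(q1 = 2.0, q2 = 2.0, q3 = 1.5, q4 = 1.0,
             q5 = 0.3, q6 = 0.2, q7 = 0.15)
    return(tab)
  }
  raw <- yaml::read_yaml(path)
  need <- paste0("q", 1:7)
  if (!all(need %in% names(raw))) {
    stop_validation("torque scale table must name all of q1..q7; missing: ",
                    paste(setdiff(need, names(raw)), collapse = ", "))
  }
  tab <- vapply(raw[need], as.numeric, numeric(1))
  if (any(!is.finite(tab)) || any(tab <= 0)) {
    stop_validation("torque scale entries must be finite and positive")
  }
  tab
}
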