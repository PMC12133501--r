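#' Arm segment geometry
#'
#' Segment lengths and mass ratios of the simulated right arm.  Defaults are
#' adult 50th-percentile values; the shoulder sits at the world origin with
#' the arm hanging along \code{-z} in the neutral pose (x forward, y medial,
#' z up).
#'
#' @param upper_arm_length,forearm_length,hand_length Metres.
#' @param mass_ratios Segment masses as fractions of body mass
#'   (upper arm, forearm, hand).
#' @param shoulder_origin World position of the shoulder centre, metres.
#' @return An object of class \code{arm_geometry}.
#' @export
arm_geometry <- function(upper_arm_length = 0.30,
                         forearm_length = 0.26,
                         hand_length = 0.08,
                         mass_ratios = c(upper_arm = 0.028,
                                         forearm = 0.016,
                                         hand = 0.006),
                         shoulder_origin = c(0, 0, 0)) {
  if (any(c(upper_arm_length, forearm_length, hand_length) <= 0)) {
    stop_validation("segment lengths must be positive")
  }
  if (any(mass_ratios <= 0 | mass_ratios >= 1)) {
    stop_validation("mass ratios must lie in (0, 1)")
  }
  structure(list(upper_arm_length = upper_arm_length,
                 forearm_length = forearm_length,
                 hand_length = hand_length,
                 mass_ratios = mass_ratios,
                 shoulder_origin = as.numeric(shoulder_origin)),
            class = "arm_geometry")
}

rot_x <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}
rot_y <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}
rot_z <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

#' Forward kinematics of the 7-DoF arm
#'
#' The kinematic chain is: shoulder orientation by the intrinsic rotation
#' sequence y (flexion q1), x (abduction q2), z (axial rotation q3); elbow
#' flexion q4 about the local y axis; forearm pronation q5 about the forearm
#' long axis; wrist flexion q6 and deviation q7.  Segments hang along the
#' local \code{-z} axis, so at the all-zero pose the elbow lies directly
#' below the shoulder at one upper-arm length.
#'
#' @param angles Length-7 joint angle vector, radians.
#' @param geometry An \code{\link{arm_geometry}}.
#' @return List with 3-vectors \code{shoulder}, \code{elbow}, \code{wrist},
#'   \code{hand}; rotation matrices \code{R_shoulder}, \code{R_elbow},
#'   \code{R_wrist}; and \code{axes}, a 3 x 4 matrix whose columns are the
#'   world-frame instantaneous rotation axis directions of q1..q4 (used to
#'   project 3-D joint torques onto the generalized coordinates).
#' @export
forward_kinematics <- function(angles, geometry = arm_geometry()) {
  if (length(angles) != 7L || any(!is.finite(angles))) {
    stop_validation("angles must be a finite length-7 vector")
  }
  q <- as.numeric(angles)
  sh <- geometry$shoulder_origin

  R1 <- rot_y(q[1])
  R12 <- R1 %*% rot_x(q[2])
  Rs <- R12 %*% rot_z(q[3])
  elbow <- sh + as.numeric(Rs %*% c(0, 0, -geometry$upper_arm_length))

  Re <- Rs %*% rot_y(-q[4])          # positive q4 flexes the forearm forward
  wrist <- elbow + as.numeric(Re %*% c(0, 0, -geometry$forearm_length))

  Rf <- Re %*% rot_z(q[5])
  Rw <- Rf %*% rot_y(-q[6]) %*% rot_x(q[7])
  hand <- wrist + as.numeric(Rw %*% c(0, 0, -geometry$hand_length))

  axes <- cbind(c(0, 1, 0),                    # q1: world y
                as.numeric(R1 %*% c(1, 0, 0)), # q2: carried x
                as.numeric(R12 %*% c(0, 0, 1)),# q3: humerus long axis
                as.numeric(Rs %*% c(0, -1, 0)))# q4: elbow flexion axis
  list(shoulder = sh, elbow = elbow, wrist = wrist, hand = hand,
       R_shoulder = Rs, R_elbow = Re, R_wrist = Rw, axes = axes)
}

#' Total arm reach
#'
#' @param geometry An \code{\link{arm_geometry}}.
#' @return Shoulder-to-fingertip distance at full extension, metres.
#' @export
arm_reach <- function(geometry = arm_geometry()) {
  geometry$upper_arm_length + geometry$forearm_length + geometry$hand_length
}
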