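#' Soft exoskeleton actuator layout
#'
#' Seven tension actuators: five spanning the shoulder (anchored on the
#' torso, ending on the upper arm) and two spanning the elbow (anchored on
#' the upper arm, ending on the forearm).  Each actuator pulls its endpoint
#' (point 2) toward its anchor (point 1).  Anchor/endpoint coordinates are
#' local to the attachment segment (\code{torso} coordinates are world
#' coordinates relative to the shoulder origin; \code{upper_arm} and
#' \code{forearm} frames have their origin at the proximal joint and the
#' segment along local \code{-z}).  The shipped coordinates are documented
#' placeholders of plausible placement, not measured hardware.
#'
#' @param path Optional YAML layout file (per-actuator \code{id},
#'   \code{anchor_segment}, \code{anchor}, \code{end_segment}, \code{end},
#'   \code{F_max}, \code{joint}).
#' @return An object of class \code{exo_layout}: list with \code{actuators}
#'   (list of 7 records), \code{Fs} (summed max shoulder force, N) and
#'   \code{Fe} (summed max elbow force, N).
#' @export
default_exo_layout <- function(path = NULL) {
  if (!is.null(path)) return(read_exo_layout(path))
  act <- function(id, a_seg, a, e_seg, e, fmax, joint) {
    list(id = id, anchor_segment = a_seg, anchor = a,
         end_segment = e_seg, end = e, F_max = fmax, joint = joint)
  }
  actuators <- list(
    act("sh_front",  "torso", c( 0.12,  0.05,  0.02), "upper_arm", c( 0.045, 0, -0.17), 40, "shoulder"),
    act("sh_back",   "torso", c(-0.12,  0.05,  0.02), "upper_arm", c(-0.045, 0, -0.17), 40, "shoulder"),
    act("sh_down",   "torso", c( 0.00,  0.05, -0.35), "upper_arm", c( 0.000,  0.050, -0.15), 40, "shoulder"),
    act("sh_medial", "torso", c( 0.00,  0.18, -0.05), "upper_arm", c( 0.000,  0.045, -0.17), 40, "shoulder"),
    act("sh_rot",    "torso", c( 0.02,  0.15, -0.10), "upper_arm", c( 0.045,  0.000, -0.22), 40, "shoulder"),
    act("el_flex",   "upper_arm", c( 0.06, 0, -0.22), "forearm", c( 0.055, 0, -0.10), 60, "elbow"),
    act("el_ext",    "upper_arm", c(-0.12, 0, -0.22), "forearm", c(-0.055, 0, -0.10), 60, "elbow"))
  exo_layout(actuators)
}

#' Construct and validate an exoskeleton layout
#'
#' @param actuators List of exactly 7 actuator records (the action space is
#'   R^7).
#' @return An \code{exo_layout}.
#' @export
exo_layout <- function(actuators) {
  if (length(actuators) != 7L) {
    stop_validation("layout must contain exactly 7 actuators, got ",
                    length(actuators))
  }
  for (a in actuators) {
    need <- c("id", "anchor_segment", "anchor", "end_segment", "end",
              "F_max", "joint")
    if (!all(need %in% names(a))) {
      stop_validation("actuator record missing fields: ",
                      paste(setdiff(need, names(a)), collapse = ", "))
    }
    if (a$F_max <= 0) stop_validation("F_max must be positive (", a$id, ")")
    if (!a$joint %in% c("shoulder", "elbow")) {
      stop_validation("joint attribution must be shoulder or elbow (", a$id, ")")
    }
  }
  fmax <- vapply(actuators, `[[`, numeric(1), "F_max")
  joint <- vapply(actuators, `[[`, character(1), "joint")
  structure(list(actuators = actuators,
                 F_max = fmax,
                 Fs = sum(fmax[joint == "shoulder"]),
                 Fe = sum(fmax[joint == "elbow"])),
            class = "exo_layout")
}

#' @rdname default_exo_layout
#' @export
read_exo_layout <- function(path) {
  raw <- yaml::read_yaml(path)
  actuators <- lapply(raw$actuators, function(a) {
    a$anchor <- as.numeric(a$anchor)
    a$end <- as.numeric(a$end)
    a$F_max <- as.numeric(a$F_max)
    a
  })
  exo_layout(actuators)
}

#' 3-D force components of a tension actuator
#'
#' Two modes are provided.  \code{unit_vector} (the default) returns the
#' physically consistent pull of the endpoint toward the anchor,
#' \eqn{F \cdot (P_1 - P_2)/\|P_1 - P_2\|}, whose magnitude equals \code{F}
#' exactly.  \code{as_printed} evaluates the component-wise
#' cosine-of-atan2 construction
#' \deqn{F_x = \cos(\mathrm{atan2}(\Delta y, \Delta x)) F,\quad
#'       F_y = \cos(\mathrm{atan2}(\Delta x, \Delta y)) F,\quad
#'       F_z = \cos(\mathrm{atan2}(\Delta z, \Delta x)) F}
#' which for generic geometry does not have magnitude \code{F} (e.g. an
#' x-aligned actuator yields a spurious z component); it is retained so the
#' construction itself stays reproducible and testable.
#'
#' @param P1 Anchor (start) point, 3-vector, metres.
#' @param P2 Endpoint (force application point), 3-vector, metres.
#' @param F Tension magnitude, Newtons (>= 0).
#' @param mode \code{"unit_vector"} or \code{"as_printed"}.
#' @return Length-3 force vector, Newtons.
#' @export
force_components <- function(P1, P2, F, mode = c("unit_vector", "as_printed")) {
  mode <- match.arg(mode)
  if (F < 0) stop_validation("force magnitude must be >= 0")
  d <- as.numeric(P1) - as.numeric(P2)
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) stop_validation("actuator endpoints coincide")
  if (mode == "unit_vector") {
    return(F * d / nd)
  }
  dx <- P2[1] - P1[1]; dy <- P2[2] - P1[2]; dz <- P2[3] - P1[3]
  c(cos(atan2(dy, dx)), cos(atan2(dx, dy)), cos(atan2(dz, dx))) * F
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Torque of an actuator force about a joint
#'
#' Standard moment computation \eqn{\tau = r \times F} with the lever arm
#' \code{r} pointing from the joint centre to the force application point
#' (right-hand-rule sign convention).  Set
#' \code{options(exotremor.lever_from_joint = FALSE)} for the opposite
#' (joint minus endpoint) convention, which flips the global sign.
#'
#' @param force 3-vector force, N.
#' @param joint_pos Joint centre, metres.
#' @param endpoint_pos Force application point, metres.
#' @return 3-vector torque, N.m.
#' @export
actuator_torque <- function(force, joint_pos, endpoint_pos) {
  if (any(!is.finite(c(force, joint_pos, endpoint_pos)))) {
    stop_validation("non-finite input to actuator_torque")
  }
  r <- as.numeric(endpoint_pos) - as.numeric(joint_pos)
  if (!isTRUE(getOption("exotremor.lever_from_joint", TRUE))) r <- -r
  cross3(r, as.numeric(force))
}

# World positions of every actuator's anchor and endpoint at a given pose.
# endpoint_shift: optional 7 x 3 matrix added to the endpoint local
# coordinates (dynamics randomization: Velcro sliding).
actuator_positions <- function(layout, angles, geometry = arm_geometry(),
                               endpoint_shift = NULL) {
  fk <- forward_kinematics(angles, geometry)
  seg_world <- function(segment, local) {
    local <- as.numeric(local)
    switch(segment,
      torso = geometry$shoulder_origin + local,
      upper_arm = fk$shoulder + as.numeric(fk$R_shoulder %*% local),
      forearm = fk$elbow + as.numeric(fk$R_elbow %*% local),
      stop_validation("unknown attachment segment: ", segment))
  }
  n <- length(layout$actuators)
  anchors <- matrix(0, n, 3)
  ends <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    a <- layout$actuators[[i]]
    end_local <- a$end
    if (!is.null(endpoint_shift)) end_local <- end_local + endpoint_shift[i, ]
    anchors[i, ] <- seg_world(a$anchor_segment, a$anchor)
    ends[i, ] <- seg_world(a$end_segment, end_local)
  }
  list(anchors = anchors, ends = ends, fk = fk)
}

#' Total joint-axis torques of the exoskeleton
#'
#' Computes world anchor/endpoint positions by forward kinematics, each
#' actuator's force vector and moment about its attributed joint (shoulder
#' or elbow), sums the moments per joint, and projects the shoulder moment
#' onto the instantaneous q1--q3 rotation axes and the elbow moment onto
#' the q4 axis.  The wrist axes q5--q7 carry no actuators and receive zero.
#'
#' @param layout An \code{\link{exo_layout}}.
#' @param forces Length-7 commanded tensions, N, within \code{[0, F_max]}.
#' @param angles Length-7 joint angles at which the geometry is evaluated.
#' @param geometry An \code{\link{arm_geometry}}.
#' @param mode Force model, see \code{\link{force_components}}.
#' @param endpoint_shift Optional 7 x 3 endpoint shift matrix, metres.
#' @param strict If \code{TRUE}, out-of-range forces raise an error;
#'   otherwise they are clamped with a warning.
#' @return Length-7 joint-axis torque vector (N.m) with attributes
#'   \code{shoulder_torque} and \code{elbow_torque} (the 3-D moments).
#' @export
total_joint_torques <- function(layout, forces, angles,
                                geometry = arm_geometry(),
                                mode = "unit_vector",
                                endpoint_shift = NULL,
                                strict = FALSE) {
  stopifnot(inherits(layout, "exo_layout"))
  if (length(forces) != 7L || any(!is.finite(forces))) {
    stop_validation("forces must be a finite length-7 vector")
  }
  out_of_range <- forces < 0 | forces > layout$F_max
  if (any(out_of_range)) {
    if (strict) stop_validation("commanded force outside [0, F_max] for actuator(s) ",
                                paste(which(out_of_range), collapse = ", "))
    warning("clamping commanded force(s) to [0, F_max]")
    forces <- clip(forces, 0, layout$F_max)
  }
  pos <- actuator_positions(layout, angles, geometry, endpoint_shift)
  tau_sh <- c(0, 0, 0)
  tau_el <- c(0, 0, 0)
  for (i in seq_len(7)) {
    if (forces[i] == 0) next
    a <- layout$actuators[[i]]
    fv <- force_components(pos$anchors[i, ], pos$ends[i, ], forces[i], mode)
    jp <- if (a$joint == "shoulder") pos$fk$shoulder else pos$fk$elbow
    tq <- actuator_torque(fv, jp, pos$ends[i, ])
    if (a$joint == "shoulder") tau_sh <- tau_sh + tq else tau_el <- tau_el + tq
  }
  ax <- pos$fk$axes
  tau <- numeric(7)
  tau[1:3] <- as.numeric(t(ax[, 1:3]) %*% tau_sh)
  tau[4] <- sum(ax[, 4] * tau_el)
  names(tau) <- paste0("q", 1:7)
  attr(tau, "shoulder_torque") <- tau_sh
  attr(tau, "elbow_torque") <- tau_el
  tau
}
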