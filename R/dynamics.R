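#' Coupled anatomical inertia, damping and stiffness matrices
#'
#' The displacement dynamics of the arm are the linear coupled second-order
#' system \eqn{I \ddot q + D \dot q + K q = \tau} in the seven generalized
#' coordinates.  Tremor propagation between joints arises from the
#' off-diagonal (anatomical coupling) entries.  The shipped default is a
#' diagonal-dominant symmetric set of plausible magnitude (inertia largest
#' at the shoulder, smallest at the wrist) with small chain-neighbour
#' coupling; it is documented configuration, replaceable via
#' \code{\link{read_anatomical_matrices}} for subject-specific values.
#'
#' @param coupling Relative strength of the chain-neighbour off-diagonal
#'   coupling (fraction of the geometric mean of the adjacent diagonal
#'   entries).  Zero gives fully decoupled joints.
#' @return An object of class \code{anatomical_matrices}: list of 7 x 7
#'   matrices \code{I}, \code{D}, \code{K}.
#' @export
default_anatomical_matrices <- function(coupling = 0.08) {
  d_i <- c(0.35, 0.35, 0.20, 0.080, 0.005, 0.004, 0.003)   # kg m^2
  d_d <- c(1.20, 1.20, 0.80, 0.600, 0.100, 0.080, 0.080)   # N m s / rad
  d_k <- c(10.0, 10.0, 6.00, 5.000, 1.200, 1.000, 0.800)   # N m / rad
  build <- function(d) {
    m <- diag(d)
    for (j in 1:6) {
      v <- coupling * sqrt(d[j] * d[j + 1])
      m[j, j + 1] <- m[j + 1, j] <- v
    }
    dimnames(m) <- list(paste0("q", 1:7), paste0("q", 1:7))
    m
  }
  anatomical_matrices(build(d_i), build(d_d), build(d_k))
}

#' Construct and validate anatomical matrices
#'
#' @param I,D,K 7 x 7 numeric matrices: coupled inertia (kg m^2), damping
#'   (N m s/rad) and stiffness (N m/rad).  \code{I} must be symmetric
#'   positive definite; \code{D} and \code{K} positive semi-definite.
#' @return An object of class \code{anatomical_matrices}.
#' @export
anatomical_matrices <- function(I, D, K) {
  chk_dim <- function(m, nm) {
    if (!is.matrix(m) || !all(dim(m) == c(7, 7))) {
      stop_validation(nm, " must be a 7 x 7 matrix")
    }
    if (any(!is.finite(m))) stop_validation(nm, " contains non-finite entries")
  }
  chk_dim(I, "I"); chk_dim(D, "D"); chk_dim(K, "K")
  if (max(abs(I - t(I))) > 1e-9) stop_validation("I must be symmetric")
  ev <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop_validation("I must be positive definite")
  for (nm in c("D", "K")) {
    m <- get(nm)
    evm <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(evm) < -1e-9) stop_validation(nm, " must be positive semi-definite")
  }
  structure(list(I = I, D = D, K = K), class = "anatomical_matrices")
}

#' Read/write anatomical matrices in the block text format
#'
#' Plain-text interchange: three blocks, each a one-line header (\code{# I},
#' \code{# D}, \code{# K}) followed by 7 rows of 7 comma-separated values.
#'
#' @param path File path.
#' @param matrices An \code{anatomical_matrices} (for writing).
#' @return \code{read_anatomical_matrices} returns an
#'   \code{anatomical_matrices}; the writer returns \code{path} invisibly.
#' @export
read_anatomical_matrices <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  idx <- grep("^#", lines)
  if (length(idx) != 3L) {
    stop_validation("expected 3 block headers (# I, # D, # K), found ",
                    length(idx))
  }
  parse_block <- function(from) {
    rows <- lines[(from + 1):(from + 7)]
    m <- t(vapply(rows, function(r) as.numeric(strsplit(r, ",")[[1]]),
                  numeric(7)))
    rownames(m) <- NULL
    m
  }
  anatomical_matrices(parse_block(idx[1]), parse_block(idx[2]),
                      parse_block(idx[3]))
}

#' @rdname read_anatomical_matrices
#' @export
write_anatomical_matrices <- function(matrices, path) {
  stopifnot(inherits(matrices, "anatomical_matrices"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in c("I", "D", "K")) {
    writeLines(paste("#", nm), con)
    writeLines(apply(matrices[[nm]], 1,
                     function(r) paste(format(r, digits = 12), collapse = ",")),
               con)
  }
  invisible(path)
}

#' Uniformly scale anatomical matrices (dynamics randomization)
#'
#' @param matrices An \code{anatomical_matrices}.
#' @param scales Length-3 multipliers for \code{I}, \code{D}, \code{K}.
#' @return Scaled \code{anatomical_matrices}.
#' @export
scale_matrices <- function(matrices, scales) {
  anatomical_matrices(matrices$I * scales[1], matrices$D * scales[2],
                      matrices$K * scales[3])
}

#' A displacement state at rest
#'
#' @return List \code{q}, \code{q_dot}, \code{q_ddot}, all zero length-7.
#' @export
rest_state <- function() {
  z <- numeric(7)
  list(q = z, q_dot = z, q_ddot = z)
}

#' Advance the coupled displacement dynamics by one control step
#'
#' Integrates \eqn{I \ddot q + D \dot q + K q = \tau} over one control
#' interval \code{dt} with a fixed number of semi-implicit Euler substeps
#' (velocity updated first, then position), a scheme that is stable for
#' stiff linear second-order systems and exactly reproducible.
#'
#' @param matrices An \code{anatomical_matrices}.
#' @param torque Length-7 applied torque, N.m (tremor + exoskeleton).
#' @param dt Control step, seconds.
#' @param init Initial \code{DisplacementState} (default rest).
#' @param n_substeps Integration substeps per control step (default 40).
#' @return Updated displacement state: list \code{q}, \code{q_dot},
#'   \code{q_ddot}.
#' @export
solve_displacement_step <- function(matrices, torque, dt,
                                    init = rest_state(), n_substeps = 40L) {
  stopifnot(inherits(matrices, "anatomical_matrices"))
  if (length(torque) != 7L || any(!is.finite(torque))) {
    stop_validation("torque must be a finite length-7 vector")
  }
  if (dt <= 0) stop_validation("dt must be positive")
  tau <- as.numeric(torque)
  prop <- attr(matrices, "propagator")
  if (!is.null(prop) && prop$dt == dt && prop$n_substeps == n_substeps) {
    # precomputed propagator: the n-substep map is linear in (state, torque)
    x <- as.numeric(prop$T %*% c(init$q_dot, init$q) + prop$U %*% tau)
    qd <- x[1:7]; q <- x[8:14]
    qdd <- as.numeric(prop$I_inv %*% (tau - matrices$D %*% qd -
                                        matrices$K %*% q))
    return(list(q = q, q_dot = qd, q_ddot = qdd))
  }
  I_inv <- attr(matrices, "I_inv")
  if (is.null(I_inv)) {
    I_inv <- tryCatch(solve(matrices$I), error = function(e) {
      stop_validation("inertia matrix is singular")
    })
  }
  h <- dt / n_substeps
  q <- init$q; qd <- init$q_dot
  D <- matrices$D; K <- matrices$K
  qdd <- numeric(7)
  for (s in seq_len(n_substeps)) {
    qdd <- as.numeric(I_inv %*% (tau - D %*% qd - K %*% q))
    qd <- qd + h * qdd
    q <- q + h * qd
  }
  list(q = q, q_dot = qd, q_ddot = qdd)
}

# Cache the inertia inverse on the matrices object (used by the env once
# per episode so the per-step solve is a pair of mat-vec products only).
precompute_inertia_inverse <- function(matrices) {
  attr(matrices, "I_inv") <- solve(matrices$I)
  matrices
}

# Assemble the exact linear map of the n-substep semi-implicit Euler sweep:
# state x = [q_dot; q] advances as x' = T x + U tau, so the per-control-step
# solve collapses to one 14x14 mat-vec.  Composed once per episode.
precompute_propagator <- function(matrices, dt, n_substeps = 40L) {
  matrices <- precompute_inertia_inverse(matrices)
  I_inv <- attr(matrices, "I_inv")
  h <- dt / n_substeps
  A <- diag(7) - h * I_inv %*% matrices$D
  B <- -h * I_inv %*% matrices$K
  T_sub <- rbind(cbind(A, B), cbind(h * A, diag(7) + h * B))
  U_sub <- rbind(h * I_inv, h^2 * I_inv)
  T_all <- diag(14)
  U_all <- matrix(0, 14, 7)
  for (k in seq_len(n_substeps)) {
    U_all <- T_sub %*% U_all + U_sub
    T_all <- T_sub %*% T_all
  }
  attr(matrices, "propagator") <- list(T = T_all, U = U_all, dt = dt,
                                       n_substeps = as.integer(n_substeps),
                                       I_inv = I_inv)
  matrices
}

#' Simulate one control step from the reference trajectory
#'
#' Implements per-step re-initialization: the displacement response to the
#' tremor and exoskeleton torques is integrated from rest at every control
#' step and added to the reference pose, so the simulated trajectory cannot
#' drift away from the voluntary movement.  (The intentional, task-load and
#' gravity torques are carried by the reference movement itself.)  Carrying
#' velocity across steps is available via \code{carry_state} for ablation.
#'
#' @param ref_angles Length-7 reference joint angles at this step.
#' @param tremor_torque,exo_torque Length-7 torque vectors, N.m.
#' @param matrices An \code{anatomical_matrices}.
#' @param dt Control step, seconds.
#' @param limits 2 x 7 joint limit matrix (\code{\link{joint_limits}}).
#' @param carry_state Optional displacement state carried from the previous
#'   step instead of rest initialization.
#' @param n_substeps Integration substeps.
#' @return List: \code{angles} (simulated, clamped to limits),
#'   \code{displacement} (the new displacement state), \code{clamped}
#'   (logical, any joint hit its limit).
#' @export
step_from_reference <- function(ref_angles, tremor_torque, exo_torque,
                                matrices, dt, limits = joint_limits(),
                                carry_state = NULL, n_substeps = 40L) {
  init <- carry_state %||% rest_state()
  disp <- solve_displacement_step(matrices, tremor_torque + exo_torque,
                                  dt, init, n_substeps)
  raw <- as.numeric(ref_angles) + disp$q
  ang <- clip(raw, limits["lower", ], limits["upper", ])
  list(angles = ang, displacement = disp,
       clamped = any(abs(ang - raw) > 0))
}
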