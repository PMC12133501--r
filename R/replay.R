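#' Loss-adjusted prioritized (LAP) replay, split into per-movement sub-buffers
#'
#' One LAP buffer per reference movement.  Sampling probability of
#' transition i within its sub-buffer follows
#' \deqn{p_i = \frac{\max(|\delta_i|^\alpha, 1)}{\sum_j \max(|\delta_j|^\alpha, 1)}}
#' and every batch draws equally many transitions from each sub-buffer, so
#' reference movements of different lengths cannot be over-sampled.
#'
#' @param movement_ids Character vector of movement identifiers.
#' @param capacity Max transitions per sub-buffer (storage grows lazily in
#'   chunks up to this cap).
#' @param s_dim,a_dim Observation/action dimensions.
#' @param alpha LAP prioritization exponent.
#' @return A replay object (environment) of class \code{lap_replay}.
#' @export
replay_create <- function(movement_ids, capacity = 1e6, s_dim = 80L,
                          a_dim = 7L, alpha = 0.4) {
  rp <- new.env(parent = emptyenv())
  rp$movement_ids <- movement_ids
  rp$capacity <- as.integer(capacity)
  rp$s_dim <- s_dim; rp$a_dim <- a_dim; rp$alpha <- alpha
  rp$buf <- lapply(movement_ids, function(id) {
    b <- new.env(parent = emptyenv())
    b$n <- 0L; b$alloc <- 0L
    b
  })
  names(rp$buf) <- movement_ids
  class(rp) <- "lap_replay"
  rp
}

buf_grow <- function(b, rp, need) {
  new_alloc <- min(rp$capacity, max(need, 2L * max(b$alloc, 1024L)))
  grow <- function(m, nc) {
    out <- matrix(0, new_alloc, nc)
    if (b$n > 0L) out[seq_len(b$n), ] <- m[seq_len(b$n), ]
    out
  }
  b$S <- if (is.null(b$S)) matrix(0, new_alloc, rp$s_dim) else grow(b$S, rp$s_dim)
  b$S2 <- if (is.null(b$S2)) matrix(0, new_alloc, rp$s_dim) else grow(b$S2, rp$s_dim)
  b$A <- if (is.null(b$A)) matrix(0, new_alloc, rp$a_dim) else grow(b$A, rp$a_dim)
  b$r <- c(b$r, numeric(new_alloc - b$alloc))
  b$done <- c(b$done, numeric(new_alloc - b$alloc))
  b$prio <- c(b$prio, numeric(new_alloc - b$alloc))
  b$alloc <- new_alloc
}

#' Add a transition to its movement's sub-buffer
#'
#' New transitions receive the buffer's current maximum priority so they
#' are sampled at least once before being down-weighted.
#'
#' @param rp A \code{\link{replay_create}} object.
#' @param movement_id Which sub-buffer.
#' @param s,a,r,s2,done The transition.
#' @return The transition's index in its sub-buffer, invisibly.
#' @export
replay_add <- function(rp, movement_id, s, a, r, s2, done) {
  b <- rp$buf[[movement_id]]
  if (is.null(b)) stop_validation("unknown movement_id: ", movement_id)
  if (b$n >= rp$capacity) {           # ring overwrite
    i <- (b$ring %||% 0L) %% rp$capacity + 1L
    b$ring <- i
  } else {
    if (b$n + 1L > b$alloc) buf_grow(b, rp, b$n + 1L)
    i <- b$n + 1L
    b$n <- i
  }
  b$S[i, ] <- s; b$A[i, ] <- a; b$r[i] <- r; b$S2[i, ] <- s2
  b$done[i] <- as.numeric(done)
  b$max_prio <- max(b$max_prio %||% 1, 1)
  b$prio[i] <- b$max_prio
  invisible(i)
}

#' LAP priority of a TD error
#'
#' \eqn{p = \max(|\delta|^\alpha, 1)}: the clamp at 1 keeps low-error
#' transitions uniformly sampled while high-error ones are up-weighted.
#'
#' @param delta TD error(s).
#' @param alpha Prioritization exponent.
#' @return Priorities, same length as \code{delta}.
#' @export
lap_priority <- function(delta, alpha = 0.4) {
  pmax(abs(delta)^alpha, 1)
}

#' Sample a batch, equally split across movement sub-buffers
#'
#' @param rp A \code{lap_replay}.
#' @param batch_size Total batch size (split equally; must be divisible by
#'   the number of non-empty sub-buffers).
#' @return List: matrices \code{S}, \code{A}, \code{S2}; vectors \code{r},
#'   \code{done}; bookkeeping \code{movement} and \code{index} for
#'   priority updates.
#' @export
replay_sample <- function(rp, batch_size) {
  ids <- names(rp$buf)[vapply(rp$buf, function(b) b$n > 0L, logical(1))]
  if (length(ids) == 0L) stop_validation("replay buffer is empty")
  k <- batch_size %/% length(ids)
  S <- matrix(0, 0, rp$s_dim); S2 <- matrix(0, 0, rp$s_dim)
  A <- matrix(0, 0, rp$a_dim)
  r <- numeric(0); done <- numeric(0)
  movement <- character(0); index <- integer(0)
  for (id in ids) {
    b <- rp$buf[[id]]
    pr <- b$prio[seq_len(b$n)]
    idx <- sample.int(b$n, k, replace = TRUE, prob = pr)
    S <- rbind(S, b$S[idx, , drop = FALSE])
    S2 <- rbind(S2, b$S2[idx, , drop = FALSE])
    A <- rbind(A, b$A[idx, , drop = FALSE])
    r <- c(r, b$r[idx]); done <- c(done, b$done[idx])
    movement <- c(movement, rep(id, k)); index <- c(index, idx)
  }
  list(S = S, A = A, r = r, S2 = S2, done = done,
       movement = movement, index = index)
}

#' Update priorities after a critic step
#'
#' @param rp A \code{lap_replay}.
#' @param movement,index Bookkeeping vectors from \code{\link{replay_sample}}.
#' @param delta TD errors of the sampled transitions.
#' @return Invisibly, \code{rp}.
#' @export
replay_update_priority <- function(rp, movement, index, delta) {
  pr <- lap_priority(delta, rp$alpha)
  for (id in unique(movement)) {
    sel <- movement == id
    b <- rp$buf[[id]]
    b$prio[index[sel]] <- pr[sel]
    b$max_prio <- max(b$max_prio %||% 1, pr[sel])
  }
  invisible(rp)
}

#' Total stored transitions
#'
#' @param rp A \code{lap_replay}.
#' @return Named integer vector of per-sub-buffer sizes.
#' @export
replay_sizes <- function(rp) {
  vapply(rp$buf, function(b) b$n, integer(1))
}
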