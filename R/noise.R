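#' Pink (1/f) noise sequences for action exploration
#'
#' Generates temporally correlated noise whose power spectral density falls
#' off as \eqn{1/f} (log-log slope about -1, between white noise at 0 and
#' brown noise at -2), via the spectral method: Gaussian Fourier
#' coefficients scaled by \eqn{1/\sqrt{f}}, inverse FFT, then normalized to
#' unit variance per dimension.  One independent sequence per action
#' dimension; regenerate per episode for stateless, seedable exploration.
#'
#' @param n_steps Sequence length.
#' @param n_dim Number of independent dimensions (columns).
#' @param seed Optional integer seed.
#' @return \code{n_steps} x \code{n_dim} matrix, unit variance per column.
#' @export
pink_noise <- function(n_steps, n_dim = 1L, seed = NULL) {
  gen <- function() {
    n <- as.integer(n_steps)
    out <- matrix(0, n, n_dim)
    nf <- n %/% 2L + 1L                  # rfft bin count
    f <- seq_len(nf) - 1L
    amp <- c(0, 1 / sqrt(f[-1]))         # zero out DC
    for (j in seq_len(n_dim)) {
      re <- rnorm(nf) * amp
      im <- rnorm(nf) * amp
      im[1] <- 0
      if (n %% 2L == 0L) im[nf] <- 0
      half <- complex(real = re, imaginary = im)
      mirror <- if (n %% 2L == 0L) half[2:(nf - 1L)] else half[2:nf]
      full <- c(half, Conj(rev(mirror)))
      x <- Re(stats::fft(full, inverse = TRUE)) / n
      out[, j] <- x / stats::sd(x)
    }
    out
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Add exploration noise to a policy action
#'
#' @param policy_action Length-d action in [-1, 1].
#' @param noise One row of a pre-generated noise sequence
#'   (\code{\link{pink_noise}}), or white noise.
#' @param scale Noise scale; 0 returns the action unchanged.
#' @return Noisy action, clipped to [-1, 1].
#' @export
explore_action <- function(policy_action, noise, scale) {
  clip(policy_action + scale * noise, -1, 1)
}

#' Log-log spectral slope of a noise sequence
#'
#' Least-squares slope of log power spectral density against log frequency;
#' about 0 for white noise, about -1 for pink, about -2 for brown.
#'
#' @param x Numeric vector.
#' @return Scalar slope estimate.
#' @export
psd_slope <- function(x) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  nf <- n %/% 2L
  f <- (1:nf) / n
  p <- sp[2:(nf + 1L)]
  keep <- p > 0
  unname(coef(stats::lm(log(p[keep]) ~ log(f[keep])))[2])
}
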