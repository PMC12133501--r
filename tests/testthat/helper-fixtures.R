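# Shared small fixtures, built in code at test time.

fix_trajectory <- function(label = "elbow_flexion_extension", seed = 1L,
                           duration_s = 4, dt = 1 / 30) {
  generate_synthetic_movement(label, duration_s, dt, 1, seed)
}

fix_env <- function(axes = 4L, profile = "training", seed = 1L, ...) {
  tremor_env(fix_trajectory(seed = seed), axes, profile, env_config(...))
}

fix_spec <- function(axes = 4L, seed = 7L, noise_sigma = 0,
                     ranges = "training") {
  sample_tremor_spec(ranges, axes, noise_sigma = noise_sigma, seed = seed)
}

# dominant FFT frequencies (Hz) of a real signal
dominant_freqs <- function(x, dt, k = 2) {
  n <- length(x)
  sp <- Mod(stats::fft(x))[2:(n %/% 2)]
  f <- (1:(n %/% 2 - 1)) / (n * dt)
  f[order(sp, decreasing = TRUE)][seq_len(k)]
}
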