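# Short-duration parameter set for mechanics-level tests where only the
# qualitative settled state matters (bumps form well within 600 ms).
params_fast <- function(...) {
  cann_params(duration = 600, window = c(200, 500), final_window = 50, ...)
}

# tiny noise-free generator config for exact-recovery tests
config_tiny <- function(n = 10, seed = 1, noise = 0, ...) {
  generator_config(n_neurons = n, trial_noise_sd = noise, seed = seed, ...)
}

# synthetic one-bump activity profile on the ring (Gaussian, peak < 1)
bump_profile <- function(center_deg, width = 12, height = 0.9, L = 180) {
  pos <- (seq_len(L) - 1) * 2
  height * exp(-circular_disparity(pos, center_deg)^2 / (2 * width^2))
}
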