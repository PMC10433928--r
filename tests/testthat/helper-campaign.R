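# Shared fixtures: small campaigns built in code.

# Two species, two trees, all measurement noise off (trait spread stays on:
# it assigns ground truth, it is not noise).
zero_noise_config <- function(seed = 101, n_trees = 2,
                              species = species_presets()[c(1, 5), ]) {
  sim_config(
    species = species, n_trees = n_trees,
    sigma_js = 0, sigma_gs = 0, sigma_la = 0, sigma_anat = 0,
    seed = seed
  )
}

small_config <- function(seed = 202, n_trees = 2, ...) {
  sim_config(species = species_presets()[c(1, 5), ], n_trees = n_trees,
             seed = seed, ...)
}

# Closed-form deficit at which the noise-free flux curve peaks.
d_star <- function(gsref, m) exp(gsref / m - 1)
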