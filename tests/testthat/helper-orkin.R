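# Shared fixtures, built in code.

# Random but well-formed kinetic parameter packs (all constants positive,
# spanning several decades).
random_kinetic_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    kinetic_params(A = 10^runif(1, -1, 1),
                   C_G = 10^runif(1, -1, 1),
                   k_G_f = 10^runif(1, -1, 1),
                   k_OG_f = 10^runif(1, -1, 1.5),
                   K_G = 10^runif(1, -1, 1),
                   K_OG = 10^runif(1, -2, 1),
                   K_O = 10^runif(1, -6, -1))
  })
}

# Noiseless dose-response series from a hill_params object: n doses at
# half-decade spacing centered on the EC50.
noiseless_series <- function(h, n = 8, step = 0.5) {
  ld <- h$EC50 + seq(-(n - 1) / 2, (n - 1) / 2) * step
  list(doses = 10^ld, responses = hill_activity(h, 10^ld))
}

# Small standard generator spec for quick tests.
quick_spec <- function(seed, n_receptors = 40, n_odorants = 12,
                       density = 0.25, noise = 0.05, ...) {
  generator_spec(n_receptors = n_receptors, n_odorants = n_odorants,
                 interaction_density = density, noise_sigma = noise,
                 seed = seed, ...)
}
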