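# Shared fixtures: all built in code, seeded for reproducibility.

# An optimized parameter set in the empirically observed regime (time
# constants of a few ms, strong inhibitory gain, sub-unity coupling).
optimized_params <- function() {
  sgm_params(tau_e = 0.0073, tau_i = 0.0085, tau_G = 0.0061,
             g_ii = 4.4865, g_ei = 2.9469, v = 18.3071, alpha = 0.4639)
}

random_conn <- function(n = 10, sparsity = 0.3, seed = 7) {
  generate_connectome("random", n = n, sparsity = sparsity, seed = seed)
}

# Small connectome with genuine fiber distances (so the Laplacian is
# frequency-dependent).
distance_conn <- function(n = 20, sparsity = 0.3, seed = 11) {
  generate_connectome("distance", n = n, sparsity = sparsity, seed = seed)
}

# Textbook Pearson correlation via explicit sums, as an oracle independent
# of stats::cor.
pearson_by_hand <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}
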