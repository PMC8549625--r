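# Shared fixture builders (everything generated in code; no stored data).

# A flat-fitness configuration on the standard 500-bin mesh, used for
# no-selection variance dynamics.
flat_fitness_config <- function(approach, generations = 20L,
                                sigma_seg = NULL, grid_bins = 500L) {
  eeipm_config(
    grid = list(a_min = 0, a_max = 40, n_a = grid_bins,
                e_min = 0, e_max = 40, n_e = grid_bins),
    init = list(mean_A = 18, mean_E = 18, var_A = 2, var_E = 2),
    fitness = list(form = "linear", beta0 = 1, beta_z = 0),
    genetic = list(approach = approach, sigma_seg = sigma_seg),
    environment = list(mean0 = 18, trend = 0, sigma_EE = 2),
    run = list(generations = generations, engine = "fast")
  )
}

# Normalized L1 distance between the densities of two states.
state_l1 <- function(a, b) sum(abs(a$density / a$n - b$density / b$n))

# Brute-force oracle for the mid-parent distribution of a discrete
# breeding-value distribution: enumerate all parental pairings.
midparent_oracle <- function(values, probs) {
  pair_vals <- outer(values, values, function(x, y) (x + y) / 2)
  pair_probs <- outer(probs, probs)
  agg <- tapply(as.vector(pair_probs), as.vector(pair_vals), sum)
  list(values = as.numeric(names(agg)), probs = as.numeric(agg))
}
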