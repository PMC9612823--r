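# Shared fixtures, built in code at test time.

premise_pairs <- function() paste0(LETTERS[1:6], ">", LETTERS[2:7])

inferred_pairs <- function() c("B>D", "C>E", "D>F", "B>E", "C>F", "B>F")

named_counts <- function(values, pairs) stats::setNames(values, pairs)

# small cohort reused by several suites
small_cohort <- function(n = 8, regime = "OR", kappa = 0.9, seed = 42) {
  profiles <- participant_profiles(n = n, regime = regime, kappa = kappa,
                                   seed = seed)
  simulate_cohort(profiles, seed = seed)
}

# per-participant texture patterns with injected distance-decay structure,
# plus iid measurement noise
structured_patterns <- function(v = 50, lambda = 2, noise_sd = 1, seed = 1) {
  pat <- simulate_patterns(v = v, lambda = lambda, seed = seed)
  pat + matrix(stats::rnorm(length(pat), sd = noise_sd), nrow = nrow(pat))
}
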