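# shared fixtures and small utilities for the suite

fixture_games <- function() {
  list(coexistence = make_symmetric_game("coexistence"),
       dominance = make_symmetric_game("dominance"),
       coordination = make_symmetric_game("coordination"))
}

# random finite 2x2 payoff matrices for property-style loops
random_games <- function(n, seed = 123, lo = -2, hi = 3) {
  set.seed(seed)
  lapply(seq_len(n), function(i) make_symmetric_game(stats::runif(4, lo, hi)))
}

# z-score of an empirical binomial frequency against a predicted probability
binom_z <- function(freq, p, n) (freq - p) / sqrt(p * (1 - p) / n)
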