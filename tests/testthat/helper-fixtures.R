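# Small fixtures built in code, shared across test files.

# A session with explicit choices/rewards and flat true probabilities.
make_session <- function(choices, rewards, p0 = 0.5, p1 = 0.5) {
  n <- length(choices)
  bandit_session(data.frame(
    trial = seq_len(n),
    choice = as.integer(choices),
    reward = as.integer(rewards),
    p0 = rep_len(p0, n), p1 = rep_len(p1, n)
  ))
}

# A schedule whose probabilities are overridden to fixed values per bandit.
make_flat_schedule <- function(n_trials, p0, p1, seed = 1) {
  ws <- generate_walk(n_trials, seed = seed)
  ws$p[, 1] <- p0
  ws$p[, 2] <- p1
  ws
}

# Simulated observer session used by several fitting tests.
make_observer_session <- function(n_trials = 220, seed = 11,
                                  params = observer_params(5, 0.3, 0.1, 0.5, 0.5)) {
  ws <- generate_walk(n_trials, seed = seed)
  simulate_session(ws, observer_agent(params), seed = seed + 1)
}
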