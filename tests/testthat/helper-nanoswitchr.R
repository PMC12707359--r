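# Shared fixtures for the test suite. Everything is generated in code;
# seeds are fixed so tests are reproducible.

default_params <- function(...) kinetic_params(...)

# A state sequence built directly from dwell specifications:
# states = c("unbound","bound",...), dwells in seconds.
make_sequence <- function(states, dwells) {
  t_end <- cumsum(dwells)
  new_state_sequence(data.frame(state = states,
                                t_start = c(0, head(t_end, -1)),
                                t_end = t_end,
                                stringsAsFactors = FALSE))
}

# Random alternating state sequence for property tests.
random_sequence <- function(n_intervals, mean_dwell = 5) {
  start <- sample(c("unbound", "bound"), 1)
  states <- if (start == "unbound")
    rep(c("unbound", "bound"), length.out = n_intervals)
  else rep(c("bound", "unbound"), length.out = n_intervals)
  dwells <- stats::rexp(n_intervals, 1 / mean_dwell) + 1e-6
  make_sequence(states, dwells)
}

# Brute-force UTB oracle: scan consecutive state pairs and bin the
# transition times with an explicit loop (independent of count_utb).
brute_force_utb <- function(states, edges) {
  counts <- integer(length(edges) - 1)
  if (nrow(states) < 2) return(counts)
  for (i in 2:nrow(states)) {
    if (states$state[i - 1] == "unbound" && states$state[i] == "bound") {
      tt <- states$t_start[i]
      for (k in seq_len(length(edges) - 1)) {
        if (tt >= edges[k] && tt < edges[k + 1]) {
          counts[k] <- counts[k] + 1L
          break
        }
      }
    }
  }
  counts
}

# Small two-injection schedule used by several tests.
tiny_schedule <- function(conc = c(500, 500), n_intervals = 3,
                          drift_rate = 0) {
  sample_schedule(conc, rep("calibrant", length(conc)), flow_min = 1,
                  n_intervals = n_intervals, drift_rate = drift_rate)
}
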