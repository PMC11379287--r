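# Shared fixtures for the suite. Everything is built in code; no data files.

base_P <- baseline_parameters()

# Degenerate world: no transmitted resistance, no adverse events -> the two
# arms can differ only by the entry test cost.
no_resistance_params <- function() {
  apply_overrides(base_P, list(tdr_nrti = 0, tdr_pi = 0, tdr_insti = 0,
                               adverse_event_prob = 0))
}

# Reduced state space for hand oracles: single resistance class, no adverse
# events, no opportunistic infections.
reduced_params <- function() {
  apply_overrides(base_P, list(tdr_nrti = 0, tdr_pi = 0, tdr_insti = 0,
                               adverse_event_prob = 0,
                               oi_prob_failure = 0, oi_prob_success = 0))
}

# Occupancy by cycle from a trace, aggregated over a grouping column.
occupancy_by <- function(outcome, ...) {
  st <- outcome$trace$states
  aggregate(occupancy ~ ., data = st[, c("cycle", ..., "occupancy")],
            FUN = sum)
}
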