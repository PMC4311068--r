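# Shared fixtures for the test suite. Everything is built in code; no
# stored data files.

# A minimal hand-specifiable events tibble.
make_events <- function(actions, outcomes, session = 1L,
                        onsets = seq(0, by = 5, length.out = length(actions)),
                        block_type = "80/20") {
  n <- length(actions)
  tibble::tibble(
    trial = seq_len(n) - 1L,
    session = rep_len(as.integer(session), n),
    block_id = 1L,
    block_type = rep_len(block_type, n),
    action = actions,
    outcome = outcomes,
    onset_s = onsets,
    correct = NA,
    reached_criterion = FALSE
  )
}

# Cohort-median parameters from the fitted-parameter quartile table.
median_params <- function() agent_params(0.62, 2.73, 0.84)

# Simulate a small cohort of event tables from known transformed params.
simulate_known_cohort <- function(n_subjects, prior = cohort_spec()$prior,
                                  cfg = task_config()) {
  thetas <- MASS::mvrnorm(n_subjects, prior$mu, prior$sigma)
  thetas <- matrix(thetas, ncol = 3)
  list(thetas = thetas,
       events = lapply(seq_len(n_subjects), function(i)
         simulate_agent(from_theta(thetas[i, ]), cfg)))
}
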