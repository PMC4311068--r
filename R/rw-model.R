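#' Rescorla-Wagner agent parameters
#'
#' Natural-space parameters of the RW/softmax observation model: the
#' learning rate `epsilon` (fraction of each prediction error incorporated
#' into the value estimate, bounded \[0, 1\]) and the reward and punishment
#' sensitivities `beta_rew`, `beta_pun` (non-negative scalings of positive
#' and negative feedback into effective reinforcement; they also set how
#' deterministic the softmax choice rule is).
#'
#' @param epsilon learning rate in \[0, 1\].
#' @param beta_rew reward sensitivity, >= 0.
#' @param beta_pun punishment sensitivity, >= 0.
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(epsilon, beta_rew, beta_pun) {
  stopifnot(is.finite(epsilon), is.finite(beta_rew), is.finite(beta_pun))
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]")
  if (beta_rew < 0 || beta_pun < 0) stop("sensitivities must be >= 0")
  structure(list(epsilon = epsilon, beta_rew = beta_rew,
                 beta_pun = beta_pun), class = "agent_params")
}

#' Parameter transforms between natural and unconstrained space
#'
#' Fitting happens in unconstrained space: the learning rate is
#' logit-transformed (inverse sigmoid, `log(eps / (1 - eps))`) and the two
#' sensitivities are log-transformed, giving the vector
#' `theta = (eps', log beta_rew, log beta_pun)`. The reverse map applies
#' the logistic sigmoid and `exp`.
#'
#' @param params an [agent_params()].
#' @param theta a numeric 3-vector in transformed space.
#' @return `to_theta` returns the 3-vector; `from_theta` an
#'   [agent_params()].
#' @export
to_theta <- function(params) {
  c(stats::qlogis(params$epsilon), log(params$beta_rew), log(params$beta_pun))
}

#' @rdname to_theta
#' @export
from_theta <- function(theta) {
  stopifnot(length(theta) == 3)
  agent_params(epsilon = stats::plogis(theta[1]),
               beta_rew = exp(theta[2]),
               beta_pun = exp(theta[3]))
}

#' Softmax choice probabilities
#'
#' Maps a pair of action values to choice probabilities via normalized
#' exponentials, computed with max-subtraction for numerical stability.
#' Probabilities sum to 1 and preserve the ordering of the values.
#'
#' @param q numeric 2-vector of action values.
#' @return Numeric 2-vector of probabilities.
#' @export
softmax_prob <- function(q) {
  if (length(q) != 2 || !all(is.finite(q))) stop("q must be 2 finite values")
  e <- exp(q - max(q))
  e / sum(e)
}

#' Effective reinforcement of an outcome
#'
#' Positive feedback enters the value update as `beta_rew`, negative
#' feedback as `-beta_pun`.
#'
#' @param outcome `"reward"`/`"punishment"` (or the TSV codes `1`/`-1`);
#'   vectorized.
#' @param params an [agent_params()].
#' @return Numeric vector of effective reinforcements.
#' @export
effective_reinforcement <- function(outcome, params) {
  if (is.numeric(outcome)) {
    if (!all(outcome %in% c(1, -1))) stop("numeric outcomes must be 1 or -1")
    outcome <- ifelse(outcome > 0, "reward", "punishment")
  }
  if (!all(outcome %in% c("reward", "punishment")))
    stop("unknown outcome code")
  ifelse(outcome == "reward", params$beta_rew, -params$beta_pun)
}

#' One Rescorla-Wagner value update
#'
#' `Q <- Q + epsilon * (r - Q)` for the chosen action; the unchosen
#' action's value is left untouched by the caller.
#'
#' @param q_chosen current value of the chosen action.
#' @param r effective reinforcement received.
#' @param epsilon learning rate in \[0, 1\].
#' @return Updated value.
#' @export
update_value <- function(q_chosen, r, epsilon) {
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]")
  q_chosen + epsilon * (r - q_chosen)
}

# Encode an events tibble for the C++ likelihood core.
encode_events <- function(events) {
  if (nrow(events) == 0) stop("events must contain at least one trial")
  if (!all(events$action %in% c("L", "R"))) stop("actions must be 'L'/'R'")
  list(choice = as.integer(events$action == "R"),
       outcome = ifelse(events$outcome == "reward", 1L, -1L),
       session = as.integer(events$session))
}

#' Log-likelihood of a choice sequence under the RW/softmax model
#'
#' Steps the value recursion trial by trial from `Q0 = (0, 0)`, summing the
#' log softmax probability of each chosen action. The trial-wise value,
#' effective-reinforcement and prediction-error traces are returned as a
#' side product (`pe[t] = r_eff[t] - Q_{t-1}(chosen action)`).
#'
#' @param events a trial-record tibble (needs `action`, `outcome`,
#'   `session`).
#' @param params an [agent_params()].
#' @param carry_over if `TRUE` (default) values carry across the session
#'   boundary — subjects are not told of reversals, so learning is treated
#'   as one continuous stream; if `FALSE` values reset to 0 at each new
#'   session.
#' @return A list with `loglik` (scalar) and `trace`, a tibble with
#'   columns `trial`, `q_left`, `q_right`, `r_eff`, `pe` (values are those
#'   *before* the trial's update).
#' @export
sequence_loglik <- function(events, params, carry_over = TRUE) {
  enc <- encode_events(events)
  res <- rw_loglik_cpp(enc$choice, enc$outcome, enc$session,
                       params$epsilon, params$beta_rew, params$beta_pun,
                       carry_over)
  list(loglik = res$loglik,
       trace = tibble::tibble(trial = events$trial,
                              q_left = res$q_left, q_right = res$q_right,
                              r_eff = res$r_eff, pe = res$pe))
}

#' Simulate an RW/softmax agent on the reversal task
#'
#' Choices are sampled from the softmax of the agent's running values,
#' which are updated from the feedback the task environment returns.
#'
#' @param params an [agent_params()].
#' @param cfg a [task_config()].
#' @param carry_over carry values across sessions (see
#'   [sequence_loglik()]).
#' @return A trial-record tibble (see [run_session()]).
#' @export
simulate_agent <- function(params, cfg = task_config(), carry_over = TRUE) {
  q <- c(0, 0)
  agent <- list(
    choose = function() {
      p <- softmax_prob(q)
      if (stats::runif(1) < p[1]) "L" else "R"
    },
    observe = function(action, outcome) {
      i <- if (action == "L") 1L else 2L
      r <- effective_reinforcement(outcome, params)
      q[i] <<- update_value(q[i], r, params$epsilon)
    }
  )
  if (!carry_over) {
    out <- vector("list", cfg$n_sessions)
    prev <- NULL
    blocks_done <- 0L
    for (s in seq_len(cfg$n_sessions)) {
      q <- c(0, 0)
      out[[s]] <- run_session(agent, cfg, session = s,
                              trial_offset = (s - 1L) * cfg$n_trials_per_session,
                              block_id_offset = blocks_done,
                              prev_block_label = prev)
      prev <- out[[s]]$block_type[nrow(out[[s]])]
      blocks_done <- max(out[[s]]$block_id)
    }
    return(do.call(rbind, out))
  }
  run_task(agent, cfg)
}

#' Write / read a per-subject prediction-error trace
#'
#' Tab-separated columns `trial`, `q_left`, `q_right`, `r_eff`, `pe`.
#'
#' @param trace the `trace` tibble from [sequence_loglik()].
#' @param path file path.
#' @return `write_pe_trace` returns `path` invisibly; `read_pe_trace` the
#'   tibble.
#' @export
write_pe_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_pe_trace
#' @export
read_pe_trace <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}
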