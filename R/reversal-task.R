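#' Task configuration for the probabilistic reversal-learning task
#'
#' The task presents two response options (left/right) whose reward
#' probabilities are set by the current block. Three block types exist:
#' 20/80, 80/20 and 50/50 (probability of reward for the left and right
#' response, respectively). A block ends — and the block type changes,
#' unannounced — once at least `min_block_trials` trials have been played
#' *and* at least `criterion_correct_frac` of the block's responses were
#' correct, or automatically after `max_block_trials` trials.
#'
#' @param n_trials_total total number of trials across all sessions.
#' @param n_sessions number of scanning sessions the trials are split into.
#' @param min_block_trials minimum trials before the learning criterion can
#'   end a block.
#' @param criterion_correct_frac fraction of correct responses within the
#'   block required by the learning criterion.
#' @param max_block_trials trial count at which a block ends automatically.
#' @param iti_range_s inter-trial interval range in seconds (uniform jitter).
#' @param feedback_duration_s feedback display duration in seconds.
#' @param max_rt_s maximum response time in seconds (bookkeeping only;
#'   simulated agents respond instantly).
#' @param criterion_rule how a response is scored "correct" for the
#'   block-switching criterion. `"higher_prob"` counts a choice of the
#'   higher-reward-probability action as correct in asymmetric blocks and
#'   falls back to feedback (rewarded = correct) in 50/50 blocks, where no
#'   action is objectively better. `"feedback"` scores every trial by its
#'   feedback.
#'
#' @return A list of class `task_config`.
#' @export
task_config <- function(n_trials_total = 200L,
                        n_sessions = 2L,
                        min_block_trials = 10L,
                        criterion_correct_frac = 0.70,
                        max_block_trials = 16L,
                        iti_range_s = c(1.0, 6.5),
                        feedback_duration_s = 1.0,
                        max_rt_s = 2.0,
                        criterion_rule = c("higher_prob", "feedback")) {
  criterion_rule <- match.arg(criterion_rule)
  stopifnot(n_trials_total >= 1, n_sessions >= 1,
            n_trials_total %% n_sessions == 0,
            min_block_trials <= max_block_trials,
            criterion_correct_frac > 0, criterion_correct_frac < 1,
            length(iti_range_s) == 2, iti_range_s[1] <= iti_range_s[2])
  structure(list(
    n_trials_total = as.integer(n_trials_total),
    n_sessions = as.integer(n_sessions),
    n_trials_per_session = as.integer(n_trials_total / n_sessions),
    min_block_trials = as.integer(min_block_trials),
    criterion_correct_frac = criterion_correct_frac,
    max_block_trials = as.integer(max_block_trials),
    iti_range_s = as.numeric(iti_range_s),
    feedback_duration_s = feedback_duration_s,
    max_rt_s = max_rt_s,
    criterion_rule = criterion_rule
  ), class = "task_config")
}

#' Reward-allocation block types
#'
#' @return A data frame with one row per block type: `label`,
#'   `reward_prob_left`, `reward_prob_right`.
#' @export
block_types <- function() {
  data.frame(
    label = c("20/80", "80/20", "50/50"),
    reward_prob_left = c(0.2, 0.8, 0.5),
    reward_prob_right = c(0.8, 0.2, 0.5),
    stringsAsFactors = FALSE
  )
}

block_row <- function(label) {
  bt <- block_types()
  i <- match(label, bt$label)
  if (is.na(i)) stop("unknown block type: ", label)
  bt[i, ]
}

#' Sample a feedback outcome for one trial
#'
#' Returns `"reward"` with the probability the current block assigns to the
#' chosen action, else `"punishment"`.
#'
#' @param block a block label (`"20/80"`, `"80/20"`, `"50/50"`) or a row of
#'   [block_types()].
#' @param action `"L"` or `"R"`.
#' @return `"reward"` or `"punishment"`.
#' @export
sample_outcome <- function(block, action) {
  if (is.character(block)) block <- block_row(block)
  if (!action %in% c("L", "R")) stop("action must be 'L' or 'R'")
  p <- if (action == "L") block$reward_prob_left else block$reward_prob_right
  if (stats::runif(1) < p) "reward" else "punishment"
}

#' Block-switching rule
#'
#' A block ends when (a) at least `min_block_trials` trials have been played
#' and the fraction correct within the block reaches
#' `criterion_correct_frac`, or (b) `max_block_trials` trials have been
#' played regardless of performance.
#'
#' @param n_block_trials trials played so far in the block.
#' @param n_block_correct of these, how many were correct.
#' @param cfg a [task_config()].
#' @return `TRUE` if the block should end after this trial.
#' @export
should_switch_block <- function(n_block_trials, n_block_correct, cfg = task_config()) {
  if (n_block_trials < 0 || n_block_correct < 0)
    stop("trial counts must be non-negative")
  if (n_block_correct > n_block_trials)
    stop("n_block_correct cannot exceed n_block_trials")
  if (n_block_trials >= cfg$max_block_trials) return(TRUE)
  n_block_trials >= cfg$min_block_trials &&
    n_block_correct / n_block_trials >= cfg$criterion_correct_frac
}

# Is `action` correct on this block under the switching-criterion rule?
# outcome is needed for 50/50 blocks (and for the pure feedback rule).
criterion_correct <- function(block, action, outcome, rule) {
  if (rule == "feedback" || block$reward_prob_left == block$reward_prob_right)
    return(outcome == "reward")
  best <- if (block$reward_prob_left > block$reward_prob_right) "L" else "R"
  action == best
}

draw_next_block <- function(current_label = NULL) {
  labels <- block_types()$label
  if (!is.null(current_label)) labels <- setdiff(labels, current_label)
  sample(labels, 1)
}

#' Run one session of the reversal-learning task
#'
#' Drives the block schedule, outcome sampling and onset bookkeeping for one
#' session, querying `agent` for a choice on every trial and reporting the
#' outcome back. Simulated agents respond instantly, so the feedback onset
#' coincides with the trial onset; trials are separated by the 1 s feedback
#' display plus a uniformly jittered inter-trial interval.
#'
#' @param agent a list with elements `choose` (a function of no arguments
#'   returning `"L"` or `"R"`) and, optionally, `observe` (a function called
#'   with `(action, outcome)` after every trial). Stateful agents keep their
#'   state in the closure environment.
#' @param cfg a [task_config()].
#' @param session session number (recorded on every trial).
#' @param trial_offset 0-based index of the session's first trial in the
#'   whole experiment.
#' @param block_id_offset number of blocks already played in earlier
#'   sessions.
#' @param prev_block_label block type of the last block of the previous
#'   session, so the first block of this session differs from it.
#'
#' @return A tibble of trial records: `trial` (0-based, experiment-wide),
#'   `session`, `block_id`, `block_type`, `action`, `outcome`, `onset_s`
#'   (seconds from session start), `correct` (switching-criterion scoring)
#'   and `reached_criterion` (block-level flag on the block's final trial).
#' @export
run_session <- function(agent, cfg = task_config(), session = 1L,
                        trial_offset = 0L, block_id_offset = 0L,
                        prev_block_label = NULL) {
  n <- cfg$n_trials_per_session
  bt_label <- draw_next_block(prev_block_label)
  block <- block_row(bt_label)
  block_id <- block_id_offset + 1L
  n_block <- 0L
  n_correct <- 0L

  rec <- tibble::tibble(
    trial = integer(n), session = integer(n), block_id = integer(n),
    block_type = character(n), action = character(n), outcome = character(n),
    onset_s = numeric(n), correct = logical(n), reached_criterion = logical(n)
  )
  t_now <- 0.0
  for (i in seq_len(n)) {
    action <- agent$choose()
    outcome <- sample_outcome(block, action)
    if (!is.null(agent$observe)) agent$observe(action, outcome)

    n_block <- n_block + 1L
    ok <- criterion_correct(block, action, outcome, cfg$criterion_rule)
    if (ok) n_correct <- n_correct + 1L

    switch_now <- should_switch_block(n_block, n_correct, cfg)
    crit <- switch_now && n_block < cfg$max_block_trials

    rec$trial[i] <- trial_offset + i - 1L
    rec$session[i] <- session
    rec$block_id[i] <- block_id
    rec$block_type[i] <- bt_label
    rec$action[i] <- action
    rec$outcome[i] <- outcome
    rec$onset_s[i] <- t_now
    rec$correct[i] <- ok
    rec$reached_criterion[i] <- if (switch_now) crit else FALSE

    t_now <- t_now + cfg$feedback_duration_s +
      stats::runif(1, cfg$iti_range_s[1], cfg$iti_range_s[2])

    if (switch_now) {
      bt_label <- draw_next_block(bt_label)
      block <- block_row(bt_label)
      block_id <- block_id + 1L
      n_block <- 0L
      n_correct <- 0L
    }
  }
  rec
}

#' Run the full multi-session task for one agent
#'
#' @inheritParams run_session
#' @return A tibble of trial records for all sessions (see [run_session()]);
#'   onsets restart at 0 within each session.
#' @export
run_task <- function(agent, cfg = task_config()) {
  out <- vector("list", cfg$n_sessions)
  prev <- NULL
  blocks_done <- 0L
  for (s in seq_len(cfg$n_sessions)) {
    out[[s]] <- run_session(agent, cfg, session = s,
                            trial_offset = (s - 1L) * cfg$n_trials_per_session,
                            block_id_offset = blocks_done,
                            prev_block_label = prev)
    prev <- out[[s]]$block_type[nrow(out[[s]])]
    blocks_done <- max(out[[s]]$block_id)
  }
  do.call(rbind, out)
}

#' An agent that chooses uniformly at random
#' @return An agent list usable with [run_session()].
#' @export
random_agent <- function() {
  list(choose = function() sample(c("L", "R"), 1), observe = NULL)
}

#' Behavioral accuracy summary
#'
#' Percent correct responses over the event table. Under the
#' `"asymmetric"` convention (the default, used for all behavioral
#' summaries) a trial is correct iff the higher-reward-probability action
#' was chosen, and 50/50 trials — where no action is better — are excluded.
#' Under `"feedback"` every rewarded trial counts as correct.
#'
#' @param events a trial-record tibble from [run_task()] or [read_events()].
#' @param convention `"asymmetric"` or `"feedback"`.
#' @return Percent correct (0–100).
#' @export
percent_correct <- function(events, convention = c("asymmetric", "feedback")) {
  convention <- match.arg(convention)
  if (convention == "feedback")
    return(100 * mean(events$outcome == "reward"))
  asym <- events$block_type != "50/50"
  if (!any(asym)) stop("no asymmetric-block trials in events")
  best <- ifelse(events$block_type == "80/20", "L", "R")
  100 * mean((events$action == best)[asym])
}

#' Number of blocks ended by reaching the learning criterion
#'
#' @param events a trial-record tibble.
#' @return Count of blocks whose final trial carries `reached_criterion`.
#' @export
n_criterion_blocks <- function(events) {
  sum(events$reached_criterion)
}

#' Write / read a per-subject events table
#'
#' Tab-separated, one row per trial, columns `trial`, `session`, `block_id`,
#' `block_type`, `action` (`L`/`R`), `outcome` (`1` reward / `-1`
#' punishment), `onset_s`. The reader tolerates an optional `missed` column
#' and drops trials flagged as missed (the model likelihood is defined only
#' over made choices).
#'
#' @param events a trial-record tibble.
#' @param path file path.
#' @return `write_events` returns `path` invisibly; `read_events` returns a
#'   trial-record tibble.
#' @export
write_events <- function(events, path) {
  out <- data.frame(
    trial = events$trial, session = events$session,
    block_id = events$block_id, block_type = events$block_type,
    action = events$action,
    outcome = ifelse(events$outcome == "reward", 1L, -1L),
    onset_s = events$onset_s
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("missed" %in% names(d)) d <- d[!as.logical(d$missed), , drop = FALSE]
  tibble::tibble(
    trial = as.integer(d$trial), session = as.integer(d$session),
    block_id = as.integer(d$block_id), block_type = d$block_type,
    action = d$action,
    outcome = ifelse(d$outcome > 0, "reward", "punishment"),
    onset_s = as.numeric(d$onset_s)
  )
}
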