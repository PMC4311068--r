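test_that("softmax probabilities normalize, preserve order, and are shift-invariant", {
  expect_equal(softmax_prob(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax_prob(c(1, 0)), c(0.7310586, 0.2689414), tolerance = 1e-7)
  set.seed(5)
  for (i in 1:20) {
    q <- rnorm(2, sd = 5)
    p <- softmax_prob(q)
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(order(p), order(q))
    expect_equal(softmax_prob(q + rnorm(1)), p)
  }
  # stable at extreme values
  expect_equal(softmax_prob(c(1000, 0)), c(1, 0))
  expect_error(softmax_prob(c(NA, 0)))
  expect_error(softmax_prob(c(Inf, 0)))
})

test_that("value update and effective reinforcement follow the learning rule", {
  p <- agent_params(0.62, 2.73, 0.84)
  expect_equal(effective_reinforcement("reward", p), 2.73)
  expect_equal(effective_reinforcement("punishment", p), -0.84)
  expect_equal(effective_reinforcement("punishment", agent_params(0.5, 1, 0)), 0)
  expect_equal(effective_reinforcement(c(1, -1), p), c(2.73, -0.84))
  expect_error(effective_reinforcement("draw", p))

  expect_equal(update_value(0, 2.73, 1), 2.73)     # full-update limit
  expect_equal(update_value(5, 5, 0.5), 5)         # zero-PE fixed point
  expect_equal(update_value(0, -0.84, 0.62), -0.5208)
  expect_error(update_value(0, 1, 1.5))
  expect_error(agent_params(1.2, 1, 1))
  expect_error(agent_params(0.5, -1, 1))
})

test_that("parameter transforms round-trip to machine precision", {
  set.seed(8)
  for (i in 1:25) {
    p <- agent_params(runif(1), exp(rnorm(1)), exp(rnorm(1)))
    q <- from_theta(to_theta(p))
    expect_equal(unlist(q), unlist(p), tolerance = 1e-12)
  }
  th <- c(0.3, -1, 2)
  expect_equal(to_theta(from_theta(th)), th, tolerance = 1e-12)
})

test_that("sequence log-likelihood matches closed-form hand computation", {
  # 3 trials stepped by hand: eps = 0.5, beta_rew = beta_pun = 1
  # t1: Q=(0,0), choose L, reward   -> p = 0.5,           Q_L -> 0.5
  # t2: choose L, punishment        -> p = plogis(0.5),   Q_L -> -0.25
  # t3: choose R, reward            -> p = plogis(0.25)
  ev <- make_events(c("L", "L", "R"), c("reward", "punishment", "reward"))
  res <- sequence_loglik(ev, agent_params(0.5, 1, 1))
  expect_equal(res$loglik, log(0.5) + log(plogis(0.5)) + log(plogis(0.25)),
               tolerance = 1e-12)
  expect_equal(res$trace$q_left, c(0, 0.5, -0.25))
  expect_equal(res$trace$q_right, c(0, 0, 0))
  expect_equal(res$trace$pe, c(1, -1.5, 1))
  expect_equal(res$trace$r_eff, c(1, -1, 1))

  # zero sensitivities: values never move, every choice is a coin flip
  set.seed(9)
  ev2 <- simulate_agent(median_params(), task_config())
  res2 <- sequence_loglik(ev2, agent_params(0.7, 0, 0))
  expect_equal(res2$loglik, nrow(ev2) * log(0.5), tolerance = 1e-12)
  expect_true(all(res2$trace$pe == 0))

  # determinism
  expect_identical(sequence_loglik(ev2, median_params()),
                   sequence_loglik(ev2, median_params()))
  expect_error(sequence_loglik(ev2[0, ], median_params()))
})

test_that("PE/update consistency holds on every simulated trial", {
  set.seed(10)
  p <- median_params()
  ev <- simulate_agent(p, task_config())
  tr <- sequence_loglik(ev, p)$trace
  q <- cbind(tr$q_left, tr$q_right)
  idx <- ifelse(ev$action == "L", 1, 2)
  for (t in seq_len(nrow(ev) - 1)) {
    # only within a session when values carry over (they do by default)
    dq <- q[t + 1, idx[t]] - q[t, idx[t]]
    expect_equal(dq, p$epsilon * tr$pe[t], tolerance = 1e-10)
    # unchosen value untouched
    expect_equal(q[t + 1, 3 - idx[t]], q[t, 3 - idx[t]])
  }
  expect_equal(tr$pe, tr$r_eff - q[cbind(seq_len(nrow(ev)), idx)])
})

test_that("session boundary handling: carry-over versus reset", {
  ev <- make_events(c("L", "L"), c("reward", "reward"), session = c(1L, 2L))
  p <- agent_params(0.5, 2, 1)
  carried <- sequence_loglik(ev, p, carry_over = TRUE)
  reset <- sequence_loglik(ev, p, carry_over = FALSE)
  expect_equal(carried$trace$q_left[2], 1)  # 0 + 0.5 * (2 - 0)
  expect_equal(reset$trace$q_left[2], 0)    # values restart at 0
  expect_equal(reset$trace$pe, c(2, 2))
})

test_that("generative choices favor the generating parameters", {
  set.seed(12)
  # zero sensitivities give unbiased choices
  ev0 <- simulate_agent(agent_params(0.5, 0, 0), task_config())
  expect_lt(abs(mean(ev0$action == "L") - 0.5), 0.12)
  # strong reward sensitivity saturates choice of the 0.8 action within a
  # single non-reversing block (blocks switch only at the session end)
  cfg1 <- task_config(n_trials_total = 100, n_sessions = 1,
                      min_block_trials = 100, max_block_trials = 100)
  repeat {
    evs <- simulate_agent(agent_params(0.5, 20, 0.5), cfg1)
    if (evs$block_type[1] == "80/20") break
  }
  late <- evs[51:100, ]
  expect_gt(mean(late$action == "L"), 0.9)
  # likelihood of the generating parameters beats strong perturbations
  gen <- median_params()
  wins <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    ev <- simulate_agent(gen, task_config())
    ll_gen <- sequence_loglik(ev, gen)$loglik
    ll_bad <- sequence_loglik(ev, agent_params(0.05, 8, 4))$loglik
    if (ll_gen > ll_bad) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("PE traces round-trip through the TSV dialect", {
  set.seed(13)
  ev <- simulate_agent(median_params(), task_config())
  tr <- sequence_loglik(ev, median_params())$trace
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pe_trace(tr, path)
  expect_equal(as.data.frame(read_pe_trace(path)), as.data.frame(tr),
               tolerance = 1e-10)
})
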