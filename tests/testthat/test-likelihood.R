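test_that("a single symmetric trial scores log(0.5)", {
  cfg <- task_config("protection", n_trials = 2, n_practice = 0)
  d <- trial_table(1, state = 1, choice = "a", creature = "X", outcome = 5)
  p <- agent_params(0.5, 0.5, lam = 0.5, pi_stick = 0, beta = 3)
  ll <- subject_loglik(p, make_session(d, cfg))
  expect_equal(ll$total, log(0.5), tolerance = 1e-12)
})

test_that("compiled likelihood equals the naive oracle on a fixed 3-trial fixture", {
  cfg <- task_config("protection", n_trials = 3, n_practice = 0)
  d <- trial_table(3,
                   state = c(1L, 2L, 1L),
                   choice = c("a", "b", "a"),
                   creature = c("X", "X", "X"),
                   outcome = c(8L, 2L, 6L),
                   stakes = c(5L, 1L, 5L),
                   positions = c("ab", "ba", "ab"))
  p <- agent_params(0.7, 0.4, lam = 0.6, pi_stick = 0.2, beta = 4)
  ses <- make_session(d, cfg)
  got <- subject_loglik(p, ses)
  want <- oracle_loglik(p, ses)
  expect_equal(got$total, want$total, tolerance = 1e-10)
  expect_equal(got$per_trial, want$per_trial, tolerance = 1e-10)
  ## frozen value from the oracle, so a silent change in either path trips
  expect_equal(got$total, -0.930480879536486, tolerance = 1e-9)
})

test_that("compiled likelihood equals the oracle on fuzzed short sessions", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(2:5, 1)
    variant <- sample(c("protection", "reward", "punishment"), 1)
    ses <- random_session(n, variant, seed = i)
    p <- agent_params(omega = runif(1), alpha = runif(1), lam = runif(1),
                      pi_stick = runif(1), beta = runif(1, 0, 15))
    expect_equal(subject_loglik(p, ses)$total,
                 oracle_loglik(p, ses)$total, tolerance = 1e-10)
  }
})

test_that("condition-split parameters are resolved per trial like the oracle", {
  ses <- random_session(5, "protection", seed = 3)
  p <- agent_params(omega = c(protection = 0.8, reward = 0.1),
                    alpha = c(low = 0.3, high = 0.7),
                    lam = 0.5, pi_stick = 0.1, beta = 5)
  expect_equal(subject_loglik(p, ses)$total,
               oracle_loglik(p, ses)$total, tolerance = 1e-10)
})

test_that("the generating parameters outscore perturbed omega on rich data", {
  cfg <- task_config("protection", n_trials = 1000, n_practice = 0)
  truth <- agent_params(0.5, 0.5, lam = 0.5, pi_stick = 0.1, beta = 5)
  ses <- simulate_subject(truth, cfg, seed = 31)
  ll0 <- subject_loglik(truth, ses)$total
  for (d in c(-0.3, 0.3)) {
    p <- truth; p$omega <- 0.5 + d
    expect_gte(ll0, subject_loglik(p, ses)$total)
  }
})

test_that("likelihood ignores left/right position labels when pi = 0", {
  ses <- random_session(5, seed = 8)
  p <- agent_params(0.6, 0.5, lam = 0.3, pi_stick = 0, beta = 6)
  ll1 <- subject_loglik(p, ses)$total
  d2 <- ses$data
  d2$dwelling_positions <- ifelse(d2$dwelling_positions == "ab", "ba", "ab")
  d2$response_key <- ifelse(d2$response_key == "left", "right", "left")
  ll2 <- subject_loglik(p, make_session(d2, ses$config))$total
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("missed trials contribute zero and freeze the agent state", {
  ses <- random_session(5, seed = 12)
  d <- ses$data
  d$choice[3] <- NA; d$response_key[3] <- NA
  d$creature[3] <- NA; d$outcome_units[3] <- NA
  with_miss <- subject_loglik(agent_params(0.5, 0.5, beta = 5),
                              make_session(d, ses$config))
  dropped <- subject_loglik(agent_params(0.5, 0.5, beta = 5),
                            make_session(d[-3, ], ses$config))
  expect_equal(with_miss$per_trial[3], 0)
  expect_equal(with_miss$total, dropped$total, tolerance = 1e-12)
})

test_that("omega profile recovers a pure planner and is flat at beta = 0", {
  cfg <- task_config("protection", n_trials = 600, n_practice = 0)
  ses <- simulate_subject(agent_params(1, 0.7, lam = 0.5, pi_stick = 0,
                                       beta = 8), cfg, seed = 44)
  grid <- seq(0, 1, 0.1)
  prof <- negloglik_surface(ses, agent_params(0.5, 0.7, lam = 0.5,
                                              pi_stick = 0, beta = 8), grid)
  expect_equal(grid[which.min(prof)], 1)
  ## beta = 0 scores every choice at exactly 0.5: identically flat profile
  ses0 <- simulate_subject(agent_params(0.5, 0.5, beta = 0), cfg, seed = 45)
  prof0 <- negloglik_surface(ses0, agent_params(0.5, 0.5, beta = 0), grid)
  expect_lt(max(prof0) - min(prof0), 1e-9)
  expect_length(negloglik_surface(ses, agent_params(0.5, 0.5, beta = 5), 0.3), 1L)
})

test_that("per-trial log probabilities are never positive", {
  ses <- random_session(5, seed = 20)
  ll <- subject_loglik(agent_params(0.9, 0.8, beta = 12), ses)
  expect_true(all(ll$per_trial <= 0))
})
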