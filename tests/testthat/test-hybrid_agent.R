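test_that("model-based values plan through the transition map", {
  tm <- default_transition_map()
  q2 <- c(X = 3, Y = 8)
  expect_equal(mb_values(1, q2, tm), c(3, 8))
  expect_equal(mb_values(2, q2, tm), c(8, 3))  # crossed map, same creatures
  ## updating one creature's value shifts planning in BOTH states
  st <- init_agent_state(q0 = 0)
  st <- update_state(st, state = 1, choice = 1, creature = 1,
                     reward_internal = 9, response_key = 1,
                     alpha = 1, lam = 0)
  expect_equal(mb_values(1, st$q_stage2, tm)[1], 9)
  expect_equal(mb_values(2, st$q_stage2, tm)[2], 9)
})

test_that("hybrid weighting interpolates between the two controllers", {
  expect_equal(hybrid_values(c(1, 2), c(5, 6), 1), c(5, 6))
  expect_equal(hybrid_values(c(1, 2), c(5, 6), 0), c(1, 2))
  expect_equal(hybrid_values(c(0, 4), c(2, 0), 0.5), c(1, 2))
  expect_error(hybrid_values(c(0, 0), c(1, 1), 1.2), "\\[0, 1\\]")
})

test_that("sticky softmax matches closed forms and normalizes", {
  expect_equal(choice_probability(c(7, 2), 0L, 1L, 0, 0), c(0.5, 0.5))
  p <- choice_probability(c(2, 1), 0L, 1L, 1, 0)
  expect_equal(p[1], 1 / (1 + exp(-1)), tolerance = 1e-10)
  ## equal values, previous response matches dwelling a's key
  p2 <- choice_probability(c(3, 3), 1L, 1L, 1, 0.5)
  expect_equal(p2[1], 1 / (1 + exp(-0.5)), tolerance = 1e-10)
  set.seed(4)
  for (i in 1:25) {
    ## strict interior holds while beta * gap stays representable
    p <- choice_probability(runif(2, 0, 9), sample(0:2, 1),
                            sample(1:2, 1), runif(1, 0, 3), runif(1))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0 & p < 1))
  }
  ## extreme sharpness saturates gracefully, never NaN
  psat <- choice_probability(c(9, 0), 0L, 1L, 20, 0)
  expect_equal(sum(psat), 1)
  expect_false(any(is.nan(psat)))
})

test_that("value updates follow the two prediction errors", {
  st0 <- init_agent_state(q0 = 0)
  ## alpha = 0: frozen
  st <- update_state(st0, 1, 1, 1, 5, 1, alpha = 0, lam = 1)
  expect_equal(st$q_mf, st0$q_mf)
  expect_equal(st$q_stage2, st0$q_stage2)
  ## alpha = 1, lambda = 1: full transfer to the first stage
  st <- update_state(st0, 1, 1, 1, 5, 1, alpha = 1, lam = 1)
  expect_equal(unname(st$q_stage2["X"]), 5)
  expect_equal(st$q_mf[1, 1], 5)
  ## alpha = 1, lambda = 0: delta1 = 0 at choice time, no trace transfer
  st <- update_state(st0, 1, 1, 1, 5, 1, alpha = 1, lam = 0)
  expect_equal(unname(st$q_stage2["X"]), 5)
  expect_equal(st$q_mf[1, 1], 0)
  expect_equal(st$prev_response, 1L)
})

test_that("all cached values remain inside the reward range under fuzzing", {
  set.seed(11)
  for (rep in 1:10) {
    st <- init_agent_state(q0 = runif(1, 0, 9))
    al <- runif(1); lm <- runif(1)
    for (t in 1:300) {
      s <- sample(1:2, 1); ch <- sample(1:2, 1)
      cr <- default_transition_map()[s, ch]
      st <- update_state(st, s, ch, cr, sample(0:9, 1), sample(1:2, 1),
                         al, lm)
    }
    expect_true(all(st$q_mf >= 0 & st$q_mf <= 9))
    expect_true(all(st$q_stage2 >= 0 & st$q_stage2 <= 9))
  }
})

test_that("internal reward aligns valence so more is always better", {
  expect_equal(internal_reward("reward", 7), 7)
  expect_equal(internal_reward("punishment", 0), 9)
  expect_equal(internal_reward("punishment", 9), 0)
  expect_equal(internal_reward("protection", 3), 3)
  expect_error(internal_reward("reward", 12), "outcome_units")
})

test_that("simulation is deterministic given the seed and respects the map", {
  cfg <- task_config(n_trials = 60, n_practice = 10)
  p <- agent_params(0.6, 0.5, lam = 0.4, pi_stick = 0.1, beta = 4)
  a <- simulate_subject(p, cfg, seed = 21)
  b <- simulate_subject(p, cfg, seed = 21)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data$choice,
                         simulate_subject(p, cfg, seed = 22)$data$choice))
  d <- a$data[!is.na(a$data$choice), ]
  tm <- cfg$transition_map
  expect_equal(match(d$creature, c("X", "Y")),
               unname(tm[cbind(d$state, match(d$choice, c("a", "b")))]))
  expect_true(all(abs(d$final_result) <= 45))
})

test_that("an indifferent agent visits both creatures equally often", {
  p <- agent_params(0.5, 0.5, beta = 0)
  ss <- simulate_subject(p, task_config(n_trials = 2000, n_practice = 0),
                         seed = 9)
  expect_lt(abs(mean(ss$data$creature == "X") - 0.5), 0.05)
})

test_that("a pure planner tracks the better creature when walks drift slowly", {
  cfg <- task_config(n_trials = 220, n_practice = 20, walk_sigma = 0.5)
  hit <- sapply(1:6, function(s) {
    ss <- simulate_subject(agent_params(1, 0.9, lam = 1, pi_stick = 0,
                                        beta = 20), cfg, seed = s)
    d <- ss$data[!ss$data$practice, ]
    mean(d$creature == ifelse(d$walk_X >= d$walk_Y, "X", "Y"))
  })
  expect_gt(mean(hit), 0.8)
})

test_that("missed trials are recorded as gaps when a miss rate is configured", {
  cfg <- task_config(n_trials = 400, n_practice = 0, miss_prob = 0.3)
  ss <- simulate_subject(agent_params(0.5, 0.5), cfg, seed = 2)
  mf <- mean(is.na(ss$data$choice))
  expect_gt(mf, 0.2); expect_lt(mf, 0.4)
  expect_true(all(is.na(ss$data$outcome_units[is.na(ss$data$choice)])))
})
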