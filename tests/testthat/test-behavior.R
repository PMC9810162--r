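test_that("stay coding follows creatures across states with hand-checked values", {
  cfg <- task_config("protection", n_trials = 4, n_practice = 0)
  d <- trial_table(4,
                   state = c(1L, 2L, 2L, 1L),
                   choice = c("a", "b", "a", "b"),
                   creature = c("X", "X", "Y", "Y"),
                   outcome = c(8L, 3L, 6L, 1L),
                   stakes = c(1L, 5L, 1L, 1L))
  rec <- code_stay(make_session(d, cfg), subject_id = 7L)
  ## trial 2: same creature X via the other state -> stay = 1, diff state
  ## trial 3: X -> Y switch, same state; trial 4: Y -> Y stay, diff state
  expect_equal(rec$stay, c(1L, 0L, 1L))
  expect_equal(rec$same_state, c(-0.5, 0.5, -0.5))
  expect_equal(rec$prev_outcome, c(8, 3, 6) - 4.5)
  expect_equal(rec$stakes, c(0.5, -0.5, -0.5))
  expect_equal(rec$subject_id, rep(7L, 3))
})

test_that("punishment outcomes are valence-aligned before centering", {
  cfg <- task_config("punishment", n_trials = 2, n_practice = 0)
  d <- trial_table(2, state = c(1L, 1L), choice = c("a", "a"),
                   creature = c("X", "X"), outcome = c(9L, 0L))
  rec <- code_stay(make_session(d, cfg))
  expect_equal(rec$prev_outcome, (9 - 9) - 4.5)  # 9 flames = worst
})

test_that("stay chains break after missed trials and at session start", {
  cfg <- task_config("protection", n_trials = 5, n_practice = 0)
  d <- trial_table(5, state = rep(1L, 5), choice = c("a", "a", NA, "a", "a"),
                   creature = c("X", "X", NA, "X", "X"),
                   outcome = c(5L, 5L, NA, 5L, 5L))
  rec <- code_stay(make_session(d, cfg))
  ## trials 2 and 5 are codable; 3 missed, 4 follows the miss, 1 has no prev
  expect_equal(rec$trial_index, c(1L, 4L))
})

test_that("stay coding ignores dwelling positions entirely", {
  ses <- random_session(30, seed = 14)
  rec1 <- code_stay(ses)
  d2 <- ses$data
  d2$dwelling_positions <- ifelse(d2$dwelling_positions == "ab", "ba", "ab")
  rec2 <- code_stay(make_session(d2, ses$config))
  expect_equal(rec1$stay, rec2$stay)
})

test_that("the mixed stay model recovers the expected coefficient structure", {
  cfg <- task_config("protection", n_trials = 120, n_practice = 20)
  rec <- simulate_stay_cohort(0.5, 12, cfg, seed0 = 500)
  fit <- fit_stay_model(rec)
  co <- fit$coefficients
  expect_setequal(co$term, c("(Intercept)", "prev_outcome", "same_state",
                             "prev_outcome:same_state"))
  expect_true(all(is.finite(co$estimate)))
  expect_gte(fit$tau00, 0)
  expect_true(fit$r2_conditional >= 0 && fit$r2_conditional <= 1)
  expect_gt(co$estimate[co$term == "prev_outcome"], 0)
  expect_error(fit_stay_model(rec[rec$subject_id == 1, ]), "2 subjects")
})

test_that("the model-free interaction weakens as omega rises", {
  cfg <- task_config("protection", n_trials = 100, n_practice = 10)
  get_int <- function(om, seed0) {
    rec <- simulate_stay_cohort(om, 24, cfg, seed0 = seed0)
    co <- fit_stay_model(rec)$coefficients
    co$estimate[co$term == "prev_outcome:same_state"]
  }
  ints <- c(get_int(0, 3000), get_int(0.5, 4000), get_int(1, 5000))
  expect_true(all(diff(ints) < 0))
})

test_that("shuffled outcomes wipe out every stay slope", {
  cfg <- task_config("protection", n_trials = 120, n_practice = 20)
  rec <- simulate_stay_cohort(0.7, 12, cfg, seed0 = 900)
  set.seed(1)
  rec$prev_outcome <- sample(rec$prev_outcome)
  co <- fit_stay_model(rec)$coefficients
  slopes <- co[co$term != "(Intercept)", ]
  expect_true(all(abs(slopes$z) < 3))
})

test_that("corrected reward rate is exactly 1 for flat equal payoffs", {
  cfg <- task_config("protection", n_trials = 10, n_practice = 0)
  d <- trial_table(10, state = rep(1L, 10), choice = rep("a", 10),
                   creature = rep("X", 10), outcome = rep(4L, 10))
  d$walk_X <- 4; d$walk_Y <- 4
  expect_equal(corrected_reward_rate(make_session(d, cfg)), 1)
})

test_that("an oracle chooser beats the average payoff on offer", {
  cfg <- task_config("protection", n_trials = 300, n_practice = 0)
  w <- init_payoff_walks(cfg, 8)$values
  best <- ifelse(w[, 1] >= w[, 2], "X", "Y")
  d <- trial_table(300, state = rep(1L, 300),
                   choice = ifelse(best == "X", "a", "b"),
                   creature = best,
                   outcome = as.integer(pmin(9, pmax(0,
                     round(ifelse(best == "X", w[, 1], w[, 2]))))))
  d$walk_X <- w[, 1]; d$walk_Y <- w[, 2]
  expect_gt(corrected_reward_rate(make_session(d, cfg)), 1)
})

test_that("an indifferent chooser earns about the average on offer", {
  cfg <- task_config("protection", n_trials = 2500, n_practice = 0)
  ses <- simulate_subject(agent_params(0.5, 0.5, beta = 0), cfg, seed = 19)
  expect_lt(abs(corrected_reward_rate(ses) - 1), 0.06)
})

test_that("exclusion thresholds follow the strict 20% rule", {
  mk <- function(n_missed) {
    ch <- rep("a", 100); ch[seq_len(n_missed)] <- NA
    d <- trial_table(100, state = rep(1L, 100), choice = ch,
                     creature = ifelse(is.na(ch), NA, "X"),
                     outcome = ifelse(is.na(ch), NA, 5L))
    make_session(d, task_config(n_trials = 100, n_practice = 0))
  }
  expect_true(apply_exclusions(mk(0))$keep)
  expect_true(apply_exclusions(mk(20))$keep)      # exactly 20%: kept
  drop <- apply_exclusions(mk(21))
  expect_false(drop$keep)
  expect_equal(drop$reason, "missed_over_20pct")
  expect_false(apply_exclusions(mk(0), comprehension_score = 0.4)$keep)
  expect_true(apply_exclusions(mk(0), comprehension_score = 0.5)$keep)
})
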