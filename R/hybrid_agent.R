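## Hybrid model-based / model-free learner for the deterministic-transition
## two-step task.  Model-free values are SARSA(lambda)-style caches over the
## four first-stage dwelling stimuli (2 states x 2 slots); model-based values
## plan through the transition map to the two creatures' learned payoffs.

#' Agent parameters for the hybrid learner
#'
#' `omega` and `alpha` may be scalars or named vectors keyed by condition
#' label (task variant and/or stakes level, e.g. `c(protection = .7,
#' reward = .2)` or `c(low = .5, high = .6)` or crossed labels like
#' `"protection.high"`); `lam`, `pi_stick` and `beta` are always shared.
#'
#' @param omega Model-based weight(s) in `[0, 1]`.
#' @param alpha Learning rate(s) in `[0, 1]`.
#' @param lam Eligibility trace in `[0, 1]`.
#' @param pi_stick Perseveration bonus on the previous response key, in
#'   `[0, 1]` (the bounded parameterization used for fitting).
#' @param beta Softmax inverse temperature in `[0, 20]`.
#' @return An `agent_params` object.
#' @export
agent_params <- function(omega, alpha, lam = 0.5, pi_stick = 0, beta = 5) {
  chk01 <- function(x, nm) {
    if (any(x < 0 | x > 1))
      stop(sprintf("%s must lie in [0, 1]", nm), call. = FALSE)
  }
  chk01(omega, "omega"); chk01(alpha, "alpha"); chk01(lam, "lam")
  chk01(pi_stick, "pi_stick")
  if (beta < 0 || beta > 20) stop("beta must lie in [0, 20]", call. = FALSE)
  structure(list(omega = omega, alpha = alpha, lam = lam,
                 pi_stick = pi_stick, beta = beta),
            class = "agent_params")
}

## Resolve a possibly condition-split parameter for one trial.
resolve_param <- function(p, variant, stakes_level) {
  if (length(p) == 1L && is.null(names(p))) return(unname(p))
  keys <- c(paste(variant, stakes_level, sep = "."), variant, stakes_level)
  for (k in keys) if (k %in% names(p)) return(unname(p[[k]]))
  stop(sprintf("no parameter entry for condition '%s'/'%s'", variant, stakes_level),
       call. = FALSE)
}

#' Fresh agent state
#'
#' All action values start at the payoff-range midpoint (4.5), an unbiased
#' prior between the low- and high-initialized creatures.
#'
#' @param q0 Initial value for every cached value.
#' @return List with `q_mf` (2 states x 2 dwelling slots), `q_stage2`
#'   (2 creatures) and `prev_response` (0 = none yet).
#' @export
init_agent_state <- function(q0 = 4.5) {
  list(q_mf = matrix(q0, 2, 2, dimnames = list(state = c("1", "2"),
                                               choice = c("a", "b"))),
       q_stage2 = c(X = q0, Y = q0),
       prev_response = 0L)
}

#' Model-based values of the two dwellings in a first-stage state
#'
#' Plans through the deterministic transition map: the value of a dwelling
#' is the learned payoff of the creature it leads to, so second-stage
#' learning generalizes across both first-stage states.
#'
#' @param state First-stage state (1 or 2).
#' @param q_stage2 Length-2 creature value vector.
#' @param transition_map 2x2 map, see [default_transition_map()].
#' @return Length-2 value vector over dwellings (a, b).
#' @export
mb_values <- function(state, q_stage2, transition_map = default_transition_map()) {
  unname(q_stage2[transition_map[state, ]])
}

#' Weighted combination of model-based and model-free values
#'
#' @param q_mf_pair,q_mb_pair Length-2 value vectors over dwellings.
#' @param omega Model-based weight in `[0, 1]`.
#' @return `omega * q_mb + (1 - omega) * q_mf`, elementwise.
#' @export
hybrid_values <- function(q_mf_pair, q_mb_pair, omega) {
  if (omega < 0 || omega > 1) stop("omega must lie in [0, 1]", call. = FALSE)
  omega * q_mb_pair + (1 - omega) * q_mf_pair
}

#' Sticky softmax choice probabilities
#'
#' Softmax over `beta * (value + pi_stick * rep)`, where `rep` marks the
#' dwelling whose response key (left/right) repeats the previous trial's
#' response.  On the first trial `rep` is zero for both options.
#'
#' @param values Length-2 hybrid value vector over dwellings (a, b).
#' @param prev_response Previous response key: 1 = left, 2 = right,
#'   0 = none.
#' @param key_a Response key of dwelling a on this trial (1 = left,
#'   2 = right); dwelling b holds the other key.
#' @param beta Inverse temperature (>= 0).
#' @param pi_stick Perseveration bonus.
#' @return Length-2 probability vector over dwellings (a, b), summing to 1.
#' @export
choice_probability <- function(values, prev_response, key_a, beta, pi_stick) {
  if (beta < 0) stop("beta must be non-negative", call. = FALSE)
  keys <- c(key_a, 3L - key_a)
  rep_bonus <- as.numeric(prev_response != 0L & keys == prev_response)
  z <- beta * (values + pi_stick * rep_bonus)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Temporal-difference update after one trial
#'
#' Two prediction errors drive learning: at the first stage the chosen
#' dwelling's cached value moves toward the creature's current value
#' (`delta1`), and at the second stage the creature value moves toward the
#' delivered reward (`delta2`), with `lambda` controlling how much of
#' `delta2` also transfers back to the first-stage cache.
#'
#' @param agent_state State from [init_agent_state()].
#' @param state,choice First-stage state and chosen dwelling (1/2).
#' @param creature Visited creature (1 = X, 2 = Y).
#' @param reward_internal Internal reward in `[0, 9]` ("more is better").
#' @param response_key Response key pressed (1 = left, 2 = right).
#' @param alpha,lam Learning rate and eligibility trace.
#' @return Updated agent state.
#' @export
update_state <- function(agent_state, state, choice, creature, reward_internal,
                         response_key, alpha, lam) {
  s <- agent_state
  delta1 <- s$q_stage2[creature] - s$q_mf[state, choice]
  s$q_mf[state, choice] <- s$q_mf[state, choice] + alpha * delta1
  delta2 <- reward_internal - s$q_stage2[creature]
  s$q_stage2[creature] <- s$q_stage2[creature] + alpha * delta2
  s$q_mf[state, choice] <- s$q_mf[state, choice] + alpha * lam * delta2
  s$prev_response <- as.integer(response_key)
  s
}

#' Map delivered outcome units to the agent's internal reward scale
#'
#' Aligns valence so that larger is always better internally: in the
#' punishment framing 0 flames is the best outcome, so the internal reward
#' is `base - outcome`.  Learning operates on the 0--9 unit scale, not the
#' stakes-amplified final result.
#'
#' @param variant Task variant.
#' @param outcome_units Delivered units in `[0, 9]`.
#' @param base Outcome-scale maximum (9).
#' @return Internal reward in `[0, 9]`.
#' @export
internal_reward <- function(variant, outcome_units, base = 9) {
  if (any(outcome_units < 0 | outcome_units > base))
    stop("outcome_units must lie in [0, base]", call. = FALSE)
  if (variant == "punishment") base - outcome_units else outcome_units
}

#' Simulate one subject's session on one task variant
#'
#' Iterates stakes draw, sticky-softmax choice, deterministic transition,
#' payoff-walk outcome and value update; fills certainty and
#' outcome-estimate probes on their scheduled trials (see
#' [generate_ratings()] for the rating model).
#'
#' @param params An [agent_params()] object.
#' @param config A [task_config()].
#' @param seed Integer seed; simulation is deterministic given the seed.
#' @param rating_params Optional rating-model parameters passed to
#'   [generate_ratings()]; when `NULL`, probe trials are scheduled but
#'   ratings left missing.
#' @param q0 Initial action value.
#' @return List of class `subject_session`: `data` (one row per trial in
#'   the CSV dialect), `walks` (the payoff walks), `config`, `params`.
#' @export
simulate_subject <- function(params, config, seed, rating_params = NULL,
                             q0 = 4.5) {
  validate_task_config(config)
  stopifnot(inherits(params, "agent_params"))
  walks <- init_payoff_walks(config, sub_seed(seed, "walks"))
  n <- config$n_trials
  tm <- config$transition_map
  with_seed(sub_seed(seed, "choices"), {
    stakes <- draw_stakes(config, n)
    states <- sample(1:2, n, replace = TRUE)
    key_a <- sample(1:2, n, replace = TRUE)   # side of dwelling a, counterbalanced
    missed <- runif(n) < config$miss_prob
    practice <- seq_len(n) <= config$n_practice
    probe <- rep("none", n)
    probe[!practice] <- make_probe_schedule(sum(!practice))

    st <- init_agent_state(q0)
    choice <- creature <- outcome <- resp <- rep(NA_integer_, n)
    fin <- rep(NA_integer_, n)

    for (t in seq_len(n)) {
      if (missed[t]) next
      om <- resolve_param(params$omega, config$variant,
                          stakes_level(stakes[t], config))
      al <- resolve_param(params$alpha, config$variant,
                          stakes_level(stakes[t], config))
      qmb <- mb_values(states[t], st$q_stage2, tm)
      qmf <- st$q_mf[states[t], ]
      v <- hybrid_values(qmf, qmb, om)
      p <- choice_probability(v, st$prev_response, key_a[t], params$beta,
                              params$pi_stick)
      ch <- if (runif(1) < p[1]) 1L else 2L
      cr <- tm[states[t], ch]
      out <- as.integer(round(walks$values[t, cr]))
      out <- max(0L, min(config$base_threat, out))
      choice[t] <- ch
      creature[t] <- cr
      resp[t] <- if (ch == 1L) key_a[t] else 3L - key_a[t]
      outcome[t] <- out
      fin[t] <- final_result(config$variant, stakes[t], out,
                             config$base_threat)$value
      st <- update_state(st, states[t], ch, cr,
                         internal_reward(config$variant, out), resp[t],
                         al, params$lam)
    }

    data <- data.frame(
      trial_index = seq_len(n) - 1L,
      practice = practice,
      stakes = stakes,
      state = states,
      dwelling_positions = ifelse(key_a == 1L, "ab", "ba"),
      choice = c("a", "b")[choice],
      response_key = c("left", "right")[resp],
      creature = c("X", "Y")[creature],
      outcome_units = outcome,
      final_result = fin,
      probe = probe,
      certainty = NA_integer_,
      outcome_estimate = NA_integer_,
      walk_X = walks$values[, 1],
      walk_Y = walks$values[, 2],
      stringsAsFactors = FALSE)
    session <- structure(list(data = data, walks = walks, config = config,
                              params = params),
                         class = "subject_session")
    if (!is.null(rating_params))
      session <- generate_ratings(session, rating_params,
                                  sub_seed(seed, "ratings"))
    session
  })
}

stakes_level <- function(stakes, config) {
  if (stakes == config$stakes_values[2]) "high" else "low"
}

clip09 <- function(x) as.integer(pmin(9, pmax(0, x)))
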