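## Independent, naively coded re-implementation of the hybrid-learner
## likelihood, used as the oracle against the compiled path.  Deliberately
## self-contained: it does not reuse the package's update/choice functions.

oracle_loglik <- function(params, sessions, q0 = 4.5) {
  if (inherits(sessions, "subject_session")) sessions <- list(sessions)
  get_par <- function(p, variant, lev) {
    if (length(p) == 1L && is.null(names(p))) return(unname(p))
    for (k in c(paste(variant, lev, sep = "."), variant, lev))
      if (k %in% names(p)) return(unname(p[[k]]))
    stop("no condition entry")
  }
  per <- numeric(0)
  for (ss in sessions) {
    cfg <- ss$config
    tm <- cfg$transition_map
    qmf <- matrix(q0, 2, 2)
    q2 <- c(q0, q0)
    prev <- 0L
    d <- ss$data[!ss$data$practice, , drop = FALSE]
    d <- d[order(d$trial_index), , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      if (is.na(d$choice[i])) { per <- c(per, 0); next }
      st <- d$state[i]
      ch <- if (d$choice[i] == "a") 1L else 2L
      cr <- if (d$creature[i] == "X") 1L else 2L
      keya <- if (d$dwelling_positions[i] == "ab") 1L else 2L
      lev <- if (d$stakes[i] == max(cfg$stakes_values)) "high" else "low"
      om <- get_par(params$omega, cfg$variant, lev)
      al <- get_par(params$alpha, cfg$variant, lev)
      v <- om * q2[tm[st, ]] + (1 - om) * qmf[st, ]
      keys <- c(keya, 3L - keya)
      bonus <- if (prev == 0L) c(0, 0) else as.numeric(keys == prev)
      z <- params$beta * (v + params$pi_stick * bonus)
      pr <- exp(z) / sum(exp(z))
      per <- c(per, log(pr[ch]))
      r <- if (cfg$variant == "punishment") 9 - d$outcome_units[i]
           else d$outcome_units[i]
      qmf[st, ch] <- qmf[st, ch] + al * (q2[cr] - qmf[st, ch])
      delta2 <- r - q2[cr]
      q2[cr] <- q2[cr] + al * delta2
      qmf[st, ch] <- qmf[st, ch] + al * params$lam * delta2
      prev <- if (ch == 1L) keya else 3L - keya
    }
  }
  list(total = sum(per), per_trial = per)
}

## Hand-buildable session from a raw trial table.
make_session <- function(data, config) {
  structure(list(data = data, walks = NULL, config = config, params = NULL),
            class = "subject_session")
}

## Minimal trial table with sensible defaults, overridable per column.
trial_table <- function(n, state, choice, creature, outcome,
                        stakes = rep(1L, n), positions = rep("ab", n),
                        practice = rep(FALSE, n)) {
  resp <- ifelse(is.na(choice), NA,
                 ifelse((choice == "a") == (positions == "ab"),
                        "left", "right"))
  data.frame(trial_index = seq_len(n) - 1L, practice = practice,
             stakes = stakes, state = state,
             dwelling_positions = positions, choice = choice,
             response_key = resp, creature = creature,
             outcome_units = outcome,
             final_result = NA_integer_, probe = "none",
             certainty = NA_integer_, outcome_estimate = NA_integer_,
             walk_X = 4.5, walk_Y = 4.5, stringsAsFactors = FALSE)
}

## Random short session consistent with the transition map, for fuzzing.
random_session <- function(n, variant = "protection", seed = 1) {
  cfg <- task_config(variant, n_trials = max(n, 2L), n_practice = 0L)
  withr_seed <- function(code) code
  set.seed(seed)
  state <- sample(1:2, n, TRUE)
  choice <- sample(c("a", "b"), n, TRUE)
  tm <- cfg$transition_map
  creature <- c("X", "Y")[mapply(function(s, ch) tm[s, ch], state,
                                 match(choice, c("a", "b")))]
  make_session(trial_table(n, state, choice, creature,
                           outcome = sample(0:9, n, TRUE),
                           stakes = sample(c(1L, 5L), n, TRUE),
                           positions = sample(c("ab", "ba"), n, TRUE)),
               cfg)
}

## Stay records for a simulated cohort at a fixed omega (shared helper for
## behavior tests and the acceptance stay-signature criterion).
simulate_stay_cohort <- function(omega, n_subjects, cfg, seed0,
                                 alpha = 0.6, lam = 0.6, beta = 5) {
  do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    ss <- simulate_subject(agent_params(omega, alpha, lam = lam,
                                        pi_stick = 0, beta = beta),
                           cfg, seed = seed0 + s)
    code_stay(ss, subject_id = s)
  }))
}
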