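## Trial-wise choice likelihood: R-facing wrappers around the compiled core.

## Convert a session data.frame (CSV dialect) into the flat integer arrays
## the compiled likelihood consumes.  Practice trials are dropped; missed
## trials are kept with 0 codes (they freeze the agent state).
session_arrays <- function(data, variant, config_stakes = c(1L, 5L)) {
  d <- data[!data$practice, , drop = FALSE]
  d <- d[order(d$trial_index), , drop = FALSE]
  missed <- is.na(d$choice)
  choice <- match(d$choice, c("a", "b"))
  creature <- match(d$creature, c("X", "Y"))
  resp <- match(d$response_key, c("left", "right"))
  key_a <- ifelse(d$dwelling_positions == "ab", 1L, 2L)
  reward <- ifelse(missed, 0,
                   internal_reward(variant, ifelse(missed, 0L, d$outcome_units)))
  list(n = nrow(d),
       state = as.integer(d$state),
       choice = ifelse(missed, 0L, choice),
       resp = ifelse(missed, 0L, resp),
       creature = ifelse(missed, 0L, creature),
       reward = as.numeric(reward),
       key_a = as.integer(key_a),
       stakes_high = as.integer(d$stakes == max(config_stakes)),
       trial_index = d$trial_index,
       variant = variant)
}

#' Choice log-likelihood of one subject's session(s)
#'
#' Scores the observed first-stage choices under the hybrid learner with
#' the observed outcomes driving the value updates.  Practice trials are
#' excluded; missed trials contribute zero and freeze the agent state.
#'
#' @param params An [agent_params()] object (condition-split `omega`/
#'   `alpha` resolved per trial by variant and stakes level).
#' @param sessions A single `subject_session` (or its `data` plus
#'   `variant`), or a list of sessions fit jointly with the agent state
#'   reset at each session start.
#' @param q0 Initial action value.
#' @param transition_map Transition map shared by the sessions.
#' @return List with `total` (sum) and `per_trial` (vector of per-trial log
#'   probabilities over analyzable, non-missed trials in order; missed
#'   trials appear as 0).
#' @export
subject_loglik <- function(params, sessions, q0 = 4.5,
                           transition_map = default_transition_map()) {
  if (inherits(sessions, "subject_session")) sessions <- list(sessions)
  arrs <- lapply(sessions, function(s)
    session_arrays(s$data, s$config$variant, s$config$stakes_values))
  flat <- flatten_sessions(list(arrs), params_template = params)
  mats <- params_matrices(list(params), flat)
  ll <- cpp_hybrid_loglik(flat$subj, flat$reset, flat$state, flat$choice,
                          flat$resp, flat$creature, flat$reward, flat$key_a,
                          flat$oidx, flat$aidx,
                          as.integer(t(transition_map)),
                          mats$omega, mats$alpha, mats$lam, mats$pik,
                          mats$beta, q0, TRUE)
  list(total = sum(ll), per_trial = ll)
}

## Flatten a cohort: `cohort_arrays` is a list (one element per subject) of
## lists of session arrays.  Builds the condition-index columns from the
## label sets found in `params_template` (fitting passes a model_spec
## instead via spec_indices).
flatten_sessions <- function(cohort_arrays, params_template = NULL,
                             spec = NULL) {
  subj <- reset <- state <- choice <- resp <- creature <- key_a <-
    oidx <- aidx <- integer(0)
  reward <- numeric(0)
  variants <- character(0)
  for (s in seq_along(cohort_arrays)) {
    for (a in cohort_arrays[[s]]) {
      n <- a$n
      subj <- c(subj, rep(s, n))
      reset <- c(reset, c(1L, rep(0L, n - 1L)))
      state <- c(state, a$state); choice <- c(choice, a$choice)
      resp <- c(resp, a$resp); creature <- c(creature, a$creature)
      reward <- c(reward, a$reward); key_a <- c(key_a, a$key_a)
      idx <- condition_indices(a, params_template, spec)
      oidx <- c(oidx, idx$o); aidx <- c(aidx, idx$a)
      variants <- c(variants, rep(a$variant, n))
    }
  }
  list(subj = subj, reset = reset, state = state, choice = choice,
       resp = resp, creature = creature, reward = reward, key_a = key_a,
       oidx = oidx, aidx = aidx, variant = variants,
       n_omega = max(oidx), n_alpha = max(aidx))
}

## Per-trial column index into the omega/alpha matrices.
condition_indices <- function(a, params_template, spec) {
  n <- a$n
  if (!is.null(spec)) {
    o <- spec_index(spec, "omega", a$variant, a$stakes_high)
    al <- spec_index(spec, "alpha", a$variant, a$stakes_high)
    return(list(o = o, a = al))
  }
  lev <- ifelse(a$stakes_high == 1L, "high", "low")
  idx_for <- function(p) {
    if (length(p) == 1L && is.null(names(p))) return(rep(1L, n))
    keys <- cbind(paste(a$variant, lev, sep = "."), rep(a$variant, n), lev)
    sapply(seq_len(n), function(i) {
      for (k in keys[i, ]) {
        j <- match(k, names(p))
        if (!is.na(j)) return(j)
      }
      stop(sprintf("no parameter entry for condition '%s'/'%s'",
                   a$variant, lev[i]), call. = FALSE)
    })
  }
  list(o = idx_for(params_template$omega), a = idx_for(params_template$alpha))
}

## Natural-scale parameter matrices for the compiled core (one row per
## subject; columns follow the order of the names of omega/alpha).
params_matrices <- function(params_list, flat) {
  S <- length(params_list)
  omega <- matrix(NA_real_, S, flat$n_omega)
  alpha <- matrix(NA_real_, S, flat$n_alpha)
  lam <- pik <- beta <- numeric(S)
  for (s in seq_len(S)) {
    p <- params_list[[s]]
    omega[s, ] <- rep_len(unname(p$omega), flat$n_omega)
    alpha[s, ] <- rep_len(unname(p$alpha), flat$n_alpha)
    lam[s] <- p$lam; pik[s] <- p$pi_stick; beta[s] <- p$beta
  }
  list(omega = omega, alpha = alpha, lam = lam, pik = pik, beta = beta)
}

#' Profile of the negative log-likelihood across a grid of omega values
#'
#' Identifiability diagnostic: all other parameters held fixed.
#'
#' @param sessions As in [subject_loglik()].
#' @param params Baseline [agent_params()] (its `omega` is replaced).
#' @param omega_grid Numeric vector of omega values.
#' @return Numeric vector of negative log-likelihoods, one per grid point.
#' @export
negloglik_surface <- function(sessions, params, omega_grid) {
  vapply(omega_grid, function(w) {
    p <- params
    p$omega <- rep(w, length.out = length(p$omega))
    names(p$omega) <- names(params$omega)
    -subject_loglik(p, sessions)$total
  }, numeric(1))
}
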