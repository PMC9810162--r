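## Model-agnostic behavioral analyses: stay-probability coding and logistic
## mixed model, corrected reward rate, exclusion rules.

#' Derive stay records from one subject's session
#'
#' "Stay" means revisiting the same second-stage creature as on the
#' previous analyzable trial -- coded on creatures, not dwellings, so a
#' model-based learner registers as staying even when the first-stage
#' state differs.  The previous trial's outcome enters on the internal
#' ("more is better") scale centered at the scale midpoint 4.5;
#' `same_state` and `stakes` use +-0.5 effect codes so the outcome main
#' effect is the average slope across same- and different-state trials.
#' Trials following a missed trial have no defined predecessor and are
#' dropped, as is the first analyzable trial.
#'
#' @param session A `subject_session`, or a data frame in the CSV dialect
#'   (then `variant` must be supplied).
#' @param variant Task variant of the data.
#' @param subject_id Identifier copied into the records.
#' @return Data frame of stay records: `subject_id`, `variant`,
#'   `trial_index`, `stay` (0/1), `prev_outcome` (centered),
#'   `same_state` (+-0.5), `stakes` (+-0.5, current trial),
#'   `trial_position` (analyzable-trial counter).
#' @export
code_stay <- function(session, variant = NULL, subject_id = 1L) {
  if (inherits(session, "subject_session")) {
    variant <- session$config$variant
    data <- session$data
  } else data <- session
  if (is.null(variant)) stop("variant must be supplied", call. = FALSE)
  d <- data[!data$practice, , drop = FALSE]
  if (is.unsorted(d$trial_index))
    stop("trials must be ordered by trial_index", call. = FALSE)
  n <- nrow(d)
  if (n < 2L) return(empty_stay_records())
  responded <- !is.na(d$choice)
  cur <- 2:n
  prev <- cur - 1L
  ok <- responded[cur] & responded[prev]
  cur <- cur[ok]; prev <- prev[ok]
  if (!length(cur)) return(empty_stay_records())
  high <- d$stakes == max(d$stakes)
  data.frame(
    subject_id = subject_id,
    variant = variant,
    trial_index = d$trial_index[cur],
    stay = as.integer(d$creature[cur] == d$creature[prev]),
    prev_outcome = internal_reward(variant, d$outcome_units[prev]) - 4.5,
    same_state = ifelse(d$state[cur] == d$state[prev], 0.5, -0.5),
    stakes = ifelse(high[cur], 0.5, -0.5),
    trial_position = seq_len(nrow(d))[cur],
    stringsAsFactors = FALSE)
}

empty_stay_records <- function() {
  data.frame(subject_id = integer(0), variant = character(0),
             trial_index = integer(0), stay = integer(0),
             prev_outcome = numeric(0), same_state = numeric(0),
             stakes = numeric(0), trial_position = integer(0))
}

#' Logistic mixed model of stay probability
#'
#' Fits `stay ~ prev_outcome * same_state` (optionally further crossed
#' with `variant`, `stakes` and/or `trial_position`) with a subject random
#' intercept by Laplace-approximate marginal likelihood (lme4).  A
#' positive `prev_outcome` main effect signals model-based control (the
#' outcome transfers across first-stage states); a positive
#' `prev_outcome:same_state` interaction signals model-free control (the
#' outcome only acts when the state repeats).
#'
#' @param records Stay records from [code_stay()] (rows from several
#'   subjects bound together).
#' @param moderators Character subset of `c("variant", "stakes",
#'   "trial_position")` crossed into the formula.
#' @param random_slopes Add a random slope for `prev_outcome`.
#' @return A `stay_model_result` list: `coefficients` (estimate, SE, z, p,
#'   2.5/97.5% Wald CI), `tau00` (random-intercept variance),
#'   `r2_conditional` (latent-scale variance partition), `formula`,
#'   `converged`, and the fitted `model`.
#' @export
fit_stay_model <- function(records, moderators = character(0),
                           random_slopes = FALSE) {
  if (length(unique(records$subject_id)) < 2L)
    stop("need at least 2 subjects for the mixed model", call. = FALSE)
  if (length(moderators))
    moderators <- match.arg(moderators,
                            c("variant", "stakes", "trial_position"),
                            several.ok = TRUE)
  if ("variant" %in% moderators &&
      length(unique(records$variant)) < 2L)
    moderators <- setdiff(moderators, "variant")
  fixed <- paste(c("prev_outcome", "same_state", moderators), collapse = " * ")
  re <- if (random_slopes) "(1 + prev_outcome | subject_id)"
        else "(1 | subject_id)"
  fml <- stats::as.formula(paste("stay ~", fixed, "+", re))
  fit <- suppressMessages(lme4::glmer(fml, data = records, family = stats::binomial()))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L
  if (!conv)
    warning("stay model convergence issue reported by lme4", call. = FALSE)
  est <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(est),
                      estimate = est[, "Estimate"],
                      se = est[, "Std. Error"],
                      z = est[, "z value"],
                      p = est[, "Pr(>|z|)"],
                      ci_lo = est[, "Estimate"] - 1.96 * est[, "Std. Error"],
                      ci_hi = est[, "Estimate"] + 1.96 * est[, "Std. Error"],
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- lme4::VarCorr(fit)
  tau00 <- as.numeric(vc$subject_id[1, 1])
  ## Nakagawa latent-scale conditional R^2 for the logit link
  var_f <- var(as.vector(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  var_r <- sum(vapply(vc, function(v) v[1, 1], numeric(1)))
  r2c <- (var_f + var_r) / (var_f + var_r + pi^2 / 3)
  structure(list(coefficients = coefs, tau00 = tau00,
                 r2_conditional = r2c, formula = deparse(fml),
                 converged = conv, model = fit),
            class = "stay_model_result")
}

#' Corrected reward rate for one session
#'
#' Average internal outcome earned divided by the average internal outcome
#' available across both creatures' payoff walks, over analyzable
#' (non-practice, responded) trials.  Values above 1 mean the subject
#' earned more than the indiscriminate average of what the walks offered.
#'
#' @param session A `subject_session`, or a data frame carrying `walk_X`
#'   and `walk_Y` columns (then `variant` must be supplied).
#' @param variant Task variant.
#' @return Single numeric rate.
#' @export
corrected_reward_rate <- function(session, variant = NULL) {
  if (inherits(session, "subject_session")) {
    variant <- session$config$variant
    data <- session$data
  } else data <- session
  if (is.null(variant)) stop("variant must be supplied", call. = FALSE)
  d <- data[!data$practice & !is.na(data$choice), , drop = FALSE]
  if (!nrow(d)) stop("no analyzable trials", call. = FALSE)
  earned <- mean(internal_reward(variant, d$outcome_units))
  avail <- mean(internal_reward(variant,
                                pmin(9, pmax(0, c(d$walk_X, d$walk_Y)))))
  if (avail == 0) stop("zero average outcome available", call. = FALSE)
  earned / avail
}

#' Apply the preregistered exclusion rules to one session
#'
#' Drop if more than 20% of non-practice trials were missed (strict
#' inequality: exactly 20% is kept) or, when a comprehension score is
#' provided, if it is below 0.5.
#'
#' @param session A `subject_session` or data frame.
#' @param comprehension_score Optional proportion of comprehension checks
#'   answered correctly.
#' @return List with `keep` (logical), `reason` (`NA` if kept),
#'   `missed_fraction`.
#' @export
apply_exclusions <- function(session, comprehension_score = NULL) {
  data <- if (inherits(session, "subject_session")) session$data else session
  d <- data[!data$practice, , drop = FALSE]
  mf <- mean(is.na(d$choice))
  if (mf > 0.20)
    return(list(keep = FALSE, reason = "missed_over_20pct",
                missed_fraction = mf))
  if (!is.null(comprehension_score) && comprehension_score < 0.5)
    return(list(keep = FALSE, reason = "comprehension_below_50pct",
                missed_fraction = mf))
  list(keep = TRUE, reason = NA_character_, missed_fraction = mf)
}
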