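## Metacognitive (certainty) and predictive (outcome-estimate) bias:
## probe extraction, slope estimation, association with fitted parameters.

#' Extract probe responses from a session
#'
#' @param session A `subject_session` or data frame in the CSV dialect.
#' @param subject_id Identifier copied into the tables.
#' @return List with data frames `certainty` and `estimate`, each with
#'   `subject_id`, `trial_index`, `outcome` (units received) and `rating`
#'   (0--9).  Errors if a rating is out of range or both probe types
#'   appear on one trial.
#' @export
extract_probes <- function(session, subject_id = 1L) {
  data <- if (inherits(session, "subject_session")) session$data else session
  d <- data[!data$practice, , drop = FALSE]
  both <- !is.na(d$certainty) & !is.na(d$outcome_estimate)
  if (any(both))
    stop("certainty and outcome estimate elicited on the same trial",
         call. = FALSE)
  chk <- c(d$certainty, d$outcome_estimate)
  if (any(chk < 0 | chk > 9, na.rm = TRUE))
    stop("probe ratings must lie in [0, 9]", call. = FALSE)
  tab <- function(col) {
    keep <- !is.na(d[[col]]) & !is.na(d$outcome_units)
    data.frame(subject_id = rep(subject_id, sum(keep)),
               trial_index = d$trial_index[keep],
               outcome = d$outcome_units[keep],
               rating = d[[col]][keep],
               stringsAsFactors = FALSE)
  }
  list(certainty = tab("certainty"), estimate = tab("outcome_estimate"))
}

#' Per-subject rating-on-outcome slopes (bias coefficients)
#'
#' The bias coefficient is the slope linking a subject's ratings to the
#' realized outcomes.  The `"mixed"` method fits a linear mixed model of
#' rating on outcome with per-subject random intercepts and slopes and
#' returns fixed + random slope per subject; `"per_subject"` fits ordinary
#' least squares within each subject (the fallback when the mixed model
#' does not converge).
#'
#' @param probes Data frame with `subject_id`, `outcome`, `rating` (one
#'   probe type; rows from several subjects bound together).
#' @param method `"mixed"` or `"per_subject"`.
#' @param min_probes Minimum probes per subject for a defined coefficient.
#' @return Data frame with `subject_id`, `slope`, `n_probes`, `method`.
#' @export
bias_slopes <- function(probes, method = c("mixed", "per_subject"),
                        min_probes = 3L) {
  method <- match.arg(method)
  counts <- table(probes$subject_id)
  keep_ids <- names(counts)[counts >= min_probes]
  probes <- probes[as.character(probes$subject_id) %in% keep_ids, , drop = FALSE]
  if (!nrow(probes))
    return(data.frame(subject_id = integer(0), slope = numeric(0),
                      n_probes = integer(0), method = character(0)))
  if (method == "mixed" && length(keep_ids) >= 2L) {
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(rating ~ outcome + (1 + outcome | subject_id),
                   data = probes,
                   control = lme4::lmerControl(check.conv.singular =
                     lme4::.makeCC(action = "ignore", tol = 1e-4))))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      re <- lme4::ranef(fit)$subject_id
      slopes <- lme4::fixef(fit)[["outcome"]] + re[, "outcome"]
      return(data.frame(subject_id = type.convert(rownames(re), as.is = TRUE),
                        slope = slopes,
                        n_probes = as.integer(counts[rownames(re)]),
                        method = "mixed", stringsAsFactors = FALSE))
    }
    warning("mixed bias model failed; falling back to per-subject OLS",
            call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(probes, probes$subject_id), function(d) {
    sl <- if (var(d$outcome) == 0) NA_real_
          else unname(coef(lm(rating ~ outcome, data = d))[2])
    data.frame(subject_id = d$subject_id[1], slope = sl,
               n_probes = nrow(d), method = "per_subject",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Regress bias coefficients on fitted model parameters
#'
#' Linear regression of per-subject bias slopes on the subject-level
#' posterior means of the model-based weight (omega) and learning rate
#' (alpha) for one task variant.
#'
#' @param bias Data frame from [bias_slopes()].
#' @param summary A [posterior_means()] result whose `subject` table rows
#'   align with `bias$subject_id`.
#' @param variant Variant label selecting the omega/alpha columns (use
#'   `"all"` for an M1 fit).
#' @return Data frame of regression terms with estimates, SE, t, p and
#'   95% CI, plus attribute `"degenerate"` when a predictor is constant.
#' @export
relate_bias_to_params <- function(bias, summary, variant = "all") {
  subj <- summary$subject
  ocol <- grep(sprintf("^omega\\[%s(\\.|\\])", variant), names(subj), value = TRUE)
  acol <- grep(sprintf("^alpha\\[%s(\\.|\\])", variant), names(subj), value = TRUE)
  if (!length(ocol) || !length(acol))
    stop(sprintf("no omega/alpha columns for variant '%s'", variant),
         call. = FALSE)
  idx <- match(bias$subject_id, subj$subject)
  d <- data.frame(bias = bias$slope,
                  omega = rowMeans(subj[idx, ocol, drop = FALSE]),
                  alpha = rowMeans(subj[idx, acol, drop = FALSE]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3L)
    stop("need at least 3 matched subjects", call. = FALSE)
  degenerate <- var(d$omega) == 0 || var(d$alpha) == 0
  fml <- if (degenerate) bias ~ 1 else bias ~ omega + alpha
  fit <- lm(fml, data = d)
  est <- summary(fit)$coefficients
  out <- data.frame(term = rownames(est),
                    estimate = est[, 1], se = est[, 2],
                    t = est[, 3], p = est[, 4],
                    ci_lo = est[, 1] - 1.96 * est[, 2],
                    ci_hi = est[, 1] + 1.96 * est[, 2],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "degenerate") <- degenerate
  if (degenerate)
    warning("constant predictor; bias regression degenerate", call. = FALSE)
  out
}
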