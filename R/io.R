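## Dataset readers/writers, scenario/config serialization, run manifests,
## and the command-layer functions behind the CLI script (inst/cli.R).

config_to_list <- function(cfg) {
  l <- unclass(cfg)
  l$transition_map <- as.vector(cfg$transition_map)
  l
}

config_from_list <- function(l) {
  task_config(variant = l$variant, n_trials = l$n_trials,
              n_practice = l$n_practice,
              stakes_values = unlist(l$stakes_values),
              stakes_prob = l$stakes_prob, walk_sigma = l$walk_sigma,
              walk_bounds = unlist(l$walk_bounds),
              init_ranges = l$init_ranges, base_threat = l$base_threat,
              transition_map = matrix(as.integer(unlist(l$transition_map)),
                                      2, 2,
                                      dimnames = list(state = c("1", "2"),
                                                      choice = c("a", "b"))),
              miss_prob = l$miss_prob)
}

#' Write a cohort to a directory of per-subject CSVs plus a manifest
#'
#' One CSV per subject x variant in the trial-record dialect (missing
#' values as empty cells; walk columns at full precision so the cohort
#' round-trips losslessly), and `manifest.json` recording the scenario,
#' seed, configs and file list.
#'
#' @param cohort A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scenario <- attr(cohort, "scenario")
  files <- character(0)
  for (subj in cohort) {
    for (v in names(subj$sessions)) {
      f <- sprintf("sub%03d_%s.csv", subj$subject_id, v)
      d <- subj$sessions[[v]]$data
      for (col in c("walk_X", "walk_Y"))
        d[[col]] <- sprintf("%.17g", d[[col]])
      write.csv(d, file.path(dir, f), row.names = FALSE, na = "",
                quote = FALSE)
      files <- c(files, f)
    }
  }
  manifest <- list(
    command = "simulate",
    scenario = scenario$name,
    n_subjects = length(cohort),
    seed = attr(cohort, "seed"),
    configs = lapply(scenario$configs, config_to_list),
    order = lapply(cohort, function(s) s$order),
    files = files,
    version = as.character(utils::packageVersion("protectRL")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  true <- attr(cohort, "true")
  if (!is.null(true))
    write.csv(true, file.path(dir, "true_params.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.json` and subject CSVs.
#' @return A `cohort` list mirroring [generate_study()] output (without
#'   agent parameters; `walks` rebuilt from the stored walk columns).
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  configs <- lapply(manifest$configs, config_from_list)
  cohort <- lapply(seq_len(manifest$n_subjects), function(s) {
    ## jsonlite simplifies the per-subject order lists to a matrix when all
    ## subjects share the same number of variants
    order_v <- if (is.matrix(manifest$order)) manifest$order[s, ]
               else unlist(manifest$order[[s]])
    sessions <- lapply(order_v, function(v) {
      f <- file.path(dir, sprintf("sub%03d_%s.csv", s, v))
      d <- tryCatch(
        read.csv(f, na.strings = "", stringsAsFactors = FALSE,
                 colClasses = c(walk_X = "numeric", walk_Y = "numeric")),
        error = function(e)
          stop(sprintf("failed to parse %s: %s", f, conditionMessage(e)),
               call. = FALSE))
      validate_trial_data(d, f)
      walks <- structure(list(values = cbind(X = d$walk_X, Y = d$walk_Y),
                              seed = NA_integer_), class = "payoff_walks")
      structure(list(data = d, walks = walks, config = configs[[v]],
                     params = NULL), class = "subject_session")
    })
    names(sessions) <- order_v
    list(subject_id = s, order = order_v, sessions = sessions, params = NULL)
  })
  attr(cohort, "manifest") <- manifest
  class(cohort) <- "cohort"
  cohort
}

validate_trial_data <- function(d, file) {
  need <- c("trial_index", "practice", "stakes", "state",
            "dwelling_positions", "choice", "response_key", "creature",
            "outcome_units", "final_result")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop(sprintf("%s: missing columns %s", file,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  bad <- which(!is.na(d$outcome_units) &
                 (d$outcome_units < 0 | d$outcome_units > 9))
  if (length(bad))
    stop(sprintf("%s: outcome out of range at row %d", file, bad[1]),
         call. = FALSE)
  invisible(d)
}

## --- command layer -------------------------------------------------------

resolve_scenario <- function(scenario) {
  if (inherits(scenario, "cohort_scenario")) return(scenario)
  if (!scenario %in% c("study1", "study2", "study3"))
    stop(sprintf("unknown scenario preset '%s'", scenario), call. = FALSE)
  cohort_scenario(scenario)
}

#' Simulate a cohort and write it to disk
#' @param scenario Preset name or [cohort_scenario()].
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param n_subjects Optional cohort-size override.
#' @return Invisibly, the output directory.
#' @export
cmd_simulate <- function(scenario, out_dir, seed = 1L, n_subjects = NULL) {
  sc <- resolve_scenario(scenario)
  cohort <- generate_study(sc, seed = seed, n_subjects = n_subjects)
  write_cohort(cohort, out_dir)
  message(sprintf("wrote %d subjects x %d variants to %s",
                  length(cohort), length(sc$configs), out_dir))
  invisible(out_dir)
}

#' Fit a hierarchical model to a cohort directory
#'
#' Writes `posterior_subject.csv` (subject-level natural-scale posterior
#' means), `posterior_group.csv`, `waic.json` and `fit_manifest.json`.
#'
#' @param data_dir Cohort directory from [cmd_simulate()].
#' @param model_id `"M1"`..`"M4"`.
#' @param preset `"desk"` or `"paper"` MCMC preset.
#' @param out_dir Output directory.
#' @param seed Sampler seed.
#' @return Invisibly, a list with the fit, summary and WAIC.
#' @export
cmd_fit <- function(data_dir, model_id = "M3", preset = "desk",
                    out_dir = data_dir, seed = 1L) {
  cohort <- read_cohort(data_dir)
  variants <- unique(unlist(lapply(cohort, function(s) s$order)))
  spec <- model_spec(model_id, variants)
  fit <- fit_hier(cohort, spec, preset = preset, seed = seed)
  post <- posterior_means(fit)
  pw <- pointwise_loglik(fit)
  w <- waic(pw, model_id = model_id)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(post$subject,
            file.path(out_dir, sprintf("posterior_subject_%s.csv", model_id)),
            row.names = FALSE)
  write.csv(post$group,
            file.path(out_dir, sprintf("posterior_group_%s.csv", model_id)),
            row.names = FALSE)
  jsonlite::write_json(
    list(model_id = model_id, waic = w$waic, lppd = w$lppd,
         p_waic = w$p_waic, n_obs = w$n_obs,
         rhat_max = max(fit$rhat, na.rm = TRUE)),
    file.path(out_dir, sprintf("waic_%s.json", model_id)),
    auto_unbox = TRUE, digits = NA)
  message(sprintf("%s: WAIC %.1f (p_waic %.1f), max split-Rhat %.3f",
                  model_id, w$waic, w$p_waic, max(fit$rhat, na.rm = TRUE)))
  invisible(list(fit = fit, summary = post, waic = w))
}

#' Run the model-agnostic analyses on a cohort directory
#'
#' Applies the exclusion rules, codes stay records, fits the stay
#' logistic mixed model, computes corrected reward rates and bias slopes,
#' and (when a posterior summary CSV is available) regresses bias on the
#' fitted parameters.  Results are written as CSVs.
#'
#' @param data_dir Cohort directory.
#' @param out_dir Output directory.
#' @param summary Optional [posterior_means()] result for the bias
#'   regressions.
#' @return Invisibly, a list of the result tables.
#' @export
cmd_analyze <- function(data_dir, out_dir = data_dir, summary = NULL) {
  cohort <- read_cohort(data_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  excl <- lapply(cohort, function(s) {
    res <- lapply(s$sessions, apply_exclusions)
    keep <- all(vapply(res, `[[`, logical(1), "keep"))
    list(subject_id = s$subject_id, keep = keep,
         reason = paste(stats::na.omit(vapply(res, `[[`, character(1),
                                              "reason")), collapse = ";"))
  })
  excl_df <- do.call(rbind, lapply(excl, as.data.frame))
  kept <- vapply(excl, `[[`, logical(1), "keep")
  if (any(!kept))
    message(sprintf("excluded %d subject(s): %s", sum(!kept),
                    paste(excl_df$subject_id[!kept], collapse = ", ")))
  cohort_kept <- cohort[kept]

  stay <- do.call(rbind, lapply(cohort_kept, function(s)
    do.call(rbind, lapply(s$sessions, code_stay, subject_id = s$subject_id))))
  stay_fit <- NULL
  stay_tab <- NULL
  if (length(cohort_kept) >= 2L) {
    mods <- if (length(unique(stay$variant)) > 1L) "variant" else character(0)
    stay_fit <- fit_stay_model(stay, moderators = mods)
    stay_tab <- stay_fit$coefficients
  } else {
    warning("fewer than 2 subjects: mixed stay model refused, ",
            "per-subject logistic fits used instead", call. = FALSE)
    stay_tab <- do.call(rbind, lapply(split(stay, stay$subject_id),
      function(d) {
        fit <- stats::glm(stay ~ prev_outcome * same_state, data = d,
                          family = stats::binomial())
        est <- summary(fit)$coefficients
        data.frame(subject_id = d$subject_id[1], term = rownames(est),
                   estimate = est[, 1], se = est[, 2],
                   row.names = NULL)
      }))
  }
  rates <- do.call(rbind, lapply(cohort_kept, function(s)
    do.call(rbind, lapply(names(s$sessions), function(v)
      data.frame(subject_id = s$subject_id, variant = v,
                 corrected_reward_rate =
                   corrected_reward_rate(s$sessions[[v]]))))))

  probes <- lapply(cohort_kept, function(s)
    lapply(s$sessions, extract_probes, subject_id = s$subject_id))
  bind_probe <- function(type) do.call(rbind, lapply(probes, function(pp)
    do.call(rbind, lapply(pp, `[[`, type))))
  bias_cert <- bias_slopes(bind_probe("certainty"))
  bias_est <- bias_slopes(bind_probe("estimate"))

  write.csv(excl_df, file.path(out_dir, "exclusions.csv"), row.names = FALSE)
  write.csv(stay, file.path(out_dir, "stay_records.csv"), row.names = FALSE)
  write.csv(stay_tab, file.path(out_dir, "stay_model.csv"), row.names = FALSE)
  write.csv(rates, file.path(out_dir, "reward_rate.csv"), row.names = FALSE)
  write.csv(bias_cert, file.path(out_dir, "bias_certainty.csv"),
            row.names = FALSE)
  write.csv(bias_est, file.path(out_dir, "bias_estimate.csv"),
            row.names = FALSE)

  bias_reg <- NULL
  if (!is.null(summary)) {
    variants <- unique(stay$variant)
    bias_reg <- do.call(rbind, lapply(variants, function(v) {
      tab <- tryCatch(relate_bias_to_params(bias_est, summary, variant = v),
                      error = function(e) NULL)
      if (is.null(tab)) return(NULL)
      cbind(variant = v, tab)
    }))
    if (!is.null(bias_reg))
      write.csv(bias_reg, file.path(out_dir, "bias_regression.csv"),
                row.names = FALSE)
  }
  invisible(list(exclusions = excl_df, stay = stay, stay_model = stay_tab,
                 stay_fit = stay_fit, reward_rate = rates,
                 bias_certainty = bias_cert, bias_estimate = bias_est,
                 bias_regression = bias_reg))
}

#' Parameter-recovery report: simulate, fit, correlate
#'
#' Generates a scaled cohort from a scenario, fits the requested model,
#' and reports the correlation between generating and recovered
#' subject-level parameters plus group-mean errors.
#'
#' @param scenario Preset name or [cohort_scenario()].
#' @param model_id Model to fit.
#' @param out_dir Output directory (`NULL` to skip writing).
#' @param seed Master seed.
#' @param n_subjects,preset Scale controls.
#' @return A data frame with one row per parameter: `parameter`, `r`
#'   (true-vs-recovered correlation), `true_mean`, `recovered_mean`,
#'   `uninformative` (flagged when the generating values carry no
#'   information, e.g. beta near 0 or zero variance).
#' @export
cmd_recover <- function(scenario, model_id = "M1", out_dir = NULL,
                        seed = 1L, n_subjects = 20L, preset = "desk") {
  sc <- resolve_scenario(scenario)
  cohort <- generate_study(sc, seed = seed, n_subjects = n_subjects)
  true <- attr(cohort, "true")
  spec <- model_spec(model_id, names(sc$configs))
  fit <- fit_hier(cohort, spec, preset = preset, seed = sub_seed(seed, "fit"))
  post <- posterior_means(fit)
  kinds <- fit$model$kinds

  rows <- lapply(seq_len(nrow(kinds)), function(i) {
    nm <- kinds$name[i]; kind <- kinds$kind[i]; lab <- kinds$label[i]
    true_col <- switch(kind,
      omega = , alpha = {
        cand <- paste0(kind, ".", lab)
        if (cand %in% names(true)) cand
        else grep(paste0("^", kind, "\\."), names(true), value = TRUE)
      },
      lam = "lam", pi = "pi", beta = "beta")
    tv <- rowMeans(true[, true_col, drop = FALSE])
    rv <- post$subject[[nm]]
    uninf <- sd(tv) < 1e-8 || mean(true$beta) < 0.5
    data.frame(parameter = nm,
               r = if (uninf) NA_real_ else stats::cor(tv, rv),
               true_mean = mean(tv), recovered_mean = mean(rv),
               uninformative = uninf, stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(rep, file.path(out_dir,
                             sprintf("recovery_%s.csv", model_id)),
              row.names = FALSE)
  }
  rep
}
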