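## Synthetic cohorts: group-level parameter draws calibrated to printed
## cohort summaries, full simulated studies (both variants per subject,
## order counterbalanced), and a synthetic probe-rating generator.

#' Rating-generator parameters (synthetic)
#'
#' The task defines the probes but no generative model for the ratings;
#' this generator is the package's own synthetic construction.  Outcome
#' estimates are an affine function of the visited creature's latent
#' payoff plus Gaussian noise, rounded and clipped to 0--9; certainty is
#' an affine function of the absolute latent payoff difference between the
#' creatures.  The intercept defaults to `(1 - slope) * 4.5` so ratings
#' stay centered mid-scale.
#'
#' @param slope Estimate slope on the latent payoff.
#' @param intercept Estimate intercept.
#' @param noise_sd Gaussian rating noise SD.
#' @param cert_intercept,cert_slope Certainty affine parameters.
#' @return List of rating parameters.
#' @export
rating_params <- function(slope = 0.6, intercept = (1 - slope) * 4.5,
                          noise_sd = 1.0, cert_intercept = 3,
                          cert_slope = 0.8) {
  list(slope = slope, intercept = intercept, noise_sd = noise_sd,
       cert_intercept = cert_intercept, cert_slope = cert_slope)
}

#' Fill scheduled probe ratings in a simulated session
#'
#' @param session A `subject_session` whose `data` carries a `probe`
#'   column.
#' @param params A [rating_params()] list.
#' @param seed Integer seed.
#' @return The session with `certainty` and `outcome_estimate` filled on
#'   their scheduled, responded trials.
#' @export
generate_ratings <- function(session, params = rating_params(), seed = 1L) {
  d <- session$data
  if (is.null(d$probe)) stop("session has no probe schedule", call. = FALSE)
  with_seed(seed, {
    est_t <- which(d$probe == "estimate" & !is.na(d$choice))
    cert_t <- which(d$probe == "certainty" & !is.na(d$choice))
    if (length(est_t)) {
      truth <- ifelse(d$creature[est_t] == "X", d$walk_X[est_t],
                      d$walk_Y[est_t])
      d$outcome_estimate[est_t] <- clip09(round(
        params$intercept + params$slope * truth +
          rnorm(length(est_t), 0, params$noise_sd)))
    }
    if (length(cert_t)) {
      gap <- abs(d$walk_X[cert_t] - d$walk_Y[cert_t])
      d$certainty[cert_t] <- clip09(round(
        params$cert_intercept + params$cert_slope * gap +
          rnorm(length(cert_t), 0, params$noise_sd)))
    }
  })
  session$data <- d
  session
}

#' Cohort scenario: a stated synthetic world for one study
#'
#' Presets mirror the three studies' structure: 200 subjects, two task
#' variants per subject, 100 (`study1`) or 200 (`study2`, `study3`)
#' analyzable trials per variant, and group omega/alpha means and SDs at
#' the printed cohort values.  Group values for the shared `lam`, `pi` and
#' `beta` are synthetic defaults (their cohort summaries are in a
#' supplementary spreadsheet not reproduced here).
#'
#' @param name `"study1"`, `"study2"`, `"study3"`, or `"custom"`.
#' @param n_subjects Cohort size.
#' @param configs Named list of two [task_config()]s (for custom
#'   scenarios).
#' @param omega,alpha Named lists: per-variant `c(mean, sd)` on the
#'   natural scale.
#' @param lam,pi_stick,beta Shared `c(mean, sd)` group values (natural
#'   scale; beta on `[0, 20]`).
#' @param rating `c(slope_mean, slope_sd, noise_sd)` of the synthetic
#'   rating generator.
#' @return A `cohort_scenario` object.
#' @export
cohort_scenario <- function(name = c("study1", "study2", "study3", "custom"),
                            n_subjects = NULL, configs = NULL,
                            omega = NULL, alpha = NULL,
                            lam = c(0.50, 0.20), pi_stick = c(0.20, 0.15),
                            beta = c(5, 2),
                            rating = c(slope_mean = 0.6, slope_sd = 0.2,
                                       noise_sd = 1.0)) {
  name <- match.arg(name)
  if (name != "custom") {
    presets <- list(
      study1 = list(omega = list(protection = c(0.72, 0.14),
                                 reward = c(0.14, 0.22)),
                    alpha = list(protection = c(0.47, 0.33),
                                 reward = c(0.43, 0.32))),
      study2 = list(omega = list(protection = c(0.76, 0.18),
                                 direct_reward = c(0.55, 0.25)),
                    alpha = list(protection = c(0.48, 0.35),
                                 direct_reward = c(0.51, 0.37))),
      study3 = list(omega = list(protection = c(0.74, 0.14),
                                 punishment = c(0.54, 0.25)),
                    alpha = list(protection = c(0.58, 0.35),
                                 punishment = c(0.51, 0.37))))
    omega <- omega %||% presets[[name]]$omega
    alpha <- alpha %||% presets[[name]]$alpha
    configs <- configs %||% preset_config(name)
    n_subjects <- n_subjects %||% 200L
  }
  if (is.null(configs) || is.null(omega) || is.null(alpha) ||
      is.null(n_subjects))
    stop("custom scenarios need n_subjects, configs, omega and alpha",
         call. = FALSE)
  sc <- structure(list(name = name, n_subjects = as.integer(n_subjects),
                       configs = configs, omega = omega, alpha = alpha,
                       lam = lam, pi_stick = pi_stick, beta = beta,
                       rating = rating),
                  class = "cohort_scenario")
  ## fail early if any preset entry is not moment-matchable
  for (v in names(sc$omega)) latent_moments(sc$omega[[v]], "omega",
                                            paste0("omega.", v))
  for (v in names(sc$alpha)) latent_moments(sc$alpha[[v]], "alpha",
                                            paste0("alpha.", v))
  latent_moments(sc$lam, "lam", "lam")
  latent_moments(sc$pi_stick, "pi", "pi")
  latent_moments(sc$beta, "beta", "beta")
  sc
}

## Latent-scale (mu, sigma) whose sigmoid-transformed population matches
## the requested natural-scale mean and SD (Gaussian quadrature on a fixed
## z grid + Nelder-Mead).  Errors when the target moments are infeasible
## for a bounded variable.
latent_moments <- function(target, kind, label) {
  m <- target[1]; s <- target[2]
  if (kind == "beta") { m <- m / 20; s <- s / 20 }
  if (m <= 0 || m >= 1)
    stop(sprintf("%s: mean must lie strictly inside the bounds", label),
         call. = FALSE)
  if (s >= sqrt(m * (1 - m)))
    stop(sprintf("%s: SD %.3f is unattainable for a bounded mean %.2f",
                 label, target[2], target[1]), call. = FALSE)
  if (s == 0) return(c(mu = stats::qlogis(m), sigma = 0))
  z <- seq(-6, 6, length.out = 801)
  w <- stats::dnorm(z); w <- w / sum(w)
  obj <- function(par) {
    x <- stats::plogis(par[1] + exp(par[2]) * z)
    mu_x <- sum(w * x)
    sd_x <- sqrt(sum(w * (x - mu_x)^2))
    (mu_x - m)^2 + (sd_x - s)^2
  }
  fit <- stats::optim(c(stats::qlogis(m), log(4 * s)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (fit$value > 1e-6)
    stop(sprintf("%s: could not match moments (residual %.2g)", label,
                 fit$value), call. = FALSE)
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Draw per-subject agent parameters for a scenario
#'
#' Subjects are sampled on the unconstrained latent scale with latent
#' mean/SD chosen by moment matching, so natural-scale sample moments
#' approximate the scenario's stated means/SDs and the generated cohort
#' is exactly the population the hierarchical model assumes.
#'
#' @param scenario A [cohort_scenario()].
#' @param seed Integer seed.
#' @return List with `params` (list of [agent_params()], one per subject)
#'   and `true` (data frame of the drawn natural-scale values).
#' @export
sample_cohort_params <- function(scenario, seed = 1L) {
  S <- scenario$n_subjects
  variants <- names(scenario$omega)
  with_seed(sub_seed(seed, "params"), {
    draw <- function(target, kind, label) {
      lm_ <- latent_moments(target, kind, label)
      th <- lm_["mu"] + lm_["sigma"] * rnorm(S)
      transform_to_natural(th, kind)
    }
    om <- sapply(variants, function(v)
      draw(scenario$omega[[v]], "omega", paste0("omega.", v)))
    al <- sapply(variants, function(v)
      draw(scenario$alpha[[v]], "alpha", paste0("alpha.", v)))
    if (S == 1L) { om <- matrix(om, 1); al <- matrix(al, 1)
                   colnames(om) <- colnames(al) <- variants }
    lam <- draw(scenario$lam, "lam", "lam")
    pik <- draw(scenario$pi_stick, "pi", "pi")
    bet <- draw(scenario$beta, "beta", "beta")
    params <- lapply(seq_len(S), function(s)
      agent_params(omega = setNames(om[s, ], variants),
                   alpha = setNames(al[s, ], variants),
                   lam = lam[s], pi_stick = pik[s], beta = bet[s]))
    true <- data.frame(subject = seq_len(S),
                       setNames(as.data.frame(om), paste0("omega.", variants)),
                       setNames(as.data.frame(al), paste0("alpha.", variants)),
                       lam = lam, pi = pik, beta = bet)
    list(params = params, true = true)
  })
}

#' Generate a complete synthetic study
#'
#' Simulates both task variants for every subject (presentation order
#' counterbalanced: odd-numbered subjects play protection first), with
#' probe schedules and synthetic ratings.
#'
#' @param scenario A [cohort_scenario()].
#' @param seed Integer master seed.
#' @param n_subjects Optional override of the scenario's cohort size
#'   (for scaled-down runs).
#' @return A `cohort` list of subjects, each with `subject_id`, `order`,
#'   `sessions` (named list of `subject_session`), `params`; attributes
#'   `scenario`, `true` (generating parameter table), `seed`.
#' @export
generate_study <- function(scenario, seed = 1L, n_subjects = NULL) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  if (!is.null(n_subjects)) {
    scenario$n_subjects <- as.integer(n_subjects)
  }
  S <- scenario$n_subjects
  variants <- names(scenario$configs)
  drawn <- sample_cohort_params(scenario, seed)
  rt <- scenario$rating
  with_seed(sub_seed(seed, "rating_slopes"), {
    slopes <- rnorm(S, rt[["slope_mean"]], rt[["slope_sd"]])
  })
  cohort <- lapply(seq_len(S), function(s) {
    order_v <- if (s %% 2L == 1L) variants else rev(variants)
    rp <- rating_params(slope = slopes[s], noise_sd = rt[["noise_sd"]])
    sessions <- lapply(order_v, function(v)
      simulate_subject(drawn$params[[s]], scenario$configs[[v]],
                       seed = sub_seed(seed, "subj", s, v),
                       rating_params = rp))
    names(sessions) <- order_v
    list(subject_id = s, order = order_v, sessions = sessions,
         params = drawn$params[[s]], rating_slope = slopes[s])
  })
  attr(cohort, "scenario") <- scenario
  attr(cohort, "true") <- cbind(drawn$true, rating_slope = slopes)
  attr(cohort, "seed") <- seed
  class(cohort) <- "cohort"
  cohort
}
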