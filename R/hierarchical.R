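## Hierarchical Bayesian estimation of the hybrid learner across a cohort.
##
## Subject-level parameters use the non-centered parameterization
## theta_subject = mu_group + sigma_group * epsilon_subject, with standard
## normal priors on mu and epsilon and a half-normal(0, 1) prior on sigma.
## Latent parameters map to the natural scale by the logistic sigmoid
## (omega, alpha, lambda, pi in [0, 1]; beta additionally scaled to
## [0, 20]).  Posterior draws come from an adaptive Metropolis-within-Gibbs
## sampler over the latent space: subject offset blocks are updated jointly
## (independently across subjects given the group level), then each
## parameter's (mu, sigma) pair, with proposal scales adapted toward
## standard acceptance targets during warmup only.

MODEL_IDS <- c("M1", "M2", "M3", "M4")

#' Parameter-tying scheme for the four candidate models
#'
#' M1 ties `omega` and `alpha` across everything; M2 splits them by stakes
#' level; M3 by task variant; M4 by variant x stakes.  `lambda`, `pi` and
#' `beta` are shared in all models.
#'
#' @param model_id `"M1"`, `"M2"`, `"M3"` or `"M4"`.
#' @param variants Character vector of variant labels present in the
#'   cohort (in a fixed order).
#' @return A `model_spec` object.
#' @export
model_spec <- function(model_id, variants) {
  model_id <- match.arg(model_id, MODEL_IDS)
  labels <- switch(model_id,
    M1 = "all",
    M2 = c("low", "high"),
    M3 = variants,
    M4 = as.vector(outer(variants, c("low", "high"), paste, sep = ".")))
  structure(list(model_id = model_id, variants = variants,
                 split_labels = labels),
            class = "model_spec")
}

## Per-trial column index for a condition-split parameter under a spec.
spec_index <- function(spec, kind, variant, stakes_high) {
  n <- length(stakes_high)
  lab <- switch(spec$model_id,
    M1 = rep("all", n),
    M2 = ifelse(stakes_high == 1L, "high", "low"),
    M3 = rep(variant, n),
    M4 = paste(variant, ifelse(stakes_high == 1L, "high", "low"), sep = "."))
  idx <- match(lab, spec$split_labels)
  if (anyNA(idx))
    stop(sprintf("condition label absent from model spec (%s)", variant),
         call. = FALSE)
  idx
}

#' Names and kinds of the free parameters under a model spec
#' @param spec A [model_spec()].
#' @return Data frame with columns `name` (e.g. `"omega[protection]"`),
#'   `kind` (`omega`/`alpha`/`lam`/`pi`/`beta`) and `label`.
#' @export
param_kinds <- function(spec) {
  sl <- spec$split_labels
  data.frame(
    name = c(paste0("omega[", sl, "]"), paste0("alpha[", sl, "]"),
             "lam", "pi", "beta"),
    kind = c(rep("omega", length(sl)), rep("alpha", length(sl)),
             "lam", "pi", "beta"),
    label = c(sl, sl, "all", "all", "all"),
    stringsAsFactors = FALSE)
}

#' Map an unconstrained latent parameter to its natural scale
#'
#' Logistic sigmoid into `[0, 1]` for `omega`, `alpha`, `lam` and `pi`;
#' the sigmoid multiplied by 20 for `beta` (range `[0, 20]`).
#'
#' @param theta_raw Unconstrained value(s).
#' @param kind Parameter kind.
#' @return Natural-scale value(s).
#' @export
transform_to_natural <- function(theta_raw, kind) {
  p <- stats::plogis(theta_raw)
  if (kind == "beta") 20 * p else p
}

## Natural-scale matrix (subjects x params) from latent group/offset state.
natural_matrix <- function(mu, sigma, eps, kinds) {
  theta <- sweep(sweep(eps, 2, sigma, "*"), 2, mu, "+")
  nat <- stats::plogis(theta)
  bcol <- which(kinds == "beta")
  nat[, bcol] <- 20 * nat[, bcol]
  nat
}

#' Assemble a cohort's joint log-density under a model spec
#'
#' Flattens the cohort once and returns closures evaluating per-subject
#' log-likelihoods and the joint log posterior for any latent state, used
#' by [fit_hier()] and available directly for diagnostics.
#'
#' @param cohort List of subjects, each a list with `subject_id` and
#'   `sessions` (list of `subject_session` objects, one per variant).
#' @param spec A [model_spec()].
#' @param q0 Initial action value.
#' @return A `hb_model` list: `flat` arrays, `kinds`, `n_subjects`,
#'   `loglik(mu, sigma, eps)` (per-subject vector),
#'   `logpost(mu, sigma, eps)`, and `pointwise(mu, sigma, eps)`.
#' @export
build_model <- function(cohort, spec, q0 = 4.5) {
  stopifnot(inherits(spec, "model_spec"))
  pk <- param_kinds(spec)
  S <- length(cohort)
  if (S > 0L) {
    arrays <- lapply(cohort, function(subj)
      lapply(subj$sessions, function(ss) {
        if (!ss$config$variant %in% spec$variants)
          stop(sprintf("variant '%s' not in model spec", ss$config$variant),
               call. = FALSE)
        session_arrays(ss$data, ss$config$variant, ss$config$stakes_values)
      }))
    tm <- cohort[[1]]$sessions[[1]]$config$transition_map
    flat <- flatten_sessions(arrays, spec = spec)
  } else {
    flat <- NULL
    tm <- default_transition_map()
  }
  n_split <- length(spec$split_labels)
  ocols <- seq_len(n_split)
  acols <- n_split + seq_len(n_split)
  lcol <- 2L * n_split + 1L; pcol <- lcol + 1L; bcol <- pcol + 1L

  loglik <- function(mu, sigma, eps, pointwise = FALSE) {
    if (S == 0L) return(numeric(0))
    nat <- natural_matrix(eps = eps, mu = mu, sigma = sigma, kinds = pk$kind)
    cpp_hybrid_loglik(flat$subj, flat$reset, flat$state, flat$choice,
                      flat$resp, flat$creature, flat$reward, flat$key_a,
                      flat$oidx, flat$aidx, as.integer(t(tm)),
                      nat[, ocols, drop = FALSE], nat[, acols, drop = FALSE],
                      nat[, lcol], nat[, pcol], nat[, bcol], q0, pointwise)
  }
  logprior <- function(mu, sigma, eps) {
    if (any(sigma < 0)) return(-Inf)
    sum(stats::dnorm(mu, log = TRUE)) +
      sum(stats::dnorm(sigma, log = TRUE) + log(2)) +
      sum(stats::dnorm(eps, log = TRUE))
  }
  structure(list(spec = spec, kinds = pk, n_subjects = S,
                 n_params = nrow(pk), n_trials = if (is.null(flat)) 0L
                 else length(flat$subj),
                 flat = flat, q0 = q0,
                 loglik = loglik, logprior = logprior,
                 logpost = function(mu, sigma, eps)
                   logprior(mu, sigma, eps) + sum(loglik(mu, sigma, eps))),
            class = "hb_model")
}

#' Fit a hierarchical model by adaptive MCMC
#'
#' The `"paper"` preset runs 4 chains of 4000 iterations (half warmup);
#' the `"desk"` preset, intended for interactive use and tests, runs
#' 2 chains of 1000.  Proposal scales adapt only during warmup.  Split-R
#' hat is computed for the group-level parameters and a warning is issued
#' above 1.1 -- nonconvergence is reported, never silently ignored.
#'
#' @param model A [build_model()] result, or a cohort (then `spec` must be
#'   given).
#' @param spec Model spec when `model` is a cohort.
#' @param preset `"desk"`, `"paper"`, or `"custom"`.
#' @param chains,iter,warmup Custom MCMC sizes (used when
#'   `preset = "custom"`).
#' @param seed Master seed.
#' @param thin Keep every `thin`-th post-warmup draw.
#' @param progress Print progress lines.
#' @return An `hbfit` object with elements `draws` (list of `mu`, `sigma`
#'   arrays `[draw, param]` and `eps` `[draw, subject, param]`), `chain`
#'   (chain index per draw), `rhat`, `accept`, `model`.
#' @export
fit_hier <- function(model, spec = NULL,
                     preset = c("desk", "paper", "custom"),
                     chains = 2L, iter = 1000L, warmup = NULL, seed = 1L,
                     thin = NULL, progress = FALSE) {
  preset <- match.arg(preset)
  if (!inherits(model, "hb_model")) model <- build_model(model, spec)
  if (preset == "desk") { chains <- 2L; iter <- 1000L }
  if (preset == "paper") { chains <- 4L; iter <- 4000L }
  if (is.null(warmup)) warmup <- iter %/% 2L
  keep <- iter - warmup
  if (is.null(thin)) thin <- max(1L, keep %/% 500L)
  S <- model$n_subjects; K <- model$n_params
  kinds <- model$kinds$kind

  draws_mu <- draws_sigma <- NULL
  draws_eps <- NULL
  chain_id <- integer(0)
  acc_all <- numeric(0)

  for (ch in seq_len(chains)) {
    with_seed(sub_seed(seed, "sampler", ch), {
      mu <- rnorm(K, 0, 0.3)
      sigma <- rep(0.5, K)
      eps <- matrix(rnorm(S * K, 0, 0.3), S, K)
      ll <- model$loglik(mu, sigma, eps)
      ls_subj <- matrix(log(0.5), S, K)  # per subject x coordinate scale
      ls_grp <- matrix(log(0.1), 2, K)   # row 1 = mu, row 2 = sigma
      n_keep_ch <- 0L
      acc_sum <- 0; acc_n <- 0

      for (it in seq_len(iter)) {
        gam <- if (it <= warmup) (it + 10)^-0.6 else 0

        ## coordinate-wise subject-offset proposals; subjects are
        ## conditionally independent so acceptance is vectorized per subject
        if (S > 0L) for (k in seq_len(K)) {
          eps_prop <- eps
          eps_prop[, k] <- eps[, k] + exp(ls_subj[, k]) * rnorm(S)
          ll_prop <- model$loglik(mu, sigma, eps_prop)
          logr <- (ll_prop - ll) -
            0.5 * (eps_prop[, k]^2 - eps[, k]^2)
          a <- pmin(1, exp(logr))
          take <- runif(S) < a
          eps[take, k] <- eps_prop[take, k]
          ll[take] <- ll_prop[take]
          ls_subj[, k] <- ls_subj[, k] + gam * (a - 0.44)
          acc_sum <- acc_sum + sum(a); acc_n <- acc_n + S
        }

        ## group-level (mu_k, sigma_k) random-walk updates
        for (k in seq_len(K)) {
          mu_p <- mu; sg_p <- sigma
          mu_p[k] <- mu[k] + exp(ls_grp[1, k]) * rnorm(1)
          sg_p[k] <- abs(sigma[k] + exp(ls_grp[2, k]) * rnorm(1))
          ll_prop <- model$loglik(mu_p, sg_p, eps)
          logr <- sum(ll_prop - ll) -
            0.5 * (mu_p[k]^2 - mu[k]^2) - 0.5 * (sg_p[k]^2 - sigma[k]^2)
          a <- min(1, exp(logr))
          if (runif(1) < a) { mu <- mu_p; sigma <- sg_p; ll <- ll_prop }
          ls_grp[, k] <- ls_grp[, k] + gam * (a - 0.3)
        }

        if (it > warmup && (it - warmup) %% thin == 0L) {
          draws_mu <- rbind(draws_mu, mu)
          draws_sigma <- rbind(draws_sigma, sigma)
          draws_eps <- c(draws_eps, list(eps))
          chain_id <- c(chain_id, ch)
          n_keep_ch <- n_keep_ch + 1L
        }
        if (progress && it %% 200L == 0L)
          message(sprintf("chain %d iter %d / %d", ch, it, iter))
      }
      acc_all <- c(acc_all, if (acc_n > 0) acc_sum / acc_n else NA_real_)
    })
  }

  eps_arr <- if (S > 0L)
    array(unlist(draws_eps), dim = c(S, K, length(draws_eps))) else NULL
  rownames(draws_mu) <- NULL; rownames(draws_sigma) <- NULL
  colnames(draws_mu) <- colnames(draws_sigma) <- model$kinds$name

  rhat <- c(apply_rhat(draws_mu, chain_id), apply_rhat(draws_sigma, chain_id))
  names(rhat) <- c(paste0("mu.", model$kinds$name),
                   paste0("sigma.", model$kinds$name))
  bad <- rhat[is.finite(rhat) & rhat > 1.1]
  if (length(bad))
    warning(sprintf("split-Rhat above 1.1 for: %s",
                    paste(names(bad), collapse = ", ")), call. = FALSE)

  structure(list(draws = list(mu = draws_mu, sigma = draws_sigma,
                              eps = eps_arr),
                 chain = chain_id, rhat = rhat,
                 accept = acc_all, model = model,
                 preset = preset, seed = seed),
            class = "hbfit")
}

## Split-Rhat per column of a draws matrix.
apply_rhat <- function(mat, chain_id) {
  apply(mat, 2, function(x) split_rhat(x, chain_id))
}

#' Split-R hat convergence diagnostic
#' @param x Vector of draws (chains concatenated).
#' @param chain_id Chain index per draw.
#' @return Potential scale reduction factor on split chains.
#' @export
split_rhat <- function(x, chain_id) {
  halves <- list()
  for (ch in unique(chain_id)) {
    xs <- x[chain_id == ch]
    h <- length(xs) %/% 2L
    if (h < 2L) return(NA_real_)
    halves <- c(halves, list(xs[seq_len(h)]), list(xs[(h + 1L):(2L * h)]))
  }
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  B <- n * var(means)
  W <- mean(vars)
  if (W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Natural-scale posterior means per subject and group
#'
#' Per-subject means average the transformed parameter over all stored
#' draws; group rows report the mean and SD across subjects of those
#' posterior means (the scale on which cohort parameter summaries are
#' reported), plus latent-scale group posterior means.
#'
#' @param fit An `hbfit` object.
#' @return A `posterior_summary` list: `subject` (data frame subject x
#'   parameter of natural-scale posterior means), `group` (data frame with
#'   natural mean/SD across subjects and latent `mu`/`sigma` posterior
#'   means), `model_id`, `rhat`.
#' @export
posterior_means <- function(fit) {
  stopifnot(inherits(fit, "hbfit"))
  kinds <- fit$model$kinds
  S <- fit$model$n_subjects
  D <- nrow(fit$draws$mu)
  acc <- matrix(0, S, nrow(kinds))
  for (d in seq_len(D)) {
    acc <- acc + natural_matrix(fit$draws$mu[d, ], fit$draws$sigma[d, ],
                                fit$draws$eps[, , d, drop = FALSE][, , 1],
                                kinds$kind)
  }
  subj <- as.data.frame(acc / D)
  names(subj) <- kinds$name
  subj <- cbind(subject = seq_len(S), subj)
  group <- data.frame(
    parameter = kinds$name,
    kind = kinds$kind,
    natural_mean = vapply(kinds$name, function(nm) mean(subj[[nm]]), numeric(1)),
    natural_sd = vapply(kinds$name, function(nm) sd(subj[[nm]]), numeric(1)),
    mu_latent = colMeans(fit$draws$mu),
    sigma_latent = colMeans(fit$draws$sigma),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(subject = subj, group = group,
                 model_id = fit$model$spec$model_id, rhat = fit$rhat),
            class = "posterior_summary")
}

#' Per-subject difference in model-based weighting between variants
#'
#' `omega` for the protection variant minus `omega` for the comparison
#' variant; positive values mean more model-based control under
#' protection.
#'
#' @param summary A [posterior_means()] result from an M3/M4 fit.
#' @param protection_label,other_label Variant labels.
#' @return Numeric vector, one difference per subject.
#' @export
omega_difference <- function(summary, protection_label = "protection",
                             other_label) {
  subj <- summary$subject
  pick <- function(lab) {
    cols <- grep(sprintf("^omega\\[%s(\\.|\\])", lab), names(subj), value = TRUE)
    if (!length(cols))
      stop(sprintf("no omega parameter for variant '%s'", lab), call. = FALSE)
    rowMeans(subj[, cols, drop = FALSE])  # average over stakes splits (M4)
  }
  pick(protection_label) - pick(other_label)
}

#' Pointwise log-likelihood matrix over posterior draws
#'
#' @param fit An `hbfit` object.
#' @param n_draws Number of stored draws to use (evenly thinned).
#' @return Matrix `[draw, trial]` of log pointwise predictive densities
#'   (analyzable trials, subject-major order; missed trials excluded).
#' @export
pointwise_loglik <- function(fit, n_draws = 400L) {
  D <- nrow(fit$draws$mu)
  use <- unique(round(seq(1, D, length.out = min(n_draws, D))))
  scored <- fit$model$flat$choice != 0L
  out <- matrix(NA_real_, length(use), sum(scored))
  for (i in seq_along(use)) {
    d <- use[i]
    pw <- fit$model$loglik(fit$draws$mu[d, ], fit$draws$sigma[d, ],
                           fit$draws$eps[, , d, drop = FALSE][, , 1],
                           pointwise = TRUE)
    out[i, ] <- pw[scored]
  }
  out
}
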