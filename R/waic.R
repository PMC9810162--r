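#' Watanabe-Akaike information criterion from pointwise log-likelihoods
#'
#' `lppd = sum_i log mean_s exp(ll[s, i])` (computed with a stable
#' log-sum-exp), `p_waic = sum_i var_s(ll[s, i])` using the sample (n - 1)
#' variance, and `waic = -2 * (lppd - p_waic)`.  Observations are trials,
#' matching the per-trial granularity of the likelihood; lower is better.
#'
#' @param pointwise Matrix `[draw, observation]` of log probabilities,
#'   with at least 2 draws.
#' @param model_id Optional label carried into the result.
#' @return A `waic_result` list: `waic`, `lppd`, `p_waic`, `pointwise`
#'   (per-observation `-2 * (lppd_i - p_i)` contributions), `n_obs`,
#'   `model_id`.
#' @export
waic <- function(pointwise, model_id = NULL) {
  if (!is.matrix(pointwise) || nrow(pointwise) < 2L)
    stop("pointwise must be a matrix with at least 2 draws", call. = FALSE)
  if (any(!is.finite(pointwise)))
    stop("pointwise log-likelihoods must be finite", call. = FALSE)
  S <- nrow(pointwise)
  m <- apply(pointwise, 2, max)
  lppd_i <- m + log(colMeans(exp(sweep(pointwise, 2, m, "-"))))
  p_i <- apply(pointwise, 2, var)
  structure(list(waic = -2 * (sum(lppd_i) - sum(p_i)),
                 lppd = sum(lppd_i), p_waic = sum(p_i),
                 pointwise = -2 * (lppd_i - p_i),
                 n_obs = ncol(pointwise), model_id = model_id),
            class = "waic_result")
}

#' Rank candidate models by WAIC
#'
#' @param results Named list of `waic_result` objects fit to the same
#'   observations.
#' @return Data frame in ascending WAIC order with `model_id`, `waic`,
#'   `lppd`, `p_waic`, `delta_waic` (vs. the best), `delta_pct` (delta as
#'   percent of the best score's magnitude) and `tie` (delta below
#'   numerical noise).
#' @export
rank_models <- function(results) {
  if (inherits(results, "waic_result")) results <- list(results)
  n_obs <- vapply(results, function(r) r$n_obs, numeric(1))
  if (length(unique(n_obs)) != 1L)
    stop("models were scored on different numbers of observations",
         call. = FALSE)
  ids <- vapply(seq_along(results), function(i) {
    id <- results[[i]]$model_id
    if (is.null(id)) names(results)[i] %||% paste0("model", i) else id
  }, character(1))
  w <- vapply(results, function(r) r$waic, numeric(1))
  ord <- order(w)
  out <- data.frame(model_id = ids[ord],
                    waic = w[ord],
                    lppd = vapply(results, function(r) r$lppd, numeric(1))[ord],
                    p_waic = vapply(results, function(r) r$p_waic, numeric(1))[ord],
                    stringsAsFactors = FALSE)
  out$delta_waic <- out$waic - out$waic[1]
  out$delta_pct <- 100 * out$delta_waic / abs(out$waic[1])
  out$tie <- out$delta_waic < 1e-8
  out$tie[1] <- FALSE
  if (nrow(out) > 1L && any(out$tie)) out$tie[1] <- TRUE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
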