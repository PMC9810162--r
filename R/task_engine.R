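#' @useDynLib protectRL, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom sd var coef lm quantile setNames
#' @importFrom utils read.csv write.csv
NULL

TASK_VARIANTS <- c("protection", "reward", "direct_reward", "punishment")

#' Default deterministic transition map
#'
#' Rows = first-stage state (1, 2), columns = dwelling slot (a, b),
#' entries = creature index (1 = X, 2 = Y).  Each state reaches both
#' creatures and the mapping is crossed between states, making the two
#' first-stage states implicitly equivalent.
#'
#' @return 2x2 integer matrix.
#' @export
default_transition_map <- function() {
  m <- rbind(c(1L, 2L), c(2L, 1L))
  dimnames(m) <- list(state = c("1", "2"), choice = c("a", "b"))
  m
}

#' Task configuration for one two-step task variant
#'
#' Describes one arm of a study: the outcome framing, trial counts, the
#' stakes manipulation, the payoff random-walk parameters, and the
#' deterministic transition structure mapping (first-stage state, dwelling)
#' to a second-stage creature.
#'
#' @param variant Outcome framing, one of `"protection"`, `"reward"`,
#'   `"direct_reward"`, `"punishment"`.
#' @param n_trials Total number of trials including practice.
#' @param n_practice Leading trials flagged as practice and dropped from all
#'   analyses.
#' @param stakes_values Ordered pair (low, high) of stakes amplifiers.
#' @param stakes_prob Probability that a trial is high stakes.
#' @param walk_sigma Step SD of the Gaussian payoff random walks.
#' @param walk_bounds Reflecting bounds of the walks.
#' @param init_ranges List with elements `low` and `high`: the integer
#'   intervals from which the two creatures' initial payoffs are drawn.
#' @param base_threat Maximum outcome units at stake per unit stakes.
#' @param transition_map 2x2 integer matrix, see [default_transition_map()].
#' @param miss_prob Probability that a simulated agent misses a trial
#'   (makes no response); 0 by default.
#' @return A `task_config` object (a validated list).
#' @export
task_config <- function(variant = "protection",
                        n_trials = 120L,
                        n_practice = 20L,
                        stakes_values = c(1L, 5L),
                        stakes_prob = 0.5,
                        walk_sigma = 2,
                        walk_bounds = c(0, 9),
                        init_ranges = list(low = c(0L, 4L), high = c(5L, 9L)),
                        base_threat = 9L,
                        transition_map = default_transition_map(),
                        miss_prob = 0) {
  variant <- match.arg(variant, TASK_VARIANTS)
  cfg <- list(variant = variant,
              n_trials = as.integer(n_trials),
              n_practice = as.integer(n_practice),
              stakes_values = as.integer(stakes_values),
              stakes_prob = stakes_prob,
              walk_sigma = walk_sigma,
              walk_bounds = as.numeric(walk_bounds),
              init_ranges = lapply(init_ranges, as.numeric),
              base_threat = as.integer(base_threat),
              transition_map = transition_map,
              miss_prob = miss_prob)
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  if (cfg$n_trials <= 0L)
    stop("n_trials must be positive", call. = FALSE)
  if (cfg$n_practice < 0L || cfg$n_practice >= cfg$n_trials)
    stop("n_practice must be a non-negative integer < n_trials", call. = FALSE)
  if (length(cfg$stakes_values) != 2L || cfg$stakes_values[1] >= cfg$stakes_values[2] ||
      any(cfg$stakes_values <= 0L))
    stop("stakes_values must be an ordered pair of positive integers (low < high)",
         call. = FALSE)
  if (cfg$stakes_prob < 0 || cfg$stakes_prob > 1)
    stop("stakes_prob must be a probability", call. = FALSE)
  if (cfg$walk_sigma < 0)
    stop("walk_sigma must be non-negative", call. = FALSE)
  b <- cfg$walk_bounds
  if (length(b) != 2L || b[1] >= b[2])
    stop("walk_bounds must be an increasing pair", call. = FALSE)
  ir <- cfg$init_ranges
  if (!all(c("low", "high") %in% names(ir)))
    stop("init_ranges needs elements 'low' and 'high'", call. = FALSE)
  rng_ok <- function(r) length(r) == 2L && r[1] <= r[2] && r[1] >= b[1] && r[2] <= b[2]
  if (!rng_ok(ir$low) || !rng_ok(ir$high))
    stop("init_ranges must lie inside walk_bounds", call. = FALSE)
  if (ir$low[2] >= ir$high[1])
    stop("init_ranges must be disjoint (low below high)", call. = FALSE)
  tm <- cfg$transition_map
  if (!is.matrix(tm) || !all(dim(tm) == c(2L, 2L)) ||
      !all(sort(tm[1, ]) == 1:2) || !all(sort(tm[2, ]) == 1:2))
    stop("transition_map must map each state onto both creatures (bijection per state)",
         call. = FALSE)
  invisible(cfg)
}

#' Scenario preset task configurations
#'
#' `"study1"` uses abbreviated sessions (120 trials, first 20 practice, so
#' 100 analyzable); `"study2"` and `"study3"` use long sessions (225 trials,
#' first 25 practice, so 200 analyzable).
#'
#' @param study One of `"study1"`, `"study2"`, `"study3"`.
#' @param variant Task variant; defaults to the study's two variants.
#' @return A single `task_config` if `variant` is given, otherwise a named
#'   list of the study's two configs (protection first).
#' @export
preset_config <- function(study = c("study1", "study2", "study3"),
                          variant = NULL) {
  study <- match.arg(study)
  n <- if (study == "study1") c(120L, 20L) else c(225L, 25L)
  variants <- switch(study,
                     study1 = c("protection", "reward"),
                     study2 = c("protection", "direct_reward"),
                     study3 = c("protection", "punishment"))
  mk <- function(v) task_config(variant = v, n_trials = n[1], n_practice = n[2])
  if (!is.null(variant)) {
    if (!variant %in% variants)
      stop(sprintf("variant '%s' is not part of %s", variant, study), call. = FALSE)
    return(mk(variant))
  }
  setNames(lapply(variants, mk), variants)
}

#' Reflect a value into an interval by iterated mirror folding
#'
#' Excursions beyond a bound are mirrored back (`v > hi` becomes
#' `2 * hi - v`, `v < lo` becomes `2 * lo - v`), repeatedly until the value
#' lies inside `[lo, hi]`.  This preserves the symmetry of the Gaussian step
#' distribution at the boundary.
#'
#' @param v Numeric vector.
#' @param lo,hi Interval bounds.
#' @return Folded values in `[lo, hi]`.
#' @export
reflect_fold <- function(v, lo = 0, hi = 9) {
  width <- hi - lo
  r <- (v - lo) %% (2 * width)
  r <- ifelse(r > width, 2 * width - r, r)
  lo + r
}

#' Advance a payoff random walk by one Gaussian step with reflection
#'
#' @param value Current value(s), inside the bounds.
#' @param sigma Step standard deviation (non-negative).
#' @param lo,hi Reflecting bounds.
#' @param noise Optional fixed step(s) instead of a random Gaussian draw
#'   (used for deterministic checks).
#' @return New value(s) in `[lo, hi]`.
#' @export
step_walk <- function(value, sigma, lo = 0, hi = 9, noise = NULL) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (is.null(noise)) noise <- rnorm(length(value), 0, sigma)
  reflect_fold(value + noise, lo, hi)
}

#' Generate the per-trial payoff walks for both creatures
#'
#' Initial payoffs are drawn uniformly, one creature in the low range
#' (0--4) and the other in the high range (5--9), with the low/high
#' assignment randomized.  Subsequent rows evolve by independent Gaussian
#' random walks with reflecting bounds.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the walk is deterministic given the seed.
#' @return A `payoff_walks` object: list with `values`
#'   (`n_trials` x 2 matrix, columns = creatures X and Y) and `seed`.
#' @export
init_payoff_walks <- function(config, seed) {
  validate_task_config(config)
  b <- config$walk_bounds
  with_seed(seed, {
    low_first <- runif(1) < 0.5
    ir <- config$init_ranges
    v_low <- runif(1, ir$low[1], ir$low[2])
    v_high <- runif(1, ir$high[1], ir$high[2])
    vals <- matrix(NA_real_, nrow = config$n_trials, ncol = 2,
                   dimnames = list(NULL, c("X", "Y")))
    vals[1, ] <- if (low_first) c(v_low, v_high) else c(v_high, v_low)
    if (config$n_trials > 1L) {
      for (t in 2:config$n_trials) {
        vals[t, ] <- step_walk(vals[t - 1, ], config$walk_sigma, b[1], b[2])
      }
    }
    structure(list(values = vals, seed = seed), class = "payoff_walks")
  })
}

#' Draw a stakes amplifier for one trial
#'
#' @param config A [task_config()].
#' @param n Number of trials to draw.
#' @return Integer vector of stakes values (low or high).
#' @export
draw_stakes <- function(config, n = 1L) {
  high <- runif(n) < config$stakes_prob
  ifelse(high, config$stakes_values[2], config$stakes_values[1])
}

#' Final-result arithmetic for a trial
#'
#' The stakes amplifier applies both to the maximum threat/reward available
#' and to the outcome units delivered.  In the protection framing the
#' delivered shields are subtracted from the amplified threat, so the final
#' result is `(base_threat - outcome_units) * stakes` flames; in the reward
#' framings the result is `outcome_units * stakes` points gained; in the
#' punishment framing it is `outcome_units * stakes` flames received.
#'
#' @param variant Task variant.
#' @param stakes Stakes amplifier for the trial.
#' @param outcome_units Outcome units delivered by the creature (0--9).
#' @param base_threat Maximum units at stake per unit stakes (9).
#' @return List with `value` (non-negative magnitude displayed: flames for
#'   aversive framings, points for reward framings), `unit`
#'   (`"flames"`/`"points"`), and `points_delta` (signed contribution to the
#'   bonus: losses negative).
#' @export
final_result <- function(variant, stakes, outcome_units, base_threat = 9L) {
  variant <- match.arg(variant, TASK_VARIANTS)
  if (any(outcome_units < 0 | outcome_units > base_threat))
    stop("outcome_units must lie in [0, base_threat]", call. = FALSE)
  switch(variant,
    protection = {
      flames <- (base_threat - outcome_units) * stakes
      list(value = flames, unit = "flames", points_delta = -flames)
    },
    punishment = {
      flames <- outcome_units * stakes
      list(value = flames, unit = "flames", points_delta = -flames)
    },
    {
      pts <- outcome_units * stakes
      list(value = pts, unit = "points", points_delta = pts)
    })
}

#' Build a probe schedule over the non-practice trials
#'
#' Exactly 25% of analyzable trials carry a certainty probe and a disjoint
#' 25% carry an outcome-estimate probe (exact-count random placement, so
#' the per-subject proportions are exact rather than binomial).
#'
#' @param n_trials Number of analyzable (non-practice) trials, at least 4.
#' @param prop Proportion per probe type.
#' @return Character vector of length `n_trials` with values `"certainty"`,
#'   `"estimate"` or `"none"`.
#' @export
make_probe_schedule <- function(n_trials, prop = 0.25) {
  if (n_trials < 4L) stop("n_trials must be at least 4", call. = FALSE)
  k <- floor(n_trials * prop)
  lab <- rep("none", n_trials)
  pick <- sample.int(n_trials, 2L * k)
  lab[pick[seq_len(k)]] <- "certainty"
  lab[pick[k + seq_len(k)]] <- "estimate"
  lab
}

## --- seed plumbing -------------------------------------------------------

#' Evaluate code under a fixed RNG seed, restoring the RNG state after
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Named substreams (walks, choices, ratings, sampler, ...) get distinct
#' deterministic seeds below 2^31 so components are independently
#' reproducible from a single master seed.
#'
#' @param seed Master seed.
#' @param ... Integers and/or strings identifying the substream.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
sub_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    h <- (h * 48271 + as.numeric(p) * 3767 + 1) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}
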