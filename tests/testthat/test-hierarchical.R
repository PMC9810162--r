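test_that("latent-to-natural transforms match the stated mapping", {
  expect_equal(transform_to_natural(0, "omega"), 0.5)
  expect_equal(transform_to_natural(0, "beta"), 10)
  expect_equal(transform_to_natural(50, "beta"), 20, tolerance = 1e-12)
  expect_equal(transform_to_natural(-Inf, "alpha"), 0)
  ## monotone increasing everywhere
  g <- seq(-5, 5, 0.5)
  for (k in c("omega", "beta"))
    expect_true(all(diff(transform_to_natural(g, k)) > 0))
})

test_that("model specs tie parameters as required", {
  v2 <- c("protection", "reward")
  expect_equal(nrow(param_kinds(model_spec("M1", v2))), 5L)
  expect_equal(nrow(param_kinds(model_spec("M2", v2))), 7L)
  expect_equal(nrow(param_kinds(model_spec("M3", v2))), 7L)
  expect_equal(nrow(param_kinds(model_spec("M4", v2))), 11L)
  pk <- param_kinds(model_spec("M4", v2))
  expect_equal(sum(pk$kind == "omega"), 4L)
  expect_equal(sum(pk$kind %in% c("lam", "pi", "beta")), 3L)
})

test_that("building a model rejects unknown variants and keeps trial counts", {
  co <- generate_study(cohort_scenario("study1",
          configs = list(protection = task_config("protection", 24, 4),
                         reward = task_config("reward", 24, 4))),
        seed = 1, n_subjects = 2)
  m <- build_model(co, model_spec("M1", c("protection", "reward")))
  expect_equal(m$n_trials, 2L * 2L * 20L)
  expect_error(build_model(co, model_spec("M3", "protection")),
               "not in model spec")
})

test_that("the non-centered identity holds: only mu + sigma * eps matters", {
  co <- generate_study(cohort_scenario("study1",
          configs = list(protection = task_config("protection", 24, 4),
                         reward = task_config("reward", 24, 4))),
        seed = 2, n_subjects = 3)
  m <- build_model(co, model_spec("M1", c("protection", "reward")))
  K <- m$n_params
  set.seed(5)
  mu <- rnorm(K); sigma <- abs(rnorm(K)); eps <- matrix(rnorm(3 * K), 3, K)
  ## shift mass between mu and eps leaving mu + sigma*eps unchanged
  delta <- rnorm(K)
  mu2 <- mu + sigma * delta
  eps2 <- sweep(eps, 2, delta, "-")
  expect_equal(m$loglik(mu, sigma, eps), m$loglik(mu2, sigma, eps2),
               tolerance = 1e-9)
})

test_that("a prior-only fit recovers the standard normal group prior", {
  m <- build_model(list(), model_spec("M1", "protection"))
  fit <- fit_hier(m, preset = "custom", chains = 2L, iter = 2000L, seed = 4)
  ## random-walk draws are autocorrelated: allow ~3 effective-sample SEs
  expect_lt(max(abs(colMeans(fit$draws$mu))), 0.3)
  expect_true(all(fit$draws$sigma >= 0))
})

test_that("posterior summaries respect natural bounds and label parameters", {
  co <- generate_study(cohort_scenario("study1",
          configs = list(protection = task_config("protection", 34, 4),
                         reward = task_config("reward", 34, 4))),
        seed = 3, n_subjects = 4)
  fit <- suppressWarnings(fit_hier(co, model_spec("M3", c("protection", "reward")),
                                   preset = "custom", chains = 1L,
                                   iter = 200L, seed = 1))
  pm <- posterior_means(fit)
  expect_setequal(setdiff(names(pm$subject), "subject"),
                  param_kinds(fit$model$spec)$name)
  for (nm in c("omega[protection]", "omega[reward]", "alpha[protection]",
               "lam", "pi"))
    expect_true(all(pm$subject[[nm]] >= 0 & pm$subject[[nm]] <= 1))
  expect_true(all(pm$subject$beta >= 0 & pm$subject$beta <= 20))
})

test_that("posterior means of degenerate draws return the constant", {
  skel <- suppressWarnings(fit_hier(
    generate_study(cohort_scenario("study1",
      configs = list(protection = task_config("protection", 24, 4),
                     reward = task_config("reward", 24, 4))),
      seed = 9, n_subjects = 2),
    model_spec("M1", c("protection", "reward")),
    preset = "custom", chains = 1L, iter = 60L, warmup = 30L, seed = 2))
  D <- nrow(skel$draws$mu)
  skel$draws$mu[] <- 0
  skel$draws$sigma[] <- 0
  skel$draws$eps[] <- 0
  pm <- posterior_means(skel)
  expect_equal(unname(unlist(pm$subject[1, c("omega[all]", "alpha[all]",
                                             "lam", "pi")])),
               rep(0.5, 4))
  expect_equal(pm$subject$beta, rep(10, 2))
})

test_that("omega differences subtract variant weights per subject", {
  fake <- list(subject = data.frame(subject = 1:3,
                                    `omega[protection]` = c(0.72, 0.5, 0.9),
                                    `omega[reward]` = c(0.14, 0.5, 0.2),
                                    check.names = FALSE))
  d <- omega_difference(fake, "protection", "reward")
  expect_equal(d, c(0.58, 0, 0.7))
  expect_equal(omega_difference(fake, "reward", "protection"), -d)
  expect_error(omega_difference(fake, "protection", "punishment"),
               "no omega")
})

test_that("group recovery is ordered for cohorts generated at low vs high omega", {
  fit_mean <- function(om, seed) {
    sc <- cohort_scenario("custom", n_subjects = 8,
      configs = list(protection = task_config("protection", 110, 10)),
      omega = list(protection = c(om, 0.1)),
      alpha = list(protection = c(0.5, 0.15)))
    co <- generate_study(sc, seed = seed)
    fit <- suppressWarnings(fit_hier(co, model_spec("M1", "protection"),
                                     preset = "custom", chains = 1L,
                                     iter = 500L, seed = seed))
    mean(posterior_means(fit)$subject[["omega[all]"]])
  }
  lo <- fit_mean(0.2, 61)
  hi <- fit_mean(0.7, 62)
  expect_lt(lo, hi)
})

test_that("two seeded desk runs of the same data agree on the group mean", {
  sc <- cohort_scenario("custom", n_subjects = 6,
    configs = list(protection = task_config("protection", 110, 10)),
    omega = list(protection = c(0.6, 0.15)),
    alpha = list(protection = c(0.5, 0.15)))
  co <- generate_study(sc, seed = 77)
  m <- build_model(co, model_spec("M1", "protection"))
  means <- sapply(c(101, 202), function(s) {
    fit <- suppressWarnings(fit_hier(m, preset = "custom", chains = 1L,
                                     iter = 800L, seed = s))
    mean(posterior_means(fit)$subject[["omega[all]"]])
  })
  expect_lt(abs(means[1] - means[2]), 0.1)
})
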