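test_that("design matrix has the expected structure", {
  rows <- default_study("rows")

  joint <- build_design(rows, model_spec("d_hr",
                                         doses = c("cum_pm25", "noise_dose")))
  nm <- colnames(joint$X)
  expect_true(all(c("cum_pm25", "noise_dose") %in% nm))
  expect_length(grep("^cum_pm25:P", nm), 3)
  expect_length(grep("^noise_dose:P", nm), 3)
  expect_setequal(joint$focal,
                  c("cum_pm25", "noise_dose",
                    paste0("cum_pm25:P", 2:4), paste0("noise_dose:P", 2:4)))

  # single participant: no dummies, no interactions
  one <- build_design(rows[rows$participant == 1, ],
                      model_spec("d_hr", doses = "cum_pm25"))
  expect_length(grep("^P", colnames(one$X)), 0)
  expect_equal(one$focal, "cum_pm25")

  # canonical sort makes the matrix invariant to input row order
  set.seed(11)
  shuffled <- rows[sample(nrow(rows)), ]
  again <- build_design(shuffled, model_spec("d_hr",
                                             doses = c("cum_pm25",
                                                       "noise_dose")))
  expect_identical(again$X, joint$X)
  expect_identical(again$y, joint$y)
  expect_identical(again$blocks, joint$blocks)
})

test_that("posterior means match least squares with theta 0, flat priors", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 120
    X <- cbind(1, rnorm(n), rnorm(n))
    colnames(X) <- c("(Intercept)", "x1", "x2")
    y <- as.numeric(X %*% c(2, 1, -0.5) + rnorm(n, 0, 1.5))
    fit <- fit_bayesian_lm(y, X, rep(1L, n),
                           sampler_config(chains = 2, iter = 1500,
                                          warmup = 500, seed = seed,
                                          prior_coef_scale = 1000,
                                          fix_theta = TRUE))
    ols <- qr.solve(qr(X), y)
    post_sd <- apply(fit$draws[, 1:3], 2, sd)
    expect_true(all(abs(fit$summary$estimate[1:3] - ols) < 2 * post_sd))
    expect_true(all(fit$summary$rhat[1:3] <= 1.05))
  }
})

test_that("posterior concentrates on the truth when noise is tiny", {
  set.seed(6)
  n <- 100
  X <- cbind(1, rnorm(n))
  colnames(X) <- c("(Intercept)", "x")
  y <- as.numeric(X %*% c(1, 2) + rnorm(n, 0, 1e-3))
  fit <- fit_bayesian_lm(y, X, rep(1L, n),
                         sampler_config(chains = 2, iter = 1500,
                                        warmup = 500, seed = 1))
  sm <- fit$summary[fit$summary$term == "x", ]
  expect_lt(sm$ci_high - sm$ci_low, 0.01)
  expect_equal(sm$estimate, 2, tolerance = 1e-2, ignore_attr = TRUE)
})

test_that("scaling y scales coefficient draws exactly", {
  set.seed(4)
  n <- 60
  X <- cbind(1, rnorm(n))
  colnames(X) <- c("(Intercept)", "x")
  y <- as.numeric(X %*% c(1, 2) + rnorm(n))
  cfg <- sampler_config(chains = 1, iter = 600, warmup = 200, seed = 9)
  f1 <- fit_bayesian_lm(y, X, rep(1L, n), cfg)
  f2 <- fit_bayesian_lm(5 * y, X, rep(1L, n), cfg)
  expect_equal(f2$draws[, "x"], 5 * f1$draws[, "x"], tolerance = 1e-12)
  expect_equal(f2$draws[, "sigma"], 5 * f1$draws[, "sigma"],
               tolerance = 1e-12)
})

test_that("rerunning with the same seed reproduces draws bit-identically", {
  set.seed(14)
  n <- 80
  X <- cbind(1, rnorm(n))
  colnames(X) <- c("(Intercept)", "x")
  y <- as.numeric(X %*% c(0, 1) + rnorm(n))
  cfg <- sampler_config(chains = 2, iter = 500, warmup = 200, seed = 77)
  f1 <- fit_bayesian_lm(y, X, rep(1L, n), cfg)
  f2 <- fit_bayesian_lm(y, X, rep(1L, n), cfg)
  expect_identical(f1$draws, f2$draws)
})

test_that("the MA(1) coefficient is recovered from simulated data", {
  set.seed(33)
  n <- 400
  x <- rnorm(n)
  eta <- rnorm(n)
  y <- 1 + 0.5 * x + eta + 0.6 * c(0, eta[-n])
  X <- cbind(1, x)
  colnames(X) <- c("(Intercept)", "x")
  fit <- fit_bayesian_lm(y, X, rep(1L, n),
                         sampler_config(chains = 2, iter = 2000,
                                        warmup = 500, seed = 2))
  sm <- fit$summary[fit$summary$term == "theta", ]
  expect_lt(sm$ci_low, 0.6)
  expect_gt(sm$ci_high, 0.45)
  expect_gt(sm$estimate, 0.4)
})

test_that("Savage-Dickey estimator matches the conjugate closed form", {
  set.seed(3)
  tau <- 1; s <- 2; n <- 20
  y <- rnorm(n, 0.6, s)
  post <- conjugate_normal_posterior(y, tau, s)
  draws <- rnorm(12000, post$mean, sqrt(post$var))
  bf <- as.numeric(savage_dickey_bf(dnorm(0, 0, tau), draws))
  expect_lt(abs(bf / post$bf10 - 1), 0.05)

  # posterior identical to the prior: no information, BF10 = 1
  set.seed(5)
  prior_draws <- rnorm(12000, 0, tau)
  bf1 <- as.numeric(savage_dickey_bf(dnorm(0, 0, tau), prior_draws))
  expect_equal(bf1, 1, tolerance = 0.05)

  # posterior centred 5 posterior SDs away from 0: strong evidence
  far <- rnorm(12000, 5 * sqrt(post$var), sqrt(post$var))
  bf_far <- as.numeric(savage_dickey_bf(dnorm(0, 0, tau), far))
  expect_gt(bf_far, 10)
})

test_that("model suites report the focal dose and interaction terms", {
  rows <- default_study("rows")
  cfg <- sampler_config(chains = 2, iter = 600, warmup = 200, seed = 1)
  suite <- run_model_suite(rows, "pm25", cfg, outcomes = c("d_hr", "d_sdnn"))
  expect_equal(nrow(suite$report), 2 * 4)  # 1 main + 3 interactions each
  expect_true(all(c("estimate", "ci_low", "ci_high", "bf10", "rhat", "ess")
                  %in% names(suite$report)))
  expect_true(all(suite$report$bf10 > 0))
  expect_true(all(suite$report$ci_low <= suite$report$ci_high))
})
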