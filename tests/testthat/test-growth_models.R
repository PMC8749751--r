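test_that("the four curves match their reference values and shapes", {
  # reference parameter sets evaluated at age 0 (lengths at birth)
  expect_equal(round(predict_length(
    growth_params("LG3", 69.79, 0.444, 1.500), 0), 2), 23.69)
  expect_equal(predict_length(
    growth_params("GG3", 73.36, 0.305, 1.030), 0), 18.65, tolerance = 0.01)
  expect_equal(predict_length(
    growth_params("VBG2", 75.59, 0.213, l0 = 14.5), 0), 14.5)
  # VBG3 is zero at t0 by definition
  p <- growth_params("VBG3", 81.87, 0.168, -1.384)
  expect_equal(predict_length(p, -1.384), 0)

  # strictly increasing, asymptoting at L_inf
  ages <- seq(0, 30, by = 0.25)
  for (gp in list(p,
                  growth_params("VBG2", 75.59, 0.213, l0 = 14.5),
                  growth_params("GG3", 73.36, 0.305, 1.030),
                  growth_params("LG3", 69.79, 0.444, 1.500))) {
    l <- predict_length(gp, ages)
    expect_true(all(diff(l) > 0), info = gp$model)
    expect_equal(predict_length(gp, 1e3), gp$linf, tolerance = 1e-6)
  }
  expect_error(growth_params("GG3", 70, 0.3), "t0")
})

test_that("analytic sigma equals the 1-D likelihood minimiser", {
  expect_equal(sigma_analytic(c(50, 60), c(50, 60)), 0)
  obs <- c(50 * exp(0.1), 60 * exp(-0.1))
  expect_equal(sigma_analytic(obs, c(50, 60)), 0.1, tolerance = 1e-12)
  expect_error(sigma_analytic(c(-1, 2), c(1, 2)), "positive")

  # oracle: numeric minimisation of the full lognormal NLL over sigma
  set.seed(81)
  pred <- runif(40, 30, 80)
  obs2 <- pred * exp(rnorm(40, 0, 0.08))
  full_nll <- function(s) {
    sum(log(s) + 0.5 * log(2 * pi) +
          (log(obs2) - log(pred))^2 / (2 * s^2))
  }
  s_num <- optimize(full_nll, c(1e-4, 1), tol = 1e-10)$minimum
  expect_equal(sigma_analytic(obs2, pred), s_num, tolerance = 1e-6)
})

test_that("the concentrated NLL satisfies its closed forms and invariances", {
  p <- default_truth()
  ages <- c(2, 9)
  pred <- predict_length(p, ages)
  obs <- pred * exp(c(1, -1))  # sigma hat = 1
  r <- negative_log_likelihood(p, ages, obs)
  expect_equal(r$sigma, 1)
  expect_equal(r$nll, log(2 * pi) + 1, tolerance = 1e-12)  # 2.8379
  expect_equal(round(r$nll, 4), 2.8379)
  expect_equal(r$loglik, -r$nll)

  # identity -logL = n (ln 2pi / 2 + ln sigma + 1/2) on arbitrary data
  set.seed(82)
  ages2 <- runif(100, 0.5, 14)
  obs3 <- predict_length(p, ages2) * exp(rnorm(100, 0, 0.06))
  r2 <- negative_log_likelihood(p, ages2, obs3)
  n <- 100
  expect_equal(r2$nll, n * (log(2 * pi) / 2 + log(r2$sigma) + 0.5),
               tolerance = 1e-8)

  # invariant to reordering observations
  o <- sample(n)
  r3 <- negative_log_likelihood(p, ages2[o], obs3[o])
  expect_equal(r3$nll, r2$nll, tolerance = 1e-12)

  # concentrated value equals the joint (params, sigma) minimum
  joint <- optimize(function(s) {
    sum(log(s) + 0.5 * log(2 * pi) + log(obs3) * 0 +
          (log(obs3) - log(predict_length(p, ages2)))^2 / (2 * s^2))
  }, c(1e-4, 1))$objective
  expect_equal(r2$nll, joint, tolerance = 1e-6)

  # degenerate (perfect) fit is an error
  expect_error(negative_log_likelihood(p, ages2, predict_length(p, ages2)),
               "degenerate")
})

test_that("fit_model recovers noise-free parameters and beats a grid search", {
  truth <- growth_params("VBG3", 80, 0.2, -1.2)
  d <- exact_curve_data(truth, ages = seq(0.5, 14, length.out = 20))
  f <- fit_model("VBG3", d$age, d$length, seed = 1)
  expect_true(f$converged)
  expect_equal(f$params$linf, 80, tolerance = 1e-4)
  expect_equal(f$params$k, 0.2, tolerance = 1e-4)
  expect_equal(f$params$t0, -1.2, tolerance = 1e-4)

  # small noisy dataset: no point of a 30^3 grid beats the optimizer
  set.seed(83)
  d2 <- simulate_age_length(120, truth, 0.08, seed = 84)
  f2 <- fit_model("VBG3", d2$age, d2$length, seed = 1)
  grid_nll <- Inf
  for (li in seq(70, 95, length.out = 30)) {
    for (kk in seq(0.05, 0.5, length.out = 30)) {
      for (tt in seq(-4, 1, length.out = 30)) {
        gp <- growth_params("VBG3", li, kk, tt)
        pred <- predict_length(gp, d2$age)
        if (all(pred > 0)) {
          s <- sigma_analytic(d2$length, pred)
          nll <- 120 * (log(2 * pi) / 2 + log(s) + 0.5)
          if (nll < grid_nll) grid_nll <- nll
        }
      }
    }
  }
  expect_lte(f2$nll, grid_nll)

  # model-selection premise: the wrong family fits worse on the same data
  f_lg <- fit_model("LG3", d2$age, d2$length, seed = 1)
  expect_gt(f_lg$nll, f2$nll)

  # determinism given seed and data
  f2b <- fit_model("VBG3", d2$age, d2$length, seed = 1)
  expect_identical(f2$params, f2b$params)

  expect_error(fit_model("VBG3", 1:3, c(50, 60, 70)), "p \\+ 1")
})

test_that("VBG2 fixes the birth length and fits with two free parameters", {
  truth2 <- growth_params("VBG2", 76, 0.21, l0 = 14.5)
  d <- exact_curve_data(truth2)
  f <- fit_model("VBG2", d$age, d$length, seed = 1)
  expect_equal(f$p, 2L)
  expect_equal(f$params$linf, 76, tolerance = 1e-4)
  expect_equal(f$params$k, 0.21, tolerance = 1e-4)
  expect_equal(predict_length(f$params, 0), 14.5)
})
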