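test_that("profile engine inverts a quadratic deviance exactly", {
  # quadratic log-likelihood with curvature c: dev(x) = c (x - m)^2,
  # 95% CI = m +/- 1.96 / sqrt(c)
  for (cc in c(0.5, 1, 4)) {
    m <- 2.3
    ci <- profile_deviance_ci(function(x) cc * (x - m)^2, mle = m,
                              step = 0.5 / sqrt(cc), tol = 1e-6)
    expect_lt(abs(ci$lower - (m - 1.96 / sqrt(cc))), 1e-3)
    expect_lt(abs(ci$upper - (m + 1.96 / sqrt(cc))), 1e-3)
    expect_true(ci$lower_bounded && ci$upper_bounded)
  }
  # flat lower side is flagged as one-sided; upper side still bracketed
  expect_warning(
    one <- profile_deviance_ci(function(x) pmax(x, 0)^2 * 100, mle = 0,
                               step = 0.1, max_steps = 5L),
    "one-sided")
  expect_false(one$lower_bounded)
  expect_true(one$upper_bounded)
})

test_that("chi-square thresholds match the conventional cutoffs", {
  expect_equal(round(qchisq(0.95, 1), 2), 3.84)
  expect_equal(round(qchisq(0.95, 2), 2), 5.99)
})

test_that("profile and contour CIs behave on a fitted model", {
  set.seed(91)
  d <- simulate_age_length(400, default_truth(), 0.06, seed = 92)
  f <- fit_model("VBG3", d$age, d$length, seed = 1)
  ci <- profile_ci(f, "t0")
  expect_lte(ci$lower, f$params$t0)
  expect_gte(ci$upper, f$params$t0)

  cc <- contour_ci(f, n_grid = 41)
  # the MLE cell is the grid centre: deviance 0 there
  expect_lt(min(cc$grid$deviance), 1e-4)
  expect_false(cc$touches_boundary)
  expect_true(cc$linf_ci[1] < f$params$linf && cc$linf_ci[2] > f$params$linf)

  # contour marginal bounds contain the 1-df profile bounds (2-df threshold
  # is wider in every marginal direction)
  pli <- profile_ci(f, "linf")
  pk <- profile_ci(f, "k")
  expect_lte(cc$linf_ci[1], pli$lower + 1e-6)
  expect_gte(cc$linf_ci[2], pli$upper - 1e-6)
  expect_lte(cc$k_ci[1], pk$lower + 1e-4)
  expect_gte(cc$k_ci[2], pk$upper - 1e-4)
})

test_that("grid region engine recovers the analytic Gaussian ellipse area", {
  # bivariate Gaussian toy deviance: x' Sigma^-1 x; 95% region area is
  # pi * 5.99 * sqrt(det Sigma)
  s1 <- 1.5; s2 <- 0.4; rho <- 0.6
  Sig <- matrix(c(s1^2, rho * s1 * s2, rho * s1 * s2, s2^2), 2)
  Si <- solve(Sig)
  dev_fn <- function(x, y) {
    v <- c(x, y)
    drop(v %*% Si %*% v)
  }
  half1 <- sqrt(5.99) * s1 * 1.2
  half2 <- sqrt(5.99) * s2 * 1.2
  reg <- grid_deviance_region(dev_fn, seq(-half1, half1, length.out = 161),
                              seq(-half2, half2, length.out = 161), 5.99)
  analytic <- pi * 5.99 * sqrt(det(Sig))
  expect_equal(reg$area, analytic, tolerance = 0.03)
  expect_false(reg$touches_boundary)
  # bounding box equals the marginal +/- sqrt(threshold) * sd
  expect_equal(reg$x_ci, c(-1, 1) * sqrt(5.99) * s1, tolerance = 0.05)
  expect_equal(reg$y_ci, c(-1, 1) * sqrt(5.99) * s2, tolerance = 0.05)
})

test_that("profile CI width shrinks as n grows", {
  widths <- vapply(c(100, 400, 1600), function(n) {
    d <- simulate_age_length(n, default_truth(), 0.06, seed = 93)
    f <- fit_model("VBG3", d$age, d$length, seed = 1)
    ci <- profile_ci(f, "t0")
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("AIC arithmetic, weights and support classes match closed forms", {
  t4 <- load_fixture("table4")
  # delta for the unadjusted Gompertz row from printed AICs
  unadj <- t4[t4$dataset == "unadjusted", ]
  delta_gg3 <- unadj$aic[unadj$model == "GG3"] - min(unadj$aic)
  expect_equal(delta_gg3, 41.14, tolerance = 1e-9)

  # adjusted-DC weights from printed AICs
  dc <- t4[t4$dataset == "adjusted_dc", ]
  w <- akaike_weights(dc$aic)
  expect_equal(round(w, 2), c(1, 0, 0, 0)[order(order(dc$aic))])
  expect_equal(sum(w), 1, tolerance = 1e-12)

  expect_equal(akaike_weights(c(100, 102)), c(0.7311, 0.2689),
               tolerance = 1e-4)
  expect_equal(akaike_weights(5), 1)
  # invariant to a constant shift; monotone decreasing in delta
  a <- c(10, 12, 19, 31)
  expect_equal(akaike_weights(a), akaike_weights(a + 57), tolerance = 1e-12)
  expect_true(all(diff(akaike_weights(sort(a))) <= 0))

  expect_equal(report_support_class(c(0, 2, 3, 5, 8, 41.14)),
               c("substantial", "substantial", "intermediate", "less",
                 "intermediate", "none"))
  expect_error(report_support_class(-1), ">= 0")
})

test_that("aic_table ranks fits and rejects mismatched data", {
  d <- simulate_age_length(300, default_truth(), 0.06, seed = 94)
  fits <- lapply(c("VBG3", "VBG2", "GG3", "LG3"), function(m)
    fit_model(m, d$age, d$length, seed = 1))
  tab <- aic_table(fits)
  expect_equal(tab$delta[1], 0)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-9)
  expect_equal(tab$aic, 2 * tab$p - 2 * tab$loglik, tolerance = 1e-12)
  expect_true(all(diff(tab$aic) >= 0))
  expect_equal(tab$model[1], "VBG3")  # generating family wins

  d2 <- simulate_age_length(300, default_truth(), 0.06, seed = 95)
  f_other <- fit_model("VBG3", d2$age, d2$length, seed = 1)
  expect_error(aic_table(list(fits[[1]], f_other)), "identical data")
})
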