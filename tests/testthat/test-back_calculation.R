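test_that("radius-length regression recovers exact and noisy lines", {
  tl <- seq(40, 84, by = 2)
  s <- specimen_table(paste0("S", seq_along(tl)),
                      rep(c("female", "male"), length.out = length(tl)),
                      tl, 2014L, 6L, -0.65 + 0.08 * tl,
                      band_radii = lapply(tl, function(x) 0.7),
                      edge_type = "unknown")
  reg <- suppressWarnings(fit_radius_length(s, group_by_sex = FALSE))  # exact line
  expect_equal(reg$a, -0.65, tolerance = 1e-9)
  expect_equal(reg$b, 0.08, tolerance = 1e-9)
  expect_equal(reg$r_squared, 1, tolerance = 1e-9)

  # per-sex fits with noise: slope within 3 SE of truth
  set.seed(71)
  tl2 <- runif(200, 40, 84)
  s2 <- specimen_table(paste0("T", 1:200), "female", tl2, 2014L, 6L,
                       pmax(-0.65 + 0.08 * tl2 + rnorm(200, 0, 0.2), 0.5),
                       band_radii = lapply(tl2, function(x) 0.4),
                       edge_type = "unknown")
  reg2 <- fit_radius_length(s2, group_by_sex = TRUE)$female
  se_b <- summary(reg2$fit)$coefficients["total_length", "Std. Error"]
  expect_lt(abs(reg2$b - 0.08), 3 * se_b)
  expect_lt(reg2$slope_p, 1e-6)

  # degenerate input
  s3 <- specimen_table(c("U1", "U2", "U3"), "female", c(50, 50, 50), 2014L,
                       6L, 3.5, band_radii = list(0.7, 0.7, 0.7),
                       edge_type = "unknown")
  expect_error(fit_radius_length(s3, group_by_sex = FALSE), "degenerate")
})

test_that("slope/elevation comparison separates its two stages", {
  set.seed(72)
  tl <- runif(400, 40, 84)
  sex <- rep(c("female", "male"), each = 200)
  make_s <- function(vr) {
    specimen_table(paste0("V", seq_along(tl)), sex, tl, 2014L, 6L,
                   pmax(vr, 0.1), band_radii = lapply(tl, function(x) 0.05),
                   edge_type = "unknown")
  }
  # identical generating process in both groups: nothing significant
  same <- make_s(-0.65 + 0.08 * tl + rnorm(400, 0, 0.1))
  r_same <- compare_regressions(same)
  expect_true(r_same$slopes_equal)
  expect_gt(r_same$elevation_p, 0.05)

  # different slopes: stage 1 rejects, stage 2 refused
  slope <- ifelse(sex == "female", 0.08, 0.12)
  r_slope <- compare_regressions(make_s(-0.65 + slope * tl + rnorm(400, 0, 0.1)))
  expect_false(r_slope$slopes_equal)
  expect_true(is.na(r_slope$elevation_p))

  # equal slopes, intercept offset 0.3 mm: elevation test rejects
  icept <- ifelse(sex == "female", -0.65, -0.35)
  r_elev <- compare_regressions(make_s(icept + 0.08 * tl + rnorm(400, 0, 0.1)))
  expect_true(r_elev$slopes_equal)
  expect_lt(r_elev$elevation_p, 0.05)
})

test_that("Francis back-calculation matches hand arithmetic and its limits", {
  a <- -0.65; b <- 0.08
  expect_equal(back_calculate(80, 5.75, 5.75, a, b), 80)      # anchor at capture
  expect_equal(back_calculate(80, 5.75, 2.875, a, b), 44.0625)
  expect_equal(back_calculate(80, 5.75, 1e-9, a, b), -a / b,  # 8.125 cm
               tolerance = 1e-6)
  expect_error(back_calculate(80, 5.75, 6.0, a, b), "outside")
  expect_error(back_calculate(80, 5.75, 2.9, a, 0), "non-zero")

  # monotone in vr_i
  vr_i <- seq(0.5, 5.75, length.out = 20)
  expect_true(all(diff(back_calculate(80, 5.75, vr_i, a, b)) > 0))
})

test_that("expand_dataset counts records and is exact under the noise-free generator", {
  s <- tiny_specimens()
  reg <- list(a = -0.65, b = 0.08)
  d <- expand_dataset(s, age_scheme("adjusted_dc"), reg,
                      sexes = c("female", "male"))
  # specimen A: 3 post-birth bands -> 4 back-calculated + 1 observed
  expect_equal(sum(d$specimen_id == "A"), 5)
  expect_equal(nrow(d), sum(n_bands(s) + 1) + nrow(s))
  expect_equal(sum(d$source == "observed"), nrow(s))
  # per-specimen back-calculated lengths non-decreasing across bands
  for (id in s$specimen_id) {
    bc <- d[d$specimen_id == id & d$source == "back_calculated", ]
    expect_true(all(diff(bc$length[order(bc$band_index)]) >= 0))
  }

  # noise-free generator: back-calculated lengths equal true lengths at
  # band ages to 1e-9
  cfg <- synthetic_config(n_specimens = 50L, sigma_length = 0, radius_sd = 0)
  pop <- generate_population(cfg, seed = 13)
  reg2 <- suppressWarnings(fit_radius_length(pop$specimens, group_by_sex = FALSE))
  d2 <- expand_dataset(pop$specimens, age_scheme("adjusted_dc"), reg2,
                       sexes = c("female", "male"))
  bc2 <- d2[d2$source == "back_calculated", ]
  true_len <- unlist(pop$truth$band_lengths)
  ord <- order(match(bc2$specimen_id, pop$truth$specimen_id), bc2$band_index)
  expect_equal(bc2$length[ord], true_len, tolerance = 1e-9)

  # age-0 record count equals the specimen count (one birth band each)
  expect_equal(sum(d2$assigned_age == 0), 50)
})
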