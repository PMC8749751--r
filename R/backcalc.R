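#' Radius--length regression
#'
#' Ordinary least squares of vertebral radius (mm) on total length (cm),
#' `VR = a + b * TL`, optionally per sex. This orientation (radius on length)
#' is the one required by the scale-proportional back-calculation formula of
#' [back_calculate()], whose intercept term is `-(a/b)`.
#'
#' @param specimens validated specimen table.
#' @param group_by_sex fit separate regressions per sex (default `TRUE`).
#' @return a list of regression summaries (one per group), each with `group`,
#'   `a`, `b`, `r_squared`, `n`, `slope_p`, and the underlying `lm` fit;
#'   a single summary if `group_by_sex = FALSE`.
#' @export
fit_radius_length <- function(specimens, group_by_sex = TRUE) {
  fit_one <- function(s, label) {
    if (nrow(s) < 3) stop("need >= 3 specimens in group '", label, "'")
    if (stats::sd(s$total_length) == 0) {
      stop("degenerate regression: constant total_length in group '", label, "'")
    }
    fit <- stats::lm(vertebral_radius ~ total_length, data = s)
    sm <- summary(fit)
    list(group = label,
         a = unname(stats::coef(fit)[1]),
         b = unname(stats::coef(fit)[2]),
         r_squared = sm$r.squared,
         n = nrow(s),
         slope_p = sm$coefficients["total_length", "Pr(>|t|)"],
         fit = fit)
  }
  if (!group_by_sex) return(fit_one(specimens, "all"))
  sexes <- sort(unique(specimens$sex))
  out <- lapply(sexes, function(sx) {
    fit_one(specimens[specimens$sex == sx, , drop = FALSE], sx)
  })
  names(out) <- sexes
  out
}

#' Compare radius--length regressions between two groups
#'
#' ANCOVA-style two-stage comparison: stage 1 tests equality of slopes via
#' the length-by-group interaction; if slopes do not differ, stage 2 tests
#' equality of elevations (intercepts) under a common pooled slope. When
#' stage 1 rejects at `alpha`, the elevation test is not interpretable and is
#' reported as `NA` with an explanation.
#'
#' @param specimens validated specimen table containing exactly two groups
#'   under `group_col`.
#' @param group_col grouping column, default `"sex"`.
#' @param alpha significance level gating stage 2 (default 0.05).
#' @return list with `slope_p`, `slopes_equal`, `elevation_p`, `note`.
#' @export
compare_regressions <- function(specimens, group_col = "sex", alpha = 0.05) {
  g <- factor(specimens[[group_col]])
  if (nlevels(g) != 2) stop("need exactly two groups to compare")
  d <- data.frame(vr = specimens$vertebral_radius,
                  tl = specimens$total_length, g = g)
  full <- stats::lm(vr ~ tl * g, data = d)
  slope_p <- stats::anova(full)["tl:g", "Pr(>F)"]
  if (is.finite(slope_p) && slope_p < alpha) {
    return(list(slope_p = slope_p, slopes_equal = FALSE,
                elevation_p = NA_real_,
                note = "slopes differ; elevation test not interpretable"))
  }
  common <- stats::lm(vr ~ tl + g, data = d)
  elev_p <- stats::anova(common)["g", "Pr(>F)"]
  list(slope_p = slope_p, slopes_equal = TRUE, elevation_p = elev_p,
       note = "slopes homogeneous; elevations tested under pooled slope")
}

#' Francis proportion-based back-calculation
#'
#' Length at the time band `i` was deposited, under the scale-proportional
#' hypothesis with a radius-on-length regression `VR = a + b * TL`:
#' `L_i = -(a/b) + (L_c + a/b) * (VR_i / VR_c)`.
#' Exact at capture (`VR_i = VR_c` gives `L_c`); the `VR_i -> 0` limit is
#' `-(a/b)`, the length at which the regression predicts a zero radius.
#'
#' @param l_c length at capture, cm.
#' @param vr_c vertebral radius at capture, mm.
#' @param vr_i radius of band `i`, mm, in `(0, vr_c]`.
#' @param a,b radius-on-length regression coefficients (`b != 0`).
#' @return back-calculated length, cm. Vectorised over `vr_i`.
#' @export
back_calculate <- function(l_c, vr_c, vr_i, a, b) {
  if (any(b == 0)) stop("b must be non-zero")
  if (any(vr_c <= 0)) stop("vr_c must be positive")
  if (any(vr_i <= 0)) stop("vr_i must be positive")
  if (any(vr_i > vr_c + 1e-9)) stop("band radius outside centrum (vr_i > vr_c)")
  -(a / b) + (l_c + a / b) * (vr_i / vr_c)
}

#' Expand specimens into the combined age--length fitting dataset
#'
#' Per specimen: one back-calculated record per band (birth band included,
#' age from [age_for_band()], length from [back_calculate()]) plus one
#' observed record (age from [assign_age()], length = TL at capture), for a
#' total of `sum(bands + 1) + n_specimens` records. This combined set of
#' back-calculated and sampled lengths is the input to growth fitting;
#' growth is conventionally fitted to females only (males being scarce),
#' hence the `sexes` default.
#'
#' @param specimens validated specimen table.
#' @param scheme an [age_scheme()].
#' @param regression a single-group regression summary from
#'   [fit_radius_length()] (fields `a`, `b`).
#' @param sexes which sexes to include (default `"female"`).
#' @param include_observed include the capture records (default `TRUE`);
#'   disable for back-calculated-only sensitivity fits.
#' @return data.frame `(specimen_id, band_index, assigned_age,
#'   length, source)` with `source` in `{"back_calculated", "observed"}`.
#' @export
expand_dataset <- function(specimens, scheme, regression,
                           sexes = "female", include_observed = TRUE) {
  s <- specimens[specimens$sex %in% sexes, , drop = FALSE]
  nb <- lengths(s$band_radii)
  skip <- nb == 0
  if (any(skip)) {
    warning(sum(skip), " specimen(s) without band radii skipped")
    s <- s[!skip, , drop = FALSE]
  }
  if (nrow(s) == 0) stop("no specimens to expand")
  a <- regression$a
  b <- regression$b
  recs <- lapply(seq_len(nrow(s)), function(i) {
    radii <- s$band_radii[[i]]
    idx <- seq_along(radii) - 1L  # 0 = birth band
    bc_len <- back_calculate(s$total_length[i], s$vertebral_radius[i],
                             radii, a, b)
    bc <- data.frame(specimen_id = s$specimen_id[i], band_index = idx,
                     assigned_age = age_for_band(idx, scheme),
                     length = bc_len, source = "back_calculated",
                     stringsAsFactors = FALSE)
    if (!include_observed) return(bc)
    obs_age <- assign_age(length(radii) - 1L, s$capture_month[i], scheme)
    rbind(bc, data.frame(specimen_id = s$specimen_id[i], band_index = NA_integer_,
                         assigned_age = obs_age, length = s$total_length[i],
                         source = "observed", stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
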