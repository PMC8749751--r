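#' Profile-deviance confidence interval (generic engine)
#'
#' Given a one-parameter deviance function `dev_fn(theta)` (twice the drop in
#' log-likelihood from its maximum, so `dev_fn(mle) = 0`), walk outward from
#' the MLE in steps of `step` until the deviance crosses `threshold`, then
#' bracket the crossing by bisection to within `tol`. The default threshold
#' 3.84 is the 95% quantile of chi-square with 1 df.
#'
#' If the deviance never crosses the threshold within `max_steps` on one
#' side, that bound is returned as the last evaluated point with a warning
#' (one-sided interval).
#'
#' @param dev_fn function of one numeric argument returning the deviance.
#' @param mle the maximising parameter value.
#' @param step initial outward step size.
#' @param threshold deviance cutoff (default `qchisq(0.95, 1)` rounded
#'   convention, 3.84).
#' @param tol bisection tolerance on the parameter (default 1e-4).
#' @param max_steps maximum outward steps per side (default 200).
#' @return list with `lower`, `upper`, `mle`, `threshold`,
#'   `lower_bounded`, `upper_bounded`.
#' @export
profile_deviance_ci <- function(dev_fn, mle, step, threshold = 3.84,
                                tol = 1e-4, max_steps = 200L) {
  stopifnot(step > 0, threshold > 0)
  one_side <- function(dir) {
    x_in <- mle
    for (i in seq_len(max_steps)) {
      x_out <- mle + dir * i * step
      d <- dev_fn(x_out)
      if (is.finite(d) && d >= threshold) {
        # bisect the crossing between x_in (below) and x_out (at/above)
        lo <- x_in
        hi <- x_out
        while (abs(hi - lo) > tol) {
          mid <- (lo + hi) / 2
          if (dev_fn(mid) >= threshold) hi <- mid else lo <- mid
        }
        return(list(bound = (lo + hi) / 2, bounded = TRUE))
      }
      x_in <- x_out
    }
    warning("profile deviance did not cross threshold within search range; ",
            "one-sided interval")
    list(bound = x_in, bounded = FALSE)
  }
  lo <- one_side(-1)
  hi <- one_side(+1)
  list(lower = lo$bound, upper = hi$bound, mle = mle, threshold = threshold,
       lower_bounded = lo$bounded, upper_bounded = hi$bounded)
}

# minimum NLL with one growth parameter held fixed, nuisance parameters
# re-optimized from the MLE (true profile, not a slice)
.refit_fixed <- function(fit, parameter, value) {
  model <- fit$model
  obj_full <- .growth_objective(model, fit$ages, fit$lengths, fit$l0)
  mle <- c(log(fit$params$linf), log(fit$params$k),
           if (model != "VBG2") fit$params$t0)
  idx <- switch(parameter, linf = 1L, k = 2L,
                t0 = if (model == "VBG2") stop("VBG2 has no t0") else 3L,
                stop("unknown parameter: ", parameter))
  fixed_val <- if (parameter %in% c("linf", "k")) {
    if (value <= 0) return(Inf)
    log(value)
  } else value
  free <- setdiff(seq_along(mle), idx)
  wrap <- function(p) {
    full <- numeric(length(mle))
    full[idx] <- fixed_val
    full[free] <- p
    obj_full(full)
  }
  opt <- stats::optim(mle[free], wrap, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-11))
  opt$value
}

# approximate SEs from the numeric Hessian of the concentrated NLL in
# natural parameter space; falls back to crude scales if not PD
.fit_se <- function(fit) {
  model <- fit$model
  obj <- .growth_objective(model, fit$ages, fit$lengths, fit$l0)
  par <- c(log(fit$params$linf), log(fit$params$k),
           if (model != "VBG2") fit$params$t0)
  H <- tryCatch(stats::optimHess(par, obj), error = function(e) NULL)
  nm <- c("linf", "k", if (model != "VBG2") "t0")
  fallback <- c(linf = 0.05 * fit$params$linf, k = 0.15 * fit$params$k,
                t0 = 0.25)[nm]
  se_t <- tryCatch({
    v <- diag(solve(H))
    if (any(v <= 0)) stop("not PD")
    sqrt(v)
  }, error = function(e) NULL)
  if (is.null(se_t)) return(fallback)
  # delta method back from (log linf, log k) to natural scale
  out <- se_t
  out[1] <- se_t[1] * fit$params$linf
  out[2] <- se_t[2] * fit$params$k
  names(out) <- nm
  out
}

#' Likelihood-profile confidence interval for a growth parameter
#'
#' True profile likelihood: the parameter of interest is stepped away from
#' its MLE while the remaining growth parameters are re-optimised at every
#' profile point; the 95% CI is where the deviance
#' `2 (logL_max - logL_profile)` crosses `threshold` (3.84, chi-square 1 df),
#' located by bisection to `tol`.
#'
#' @param fit a `growth_fit` from [fit_model()].
#' @param parameter `"t0"` (the conventional target; `L_inf` and `k` being
#'   correlated are handled by [contour_ci()]), or `"linf"`/`"k"`.
#' @param threshold deviance cutoff, default 3.84.
#' @param tol bisection tolerance, default 1e-4.
#' @return list with `parameter`, `mle`, `lower`, `upper`, `threshold`,
#'   `lower_bounded`, `upper_bounded`.
#' @export
profile_ci <- function(fit, parameter = "t0", threshold = 3.84, tol = 1e-4) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!fit$converged) warning("profiling a fit flagged as non-converged")
  mle_val <- switch(parameter, linf = fit$params$linf, k = fit$params$k,
                    t0 = fit$params$t0, stop("unknown parameter: ", parameter))
  se <- .fit_se(fit)[[parameter]]
  dev_fn <- function(x) 2 * (.refit_fixed(fit, parameter, x) - fit$nll)
  ci <- profile_deviance_ci(dev_fn, mle_val, step = se / 2,
                            threshold = threshold, tol = tol)
  c(list(parameter = parameter), ci)
}

#' Profile deviance at given (L_inf, k)
#'
#' `2 (logL_max - logL(L_inf, k))` with `t0` re-optimised at the supplied
#' point (for 3-parameter models; exact for VBG2). Vectorised over pairs.
#' This is the quantity thresholded at 5.99 by [contour_ci()]; a single
#' evaluation at generating parameter values is the coverage check for the
#' joint confidence region.
#'
#' @param fit a `growth_fit`.
#' @param linf,k parameter values, cm and per year.
#' @return deviance values (0 at the MLE).
#' @export
contour_deviance <- function(fit, linf, k) {
  stopifnot(inherits(fit, "growth_fit"))
  dev_fn <- .contour_dev_fn(fit)
  mapply(dev_fn, linf, k)
}

# fast closure computing the (linf, k) profile deviance; the t0 search
# half-width is derived once from the Hessian, not per cell
.contour_dev_fn <- function(fit) {
  obj <- .growth_objective(fit$model, fit$ages, fit$lengths, fit$l0)
  has_t0 <- fit$model != "VBG2"
  t0_hat <- if (has_t0) fit$params$t0 else NA_real_
  t0_halfwidth <- if (has_t0) max(10 * .fit_se(fit)[["t0"]], 2) else NA_real_
  nll_min <- fit$nll
  function(li, kk) {
    if (li <= 0 || kk <= 0) return(Inf)
    nll <- if (!has_t0) {
      obj(c(log(li), log(kk)))
    } else {
      stats::optimize(function(t0) obj(c(log(li), log(kk), t0)),
                      interval = t0_hat + c(-1, 1) * t0_halfwidth,
                      tol = 1e-6)$objective
    }
    2 * (nll - nll_min)
  }
}

#' Thresholded deviance region on a grid (generic engine)
#'
#' Evaluates a two-argument deviance function on the Cartesian grid
#' `x_seq` x `y_seq` and delimits the region at or below `threshold`.
#' [contour_ci()] drives this with the growth-model profile deviance; it can
#' equally be used with any deviance surface (e.g. a quadratic toy
#' likelihood) for validation.
#'
#' @param dev_fn function `(x, y) -> deviance` (scalar).
#' @param x_seq,y_seq grid coordinates.
#' @param threshold deviance cutoff.
#' @return list with `grid` (data.frame `x`, `y`, `deviance`), `x_ci`,
#'   `y_ci` (bounding box of the region), `area` (cell-count area estimate),
#'   `touches_boundary`.
#' @export
grid_deviance_region <- function(dev_fn, x_seq, y_seq, threshold) {
  dev <- outer(seq_along(x_seq), seq_along(y_seq),
               Vectorize(function(i, j) dev_fn(x_seq[i], y_seq[j])))
  grid <- data.frame(x = rep(x_seq, times = length(y_seq)),
                     y = rep(y_seq, each = length(x_seq)),
                     deviance = as.vector(dev))
  inside <- grid$deviance <= threshold
  if (!any(inside)) {
    stop("no grid cell inside the region; grid does not span the minimum?")
  }
  cell <- mean(diff(x_seq)) * mean(diff(y_seq))
  list(grid = grid,
       x_ci = range(grid$x[inside]),
       y_ci = range(grid$y[inside]),
       area = sum(inside) * cell,
       touches_boundary = any(inside & (grid$x %in% range(x_seq) |
                                        grid$y %in% range(y_seq))))
}

#' Likelihood-contour confidence region for (L_inf, k)
#'
#' Evaluates the profile deviance `2 (logL_max - logL(L_inf, k))` on a grid,
#' re-optimising `t0` at every cell; the 95% joint confidence region is the
#' set of cells with deviance at or below `threshold` (5.99, chi-square
#' 2 df). Marginal CIs are reported as the region's bounding box per
#' parameter, the convention used for parenthetical CIs in growth tables.
#'
#' @param fit a `growth_fit` (3-parameter models; for VBG2 the deviance is
#'   exact with no nuisance re-optimisation).
#' @param n_grid grid points per axis (default 201).
#' @param expand half-width of the grid in approximate standard errors
#'   (default 6).
#' @param threshold deviance cutoff, default 5.99.
#' @param linf_range,k_range optional explicit axis ranges `c(lo, hi)`.
#' @return object of class `contour_region`: `grid` (data.frame `linf`, `k`,
#'   `deviance`), `threshold`, `mle`, `linf_ci`, `k_ci`, `touches_boundary`.
#' @export
contour_ci <- function(fit, n_grid = 201L, expand = 6, threshold = 5.99,
                       linf_range = NULL, k_range = NULL) {
  stopifnot(inherits(fit, "growth_fit"), n_grid >= 5)
  se <- .fit_se(fit)
  if (is.null(linf_range)) {
    linf_range <- fit$params$linf + c(-1, 1) * expand * se[["linf"]]
  }
  if (is.null(k_range)) {
    k_range <- pmax(fit$params$k + c(-1, 1) * expand * se[["k"]], 1e-6)
  }
  linf_seq <- seq(linf_range[1], linf_range[2], length.out = n_grid)
  k_seq <- seq(k_range[1], k_range[2], length.out = n_grid)
  region <- grid_deviance_region(.contour_dev_fn(fit), linf_seq, k_seq,
                                 threshold)
  if (region$touches_boundary) {
    warning("confidence region touches the grid boundary; expand the grid")
  }
  grid <- region$grid
  names(grid) <- c("linf", "k", "deviance")
  structure(list(grid = grid, threshold = threshold,
                 mle = c(linf = fit$params$linf, k = fit$params$k),
                 linf_ci = region$x_ci, k_ci = region$y_ci,
                 touches_boundary = region$touches_boundary),
            class = "contour_region")
}

#' Akaike weights from AIC values
#'
#' `w_i = exp(-0.5 delta_i) / sum(exp(-0.5 delta_j))` with
#' `delta_i = AIC_i - min(AIC)`. Invariant to adding a constant to all AICs.
#'
#' @param aic numeric vector of AIC values.
#' @return weights summing to 1.
#' @export
akaike_weights <- function(aic) {
  delta <- aic - min(aic)
  w <- exp(-0.5 * delta)
  w / sum(w)
}

#' Support class from a delta-AIC value
#'
#' Conventional evidence bands: delta 0--2 substantial support, 4--7
#' considerably less, > 10 essentially none; the gaps (2--4, 7--10] are
#' labelled intermediate.
#'
#' @param delta non-negative delta-AIC (vectorised).
#' @return character vector in
#'   `{"substantial", "intermediate", "less", "none"}`.
#' @export
report_support_class <- function(delta) {
  if (any(delta < 0)) stop("delta must be >= 0")
  ifelse(delta <= 2, "substantial",
         ifelse(delta > 10, "none",
                ifelse(delta >= 4 & delta <= 7, "less", "intermediate")))
}

#' AIC multimodel comparison table
#'
#' `AIC = 2p - 2 logL` with `p` the number of free growth parameters (sigma
#' concentrated, not counted). Reports delta-AIC, Akaike weights and support
#' class per model; optionally AICc (small-sample correction) as an extra
#' column, although ranking and weights use plain AIC.
#'
#' @param fits list of `growth_fit` objects fitted to identical data.
#' @return data.frame `(model, p, loglik, aic, aicc, delta, weight, support)`
#'   sorted by AIC.
#' @export
aic_table <- function(fits) {
  if (length(fits) == 0) stop("no fits")
  stopifnot(all(vapply(fits, inherits, logical(1), "growth_fit")))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1) stop("fits are not on identical data (n differs)")
  if (length(fits) > 1) {
    ref <- fits[[1]]
    same <- vapply(fits[-1], function(f) {
      isTRUE(all.equal(f$ages, ref$ages)) &&
        isTRUE(all.equal(f$lengths, ref$lengths))
    }, logical(1))
    if (!all(same)) stop("fits are not on identical data")
  }
  p <- vapply(fits, `[[`, numeric(1), "p")
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  n <- ns[1]
  aic <- 2 * p - 2 * ll
  aicc <- aic + 2 * p * (p + 1) / (n - p - 1)
  out <- data.frame(model = vapply(fits, `[[`, character(1), "model"),
                    p = p, loglik = ll, aic = aic, aicc = aicc,
                    delta = aic - min(aic), stringsAsFactors = FALSE)
  out$weight <- akaike_weights(out$aic)
  out$support <- report_support_class(out$delta)
  out[order(out$aic), ]
}
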