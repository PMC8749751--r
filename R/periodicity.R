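#' Marginal increment ratio
#'
#' `MIR = (VR - R_n) / (R_n - R_{n-1})`: the width of the growing margin
#' beyond the last complete translucent band, scaled by the previous band-pair
#' width. Seasonal minima mark band-completion timing. Scale-invariant:
#' multiplying all radii by a constant leaves MIR unchanged.
#'
#' @param vr vertebral radius, mm.
#' @param r_n radius of the last complete band, mm.
#' @param r_n_minus_1 radius of the penultimate band, mm.
#' @return dimensionless ratio `>= 0`. Vectorised.
#' @export
marginal_increment_ratio <- function(vr, r_n, r_n_minus_1) {
  if (any(r_n - r_n_minus_1 <= 0)) {
    stop("previous band pair width must be positive (r_n > r_n_minus_1)")
  }
  if (any(r_n > vr + 1e-12)) stop("last band radius exceeds vertebral radius")
  pmax((vr - r_n) / (r_n - r_n_minus_1), 0)
}

#' Per-specimen MIR records
#'
#' Computes MIR for every specimen with at least two post-birth bands (the
#' last two band radii plus the edge). Fish showing only the birth band are
#' excluded, as is conventional for marginal-increment analysis.
#'
#' @param specimens validated specimen table.
#' @return data.frame `(specimen_id, capture_month, mir)`; zero rows if no
#'   specimen qualifies.
#' @export
specimen_mir <- function(specimens) {
  nb <- lengths(specimens$band_radii)
  keep <- nb >= 3  # birth band + >= 2 post-birth bands
  s <- specimens[keep, , drop = FALSE]
  if (nrow(s) == 0) {
    return(data.frame(specimen_id = character(0), capture_month = integer(0),
                      mir = numeric(0)))
  }
  r_n <- vapply(s$band_radii, function(r) r[length(r)], numeric(1))
  r_p <- vapply(s$band_radii, function(r) r[length(r) - 1L], numeric(1))
  data.frame(specimen_id = s$specimen_id,
             capture_month = s$capture_month,
             mir = marginal_increment_ratio(s$vertebral_radius, r_n, r_p),
             stringsAsFactors = FALSE)
}

#' Kruskal--Wallis rank test across groups
#'
#' Thin wrapper over [stats::kruskal.test()] (tie-corrected H, chi-square
#' approximation) with the list-of-samples interface used throughout this
#' package.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return list with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  kt <- stats::kruskal.test(groups)
  H <- unname(kt$statistic)
  p <- kt$p.value
  if (!is.finite(H)) {
    # all observations tied: the tie-corrected statistic is 0/0; by
    # convention there is no evidence of a difference
    H <- 0
    p <- 1
  }
  list(statistic = H, df = unname(kt$parameter), p_value = p)
}

#' Dunn's post hoc pairwise comparisons on mean ranks
#'
#' Nonparametric multiple comparisons after a Kruskal--Wallis test: for each
#' pair of groups, `z = (Rbar_i - Rbar_j) / SE` with
#' `SE = sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` and tie correction
#' `T = sum(t^3 - t) / (12 (N - 1))`. Two-sided p-values with a Bonferroni
#' adjustment (over the number of pairs) by default.
#'
#' @param groups list of numeric samples (names used as labels).
#' @param p_adjust adjustment method passed to [stats::p.adjust()].
#' @return data.frame `(group_i, group_j, z, p_value, p_adjusted)`.
#' @export
dunn_posthoc <- function(groups, p_adjust = "bonferroni") {
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups")
  if (k < 3) warning("post hoc comparisons are uninformative with < 3 groups")
  if (is.null(names(groups))) names(groups) <- as.character(seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  pairs <- utils::combn(names(groups), 2)
  z <- apply(pairs, 2, function(p) {
    se2 <- (N * (N + 1) / 12 - tie_corr) * (1 / n[[p[1]]] + 1 / n[[p[2]]])
    if (se2 <= 0) return(0)
    (rbar[[p[1]]] - rbar[[p[2]]]) / sqrt(se2)
  })
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  data.frame(group_i = pairs[1, ], group_j = pairs[2, ], z = z,
             p_value = p, p_adjusted = stats::p.adjust(p, method = p_adjust),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Monthly centrum-edge and MIR summary
#'
#' For each calendar month of capture: sample size, proportions of translucent
#' vs opaque edges among classified specimens, and mean/SE of the marginal
#' increment ratio over MIR-eligible fish. Months without classified edges are
#' reported with `n_classified = 0` and `NA` proportions.
#'
#' @param specimens validated specimen table.
#' @return data.frame, one row per month 1--12.
#' @export
edge_analysis <- function(specimens) {
  mir <- specimen_mir(specimens)
  out <- do.call(rbind, lapply(1:12, function(m) {
    s <- specimens[specimens$capture_month == m, , drop = FALSE]
    cls <- s$edge_type[s$edge_type %in% c("opaque", "translucent")]
    mm <- mir$mir[mir$capture_month == m]
    data.frame(
      month = m,
      n = nrow(s),
      n_classified = length(cls),
      prop_translucent = if (length(cls)) mean(cls == "translucent") else NA_real_,
      prop_opaque = if (length(cls)) mean(cls == "opaque") else NA_real_,
      n_mir = length(mm),
      mean_mir = if (length(mm)) mean(mm) else NA_real_,
      se_mir = if (length(mm) > 1) stats::sd(mm) / sqrt(length(mm)) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Two-sample Kolmogorov--Smirnov test
#'
#' Wrapper over [stats::ks.test()]: `D = sup |ECDF_x - ECDF_y|` with the
#' asymptotic p-value (exact small-sample p deliberately not used, so results
#' are comparable across sample sizes and under ties).
#'
#' @param x,y non-empty numeric samples.
#' @return list with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}
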