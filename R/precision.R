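#' Percent agreement between two readers
#'
#' Proportion of paired band counts that agree within `tolerance` marks,
#' expressed as a percentage. PA with tolerance 0 is exact agreement; the
#' conventional "PA +/- 1 band" uses tolerance 1.
#'
#' @param counts_a,counts_b equal-length integer vectors of band counts.
#' @param tolerance non-negative integer, allowed absolute difference.
#' @return percentage in `[0, 100]`.
#' @export
percent_agreement <- function(counts_a, counts_b, tolerance = 0L) {
  if (length(counts_a) != length(counts_b) || length(counts_a) == 0) {
    stop("counts_a and counts_b must be non-empty and of equal length")
  }
  if (tolerance < 0) stop("tolerance must be >= 0")
  100 * mean(abs(counts_a - counts_b) <= tolerance)
}

# shared walk over the rows of a fish x readings matrix; excludes zero-mean
# fish with a warning (their per-fish error is undefined)
.per_fish <- function(count_matrix, fun) {
  m <- as.matrix(count_matrix)
  if (ncol(m) < 2) stop("need >= 2 readings per fish")
  means <- rowMeans(m)
  zero <- means <= 0
  if (any(zero)) {
    warning(sum(zero), " fish with zero mean count excluded")
    m <- m[!zero, , drop = FALSE]
    means <- means[!zero]
  }
  if (nrow(m) == 0) stop("no fish with positive mean count")
  vapply(seq_len(nrow(m)), function(j) fun(m[j, ], means[j]), numeric(1))
}

#' Average percent error of repeated age readings
#'
#' Beamish--Fournier index: for fish `j` with `R` readings,
#' `APE_j = (100/R) * sum_i |x_ij - xbar_j| / xbar_j`, averaged over fish.
#'
#' @param count_matrix matrix (fish x readings) of band counts.
#' @return APE as a percentage.
#' @export
average_percent_error <- function(count_matrix) {
  mean(.per_fish(count_matrix, function(x, xbar) {
    100 * mean(abs(x - xbar) / xbar)
  }))
}

#' Coefficient of variation of repeated age readings
#'
#' Chang's index: per-fish `CV_j = 100 * sd_j / xbar_j` with the sample
#' standard deviation (divisor `R - 1`), averaged over fish. For two readings
#' per fish, `CV = sqrt(2) * APE` on every fish.
#'
#' @inheritParams average_percent_error
#' @return CV as a percentage.
#' @export
cv_ageing <- function(count_matrix) {
  mean(.per_fish(count_matrix, function(x, xbar) {
    100 * stats::sd(x) / xbar
  }))
}

#' Bowker's test of symmetry for paired age readings
#'
#' Tests whether disagreements between two readers are symmetric about the
#' diagonal of their cross-tabulation. `X^2 = sum_{i<j} (n_ij - n_ji)^2 /
#' (n_ij + n_ji)` over informative pairs (`n_ij + n_ji > 0`); df is the number
#' of informative pairs; p is the chi-square upper tail.
#'
#' With no informative off-diagonal pair the test is undefined: df 0,
#' statistic 0, p reported as 1 with `defined = FALSE`.
#'
#' @param cross_tab square integer matrix of pair counts
#'   (reader 1 level x reader 2 level).
#' @return list with `statistic`, `df`, `p_value`, `defined`.
#' @export
bowker_symmetry <- function(cross_tab) {
  m <- as.matrix(cross_tab)
  if (nrow(m) != ncol(m)) stop("cross_tab must be square")
  stat <- 0
  df <- 0L
  for (i in seq_len(nrow(m) - 1L)) {
    for (j in seq.int(i + 1L, ncol(m))) {
      s <- m[i, j] + m[j, i]
      if (s > 0) {
        stat <- stat + (m[i, j] - m[j, i])^2 / s
        df <- df + 1L
      }
    }
  }
  if (df == 0L) {
    return(list(statistic = 0, df = 0L, p_value = 1, defined = FALSE))
  }
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       defined = TRUE)
}

#' Cross-tabulate paired reader counts
#'
#' @param counts_a,counts_b equal-length integer vectors.
#' @return square matrix over the union of observed levels.
#' @export
reader_cross_tab <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b)) stop("length mismatch")
  lev <- seq(min(counts_a, counts_b), max(counts_a, counts_b))
  table(factor(counts_a, levels = lev), factor(counts_b, levels = lev))
}

#' Age-bias table of reader 2 against reader 1
#'
#' For each reader-1 count level: number of fish, mean and sample sd of the
#' corresponding reader-2 counts. Plot the means against the levels with the
#' 1:1 line to visualise systematic bias.
#'
#' @param counts_a reader-1 counts (reference axis).
#' @param counts_b reader-2 counts.
#' @return data.frame `(level, n, mean_b, sd_b)`; `sd_b` is `NA` for n = 1.
#' @export
age_bias_table <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b) || length(counts_a) == 0) {
    stop("counts_a and counts_b must be non-empty and of equal length")
  }
  lev <- sort(unique(counts_a))
  out <- do.call(rbind, lapply(lev, function(l) {
    b <- counts_b[counts_a == l]
    data.frame(level = l, n = length(b), mean_b = mean(b),
               sd_b = if (length(b) > 1) stats::sd(b) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Full precision report for two readers
#'
#' Convenience wrapper assembling PA (exact, +/-1, +/-2), APE, CV and the
#' number of compared fish from a long reader-count table (one accepted trial
#' per reader).
#'
#' @param reader_counts data.frame from [reader_count_table()] with both
#'   readers present for each specimen.
#' @return list with `pa_exact`, `pa_within_1`, `pa_within_2`, `ape`, `cv`,
#'   `n_compared`.
#' @export
precision_report <- function(reader_counts) {
  w <- stats::reshape(
    reader_counts[reader_counts$trial == 1L,
                  c("specimen_id", "reader_id", "band_count")],
    idvar = "specimen_id", timevar = "reader_id", direction = "wide")
  w <- w[stats::complete.cases(w), ]
  if (nrow(w) == 0) stop("no specimens with counts from both readers")
  a <- w$band_count.1
  b <- w$band_count.2
  m <- cbind(a, b)
  list(pa_exact = percent_agreement(a, b, 0L),
       pa_within_1 = percent_agreement(a, b, 1L),
       pa_within_2 = percent_agreement(a, b, 2L),
       ape = average_percent_error(m),
       cv = cv_ageing(m),
       n_compared = nrow(w))
}
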