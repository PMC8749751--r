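#' Load a packaged reference table
#'
#' The package ships the published summary tables of the source age-and-growth
#' study as plain-CSV fixtures: monthly sample sizes (`table1`), the observed
#' age--length distribution in 2-cm length classes (`table2`), the combined
#' observed plus back-calculated age--length distribution (`table3`), and the
#' reference growth-model parameter sets with likelihood-contour confidence
#' bounds, log-likelihoods, AIC, delta-AIC and Akaike weights (`table4`).
#'
#' Margins are asserted on every load: table1 sums to 245 readable specimens,
#' table2 totals 245, table3 totals 1893 with 245 age-0 records.
#'
#' Length bins are lower edges of 2-cm classes; use `length_bin_lower + 1` as
#' the class midpoint when a point length is needed.
#'
#' @param name one of `"table1"`, `"table2"`, `"table3"`, `"table4"`.
#' @return a data.frame; long format `(length_bin_lower, age_group, count)`
#'   for the age--length tables (zero cells omitted).
#' @export
load_fixture <- function(name) {
  files <- c(table1 = "table1_monthly_n.csv",
             table2 = "table2_observed_agelen.csv",
             table3 = "table3_combined_agelen.csv",
             table4 = "table4_growth_fits.csv")
  if (length(name) != 1 || !name %in% names(files)) {
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; expected one of: ", paste(names(files), collapse = ", "))
  }
  path <- system.file("extdata", files[[name]], package = "bandgrowth")
  if (!nzchar(path)) stop("fixture file missing from installation: ", files[[name]])
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  switch(name,
    table1 = stopifnot(sum(df$n) == 245L, nrow(df) == 12L),
    table2 = stopifnot(sum(df$count) == 245L),
    table3 = stopifnot(sum(df$count) == 1893L,
                       sum(df$count[df$age_group == 0]) == 245L),
    table4 = stopifnot(nrow(df) == 12L,
                       all(df$model %in% c("VBG3", "VBG2", "GG3", "LG3")))
  )
  df
}

#' Marginal age-group distribution of an age--length fixture
#'
#' @param table a long-format age--length table from [load_fixture()].
#' @return data.frame `(age_group, count, prop)` sorted by age group.
#' @export
age_marginal <- function(table) {
  agg <- stats::aggregate(count ~ age_group, data = table, FUN = sum)
  agg <- agg[order(agg$age_group), ]
  agg$prop <- agg$count / sum(agg$count)
  rownames(agg) <- NULL
  agg
}
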