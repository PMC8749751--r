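#' Construct a validated specimen table
#'
#' A specimen table holds one aged individual per row: sex, total length (TL,
#' cm), capture year and month, vertebral radius (VR, mm, focus to edge along
#' the corpus calcareum), the ordered radii of all translucent bands (birth
#' band first, mm), and the optical state of the centrum edge.
#'
#' Band-count convention: `band_radii` includes the birth band as its first
#' entry, so a fish whose readers report `n` bands carries `n + 1` radii.
#' Band counts reported by [n_bands()] and consumed elsewhere exclude the
#' birth band.
#'
#' @param specimen_id character vector of unique identifiers.
#' @param sex `"female"` or `"male"`.
#' @param total_length numeric, cm, positive.
#' @param capture_year integer calendar year.
#' @param capture_month integer 1--12.
#' @param vertebral_radius numeric, mm, positive.
#' @param band_radii list of numeric vectors, each strictly increasing with
#'   last element `<=` the specimen's `vertebral_radius`; first element is
#'   the birth band.
#' @param edge_type `"opaque"`, `"translucent"` or `"unknown"`.
#' @return a `data.frame` with a `band_radii` list column, validated.
#' @seealso [read_specimens()], [write_specimens()], [n_bands()]
#' @export
specimen_table <- function(specimen_id, sex, total_length, capture_year,
                           capture_month, vertebral_radius, band_radii,
                           edge_type = "unknown") {
  df <- data.frame(
    specimen_id = as.character(specimen_id),
    sex = as.character(sex),
    total_length = as.numeric(total_length),
    capture_year = as.integer(capture_year),
    capture_month = as.integer(capture_month),
    vertebral_radius = as.numeric(vertebral_radius),
    stringsAsFactors = FALSE
  )
  df$band_radii <- lapply(band_radii, as.numeric)
  df$edge_type <- rep_len(as.character(edge_type), nrow(df))
  validate_specimens(df)
}

#' Validate a specimen table
#'
#' Checks every row against the domain invariants (positive lengths and radii,
#' month in 1--12, strictly increasing band radii bounded by the vertebral
#' radius, known factor levels) and fails with row-indexed diagnostics naming
#' the offending specimens.
#'
#' @param df a data.frame as produced by [specimen_table()].
#' @return `df`, invisibly unchanged, if valid.
#' @export
validate_specimens <- function(df) {
  required <- c("specimen_id", "sex", "total_length", "capture_year",
                "capture_month", "vertebral_radius", "band_radii", "edge_type")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("specimen table is missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0) {
      stop(sprintf("invalid specimen(s) [%s] row(s) %s: %s",
                   paste(utils::head(df$specimen_id[idx], 5), collapse = ","),
                   paste(utils::head(idx, 5), collapse = ","), what))
    }
  }
  bad(!df$sex %in% c("female", "male"), "sex must be 'female' or 'male'")
  bad(!is.finite(df$total_length) | df$total_length <= 0, "total_length must be > 0")
  bad(!is.finite(df$vertebral_radius) | df$vertebral_radius <= 0,
      "vertebral_radius must be > 0")
  bad(df$capture_month < 1 | df$capture_month > 12, "capture_month must be in 1..12")
  bad(!df$edge_type %in% c("opaque", "translucent", "unknown"),
      "edge_type must be opaque/translucent/unknown")
  nondec <- vapply(df$band_radii, function(r) {
    length(r) > 0 && (any(!is.finite(r)) || any(r <= 0) || any(diff(r) <= 0))
  }, logical(1))
  bad(nondec, "band_radii must be positive and strictly increasing")
  over <- mapply(function(r, vr) length(r) > 0 && max(r) > vr + 1e-9,
                 df$band_radii, df$vertebral_radius)
  bad(over, "last band radius exceeds vertebral_radius")
  invisible(df)
}

#' Post-birth band count per specimen
#'
#' @param specimens a specimen table.
#' @return integer vector: number of translucent bands beyond the birth band.
#' @export
n_bands <- function(specimens) {
  pmax(lengths(specimens$band_radii) - 1L, 0L)
}

#' Read specimens from CSV
#'
#' The on-disk format is plain UTF-8 comma-separated text with '.' decimals
#' and a header; `band_radii` is serialised as a `;`-separated string
#' (birth band first). Rows violating the invariants are rejected with
#' row-indexed diagnostics.
#'
#' @param path CSV file path.
#' @return validated specimen table.
#' @export
read_specimens <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("specimen_id", "sex", "total_length", "capture_year",
                "capture_month", "vertebral_radius", "band_radii", "edge_type")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("specimen CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  radii <- lapply(strsplit(as.character(raw$band_radii), ";", fixed = TRUE),
                  function(s) as.numeric(s[nzchar(s)]))
  specimen_table(raw$specimen_id, raw$sex, raw$total_length, raw$capture_year,
                 raw$capture_month, raw$vertebral_radius, radii, raw$edge_type)
}

#' Write specimens to CSV
#'
#' Inverse of [read_specimens()]: write-then-read is the identity on any valid
#' specimen table.
#'
#' @param specimens validated specimen table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(specimens, path) {
  validate_specimens(specimens)
  out <- specimens
  out$band_radii <- vapply(specimens$band_radii,
                           function(r) paste(format(r, trim = TRUE, digits = 15),
                                             collapse = ";"),
                           character(1))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Construct a reader band-count table
#'
#' One row per (specimen, reader, trial) with the count of translucent bands
#' beyond the birth band.
#'
#' @param specimen_id character vector.
#' @param reader_id integer, 1 or 2.
#' @param trial integer >= 1.
#' @param band_count non-negative integer.
#' @return validated data.frame.
#' @export
reader_count_table <- function(specimen_id, reader_id, trial, band_count) {
  df <- data.frame(specimen_id = as.character(specimen_id),
                   reader_id = as.integer(reader_id),
                   trial = as.integer(trial),
                   band_count = as.integer(band_count),
                   stringsAsFactors = FALSE)
  if (any(df$band_count < 0)) stop("band_count must be >= 0")
  if (any(df$trial < 1)) stop("trial must be >= 1")
  if (any(!df$reader_id %in% c(1L, 2L))) stop("reader_id must be 1 or 2")
  df
}

#' Read reader band counts from CSV
#' @param path CSV with columns specimen_id, reader_id, trial, band_count.
#' @return validated data.frame.
#' @export
read_reader_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("specimen_id", "reader_id", "trial", "band_count")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("reader-count CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  reader_count_table(raw$specimen_id, raw$reader_id, raw$trial, raw$band_count)
}
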