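#' Define an age-assignment scheme
#'
#' Three schemes convert post-birth band counts to decimal ages:
#' \describe{
#'   \item{unadjusted}{each band is one completed year: age = band count.}
#'   \item{adjusted_rc}{accounts for the reproductive cycle: the first band
#'     forms `birth_offset_years` after birth (default 7/12, a pulse of births
#'     in August with band deposition the following April), so
#'     age = offset + (count - 1).}
#'   \item{adjusted_dc}{additionally adds the time elapsed between the band
#'     formation month and the capture month:
#'     age = offset + (count - 1) + dm/12 with
#'     dm = (capture month - formation month) mod 12.}
#' }
#'
#' The offset is stored as exact 7/12 (not the display value 0.58) so
#' downstream likelihoods are not quantised.
#'
#' @param name `"unadjusted"`, `"adjusted_rc"` or `"adjusted_dc"`.
#' @param birth_month month of the main birth pulse (default 8, August).
#' @param band_formation_month month bands are completed (default 4, April).
#' @param birth_offset_years fraction of a year between birth and first band
#'   (default `7/12`).
#' @return an object of class `age_scheme`.
#' @export
age_scheme <- function(name = c("unadjusted", "adjusted_rc", "adjusted_dc"),
                       birth_month = 8L, band_formation_month = 4L,
                       birth_offset_years = 7 / 12) {
  name <- match.arg(name)
  stopifnot(birth_month %in% 1:12, band_formation_month %in% 1:12,
            birth_offset_years > 0, birth_offset_years < 1)
  structure(list(name = name,
                 birth_month = as.integer(birth_month),
                 band_formation_month = as.integer(band_formation_month),
                 birth_offset_years = birth_offset_years),
            class = "age_scheme")
}

#' Decimal age at capture from a band count
#'
#' Vectorised over `band_count` and `capture_month`. Capture months earlier in
#' the calendar than the formation month wrap around (a January capture is 9
#' months after the previous April band).
#'
#' @param band_count post-birth translucent band count, `>= 1` for aged fish
#'   (0 is permitted only under the unadjusted scheme, for neonates).
#' @param capture_month integer 1--12; ignored except under `adjusted_dc`.
#' @param scheme an [age_scheme()].
#' @return numeric decimal ages, years.
#' @seealso [age_group()] for the down-rounded tabulation age.
#' @export
assign_age <- function(band_count, capture_month = NULL, scheme) {
  stopifnot(inherits(scheme, "age_scheme"))
  if (any(band_count < 0)) stop("band_count must be >= 0")
  if (scheme$name != "unadjusted" && any(band_count < 1)) {
    stop("band_count must be >= 1 under adjusted schemes")
  }
  off <- scheme$birth_offset_years
  switch(scheme$name,
    unadjusted = as.numeric(band_count),
    adjusted_rc = off + (band_count - 1),
    adjusted_dc = {
      if (is.null(capture_month)) stop("adjusted_dc requires capture_month")
      if (any(capture_month < 1 | capture_month > 12)) {
        stop("capture_month must be in 1..12")
      }
      dm <- (capture_month - scheme$band_formation_month) %% 12
      off + (band_count - 1) + dm / 12
    })
}

#' Decimal age at deposition of a given band
#'
#' Band 0 is the birth band (age 0 under every scheme). Band `i >= 1` was
#' deposited at age `i` (unadjusted) or `offset + (i - 1)` (adjusted schemes).
#' Used to assign ages to back-calculated lengths.
#'
#' @param band_index integer `>= 0`, vectorised; 0 = birth band.
#' @param scheme an [age_scheme()].
#' @return numeric decimal ages, years.
#' @export
age_for_band <- function(band_index, scheme) {
  stopifnot(inherits(scheme, "age_scheme"))
  if (any(band_index < 0)) stop("band_index must be >= 0")
  ifelse(band_index == 0, 0,
         if (scheme$name == "unadjusted") as.numeric(band_index)
         else scheme$birth_offset_years + (band_index - 1))
}

#' Down-rounded age group
#'
#' @param decimal_age numeric years.
#' @return integer `floor(decimal_age)`.
#' @export
age_group <- function(decimal_age) {
  as.integer(floor(decimal_age))
}

#' Assign ages to a specimen table
#'
#' @param specimens a validated specimen table.
#' @param scheme an [age_scheme()].
#' @return data.frame `(specimen_id, scheme, band_count, decimal_age,
#'   age_group)`.
#' @export
assign_ages <- function(specimens, scheme) {
  bc <- n_bands(specimens)
  age <- assign_age(bc, specimens$capture_month, scheme)
  data.frame(specimen_id = specimens$specimen_id,
             scheme = scheme$name,
             band_count = bc,
             decimal_age = age,
             age_group = age_group(age),
             stringsAsFactors = FALSE)
}
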