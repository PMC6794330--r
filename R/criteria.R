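# Data-deficiency and criterion-B range-threshold rules ----------------------

# Range thresholds of IUCN criterion B (km2): B1 on EOO, B2 on AOO.
.EOO_THRESHOLD_KM2 <- 20000
.AOO_THRESHOLD_KM2 <- 2000
# Minimum number of georeferenced records below which a species is treated
# as insufficiently known (Data Deficient).
.DD_MIN_RECORDS <- 5

#' Data-deficiency rule
#'
#' A species with fewer than five georeferenced records is insufficiently
#' known to quantify its range and is flagged Data Deficient.
#'
#' @param n_records nonnegative integer record count.
#' @return TRUE iff `n_records < 5`.
#' @export
data_deficiency <- function(n_records) {
  stopifnot(length(n_records) == 1, is.finite(n_records))
  if (n_records < 0) stop("negative record count")
  n_records < .DD_MIN_RECORDS
}

#' Criterion-B range-threshold flags
#'
#' Strict comparisons in both directions: `meets_b1_range` is
#' `EOO < 20,000 km2`, `meets_b2_range` is `AOO < 2,000 km2`,
#' `threatened_range` their disjunction, and `widespread` requires both
#' `EOO > 20,000` AND `AOO > 2,000`.  A value exactly at a threshold sets
#' neither the threatened nor the widespread side.  These are range
#' screens only; full category assignment additionally needs the
#' criterion-B subconditions (fragmentation, locations, decline), which
#' are a narrative matter.
#'
#' @param eoo_km2,aoo_km2 nonnegative areas in km2, or `NA` when the range
#'   is unquantified (all flags come back `NA`).
#' @return A list of class `assessment_flags` with logical fields
#'   `meets_b1_range`, `meets_b2_range`, `threatened_range`, `widespread`.
#' @examples
#' range_flags(1469, 16)      # restricted on both axes
#' range_flags(68995, 30080)  # widespread
#' @export
range_flags <- function(eoo_km2, aoo_km2) {
  if (is.na(eoo_km2) || is.na(aoo_km2)) {
    f <- list(meets_b1_range = NA, meets_b2_range = NA,
              threatened_range = NA, widespread = NA)
    return(structure(f, class = "assessment_flags"))
  }
  stopifnot(eoo_km2 >= 0, aoo_km2 >= 0)
  b1 <- eoo_km2 < .EOO_THRESHOLD_KM2
  b2 <- aoo_km2 < .AOO_THRESHOLD_KM2
  structure(list(meets_b1_range = b1, meets_b2_range = b2,
                 threatened_range = b1 || b2,
                 widespread = eoo_km2 > .EOO_THRESHOLD_KM2 &&
                   aoo_km2 > .AOO_THRESHOLD_KM2),
            class = "assessment_flags")
}

#' @export
print.assessment_flags <- function(x, ...) {
  cat("assessment_flags:",
      paste(names(x), unlist(x), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Assess a species profile
#'
#' Applies the data-deficiency rule to the record count and the
#' criterion-B range screens to the profile's range values: the lower
#' confidence limits when the range was modelled (`basis == "sdm"`, the
#' precautionary choice), the point estimates when it was observed.
#' Profiles with no usable range values get `NA` range flags (an explicit
#' unknown state, distinct from FALSE).
#'
#' @param profile a `species_profile` (see [load_profiles()]) or any list
#'   with fields `n_records`, `basis`, `eoo_lower_km2`, `aoo_lower_km2`,
#'   `eoo_consensus_km2`, `aoo_consensus_km2`.
#' @return An `assessment_flags` list with the additional logical field
#'   `is_data_deficient` (NA when the record count is unknown).
#' @export
assess_species <- function(profile) {
  dd <- if (is.null(profile$n_records) || is.na(profile$n_records)) NA
        else data_deficiency(profile$n_records)
  pick <- function(lower, consensus) {
    if (identical(profile$basis, "sdm")) lower
    else if (identical(profile$basis, "observed")) {
      # observed profiles store the point estimate in the lower slot
      if (!is.null(lower) && !is.na(lower)) lower else consensus
    } else NA_real_
  }
  null_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  eoo <- pick(null_na(profile$eoo_lower_km2), null_na(profile$eoo_consensus_km2))
  aoo <- pick(null_na(profile$aoo_lower_km2), null_na(profile$aoo_consensus_km2))
  flags <- range_flags(eoo, aoo)
  flags$is_data_deficient <- dd
  flags
}
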