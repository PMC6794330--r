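# Packaged species conservation profiles and aggregate tallies ---------------

#' Load the packaged species conservation profiles
#'
#' The package ships the 43 encoded conservation profiles of the spider
#' species endemic to mainland Portugal: 42 assessed profiles plus a
#' minimal entry for the previously assessed troglobiont *Anapistula
#' ataecina* (flagged `prior_assessment`).  Each profile carries family,
#' record count, the basis of its range values (`observed`, `sdm` or
#' `unknown`), lower-confidence-limit and consensus EOO/AOO where
#' quantified, population and range trends, IUCN habitat codes and a
#' troglobiont flag.
#'
#' @param file path to a profiles JSON file; defaults to the packaged
#'   fixture.
#' @return An object of class `profile_collection`: a list of validated
#'   `species_profile` lists, with attributes `schema_version` and
#'   `notes`.
#' @examples
#' profs <- load_profiles()
#' length(profs)
#' @export
load_profiles <- function(file = system.file("extdata",
                                             "species_profiles.json",
                                             package = "rangeprofile")) {
  if (!nzchar(file) || !file.exists(file)) stop("profiles file not found")
  obj <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  if (is.null(obj$profiles) || length(obj$profiles) == 0)
    stop("no profiles in file (schema violation)")
  required <- c("species", "family", "basis", "population_trend",
                "range_trend", "habitat_codes", "troglobiont")
  profiles <- lapply(obj$profiles, function(p) {
    for (f in required)
      if (is.null(p[[f]]))
        stop(sprintf("profile '%s': missing field '%s'",
                     if (is.null(p$species)) "<unnamed>" else p$species, f))
    if (!p$basis %in% c("observed", "sdm", "unknown"))
      stop(sprintf("profile '%s': invalid basis '%s'", p$species, p$basis))
    for (f in c("population_trend", "range_trend"))
      if (!p[[f]] %in% c("decline", "stable", "unknown"))
        stop(sprintf("profile '%s': invalid %s '%s'", p$species, f, p[[f]]))
    low_ok <- function(lo, hi)
      is.null(lo) || is.null(hi) || lo <= hi
    if (!low_ok(p$eoo_lower_km2, p$eoo_consensus_km2) ||
        !low_ok(p$aoo_lower_km2, p$aoo_consensus_km2))
      stop(sprintf("profile '%s': lower bound exceeds consensus", p$species))
    p$habitat_codes <- unlist(p$habitat_codes)
    if (is.null(p$prior_assessment)) p$prior_assessment <- FALSE
    class(p) <- "species_profile"
    p
  })
  nm <- vapply(profiles, `[[`, "", "species")
  if (anyDuplicated(nm)) stop("duplicate species in profiles")
  structure(profiles, names = nm, class = "profile_collection",
            schema_version = obj$schema_version, notes = obj$notes)
}

#' @export
print.profile_collection <- function(x, ...) {
  cat(sprintf("profile_collection: %d species profiles\n", length(x)))
  invisible(x)
}

#' @export
`[.profile_collection` <- function(x, i) {
  structure(unclass(x)[i], class = "profile_collection",
            schema_version = attr(x, "schema_version"),
            notes = attr(x, "notes"))
}

#' Species-level trend
#'
#' The trend of a species is its population trend when stated; when the
#' population trend is unknown the range (EOO) trend stands in, so a
#' species whose range is judged stable but whose population has never
#' been estimated counts as stable rather than unknown.
#'
#' @param profile a `species_profile`.
#' @return `"decline"`, `"stable"` or `"unknown"`.
#' @export
species_trend <- function(profile) {
  if (profile$population_trend != "unknown") profile$population_trend
  else profile$range_trend
}

#' Tally a profile collection along one dimension
#'
#' Supported dimensions:
#' \describe{
#'   \item{trend}{counts of [species_trend()] values.}
#'   \item{family}{species per family.}
#'   \item{habitat}{species per habitat code; a species counts once for
#'     every code it lists.}
#'   \item{habitat_exclusive}{species whose habitat list is a singleton,
#'     per code.}
#'   \item{basis_quantified}{counts of range basis; `quantified` is the
#'     total with basis other than unknown.}
#'   \item{widespread, threatened_range}{counts of TRUE/FALSE/unknown
#'     after applying the criterion-B screens to each profile
#'     ([assess_species()]: lower confidence limits for modelled ranges,
#'     point estimates for observed ones).}
#' }
#'
#' @param collection a `profile_collection` (subset it with `[` to tally
#'   only the profiles assessed in one study).
#' @param dimension one of the tokens above.
#' @return A named integer vector of counts (zero-length for an empty
#'   collection where labels are data-driven).
#' @examples
#' profs <- load_profiles()
#' tally(profs, "trend")
#' @export
tally <- function(collection,
                  dimension = c("trend", "family", "habitat",
                                "habitat_exclusive", "basis_quantified",
                                "widespread", "threatened_range")) {
  stopifnot(inherits(collection, "profile_collection") ||
              is.list(collection))
  dimension <- match.arg(dimension)
  count <- function(labels) {
    t <- table(factor(unlist(labels)))
    stats::setNames(as.integer(t), names(t))
  }
  ps <- unclass(collection)
  switch(dimension,
    trend = {
      lv <- c("decline", "stable", "unknown")
      t <- table(factor(vapply(ps, species_trend, ""), levels = lv))
      stats::setNames(as.integer(t), lv)
    },
    family = count(lapply(ps, `[[`, "family")),
    habitat = count(lapply(ps, function(p) unique(p$habitat_codes))),
    habitat_exclusive = count(lapply(ps, function(p)
      if (length(unique(p$habitat_codes)) == 1) p$habitat_codes[1]
      else character(0))),
    basis_quantified = {
      b <- vapply(ps, `[[`, "", "basis")
      c(observed = sum(b == "observed"), sdm = sum(b == "sdm"),
        unknown = sum(b == "unknown"), quantified = sum(b != "unknown"))
    },
    widespread = ,
    threatened_range = {
      f <- vapply(ps, function(p) {
        v <- assess_species(p)[[dimension]]
        if (is.na(v)) "unknown" else if (v) "yes" else "no"
      }, "")
      t <- table(factor(f, levels = c("yes", "no", "unknown")))
      stats::setNames(as.integer(t), c("yes", "no", "unknown"))
    })
}

#' Assemble a structured assessment report
#'
#' Bundles a species profile (or the equivalent fields), its assessment
#' flags and computed range metrics into one JSON-ready list with full
#' provenance, the unit written by the command-style entry points.
#'
#' @param species species name.
#' @param flags an `assessment_flags` list ([assess_species()] /
#'   [range_flags()]).
#' @param metrics a [range_metrics()] object, or a list of them (e.g. the
#'   `lower_cl` / `consensus` pair of an ensemble), or NULL for
#'   data-deficient species.
#' @param provenance named list of parameters (seed, R, thresholds, ...)
#'   echoed into the report.
#' @return A list of class `assessment_report`.
#' @export
render_report <- function(species, flags, metrics = NULL,
                          provenance = list()) {
  stopifnot(is.character(species), length(species) == 1)
  as_list <- function(m) {
    if (is.null(m)) return(NULL)
    if (inherits(m, "range_metrics")) return(unclass(m))
    lapply(m, function(x) if (inherits(x, "range_metrics")) unclass(x) else x)
  }
  dd <- isTRUE(flags$is_data_deficient)
  # a data-deficient report drops the range flags (meaningless without
  # adequate data) but keeps whatever metrics the caller computed
  structure(
    list(species = species,
         package_version =
           as.character(utils::packageVersion("rangeprofile")),
         flags = if (dd) list(is_data_deficient = TRUE) else unclass(flags),
         metrics = as_list(metrics),
         provenance = provenance),
    class = "assessment_report")
}

#' Serialize an assessment report to JSON
#'
#' @param report an `assessment_report`.
#' @param file optional output path.
#' @return The JSON string (invisibly when written to `file`).
#' @export
report_json <- function(report, file = NULL) {
  stopifnot(inherits(report, "assessment_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 10,
                         null = "null")
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}
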