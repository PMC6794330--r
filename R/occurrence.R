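# Occurrence records: construction, CSV/KML I/O, grid thinning ---------------

#' Build a set of georeferenced occurrence records
#'
#' An `occurrence_set` is the raw input of every assessment path: the
#' records of one species, each a point with an optional positional error
#' radius.  Records with no stated uncertainty carry `NA`; downstream model
#' runs resolve the default (half the environmental cell edge).
#'
#' @param species_id single character species identifier.
#' @param lon,lat numeric vectors, decimal degrees WGS84.
#' @param uncertainty_km nonnegative positional error radii in km; `NA`
#'   for unstated (recycled).
#' @param source optional free-text provenance (recycled).
#' @return An object of class `occurrence_set`: a list with `species_id`
#'   and a data frame `records` (`lon`, `lat`, `uncertainty_km`, `source`).
#' @examples
#' caves <- occurrence_set("Harpactea stalitoides",
#'                         lon = c(-8.6, -8.5), lat = c(37.1, 37.2),
#'                         uncertainty_km = 0.5)
#' n_records(caves)
#' @export
occurrence_set <- function(species_id, lon = numeric(), lat = numeric(),
                           uncertainty_km = NA_real_, source = NA_character_) {
  stopifnot(is.character(species_id), length(species_id) == 1)
  n <- length(lon)
  if (length(lat) != n) stop("lon and lat lengths differ")
  if (n > 0) {
    if (any(!is.finite(lon)) || any(!is.finite(lat)))
      stop("non-finite coordinates")
    if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]")
    if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  }
  u <- rep_len(as.numeric(uncertainty_km), n)
  if (any(u < 0, na.rm = TRUE)) stop("uncertainty_km must be >= 0")
  structure(
    list(species_id = species_id,
         records = data.frame(lon = as.numeric(lon), lat = as.numeric(lat),
                              uncertainty_km = u,
                              source = rep_len(as.character(source), n),
                              stringsAsFactors = FALSE)),
    class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %s, %d record(s)\n", x$species_id,
              nrow(x$records)))
  invisible(x)
}

#' Number of records in an occurrence set
#'
#' This count is the quantity the data-deficiency rule tests (fewer than
#' five records).
#'
#' @param set an `occurrence_set`.
#' @return Integer record count.
#' @export
n_records <- function(set) {
  stopifnot(inherits(set, "occurrence_set"))
  nrow(set$records)
}

#' Read occurrence records from CSV
#'
#' Expects a header row; the default column names are `species`, `lon`,
#' `lat`, `uncertainty_km`, overridable through `column_map`.  Rows whose
#' coordinates do not parse or fall outside valid ranges abort with the
#' offending row number.
#'
#' @param file path or connection to a UTF-8, comma-separated file.
#' @param column_map named list mapping the roles `species`, `lon`, `lat`,
#'   `uncertainty_km` (optional role) to column names in the file.
#' @param species_id species to keep; default takes the (single) species
#'   present in the file.  An empty file yields an empty set with this id
#'   (or `"unknown"`).
#' @return An `occurrence_set`.
#' @export
read_occurrences_csv <- function(file,
                                 column_map = list(species = "species",
                                                   lon = "lon", lat = "lat",
                                                   uncertainty_km = "uncertainty_km"),
                                 species_id = NULL) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, encoding = "UTF-8")
  for (role in c("species", "lon", "lat")) {
    cn <- column_map[[role]]
    if (is.null(cn) || !cn %in% names(df))
      stop(sprintf("mapped column for '%s' (%s) missing from header",
                   role, if (is.null(cn)) "<unset>" else cn))
  }
  lon <- suppressWarnings(as.numeric(df[[column_map$lon]]))
  lat <- suppressWarnings(as.numeric(df[[column_map$lat]]))
  bad <- which(!is.finite(lon) | !is.finite(lat) |
                 lon < -180 | lon > 180 | lat < -90 | lat > 90)
  if (length(bad))
    stop(sprintf("invalid coordinates in row(s) %s",
                 paste(bad, collapse = ", ")))
  ucol <- column_map[["uncertainty_km"]]
  u <- if (!is.null(ucol) && ucol %in% names(df))
    suppressWarnings(as.numeric(df[[ucol]])) else rep(NA_real_, nrow(df))
  sp <- as.character(df[[column_map$species]])
  if (is.null(species_id)) {
    species_id <- if (nrow(df) == 0) "unknown" else unique(sp)
    if (length(species_id) > 1)
      stop("multiple species in file; pass species_id to select one")
  } else {
    keep <- sp == species_id
    lon <- lon[keep]; lat <- lat[keep]; u <- u[keep]
  }
  occurrence_set(species_id, lon, lat, u)
}

#' Read occurrence records from a KML point file
#'
#' Parses Point placemarks from a KML 2.2 document (the format in which
#' biodiversity record maps are commonly distributed), traversing nested
#' Folders/Documents.  The `coordinates` element is `lon,lat[,alt]`;
#' altitude is ignored.  Placemarks without a Point geometry are skipped
#' with a warning.
#'
#' @param file path or connection to a KML file.
#' @param species_id species identifier to stamp on the records; defaults
#'   to the document `name` element if present, else `"unknown"`.
#' @return An `occurrence_set`.
#' @export
read_occurrences_kml <- function(file, species_id = NULL) {
  doc <- xml2::read_xml(file)
  ns <- c(k = "http://www.opengis.net/kml/2.2")
  pm <- xml2::xml_find_all(doc, ".//k:Placemark", ns = ns)
  lon <- lat <- numeric(0)
  skipped <- 0L
  for (p in pm) {
    co <- xml2::xml_find_first(p, ".//k:Point/k:coordinates", ns = ns)
    if (inherits(co, "xml_missing")) {
      skipped <- skipped + 1L
      next
    }
    txt <- trimws(xml2::xml_text(co))
    # minus sign may arrive as U+2212 from word-processed files
    txt <- gsub("−", "-", txt)
    parts <- as.numeric(strsplit(txt, ",", fixed = TRUE)[[1]])
    if (length(parts) < 2 || any(!is.finite(parts[1:2])))
      stop("unparseable coordinates string in Placemark: ", txt)
    lon <- c(lon, parts[1]); lat <- c(lat, parts[2])
  }
  if (skipped > 0)
    warning(sprintf("%d Placemark(s) without Point geometry skipped", skipped))
  if (is.null(species_id)) {
    nm <- xml2::xml_find_first(doc, ".//k:Document/k:name", ns = ns)
    species_id <- if (inherits(nm, "xml_missing")) "unknown"
                  else xml2::xml_text(nm)
    if (!nzchar(species_id)) species_id <- "unknown"
  }
  occurrence_set(species_id, lon, lat)
}

#' Write occurrence records to CSV or KML
#'
#' Coordinates are written with enough digits that a write/read round trip
#' is the identity on (`species_id`, `lon`, `lat`).
#'
#' @param set an `occurrence_set`.
#' @param file output path or connection.
#' @param format `"csv"` or `"kml"`.
#' @return Invisibly, `file`.
#' @export
write_occurrences <- function(set, file, format = c("csv", "kml")) {
  stopifnot(inherits(set, "occurrence_set"))
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(species = rep(set$species_id, nrow(set$records)),
                     lon = formatC(set$records$lon, digits = 9, format = "f"),
                     lat = formatC(set$records$lat, digits = 9, format = "f"),
                     uncertainty_km = set$records$uncertainty_km)
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  } else {
    doc <- xml2::xml_new_root("kml",
                              xmlns = "http://www.opengis.net/kml/2.2")
    d <- xml2::xml_add_child(doc, "Document")
    xml2::xml_add_child(d, "name", set$species_id)
    for (i in seq_len(nrow(set$records))) {
      p <- xml2::xml_add_child(d, "Placemark")
      xml2::xml_add_child(p, "name", sprintf("%s %d", set$species_id, i))
      pt <- xml2::xml_add_child(p, "Point")
      xml2::xml_add_child(pt, "coordinates",
                          sprintf("%.9f,%.9f,0",
                                  set$records$lon[i], set$records$lat[i]))
    }
    xml2::write_xml(doc, file)
  }
  invisible(file)
}

#' Thin records to one per grid cell
#'
#' Model fitting uses at most one presence per environmental cell; the
#' earliest record in each occupied cell is kept, in input order.
#' Idempotent; never increases the record count.
#'
#' @param set an `occurrence_set`.
#' @param grid a [grid_spec()] on the equal-area plane.
#' @return A thinned `occurrence_set`.
#' @export
thin_to_cells <- function(set, grid) {
  stopifnot(inherits(set, "occurrence_set"), inherits(grid, "grid_spec"))
  if (nrow(set$records) == 0) return(set)
  xy <- project_equal_area(set$records$lon, set$records$lat)
  rc <- grid_cell_of(grid, xy[, 1], xy[, 2])
  key <- paste(rc[, 1], rc[, 2])
  out_of_grid <- is.na(rc[, 1])
  key[out_of_grid] <- paste0("offgrid_", which(out_of_grid))
  keep <- !duplicated(key)
  out <- set
  out$records <- set$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}
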