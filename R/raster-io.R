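# Environmental stacks and ESRI ASCII grid I/O -------------------------------

#' Stack of aligned environmental layers
#'
#' All layers share one grid and one validity mask (the land/study-area
#' mask); values must be finite wherever the mask is TRUE.
#'
#' @param grid a [grid_spec()].
#' @param layers named list of numeric matrices (`n_rows` x `n_cols`).
#' @param valid_mask logical matrix; defaults to all-TRUE.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(grid, layers, valid_mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("layers must be named")
  if (is.null(valid_mask))
    valid_mask <- matrix(TRUE, grid$n_rows, grid$n_cols)
  stopifnot(is.logical(valid_mask),
            nrow(valid_mask) == grid$n_rows, ncol(valid_mask) == grid$n_cols)
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!is.matrix(l) || nrow(l) != grid$n_rows || ncol(l) != grid$n_cols)
      stop("layer '", nm, "' does not match the grid")
    if (any(!is.finite(l[valid_mask])))
      stop("layer '", nm, "' has non-finite values on valid cells")
  }
  structure(list(grid = grid, layers = layers, valid_mask = valid_mask),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d layer(s) [%s] on %d x %d grid, %d valid cells\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$grid$n_rows, x$grid$n_cols, sum(x$valid_mask)))
  invisible(x)
}

#' Write a grid of values as an ESRI ASCII raster
#'
#' Plain-text raster interchange format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header followed by rows from the
#' top).  `NA` cells are written as the NODATA value.
#'
#' @param values numeric or logical matrix (rows index `y`, bottom-up).
#' @param grid the [grid_spec()] the matrix lives on.
#' @param file output path or connection.
#' @param nodata NODATA sentinel (default -9999).
#' @return Invisibly, `file`.
#' @export
write_ascii_grid <- function(values, grid, file, nodata = -9999) {
  stopifnot(inherits(grid, "grid_spec"),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  v <- values
  mode(v) <- "numeric"
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           sprintf("xllcorner %.6f", grid$origin_x_m),
           sprintf("yllcorner %.6f", grid$origin_y_m),
           sprintf("cellsize %.6f", grid$cell_m),
           sprintf("NODATA_value %g", nodata))
  # ASCII grids run top row first; our matrices store row 1 at the bottom
  body <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1,
                paste, collapse = " ")
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Read an ESRI ASCII raster
#'
#' @param file path or connection.
#' @return A list with `grid` (a [grid_spec()]) and `values` (numeric
#'   matrix, row 1 at the bottom; NODATA cells as `NA`).
#' @export
read_ascii_grid <- function(file) {
  lines <- readLines(file)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]])) stop("ASCII grid header missing ", k)
  nr <- hdr$nrows; nc <- hdr$ncols
  vals <- as.numeric(unlist(strsplit(trimws(lines[i:(i + nr - 1)]), "\\s+")))
  if (length(vals) != nr * nc) stop("ASCII grid body size mismatch")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]  # back to bottom-up rows
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  x0 <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  y0 <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  list(grid = grid_spec(x0, y0, hdr$cellsize, nr, nc), values = m)
}

#' Write the layers of a stack as ASCII rasters
#'
#' One file per layer, named `<prefix><layer>.asc`; masked cells are
#' NODATA.
#'
#' @param stack an [env_stack()].
#' @param prefix path prefix for the output files.
#' @return Invisibly, the vector of files written.
#' @export
write_stack_ascii <- function(stack, prefix) {
  stopifnot(inherits(stack, "env_stack"))
  files <- character(0)
  for (nm in names(stack$layers)) {
    v <- stack$layers[[nm]]
    v[!stack$valid_mask] <- NA
    f <- paste0(prefix, nm, ".asc")
    write_ascii_grid(v, stack$grid, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read aligned ASCII rasters into a stack
#'
#' @param files named character vector of `.asc` paths; names become layer
#'   names.
#' @return An [env_stack()]; cells that are NODATA in any layer are masked.
#' @export
read_stack_ascii <- function(files) {
  stopifnot(length(files) >= 1, !is.null(names(files)))
  first <- read_ascii_grid(files[[1]])
  grid <- first$grid
  layers <- list()
  valid <- !is.na(first$values)
  layers[[names(files)[1]]] <- first$values
  for (nm in names(files)[-1]) {
    g <- read_ascii_grid(files[[nm]])
    if (g$grid$n_rows != grid$n_rows || g$grid$n_cols != grid$n_cols ||
        g$grid$cell_m != grid$cell_m)
      stop("layer '", nm, "' is not aligned with the first layer")
    valid <- valid & !is.na(g$values)
    layers[[nm]] <- g$values
  }
  for (nm in names(layers)) layers[[nm]][!valid] <- 0
  env_stack(grid, layers, valid)
}
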