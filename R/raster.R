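#' Categorical habitat raster
#'
#' A square (or rectangular) grid of habitat class codes with a physical cell
#' edge length. The spatial arena for landscape metrics and invasion
#' simulations. Cells hold integer codes 0--10 (see [habitat_classes()]);
#' missing values are not permitted.
#'
#' @param grid Integer matrix of class codes in 0--10.
#' @param cell_size_m Cell edge length in meters (default 30).
#' @return An object of class `landscape_raster`: a list with elements `grid`
#'   (integer matrix) and `cell_size_m`.
#' @export
#' @examples
#' r <- landscape_raster(matrix(1L, 9, 9))
#' dim(r$grid)
landscape_raster <- function(grid, cell_size_m = 30) {
  if (!is.matrix(grid)) stop("`grid` must be a matrix", call. = FALSE)
  if (any(is.na(grid))) {
    stop("NODATA cells are not permitted in landscape rasters", call. = FALSE)
  }
  if (any(grid != as.integer(grid))) {
    stop("class codes must be integers", call. = FALSE)
  }
  storage.mode(grid) <- "integer"
  if (any(grid < 0L | grid > 10L)) {
    bad <- which(grid < 0L | grid > 10L, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "invalid class code %d at row %d, col %d (codes must be 0-10)",
      grid[bad[1], bad[2]], bad[1], bad[2]
    ), call. = FALSE)
  }
  if (!is.numeric(cell_size_m) || length(cell_size_m) != 1 || cell_size_m <= 0) {
    stop("`cell_size_m` must be a positive length", call. = FALSE)
  }
  structure(
    list(grid = grid, cell_size_m = as.numeric(cell_size_m)),
    class = "landscape_raster"
  )
}

#' @export
print.landscape_raster <- function(x, ...) {
  p <- composition_proportions(x)
  cat(sprintf(
    "<landscape_raster> %d x %d cells, %.0f m cells (%.2f km side)\n",
    nrow(x$grid), ncol(x$grid), x$cell_size_m,
    nrow(x$grid) * x$cell_size_m / 1000
  ))
  top <- sort(p[p > 0], decreasing = TRUE)
  cat(
    "composition:",
    paste(sprintf("%s %.2f", sub("^prop_", "", names(top)), top),
      collapse = ", "
    ), "\n"
  )
  invisible(x)
}

#' Tidy a landscape raster into long cell records
#'
#' @param x A [landscape_raster()].
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `code`, `class` — one row per cell.
#' @export
tidy.landscape_raster <- function(x, ...) {
  hc <- habitat_classes()
  tibble::tibble(
    row = rep(seq_len(nrow(x$grid)), times = ncol(x$grid)),
    col = rep(seq_len(ncol(x$grid)), each = nrow(x$grid)),
    code = as.integer(x$grid),
    class = hc$name[as.integer(x$grid) + 1L]
  )
}

#' Write a raster as an ESRI ASCII grid
#'
#' The dialect is the six-line `ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value` header followed by `nrows` lines of integer codes, top row
#' first. `write_ascii_grid()` followed by [read_ascii_grid()] is the identity
#' on grid values, shape, and cell size.
#'
#' @param raster A [landscape_raster()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(inherits(raster, "landscape_raster"))
  g <- raster$grid
  header <- c(
    paste("ncols", ncol(g)),
    paste("nrows", nrow(g)),
    paste("xllcorner", 0),
    paste("yllcorner", 0),
    paste("cellsize", format(raster$cell_size_m, scientific = FALSE)),
    paste("NODATA_value", -9999)
  )
  body <- apply(g, 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid into a landscape raster
#'
#' @param path Path to a `.asc` file in the dialect written by
#'   [write_ascii_grid()].
#' @return A [landscape_raster()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) {
    stop("ascii grid format error: fewer than 7 lines", call. = FALSE)
  }
  keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "NODATA_value")
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2 || tolower(parts[1]) != tolower(keys[i])) {
      stop(sprintf(
        "ascii grid format error at line %d: expected '%s <value>', got '%s'",
        i, keys[i], lines[i]
      ), call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val)) {
      stop(sprintf(
        "ascii grid format error at line %d: non-numeric value '%s'",
        i, parts[2]
      ), call. = FALSE)
    }
    hdr[[keys[i]]] <- val
  }
  nc <- as.integer(hdr$ncols)
  nr <- as.integer(hdr$nrows)
  if (nc < 1 || nr < 1) {
    stop("ascii grid format error: non-positive dimensions", call. = FALSE)
  }
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr) {
    stop(sprintf(
      "ascii grid format error: expected %d data rows, found %d",
      nr, length(body)
    ), call. = FALSE)
  }
  g <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) {
    line_no <- i + 6L
    vals <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(vals) != nc) {
      stop(sprintf(
        "ascii grid format error at line %d: expected %d values, found %d",
        line_no, nc, length(vals)
      ), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(vals))
    if (any(is.na(num)) || any(num != round(num))) {
      j <- which(is.na(num) | num != round(num))[1]
      stop(sprintf(
        "ascii grid format error at line %d, cell %d: non-integer value '%s'",
        line_no, j, vals[j]
      ), call. = FALSE)
    }
    if (any(num < 0 | num > 10)) {
      j <- which(num < 0 | num > 10)[1]
      stop(sprintf(
        "ascii grid format error at line %d, cell %d: code %s outside 0-10",
        line_no, j, vals[j]
      ), call. = FALSE)
    }
    g[i, ] <- as.integer(num)
  }
  landscape_raster(g, cell_size_m = hdr$cellsize)
}
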