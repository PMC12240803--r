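#' Masked elevation raster layer with an absolute age
#'
#' Container for one time slice of a palaeogeographic digital elevation
#' model. Row 1 is the northernmost band; columns run west to east from
#' `lon_min`. Cell ids are 0-based, row-major (`cell = row0 * ncols + col0`),
#' a fixed convention used in all exported edge and vertex tables.
#'
#' @param elevations Numeric matrix of elevations in metres.
#' @param age_ma Layer age in Ma (midpoint of the interval it represents).
#' @param cell_size_deg Cell size in degrees (square cells).
#' @param mask Optional logical matrix, `TRUE` = non-traversable (ocean).
#'   Defaults to `elevations <= 0`, the land-sea mask a DEM implies.
#' @param lon_min Western edge of the grid (degrees, default -180).
#' @param lat_max Northern edge of the grid (degrees, default chosen so the
#'   grid is centred on the equator).
#' @return An object of class `elevation_grid`.
#' @export
elevation_grid <- function(elevations, age_ma, cell_size_deg,
                           mask = NULL,
                           lon_min = -180,
                           lat_max = nrow(elevations) * cell_size_deg / 2) {
  elevations <- as.matrix(elevations)
  storage.mode(elevations) <- "double"
  if (is.null(mask)) mask <- elevations <= 0
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(elevations))) {
    stop("mask and elevations must have identical dimensions", call. = FALSE)
  }
  if (anyNA(elevations)) stop("elevations must not contain NA", call. = FALSE)
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (!is.numeric(age_ma) || length(age_ma) != 1) {
    stop("age_ma must be a single number", call. = FALSE)
  }
  if (cell_size_deg <= 0) stop("cell_size_deg must be positive", call. = FALSE)
  structure(
    list(elevations = elevations, mask = mask, age_ma = age_ma,
         cell_size_deg = cell_size_deg, lon_min = lon_min, lat_max = lat_max,
         nrows = nrow(elevations), ncols = ncol(elevations)),
    class = "elevation_grid")
}

#' @export
print.elevation_grid <- function(x, ...) {
  cat(sprintf("<elevation_grid> %d x %d cells at %g deg, age %g Ma, %d land cells\n",
              x$nrows, x$ncols, x$cell_size_deg, x$age_ma, sum(!x$mask)))
  invisible(x)
}

#' Whether a grid wraps the full circle of longitudes
#' @param grid An `elevation_grid`.
#' @return Logical.
#' @export
is_global_grid <- function(grid) {
  isTRUE(all.equal(grid$ncols * grid$cell_size_deg, 360))
}

# 0-based cell id <-> 0-based (row, col)
cell_to_rc <- function(grid, cell) {
  cbind(row = cell %/% grid$ncols, col = cell %% grid$ncols)
}

rc_to_cell <- function(grid, row, col) {
  as.integer(row) * grid$ncols + as.integer(col)
}

# cell centre coordinates, vectorised over 0-based cell ids
cell_center <- function(grid, cell) {
  rc <- cell_to_rc(grid, cell)
  cbind(lon = grid$lon_min + (rc[, "col"] + 0.5) * grid$cell_size_deg,
        lat = grid$lat_max - (rc[, "row"] + 0.5) * grid$cell_size_deg)
}

# 0-based cell id containing a lon/lat point (no land requirement);
# longitudes are wrapped into the grid's span for global grids
containing_cell <- function(grid, lon, lat) {
  if (is_global_grid(grid)) {
    lon <- ((lon - grid$lon_min) %% 360) + grid$lon_min
  }
  col <- floor((lon - grid$lon_min) / grid$cell_size_deg)
  row <- floor((grid$lat_max - lat) / grid$cell_size_deg)
  col <- pmin(pmax(col, 0), grid$ncols - 1)
  row <- pmin(pmax(row, 0), grid$nrows - 1)
  rc_to_cell(grid, row, col)
}

#' Snap a geographic point to the nearest land cell of a grid
#'
#' Returns the 0-based id of the cell containing the point when that cell is
#' unmasked; otherwise the unmasked cell whose centre has the minimum
#' great-circle distance to the point. Exact ties are broken by the lowest
#' cell id so results are reproducible.
#'
#' @param point Numeric `c(lon, lat)` in degrees.
#' @param grid An `elevation_grid` with at least one unmasked cell.
#' @param radius_km Sphere radius for the distance scan.
#' @return Integer cell id (0-based).
#' @export
snap_to_land <- function(point, grid, radius_km = 6371) {
  check_lonlat(matrix(point, ncol = 2))
  land <- which(!t(grid$mask)) - 1L  # 0-based ids; t() makes which() row-major
  land <- sort(land)
  if (length(land) == 0) stop("grid has no unmasked cells to snap to", call. = FALSE)
  own <- containing_cell(grid, point[1], point[2])
  if (own %in% land) return(as.integer(own))
  ctr <- cell_center(grid, land)
  d <- geosphere::distHaversine(matrix(point, ncol = 2), ctr, r = radius_km)
  as.integer(land[which.min(d)])  # which.min takes the first = lowest id (land sorted)
}

#' Read an ESRI ASCII grid file as an elevation layer
#'
#' Minimal reader for the plain-text ESRI ASCII raster interchange format
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header followed by
#' rows north to south). NODATA cells become masked with elevation 0.
#'
#' @param path File path.
#' @param age_ma Age to attach to the layer (Ma).
#' @param mask Optional explicit mask matrix; default derives ocean from
#'   `elevation <= 0` and NODATA.
#' @return An `elevation_grid`.
#' @export
read_ascii_grid <- function(path, age_ma, mask = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (k in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[k]])) stop(sprintf("ESRI ASCII header missing '%s' in %s", k, path), call. = FALSE)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"), quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d values, found %d in %s", nr * nc, length(vals), path), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  nd <- m == nodata
  m[nd] <- 0
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else -180
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else -nr * hdr$cellsize / 2
  if (is.null(mask)) mask <- (m <= 0) | nd else mask <- mask | nd
  elevation_grid(m, age_ma = age_ma, cell_size_deg = hdr$cellsize,
                 mask = mask, lon_min = xll, lat_max = yll + nr * hdr$cellsize)
}

#' Write an elevation layer (or any matrix) as an ESRI ASCII grid
#'
#' @param grid An `elevation_grid`, or a plain matrix together with
#'   `cell_size_deg`/`lon_min`/`lat_max` attributes taken from `template`.
#' @param path Output file path.
#' @param values Which matrix to write: `"elevation"` (masked cells as
#'   NODATA) or `"mask"` (1 = non-traversable, 0 = land).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, values = c("elevation", "mask")) {
  values <- match.arg(values)
  m <- if (values == "mask") grid$mask * 1 else grid$elevations
  nodata <- -9999
  if (values == "elevation") m[grid$mask] <- nodata
  hdr <- c(
    sprintf("ncols %d", grid$ncols),
    sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %.10g", grid$lon_min),
    sprintf("yllcorner %.10g", grid$lat_max - grid$nrows * grid$cell_size_deg),
    sprintf("cellsize %.10g", grid$cell_size_deg),
    sprintf("NODATA_value %d", nodata))
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a raster manifest (path, age_ma) into a list of elevation layers
#'
#' The manifest is a delimited file with header columns `path` and `age_ma`;
#' relative paths resolve against the manifest's directory. Layers are
#' returned ordered oldest to youngest.
#'
#' @param manifest_path Path to the CSV manifest.
#' @return List of `elevation_grid`, ages strictly decreasing.
#' @export
read_dem_manifest <- function(manifest_path) {
  tab <- utils::read.csv(manifest_path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("path", "age_ma") %in% names(tab))) {
    stop("DEM manifest needs columns 'path' and 'age_ma'", call. = FALSE)
  }
  tab <- tab[order(-tab$age_ma), , drop = FALSE]
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(tab)), function(i) {
    p <- tab$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    read_ascii_grid(p, age_ma = tab$age_ma[i])
  })
}
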