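# Minimal geographic raster container (WGS84 lon/lat, north-up,
# cell-edge anchored like the ESRI ASCII convention): a numeric matrix
# whose first row is the northernmost row, plus the lower-left corner,
# the square cell size in degrees, and a nodata sentinel.

#' Construct a geographic grid
#'
#' @param values numeric matrix; row 1 is the northernmost row.
#' @param xll,yll longitude/latitude of the lower-left corner (degrees).
#' @param cellsize cell size in degrees (> 0); cells are square.
#' @param nodata sentinel written for missing cells on export; in memory
#'   missing cells are `NA`.
#' @return object of class `eco_grid`.
#' @export
eco_grid <- function(values, xll, yll, cellsize, nodata = -9999) {
  values <- as.matrix(values)
  if (cellsize <= 0) stop("cellsize must be > 0")
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata),
            class = "eco_grid")
}

#' @export
print.eco_grid <- function(x, ...) {
  cat(sprintf("eco_grid: %d rows x %d cols, cell %g deg, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  invisible(x)
}

#' @export
dim.eco_grid <- function(x) dim(x$values)

#' Do two grids share the same geometry?
#' @param a,b `eco_grid` objects.
#' @return logical.
#' @export
same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize), c(b$xll, b$yll, b$cellsize)))
}

check_aligned <- function(grids) {
  ref <- grids[[1]]
  ok <- vapply(grids, same_geometry, logical(1), b = ref)
  if (!all(ok)) stop("raster layers do not share a common grid geometry")
  invisible(ref)
}

#' Grid extent
#' @param g an `eco_grid`.
#' @return named vector `xmin`, `xmax`, `ymin`, `ymax` in degrees.
#' @export
grid_extent <- function(g) {
  c(xmin = g$xll, xmax = g$xll + ncol(g$values) * g$cellsize,
    ymin = g$yll, ymax = g$yll + nrow(g$values) * g$cellsize)
}

#' Extract grid values at point coordinates
#'
#' @param g an `eco_grid`.
#' @param lon,lat coordinate vectors in decimal degrees. Points outside
#'   the grid extent are an error.
#' @return numeric vector of cell values.
#' @export
extract_at <- function(g, lon, lat) {
  ext <- grid_extent(g)
  out_of <- lon < ext["xmin"] | lon >= ext["xmax"] |
    lat < ext["ymin"] | lat >= ext["ymax"]
  if (any(out_of)) {
    stop(sum(out_of), " point(s) outside the raster extent")
  }
  col <- floor((lon - g$xll) / g$cellsize) + 1
  row <- nrow(g$values) - floor((lat - g$yll) / g$cellsize)
  g$values[cbind(row, col)]
}

#' Write a grid as an ESRI ASCII raster
#' @param g an `eco_grid`.
#' @param path output `.asc` file.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(g, path) {
  stopifnot(inherits(g, "eco_grid"))
  v <- g$values
  v[is.na(v)] <- g$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(v)),
               paste("nrows", nrow(v)),
               paste("xllcorner", format(g$xll, digits = 15)),
               paste("yllcorner", format(g$yll, digits = 15)),
               paste("cellsize", format(g$cellsize, digits = 15)),
               paste("NODATA_value", g$nodata)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII raster
#' @param path `.asc` file.
#' @return an `eco_grid` (nodata cells as `NA`).
#' @export
read_ascii_grid <- function(path) {
  hdr_lines <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr_lines), "\\s+")
  hdr <- stats::setNames(vapply(kv, `[`, "", 2), tolower(vapply(kv, `[`, "", 1)))
  n_hdr <- sum(names(hdr) %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                                 "cellsize", "nodata_value"))
  vals <- as.matrix(utils::read.table(path, skip = n_hdr))
  dimnames(vals) <- NULL
  nodata <- as.numeric(hdr[["nodata_value"]])
  vals[vals == nodata] <- NA
  eco_grid(vals, as.numeric(hdr[["xllcorner"]]), as.numeric(hdr[["yllcorner"]]),
           as.numeric(hdr[["cellsize"]]), nodata)
}

#' Spherical area of each grid row's cells
#'
#' Cell area on a sphere of radius 6371 km:
#' `R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))` with angles in
#' radians, so equal-longitude cells shrink toward the poles.
#'
#' @param g an `eco_grid`.
#' @return numeric vector of per-cell areas (km^2) by grid row (row 1 =
#'   northernmost).
#' @export
row_cell_areas_km2 <- function(g) {
  R <- 6371
  nr <- nrow(g$values)
  top_lat <- g$yll + (nr:1) * g$cellsize
  bot_lat <- top_lat - g$cellsize
  R^2 * (g$cellsize * pi / 180) * (sin(top_lat * pi / 180) - sin(bot_lat * pi / 180))
}

#' Area covered by a mask, in km^2
#'
#' @param mask logical matrix (or `eco_grid` of logicals); `NA` counts as
#'   `FALSE`.
#' @param g the `eco_grid` supplying the geometry.
#' @return total area in km^2.
#' @export
mask_area_km2 <- function(mask, g) {
  mv <- if (inherits(mask, "eco_grid")) mask$values else mask
  if (!identical(dim(mv), dim(g$values))) stop("mask geometry mismatch")
  mv[is.na(mv)] <- FALSE
  areas <- row_cell_areas_km2(g)
  sum(rowSums(mv) * areas)
}

#' Per-region suitable area summary
#'
#' @param mask logical matrix (or `eco_grid`) of suitable cells.
#' @param region_grid `eco_grid` of categorical region codes, aligned
#'   with the mask.
#' @return data frame: `region`, `suitable_cells`, `suitable_area_km2`.
#' @export
region_summary <- function(mask, region_grid) {
  mv <- if (inherits(mask, "eco_grid")) mask$values else mask
  if (!identical(dim(mv), dim(region_grid$values))) stop("region geometry mismatch")
  mv[is.na(mv)] <- FALSE
  areas <- row_cell_areas_km2(region_grid)
  area_m <- matrix(areas, nrow(mv), ncol(mv))
  codes <- sort(unique(as.vector(region_grid$values[!is.na(region_grid$values)])))
  out <- lapply(codes, function(cd) {
    sel <- mv & !is.na(region_grid$values) & region_grid$values == cd
    data.frame(region = cd, suitable_cells = sum(sel),
               suitable_area_km2 = sum(area_m[sel]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
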