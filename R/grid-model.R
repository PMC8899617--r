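#' Grid specification for a regular lat/lon raster
#'
#' Describes a regular geographic grid with cell-centre registration.
#' Rows are ordered north to south, columns west to east; the origin is the
#' centre of the cell in row 1, column 1.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param lat_origin,lon_origin Coordinates (decimal degrees) of the centre
#'   of the top-left (northernmost, westernmost) cell.
#' @param resolution Cell size in degrees (default 0.5).
#' @param crs_label Free-text label for the coordinate reference system.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, lat_origin, lon_origin,
                      resolution = 0.5, crs_label = "geographic WGS84") {
  stopifnot(
    length(n_rows) == 1L, length(n_cols) == 1L,
    n_rows >= 1L, n_cols >= 1L,
    n_rows == as.integer(n_rows), n_cols == as.integer(n_cols),
    is.finite(lat_origin), is.finite(lon_origin)
  )
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("resolution must be a single positive number")
  top <- lat_origin + resolution / 2
  bottom <- lat_origin - (n_rows - 1) * resolution - resolution / 2
  if (top > 90 + 1e-9 || bottom < -90 - 1e-9)
    stop("grid extends beyond [-90, 90] latitude")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         lat_origin = lat_origin, lon_origin = lon_origin,
         resolution = resolution, crs_label = crs_label),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells at %g deg, origin (%g, %g), %s\n",
              x$n_rows, x$n_cols, x$resolution, x$lat_origin, x$lon_origin,
              x$crs_label))
  invisible(x)
}

#' Latitudes / longitudes of cell centres
#'
#' @param grid A [grid_spec()].
#' @return Numeric vector of row-centre latitudes (north to south) or
#'   column-centre longitudes (west to east).
#' @export
grid_lats <- function(grid) {
  grid$lat_origin - (seq_len(grid$n_rows) - 1) * grid$resolution
}

#' @rdname grid_lats
#' @export
grid_lons <- function(grid) {
  grid$lon_origin + (seq_len(grid$n_cols) - 1) * grid$resolution
}

#' Time axis of 1-kyr (or other uniform-step) age slices
#'
#' Ages are thousands of years before present (ka), ordered oldest first by
#' convention (130, 129, ..., 10 by default). The axis must be strictly
#' monotone with a uniform step.
#'
#' @param ages Numeric vector of slice ages in ka.
#' @return An object of class `time_axis` with elements `ages`, `step`
#'   (kyr, positive) and `span` (kyr, oldest minus youngest).
#' @export
time_axis <- function(ages = seq(130, 10, by = -1)) {
  ages <- as.numeric(ages)
  if (length(ages) < 2L) stop("time axis needs at least 2 slices")
  d <- diff(ages)
  if (any(d == 0) || (any(d > 0) && any(d < 0)))
    stop("time axis must be strictly monotone")
  if (max(abs(d)) - min(abs(d)) > 1e-9)
    stop("non-uniform time axis")
  structure(
    list(ages = ages, step = abs(d[1]), span = abs(ages[1] - ages[length(ages)])),
    class = "time_axis"
  )
}

#' @export
print.time_axis <- function(x, ...) {
  cat(sprintf("<time_axis> %d slices, %g-%g ka, step %g kyr (span %g kyr)\n",
              length(x$ages), x$ages[1], x$ages[length(x$ages)], x$step, x$span))
  invisible(x)
}

check_cube_array <- function(values, grid, time) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("cube values must be a 3-d array [rows, cols, slices]")
  d <- dim(values)
  if (d[1] != grid$n_rows || d[2] != grid$n_cols || d[3] != length(time$ages))
    stop("cube dimensions do not match grid/time axis")
  invisible(TRUE)
}

#' Gridded precipitation cube
#'
#' A stack of mean-annual-precipitation slices (mm/yr) on a common grid and
#' time axis. Missing cells (sea, no data) are `NA`. A cell counts as
#' analysable land only when it is non-missing in every slice.
#'
#' @param values 3-d numeric array `[n_rows, n_cols, n_slices]`, mm/yr,
#'   `NA` for missing.
#' @param grid A [grid_spec()].
#' @param time A [time_axis()].
#' @return Object of class `precip_cube` with fields `grid`, `time`, `values`.
#' @export
precip_cube <- function(values, grid, time) {
  stopifnot(inherits(grid, "grid_spec"), inherits(time, "time_axis"))
  check_cube_array(values, grid, time)
  if (any(values < 0, na.rm = TRUE))
    stop("precipitation values must be non-negative")
  structure(list(grid = grid, time = time, values = values),
            class = "precip_cube")
}

#' @export
print.precip_cube <- function(x, ...) {
  cat(sprintf("<precip_cube> %d x %d x %d, %d land cells\n",
              x$grid$n_rows, x$grid$n_cols, length(x$time$ages),
              sum(land_mask(x))))
  invisible(x)
}

#' Gridded categorical biome cube
#'
#' Integer biome codes per cell and slice, plus a legend mapping each code to
#' a biome name and an open/forest class. Every code observed in the cube
#' must appear in the legend; the legend may contain unused codes.
#'
#' @param codes 3-d integer array `[n_rows, n_cols, n_slices]`, `NA` missing.
#' @param grid A [grid_spec()].
#' @param time A [time_axis()].
#' @param legend Data frame with columns `code` (integer), `name` (character)
#'   and `open_or_forest` (`"open"` or `"forest"`).
#' @return Object of class `biome_cube`.
#' @export
biome_cube <- function(codes, grid, time, legend) {
  stopifnot(inherits(grid, "grid_spec"), inherits(time, "time_axis"))
  check_cube_array(codes, grid, time)
  legend <- validate_biome_legend(legend)
  obs <- unique(codes[!is.na(codes)])
  if (any(obs != as.integer(obs)))
    stop("biome codes must be integer-valued")
  missing_codes <- setdiff(as.integer(obs), legend$code)
  if (length(missing_codes) > 0)
    stop("biome codes absent from legend: ",
         paste(sort(missing_codes), collapse = ", "))
  structure(list(grid = grid, time = time,
                 codes = codes, legend = legend),
            class = "biome_cube")
}

validate_biome_legend <- function(legend) {
  need <- c("code", "name", "open_or_forest")
  if (!is.data.frame(legend) || !all(need %in% names(legend)))
    stop("legend must be a data frame with columns ",
         paste(need, collapse = ", "))
  legend$code <- as.integer(legend$code)
  if (anyDuplicated(legend$code)) stop("duplicate codes in legend")
  bad <- !legend$open_or_forest %in% c("open", "forest")
  if (any(bad))
    stop("open_or_forest must be 'open' or 'forest'; offending codes: ",
         paste(legend$code[bad], collapse = ", "))
  legend[, need]
}

#' Open/forest lookup from a biome legend
#'
#' @param cube A [biome_cube()].
#' @return Named character vector mapping code (as name) to `"open"` or
#'   `"forest"`.
#' @export
open_forest_lookup <- function(cube) {
  stopifnot(inherits(cube, "biome_cube"))
  stats::setNames(cube$legend$open_or_forest, cube$legend$code)
}

#' Land mask of a cube
#'
#' A cell is analysable land only when it is non-missing in every time slice.
#'
#' @param x A `precip_cube` or `biome_cube`.
#' @return Logical matrix `[n_rows, n_cols]`.
#' @export
land_mask <- function(x) UseMethod("land_mask")

#' @export
land_mask.precip_cube <- function(x) apply(!is.na(x$values), c(1, 2), all)

#' @export
land_mask.biome_cube <- function(x) apply(!is.na(x$codes), c(1, 2), all)

#' Spherical cell areas
#'
#' Area of each grid cell in km^2 from spherical geometry:
#' `area = R^2 * resolution_rad * (sin(latN) - sin(latS))` with
#' `R = 6371` km, where `latN`/`latS` bound the cell. Areas are constant
#' along a row and proportional to the cosine of the cell-centre latitude
#' for small cells.
#'
#' @param grid A [grid_spec()].
#' @param radius_km Sphere radius (default 6371 km).
#' @return Numeric matrix `[n_rows, n_cols]` of areas, km^2.
#' @export
cell_areas <- function(grid, radius_km = 6371) {
  stopifnot(inherits(grid, "grid_spec"))
  lat <- grid_lats(grid)
  half <- grid$resolution / 2
  res_rad <- grid$resolution * pi / 180
  row_area <- radius_km^2 * res_rad *
    (sin(pmin(lat + half, 90) * pi / 180) - sin(pmax(lat - half, -90) * pi / 180))
  matrix(row_area, nrow = grid$n_rows, ncol = grid$n_cols)
}

#' Area fraction of a mask within a domain
#'
#' Fraction of the domain covered by `mask`, using spherical cell areas as
#' the default denominator; the raw cell-count fraction is always reported
#' alongside, because area-weighted and unweighted percentages can differ
#' on grids spanning many latitudes.
#'
#' @param mask Logical matrix (the cells of interest).
#' @param areas Numeric matrix of cell areas (see [cell_areas()]).
#' @param domain_mask Logical matrix of analysable cells; `mask` must be a
#'   subset of it.
#' @return List with `area_fraction` and `count_fraction`, both in `[0, 1]`.
#' @export
area_fraction <- function(mask, areas, domain_mask) {
  stopifnot(is.logical(mask), is.logical(domain_mask),
            identical(dim(mask), dim(domain_mask)),
            identical(dim(mask), dim(areas)))
  mask[is.na(mask)] <- FALSE
  domain_mask[is.na(domain_mask)] <- FALSE
  if (!any(domain_mask)) stop("empty domain mask")
  if (any(mask & !domain_mask)) stop("mask contains cells outside the domain")
  list(
    area_fraction = sum(areas[mask]) / sum(areas[domain_mask]),
    count_fraction = sum(mask) / sum(domain_mask)
  )
}

#' Locate points in grid cells
#'
#' Maps lat/lon points to (row, col) indices using half-open cell bounds
#' `[south, north) x [west, east)`: a point on a shared edge belongs to the
#' cell north/west of it is excluded from, i.e. the southern edge and
#' western edge are inclusive.
#'
#' @param grid A [grid_spec()].
#' @param lat,lon Numeric vectors of equal length, degrees.
#' @return Integer matrix with columns `row`, `col`; `NA` rows for points
#'   outside the grid extent.
#' @export
cell_index <- function(grid, lat, lon) {
  stopifnot(length(lat) == length(lon))
  half <- grid$resolution / 2
  north_edge <- grid$lat_origin + half
  west_edge <- grid$lon_origin - half
  # [south, north): a shared horizontal edge belongs to the cell north of it,
  # so ceiling of the distance below the top edge (with a float guard)
  dlat <- (north_edge - lat) / grid$resolution
  row <- as.integer(ceiling(dlat - 1e-9))
  # [west, east): floor + 1, a shared vertical edge belongs to the eastern cell
  dlon <- (lon - west_edge) / grid$resolution
  col <- as.integer(floor(dlon + 1e-12)) + 1L
  out <- cbind(row = row, col = col)
  bad <- row < 1L | row > grid$n_rows | col < 1L | col > grid$n_cols |
    !is.finite(lat) | !is.finite(lon)
  out[bad, ] <- NA_integer_
  out
}
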