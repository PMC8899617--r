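#' Read and write gridded cubes as portable text files
#'
#' Cubes are stored as a plain-text file: a commented header carrying the
#' grid specification and the age axis, followed by a wide CSV table with
#' one row per grid cell (`row,col,<one column per slice>`). Missing cells
#' are written as `NA`. The format round-trips bit-identically through
#' [write_precip_cube()] / [read_precipitation_cube()].
#'
#' @param cube A [precip_cube()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_precip_cube <- function(cube, path) {
  stopifnot(inherits(cube, "precip_cube"))
  write_cube_file(cube$values, cube$grid, cube$time, path,
                  variable = "precip", digits = 17)
}

#' @rdname write_precip_cube
#' @param variable_name Name of the variable expected in the file header.
#' @return For the reader, a validated [precip_cube()].
#' @export
read_precipitation_cube <- function(path, variable_name = "precip") {
  parsed <- read_cube_file(path, variable_name)
  precip_cube(parsed$values, parsed$grid, parsed$time)
}

#' Write / read a biome cube and its legend
#'
#' The cube uses the same header + wide-CSV layout as precipitation cubes;
#' the legend is a separate CSV with columns `code,name,open_or_forest`.
#' Reading fails with a diagnostic listing any cube code absent from the
#' legend; legend entries unused by the cube are retained.
#'
#' @param cube A [biome_cube()].
#' @param path Cube file path.
#' @param legend_path Legend CSV path.
#' @return `path` invisibly (writers); a [biome_cube()] (reader).
#' @export
write_biome_cube <- function(cube, path, legend_path = NULL) {
  stopifnot(inherits(cube, "biome_cube"))
  write_cube_file(cube$codes, cube$grid, cube$time, path,
                  variable = "biome", digits = NA)
  if (!is.null(legend_path)) write_biome_legend(cube$legend, legend_path)
  invisible(path)
}

#' @rdname write_biome_cube
#' @export
read_biome_cube <- function(path, legend_path) {
  parsed <- read_cube_file(path, "biome")
  legend <- read_biome_legend(legend_path)
  storage.mode(parsed$values) <- "integer"
  biome_cube(parsed$values, parsed$grid, parsed$time, legend)
}

#' @rdname write_biome_cube
#' @param legend Legend data frame.
#' @export
write_biome_legend <- function(legend, legend_path) {
  legend <- validate_biome_legend(legend)
  utils::write.csv(legend, legend_path, row.names = FALSE, quote = TRUE)
  invisible(legend_path)
}

#' @rdname write_biome_cube
#' @export
read_biome_legend <- function(legend_path) {
  if (!file.exists(legend_path)) stop("legend file not found: ", legend_path)
  validate_biome_legend(utils::read.csv(legend_path, stringsAsFactors = FALSE))
}

write_cube_file <- function(values, grid, time, path, variable, digits = 17) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  hdr <- c(
    "# refugia cube v1",
    paste0("# variable=", variable),
    paste0("# n_rows=", grid$n_rows),
    paste0("# n_cols=", grid$n_cols),
    paste0("# lat_origin=", format(grid$lat_origin, digits = 15)),
    paste0("# lon_origin=", format(grid$lon_origin, digits = 15)),
    paste0("# resolution=", format(grid$resolution, digits = 15)),
    paste0("# crs=", grid$crs_label),
    paste0("# ages=", paste(format(time$ages, digits = 15, trim = TRUE),
                            collapse = ","))
  )
  writeLines(hdr, con)
  n_t <- length(time$ages)
  idx <- expand.grid(col = seq_len(grid$n_cols), row = seq_len(grid$n_rows))
  flat <- matrix(values, nrow = grid$n_rows * grid$n_cols, ncol = n_t)
  cell <- (idx$col - 1L) * grid$n_rows + idx$row
  tab <- data.frame(row = idx$row, col = idx$col)
  vals <- flat[cell, , drop = FALSE]
  if (!is.na(digits)) {
    vtab <- apply(vals, 2, function(v) {
      out <- formatC(v, digits = digits, format = "g")
      out[is.na(v)] <- "NA"
      out
    })
  } else {
    vtab <- apply(vals, 2, function(v) {
      out <- as.character(v)
      out[is.na(v)] <- "NA"
      out
    })
  }
  vtab <- matrix(vtab, nrow = nrow(tab))
  colnames(vtab) <- paste0("t", seq_len(n_t))
  utils::write.csv(cbind(tab, as.data.frame(vtab)), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

read_cube_file <- function(path, variable_name) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    pat <- paste0("^# ", key, "=")
    hit <- hdr[grepl(pat, hdr)]
    if (length(hit) != 1) stop("malformed cube header: missing ", key)
    sub(pat, "", hit)
  }
  if (!identical(get("variable"), variable_name))
    stop("missing variable '", variable_name, "' (file holds '",
         get("variable"), "')")
  grid <- grid_spec(
    n_rows = as.integer(get("n_rows")), n_cols = as.integer(get("n_cols")),
    lat_origin = as.numeric(get("lat_origin")),
    lon_origin = as.numeric(get("lon_origin")),
    resolution = as.numeric(get("resolution")), crs_label = get("crs")
  )
  time <- time_axis(as.numeric(strsplit(get("ages"), ",")[[1]]))
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  n_t <- length(time$ages)
  need <- c("row", "col", paste0("t", seq_len(n_t)))
  if (!all(need %in% names(tab))) stop("cube table is missing columns")
  if (nrow(tab) != grid$n_rows * grid$n_cols)
    stop("cube table has ", nrow(tab), " rows; expected ",
         grid$n_rows * grid$n_cols)
  values <- array(NA_real_, dim = c(grid$n_rows, grid$n_cols, n_t))
  for (t in seq_len(n_t)) {
    values[cbind(tab$row, tab$col, t)] <- as.numeric(tab[[paste0("t", t)]])
  }
  list(values = values, grid = grid, time = time)
}

#' Write a single-band grid layer as an ESRI ASCII raster
#'
#' Georeferenced plain-text raster (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows north to south), readable
#' by standard GIS software. Logical layers are written as 0/1 bytes with
#' nodata 255; numeric layers use nodata -9999 by default.
#'
#' @param layer Numeric or logical matrix conforming to `grid`.
#' @param path Output path (conventionally `.asc`).
#' @param grid A [grid_spec()].
#' @param nodata Value written for `NA` cells; default 255 for logical
#'   layers, -9999 otherwise.
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path, grid, nodata = NULL) {
  stopifnot(inherits(grid, "grid_spec"),
            is.matrix(layer),
            nrow(layer) == grid$n_rows, ncol(layer) == grid$n_cols)
  logical_layer <- is.logical(layer)
  if (is.null(nodata)) nodata <- if (logical_layer) 255 else -9999
  vals <- layer
  if (logical_layer) vals <- ifelse(layer, 1L, 0L)
  vals[is.na(vals)] <- nodata
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$n_cols),
    paste("nrows", grid$n_rows),
    paste("xllcorner", format(grid$lon_origin - grid$resolution / 2, digits = 15)),
    paste("yllcorner", format(grid$lat_origin - (grid$n_rows - 1) * grid$resolution -
                                grid$resolution / 2, digits = 15)),
    paste("cellsize", format(grid$resolution, digits = 15)),
    paste("NODATA_value", format(nodata, digits = 15))
  ), con)
  for (r in seq_len(grid$n_rows)) {
    writeLines(paste(formatC(vals[r, ], digits = 17, format = "g"),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_raster
#' @param logical_layer If `TRUE`, decode the band back to logical
#'   (`1 -> TRUE`, `0 -> FALSE`, nodata -> `NA`).
#' @return For the reader, a list with `values` (matrix), `grid`
#'   (a [grid_spec()]) and `nodata`.
#' @export
read_raster <- function(path, logical_layer = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  kv <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys)) stop("not an ESRI ASCII raster: ", path)
  n_rows <- as.integer(vals["nrows"]); n_cols <- as.integer(vals["ncols"])
  res <- unname(vals["cellsize"])
  grid <- grid_spec(
    n_rows = n_rows, n_cols = n_cols,
    lat_origin = unname(vals["yllcorner"]) + (n_rows - 1) * res + res / 2,
    lon_origin = unname(vals["xllcorner"]) + res / 2,
    resolution = res
  )
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != n_rows * n_cols)
    stop("raster body has wrong number of values")
  m <- matrix(body, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  m[m == vals["nodata_value"]] <- NA
  if (logical_layer) m <- m == 1
  list(values = m, grid = grid, nodata = unname(vals["nodata_value"]))
}
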