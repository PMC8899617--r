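#' Reclassify a biome cube into open/forest states
#'
#' Collapses the full biome legend to a binary open/forest cube using the
#' legend's `open_or_forest` column (or a user-supplied lookup). The
#' default mapping shipped with the package treats forest and woodland
#' biomes (evergreen, semi-deciduous and deciduous tropical forest,
#' temperate/open conifer forest and woodland, sclerophyll woodland) as
#' forest and shrublands, savannah, grassland and desert as open; it is
#' fully overridable because the split is an analysis choice.
#'
#' @param cube A [biome_cube()].
#' @param lookup Optional named character vector `code -> "open"/"forest"`;
#'   default taken from the cube legend.
#' @return Object of class `open_forest_cube` with fields `grid`, `time`
#'   and `class` (integer array, 1 = open, 2 = forest, `NA` missing).
#' @export
reclassify_open_forest <- function(cube, lookup = NULL) {
  stopifnot(inherits(cube, "biome_cube"))
  if (is.null(lookup)) lookup <- open_forest_lookup(cube)
  obs <- unique(cube$codes[!is.na(cube$codes)])
  unmapped <- setdiff(as.character(obs), names(lookup))
  if (length(unmapped) > 0)
    stop("open/forest lookup does not map codes: ",
         paste(sort(as.integer(unmapped)), collapse = ", "))
  bad <- !lookup %in% c("open", "forest")
  if (any(bad)) stop("lookup values must be 'open' or 'forest'")
  cls <- array(NA_integer_, dim = dim(cube$codes))
  nz <- !is.na(cube$codes)
  cls[nz] <- ifelse(lookup[as.character(cube$codes[nz])] == "open", 1L, 2L)
  structure(list(grid = cube$grid, time = cube$time, class = cls),
            class = "open_forest_cube")
}

#' @export
print.open_forest_cube <- function(x, ...) {
  cat(sprintf("<open_forest_cube> %d x %d x %d (1 = open, 2 = forest)\n",
              dim(x$class)[1], dim(x$class)[2], dim(x$class)[3]))
  invisible(x)
}

#' Bivariate stable/changing x open/forest classification
#'
#' A cell is *stable* when its open/forest state never changes over the
#' record, *changing* otherwise. Changing cells are labelled by their
#' majority state across slices; an exact tie is labelled open (fixed
#' convention).
#'
#' @param of_cube An `open_forest_cube` with >= 2 slices.
#' @return Character matrix with values `stable_open`, `stable_forest`,
#'   `changing_open`, `changing_forest` (`NA` off land).
#' @export
stability_class <- function(of_cube) {
  stopifnot(inherits(of_cube, "open_forest_cube"))
  if (dim(of_cube$class)[3] < 2) stop("need at least 2 time slices")
  apply(of_cube$class, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_character_)
    n_open <- sum(v == 1L)
    n_forest <- sum(v == 2L)
    if (n_forest == 0) "stable_open"
    else if (n_open == 0) "stable_forest"
    else if (n_open >= n_forest) "changing_open"
    else "changing_forest"
  })
}

#' @rdname ecotone_levels
#' @export
stability_levels <- function() {
  c("stable_open", "stable_forest", "changing_open", "changing_forest")
}

#' Ecotone cells in a single slice
#'
#' A cell is ecotonal in a slice when its 3x3 neighbourhood (centre
#' included) contains at least one open and at least one forest land
#' cell. Off-grid and sea neighbours are ignored: coastal windows shrink
#' to the available land cells, and there is no wrap-around at grid
#' edges. The result is symmetric under swapping the open and forest
#' labels.
#'
#' @param of_slice Integer matrix, one slice of an `open_forest_cube`
#'   (1 = open, 2 = forest, `NA` missing).
#' @return Logical matrix; sea cells are `NA`.
#' @export
ecotone_slice <- function(of_slice) {
  stopifnot(is.matrix(of_slice))
  nr <- nrow(of_slice); nc <- ncol(of_slice)
  open <- !is.na(of_slice) & of_slice == 1L
  forest <- !is.na(of_slice) & of_slice == 2L
  n_open <- neighbourhood_sum(open)
  n_forest <- neighbourhood_sum(forest)
  out <- n_open >= 1 & n_forest >= 1
  out[is.na(of_slice)] <- NA
  out
}

# sum of a logical matrix over each cell's 3x3 window (centre included),
# truncated at the grid edges
neighbourhood_sum <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  acc <- matrix(0L, nr, nc)
  xi <- matrix(as.integer(x), nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    r0 <- max(1, 1 - dr); r1 <- min(nr, nr - dr)
    c0 <- max(1, 1 - dc); c1 <- min(nc, nc - dc)
    if (r0 > r1 || c0 > c1) next    # shift larger than the grid
    r_src <- r0:r1; c_src <- c0:c1
    acc[r_src + dr, c_src + dc] <- acc[r_src + dr, c_src + dc] +
      xi[r_src, c_src]
  }
  acc
}

#' Ecotone persistence over the record
#'
#' Fraction of time slices in which each cell is ecotonal (per
#' [ecotone_slice()]), classed as: `persistent` (every slice),
#' `at_least_half` (half or more but not all), `intermittent` (some but
#' less than half) and `never`.
#'
#' @param of_cube An `open_forest_cube` with >= 2 slices.
#' @return List with `fraction` (numeric matrix in `[0, 1]`) and `class`
#'   (character matrix; `NA` off land).
#' @export
ecotone_persistence <- function(of_cube) {
  stopifnot(inherits(of_cube, "open_forest_cube"))
  n_t <- dim(of_cube$class)[3]
  if (n_t < 2) stop("need at least 2 time slices")
  count <- matrix(0L, dim(of_cube$class)[1], dim(of_cube$class)[2])
  any_na <- matrix(FALSE, nrow(count), ncol(count))
  d <- dim(of_cube$class)
  for (t in seq_len(n_t)) {
    e <- ecotone_slice(matrix(of_cube$class[, , t], d[1], d[2]))
    any_na <- any_na | is.na(e)
    count <- count + ifelse(is.na(e), 0L, as.integer(e))
  }
  fraction <- count / n_t
  fraction[any_na] <- NA
  cls <- matrix(NA_character_, nrow(count), ncol(count))
  ok <- !is.na(fraction)
  cls[ok & count == n_t] <- "persistent"
  cls[ok & count < n_t & fraction >= 0.5] <- "at_least_half"
  cls[ok & count > 0 & fraction < 0.5] <- "intermittent"
  cls[ok & count == 0] <- "never"
  list(fraction = fraction, class = cls)
}

#' Category levels used by the classification layers
#'
#' Fixed level orders for the ecotone-persistence and stable/changing
#' classifications, convenient as the `levels` argument of
#' [class_share()].
#'
#' @return Character vector of category labels.
#' @export
ecotone_levels <- function() {
  c("persistent", "at_least_half", "intermittent", "never")
}

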