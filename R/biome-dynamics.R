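#' Biome richness per cell
#'
#' Number of distinct biome codes a cell passes through over the full time
#' axis. Richness 1 means a stable biome throughout.
#'
#' @param cube A [biome_cube()].
#' @return Integer matrix (`NA` off land).
#' @export
biome_richness <- function(cube) {
  stopifnot(inherits(cube, "biome_cube"))
  land <- land_mask(cube)
  out <- apply(cube$codes, c(1, 2),
               function(v) length(unique(v[!is.na(v)])))
  storage.mode(out) <- "integer"
  out[!land] <- NA_integer_
  out
}

#' Biome transition count per cell
#'
#' Number of consecutive-slice pairs whose biome code differs, i.e. how
#' often the cell switched state over the record.
#'
#' @param cube A [biome_cube()] with at least 2 slices.
#' @return Integer matrix (`NA` off land).
#' @export
transition_count <- function(cube) {
  stopifnot(inherits(cube, "biome_cube"))
  n_t <- length(cube$time$ages)
  if (n_t < 2) stop("need at least 2 time slices")
  land <- land_mask(cube)
  diffs <- cube$codes[, , -1, drop = FALSE] != cube$codes[, , -n_t, drop = FALSE]
  out <- apply(diffs, c(1, 2), sum)
  storage.mode(out) <- "integer"
  out[!land] <- NA_integer_
  out
}

#' Mean-recurrence class of biome change
#'
#' Converts a transition count into the mean recurrence interval
#' `r = span / n` (kyr between changes) and bins it into the classes used
#' to describe biome-alternation tempo. Boundaries belong to the slower
#' (less frequent) class; a cell with no changes is `"stable"`, and a
#' single change over a 120-kyr span (r = 120) falls in the explicit
#' `">60 kyr"` class.
#'
#' @param transitions Integer matrix from [transition_count()].
#' @param span_kyr Length of the analysis window in kyr (e.g.
#'   `cube$time$span`).
#' @return Matrix of ordered factor levels `stable`, `>60 kyr`,
#'   `60-20 kyr`, `20-10 kyr`, `10-5 kyr`, `<5 kyr` (as character, with
#'   attribute `levels`).
#' @export
recurrence_class <- function(transitions, span_kyr) {
  if (span_kyr <= 0) stop("span must be positive")
  if (any(transitions < 0, na.rm = TRUE)) stop("negative transition count")
  lv <- recurrence_levels()
  cls <- function(n) {
    if (is.na(n)) return(NA_character_)
    if (n == 0) return("stable")
    r <- span_kyr / n
    if (r > 60) ">60 kyr"
    else if (r >= 20) "60-20 kyr"
    else if (r >= 10) "20-10 kyr"
    else if (r >= 5) "10-5 kyr"
    else "<5 kyr"
  }
  out <- apply(transitions, c(1, 2), cls)
  attr(out, "levels") <- lv
  out
}

#' Ordered levels of the recurrence classification
#'
#' @return Character vector from `"stable"` to `"<5 kyr"`, slowest to
#'   fastest alternation.
#' @export
recurrence_levels <- function() {
  c("stable", ">60 kyr", "60-20 kyr", "20-10 kyr", "10-5 kyr", "<5 kyr")
}

#' Modal biome per cell
#'
#' The biome code occupying the most time slices at each cell; ties are
#' broken by the smallest code (a fixed, documented convention).
#'
#' @param cube A [biome_cube()].
#' @return Integer matrix of codes (`NA` off land).
#' @export
modal_biome <- function(cube) {
  stopifnot(inherits(cube, "biome_cube"))
  land <- land_mask(cube)
  out <- apply(cube$codes, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_integer_)
    counts <- table(v)
    cand <- as.integer(names(counts)[counts == max(counts)])
    min(cand)
  })
  storage.mode(out) <- "integer"
  out[!land] <- NA_integer_
  out
}

#' Pooled biome frequencies within a mask
#'
#' Pools every (cell, slice) pair inside the mask across the whole time
#' axis and reports the share of each biome code, in percent (summing to
#' 100). This is the gross abundance of each biome over the record, as
#' opposed to the per-cell modal view.
#'
#' @param cube A [biome_cube()].
#' @param mask Logical matrix or [persistence_mask()] result.
#' @return Data frame `code`, `name`, `n_cell_slices`, `pct`, sorted by
#'   `pct` descending.
#' @export
pooled_biome_frequency <- function(cube, mask) {
  stopifnot(inherits(cube, "biome_cube"))
  if (inherits(mask, "refugia_mask")) mask <- mask$mask
  stopifnot(is.logical(mask))
  land <- land_mask(cube)
  if (any(mask & !land)) stop("mask contains non-land cells")
  if (!any(mask)) stop("empty mask")
  n_t <- length(cube$time$ages)
  sel <- array(mask, dim = dim(cube$codes))  # recycled over slices
  pooled <- cube$codes[sel]
  counts <- table(pooled)
  out <- data.frame(code = as.integer(names(counts)),
                    n_cell_slices = as.integer(counts))
  out$name <- cube$legend$name[match(out$code, cube$legend$code)]
  out$pct <- 100 * out$n_cell_slices / sum(out$n_cell_slices)
  out <- out[order(-out$pct, out$code), c("code", "name", "n_cell_slices", "pct")]
  rownames(out) <- NULL
  out
}

#' Class-share table of a categorical layer within a mask
#'
#' Helper mirroring the per-refugium histograms: percentage of masked area
#' (and of cells) in each category of a categorical grid layer.
#'
#' @param layer Matrix of category labels (character or integer).
#' @param mask Logical matrix or [persistence_mask()] result.
#' @param areas Cell-area matrix.
#' @param levels Optional vector fixing category order (zero-share
#'   categories retained).
#' @return Data frame `class`, `pct_area`, `pct_cells`, `n_cells`.
#' @export
class_share <- function(layer, mask, areas, levels = NULL) {
  if (inherits(mask, "refugia_mask")) mask <- mask$mask
  stopifnot(identical(dim(layer), dim(mask)))
  vals <- layer[mask]
  wts <- areas[mask]
  keep <- !is.na(vals)
  vals <- vals[keep]; wts <- wts[keep]
  if (length(vals) == 0) stop("no classified cells in mask")
  if (is.null(levels)) levels <- sort(unique(vals))
  f <- factor(vals, levels = levels)
  a <- tapply(wts, f, sum, default = 0)
  n <- table(f)
  data.frame(class = levels,
             pct_area = 100 * as.numeric(a) / sum(wts),
             pct_cells = 100 * as.numeric(n) / length(vals),
             n_cells = as.integer(n),
             row.names = NULL)
}
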