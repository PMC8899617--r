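#' Per-slice habitability
#'
#' A cell is habitable in a slice when its precipitation lies in the closed
#' interval `[lower, upper]` of the envelope. Missing cells are not
#' habitable.
#'
#' @param precip_slice Numeric matrix, one time slice of a precipitation
#'   cube (mm/yr, `NA` missing).
#' @param thresholds A [threshold_pair()].
#' @return Logical matrix.
#' @export
slice_habitability <- function(precip_slice, thresholds) {
  stopifnot(inherits(thresholds, "threshold_pair"), is.matrix(precip_slice))
  ok <- !is.na(precip_slice) &
    precip_slice >= thresholds$lower & precip_slice <= thresholds$upper
  ok[is.na(ok)] <- FALSE
  ok
}

#' Refugia persistence mask
#'
#' A cell belongs to the persistence mask when it is habitable in every
#' time slice of the cube, i.e. the logical AND of [slice_habitability()]
#' over time. Widening the envelope can only add cells, so nested
#' envelopes produce nested masks (narrow within broad).
#'
#' @param cube A [precip_cube()] with at least 2 slices.
#' @param thresholds A [threshold_pair()].
#' @param level Label for the refugia level (e.g. `"narrow"`, `"broad"`).
#' @return Object of class `refugia_mask` with fields `grid`, `level`,
#'   `mask` (logical matrix) and `thresholds`.
#' @export
persistence_mask <- function(cube, thresholds, level = "narrow") {
  stopifnot(inherits(cube, "precip_cube"))
  if (length(cube$time$ages) < 2) stop("need at least 2 time slices")
  within <- !is.na(cube$values) &
    cube$values >= thresholds$lower & cube$values <= thresholds$upper
  mask <- apply(within, c(1, 2), all)
  structure(list(grid = cube$grid, level = level, mask = mask,
                 thresholds = thresholds),
            class = "refugia_mask")
}

#' @export
print.refugia_mask <- function(x, ...) {
  cat(sprintf("<refugia_mask> level '%s', %d cells, envelope [%g, %g] mm/yr\n",
              x$level, sum(x$mask), x$thresholds$lower, x$thresholds$upper))
  invisible(x)
}

#' Temporal precipitation statistics per cell
#'
#' Per-cell mean, standard deviation and coefficient of variation
#' (`cv = sd / mean`) of precipitation over all time slices, restricted to
#' a mask. The default divisor is the sample one (`count - 1`); set
#' `divisor = "population"` for `count`. CV is `NA` where the mean is zero.
#'
#' @param cube A [precip_cube()].
#' @param mask A [persistence_mask()] result, or a logical matrix; `NULL`
#'   computes over all land.
#' @param divisor `"sample"` (n-1) or `"population"` (n).
#' @return List of matrices `mean`, `sd`, `cv` (`NA` outside the mask),
#'   with the divisor recorded in attribute `divisor`.
#' @export
temporal_stats <- function(cube, mask = NULL,
                           divisor = c("sample", "population")) {
  stopifnot(inherits(cube, "precip_cube"))
  divisor <- match.arg(divisor)
  m <- resolve_mask(mask, cube)
  n_t <- length(cube$time$ages)
  mu <- apply(cube$values, c(1, 2), mean)
  ss <- apply(cube$values, c(1, 2), function(v) sum((v - mean(v))^2))
  denom <- if (divisor == "sample") n_t - 1 else n_t
  sd <- sqrt(ss / denom)
  mu[!m] <- NA; sd[!m] <- NA
  cv <- sd / mu
  cv[!is.na(mu) & mu == 0] <- NA
  structure(list(mean = mu, sd = sd, cv = cv), divisor = divisor)
}

resolve_mask <- function(mask, cube) {
  if (is.null(mask)) return(land_mask(cube))
  if (inherits(mask, "refugia_mask")) mask <- mask$mask
  stopifnot(is.logical(mask))
  land <- land_mask(cube)
  if (any(mask & !land)) stop("mask contains non-land cells")
  mask
}

#' Binned area summary of a grid layer
#'
#' Histogram of a per-cell layer over a mask, as percentages of the masked
#' area. Bins are left-closed right-open, except the last bin which is
#' closed; values falling below the first or above the last edge are
#' collected into open overflow bins so the percentages always total 100.
#' Area-weighted and raw cell-count percentages are both reported.
#'
#' @param layer Numeric matrix (e.g. temporal mean precipitation).
#' @param mask Logical matrix or [persistence_mask()] result.
#' @param areas Cell-area matrix from [cell_areas()].
#' @param bin_edges Strictly increasing numeric vector of edges.
#' @return Data frame with columns `bin`, `lower`, `upper`, `pct_area`,
#'   `pct_cells`, `n_cells`.
#' @export
binned_area_summary <- function(layer, mask, areas, bin_edges) {
  if (inherits(mask, "refugia_mask")) mask <- mask$mask
  stopifnot(is.matrix(layer), is.logical(mask),
            identical(dim(layer), dim(mask)))
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0) ||
      any(!is.finite(bin_edges)))
    stop("bin_edges must be finite and strictly increasing")
  vals <- layer[mask]
  wts <- areas[mask]
  if (any(is.na(vals))) stop("layer has NA values inside the mask")
  k <- length(bin_edges) - 1
  lower <- bin_edges[-length(bin_edges)]
  upper <- bin_edges[-1]
  # [e_i, e_{i+1}) with the last bin closed on the right
  bin <- findInterval(vals, bin_edges, rightmost.closed = TRUE)
  labs <- sprintf("[%g, %g%s", lower, upper,
                  c(rep(")", k - 1), "]"))
  out <- data.frame(bin = labs, lower = lower, upper = upper,
                    stringsAsFactors = FALSE)
  if (any(bin == 0)) {
    out <- rbind(data.frame(bin = sprintf("(-Inf, %g)", bin_edges[1]),
                            lower = -Inf, upper = bin_edges[1]), out)
  }
  if (any(bin == k + 1)) {
    out <- rbind(out, data.frame(bin = sprintf("(%g, Inf)", bin_edges[length(bin_edges)]),
                                 lower = bin_edges[length(bin_edges)], upper = Inf))
  }
  tot_a <- sum(wts); tot_n <- length(vals)
  out$pct_area <- vapply(seq_len(nrow(out)), function(i) {
    sel <- if (is.infinite(out$lower[i])) bin == 0
           else if (is.infinite(out$upper[i])) bin == k + 1
           else bin == match(out$bin[i], labs)
    100 * sum(wts[sel]) / tot_a
  }, numeric(1))
  out$n_cells <- vapply(seq_len(nrow(out)), function(i) {
    sel <- if (is.infinite(out$lower[i])) bin == 0
           else if (is.infinite(out$upper[i])) bin == k + 1
           else bin == match(out$bin[i], labs)
    sum(sel)
  }, integer(1))
  out$pct_cells <- 100 * out$n_cells / tot_n
  rownames(out) <- NULL
  out[, c("bin", "lower", "upper", "pct_area", "pct_cells", "n_cells")]
}

#' Label contiguous regions of a mask
#'
#' Connected-component labelling of a boolean grid under 4- (rook) or
#' 8-neighbour (queen) connectivity, used to find the largest contiguous
#' persistently habitable areas. Components are relabelled 1..k in
#' decreasing size order.
#'
#' @param mask Logical matrix or [persistence_mask()] result.
#' @param connectivity 4 or 8.
#' @param areas Optional cell-area matrix; adds `area_km2` to the table.
#' @return List with `labels` (integer matrix, 0 = background) and
#'   `regions` (data frame `label`, `n_cells`, optionally `area_km2`,
#'   sorted by size descending).
#' @export
label_contiguous_regions <- function(mask, connectivity = 4, areas = NULL) {
  if (inherits(mask, "refugia_mask")) mask <- mask$mask
  stopifnot(is.logical(mask), connectivity %in% c(4, 8))
  mask[is.na(mask)] <- FALSE
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  on_idx <- which(mask)
  if (length(on_idx) == 0)
    return(list(labels = labels,
                regions = data.frame(label = integer(0), n_cells = integer(0))))
  id <- match(seq_len(nr * nc), on_idx)  # cell -> vertex id or NA
  row <- ((on_idx - 1L) %% nr) + 1L
  col <- ((on_idx - 1L) %/% nr) + 1L
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- integer(0)
  for (o in offs) {
    r2 <- row + o[1]; c2 <- col + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    nb_id <- id[nb]
    keep <- !is.na(nb_id)
    edges <- c(edges, rbind(which(ok)[keep], nb_id[keep]))
  }
  g <- igraph::make_graph(edges = edges, n = length(on_idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  sizes <- sort(table(comp), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  new_lab <- relabel[as.character(comp)]
  labels[on_idx] <- as.integer(new_lab)
  regions <- data.frame(label = seq_along(sizes),
                        n_cells = as.integer(sizes))
  if (!is.null(areas)) {
    regions$area_km2 <- vapply(regions$label,
                               function(l) sum(areas[labels == l]), numeric(1))
  }
  rownames(regions) <- NULL
  list(labels = labels, regions = regions)
}
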