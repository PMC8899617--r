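#' Load a table of dated archaeological occupations
#'
#' Expected CSV columns: `site`, `horizon`, `age_central`, `age_min`,
#' `age_max` (all ages in ka BP, so `age_min` is the younger bound),
#' `lat`, `lon`, `region`. A missing `age_central` is filled with the
#' midpoint of the age interval. Rows violating `age_min <= age_central
#' <= age_max` are dropped with a row-level warning rather than failing
#' the whole load.
#'
#' @param path CSV path.
#' @return Validated data frame of occupation records.
#' @export
load_site_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "horizon", "age_central", "age_min", "age_max",
            "lat", "lon", "region")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("site table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0) {
    warning("site table is empty")
    return(tab[, need])
  }
  mid <- is.na(tab$age_central)
  tab$age_central[mid] <- (tab$age_min[mid] + tab$age_max[mid]) / 2
  bad <- is.na(tab$age_min) | is.na(tab$age_max) |
    tab$age_min > tab$age_max |
    tab$age_central < tab$age_min | tab$age_central > tab$age_max
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected (age interval invariant violated): rows ",
            paste(which(bad), collapse = ", "))
    tab <- tab[!bad, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab[, need]
}

#' Restrict occupations to the Late Pleistocene window
#'
#' Keeps records whose central age lies in the closed window (default
#' 10-130 ka, boundaries inclusive).
#'
#' @param records Occupation data frame (see [load_site_table()]).
#' @param window Two-element numeric, ka (younger, older).
#' @return Filtered data frame.
#' @export
filter_late_pleistocene <- function(records, window = c(10, 130)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  out <- records[records$age_central >= window[1] &
                   records$age_central <= window[2], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign occupation records to refugial zones
#'
#' Each record's coordinates are mapped to a grid cell (half-open cell
#' bounds, see [cell_index()]) and classed with precedence narrow >
#' broad > beyond: `narrow` if the cell is in the narrow persistence
#' mask, else `broad` if in the broad mask, else `beyond`.
#'
#' @param records Occupation data frame.
#' @param narrow,broad [persistence_mask()] results (narrow must be a
#'   subset of broad).
#' @return The records with added columns `row`, `col`, `zone`.
#' @export
assign_refugia_zone <- function(records, narrow, broad) {
  stopifnot(inherits(narrow, "refugia_mask"), inherits(broad, "refugia_mask"))
  if (any(narrow$mask & !broad$mask))
    stop("narrow mask is not nested within broad mask")
  idx <- cell_index(narrow$grid, records$lat, records$lon)
  outside <- is.na(idx[, "row"]) | is.na(idx[, "col"])
  if (any(outside))
    stop("record(s) outside the grid extent: rows ",
         paste(which(outside), collapse = ", "))
  in_narrow <- narrow$mask[idx]
  in_broad <- broad$mask[idx]
  records$row <- idx[, "row"]
  records$col <- idx[, "col"]
  records$zone <- ifelse(in_narrow, "narrow",
                         ifelse(in_broad, "broad", "beyond"))
  records
}

#' Occupation histogram by age bin, zone and region
#'
#' Counts occupations (by central age) in fixed-width age bins across the
#' analysis window. Bins are `[10, 20), ..., [110, 120), [120, 130]`
#' for the defaults: left-closed, with the final (oldest) bin closed.
#'
#' @param assignments Data frame from [assign_refugia_zone()] (needs
#'   `age_central`, `zone`, `region`).
#' @param bin_width Bin width in kyr (default 10).
#' @param window Analysis window in ka (default `c(10, 130)`).
#' @return Data frame `bin_lower`, `bin_upper`, `zone`, `region`, `n`
#'   covering every bin x zone x region combination (zeros included).
#' @export
occupation_histogram <- function(assignments, bin_width = 10,
                                 window = c(10, 130)) {
  if (nrow(assignments) == 0) {
    zones <- c("narrow", "broad", "beyond")
    edges <- seq(window[1], window[2], by = bin_width)
    k <- length(edges) - 1
    return(data.frame(bin_lower = rep(edges[-length(edges)], times = 3),
                      bin_upper = rep(edges[-1], times = 3),
                      zone = rep(zones, each = k),
                      region = NA_character_, n = 0L))
  }
  edges <- seq(window[1], window[2], by = bin_width)
  if (edges[length(edges)] != window[2])
    stop("window is not a multiple of bin_width")
  ages <- assignments$age_central
  in_win <- ages >= window[1] & ages <= window[2]
  ages <- ages[in_win]
  bin <- findInterval(ages, edges, rightmost.closed = TRUE)
  zones <- c("narrow", "broad", "beyond")
  regions <- sort(unique(assignments$region))
  k <- length(edges) - 1
  f_bin <- factor(bin, levels = seq_len(k))
  f_zone <- factor(assignments$zone[in_win], levels = zones)
  f_reg <- factor(assignments$region[in_win], levels = regions)
  counts <- as.data.frame(table(bin = f_bin, zone = f_zone, region = f_reg),
                          stringsAsFactors = FALSE)
  out <- data.frame(
    bin_lower = edges[as.integer(counts$bin)],
    bin_upper = edges[as.integer(counts$bin) + 1],
    zone = counts$zone, region = counts$region,
    n = as.integer(counts$Freq)
  )
  out[order(out$bin_lower, match(out$zone, zones), out$region), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Gaps in occupation continuity
#'
#' Takes the union of the closed age intervals `[age_min, age_max]` of all
#' records and returns the maximal sub-intervals of the analysis window
#' that no interval covers, with their durations (difference of bounds,
#' kyr). Two intervals that touch at a single age leave no gap; e.g.
#' dated ranges 92-70 ka and 69-58 ka leave exactly one 1-kyr gap at
#' 70-69 ka.
#'
#' @param records Occupation data frame with `age_min`, `age_max` (ka).
#' @param window Analysis window in ka; intervals are clipped to it. The
#'   default `NULL` uses the span of the records themselves (earliest to
#'   latest dated age), so gaps are breaks *between* occupations.
#' @return Data frame `gap_start`, `gap_end` (ka, younger/older bound of
#'   the uncovered interval) and `duration_kyr`; zero rows when the
#'   window is fully covered.
#' @export
continuity_gaps <- function(records, window = NULL) {
  empty <- data.frame(gap_start = numeric(0), gap_end = numeric(0),
                      duration_kyr = numeric(0))
  if (nrow(records) == 0) {
    if (is.null(window)) return(empty)
    return(data.frame(gap_start = window[1], gap_end = window[2],
                      duration_kyr = diff(window)))
  }
  if (is.null(window))
    window <- c(min(records$age_min), max(records$age_max))
  stopifnot(length(window) == 2, window[1] < window[2])
  lo <- pmax(records$age_min, window[1])
  hi <- pmin(records$age_max, window[2])
  keep <- lo <= hi
  lo <- lo[keep]; hi <- hi[keep]
  if (length(lo) == 0)
    return(data.frame(gap_start = window[1], gap_end = window[2],
                      duration_kyr = diff(window)))
  ord <- order(lo, hi)
  lo <- lo[ord]; hi <- hi[ord]
  gaps <- empty
  cover_end <- window[1]
  for (i in seq_along(lo)) {
    if (lo[i] > cover_end) {
      gaps <- rbind(gaps, data.frame(gap_start = cover_end, gap_end = lo[i],
                                     duration_kyr = lo[i] - cover_end))
    }
    cover_end <- max(cover_end, hi[i])
  }
  if (cover_end < window[2]) {
    gaps <- rbind(gaps, data.frame(gap_start = cover_end,
                                   gap_end = window[2],
                                   duration_kyr = window[2] - cover_end))
  }
  rownames(gaps) <- NULL
  gaps
}

#' Zone count summary
#'
#' Convenience tally of occupations per zone, overall and per region; the
#' three zone counts always partition the record set.
#'
#' @param assignments Data frame from [assign_refugia_zone()].
#' @return Data frame `region` (`"all"` plus each region), `narrow`,
#'   `broad`, `beyond`, `total`.
#' @export
zone_counts <- function(assignments) {
  zones <- c("narrow", "broad", "beyond")
  tally <- function(df) {
    n <- vapply(zones, function(z) sum(df$zone == z), integer(1))
    c(n, total = nrow(df))
  }
  rows <- list(c(region = "all", tally(assignments)))
  for (r in sort(unique(assignments$region))) {
    rows <- c(rows, list(c(region = r,
                           tally(assignments[assignments$region == r, ]))))
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  for (cn in c(zones, "total")) out[[cn]] <- as.integer(out[[cn]])
  out
}
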