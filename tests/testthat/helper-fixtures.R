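# Small in-code fixtures and independent oracles used across the suite.

tiny_grid <- function(nr = 4, nc = 4, lat0 = 1.75, lon0 = 10.25, res = 0.5) {
  grid_spec(nr, nc, lat0, lon0, res)
}

tiny_time <- function(n = 3, oldest = 130) {
  time_axis(seq(oldest, by = -1, length.out = n))
}

# precip cube from a function f(r, c, t) or a 3-d array
tiny_cube <- function(nr = 4, nc = 4, n_t = 3, f = function(r, c, t) 500,
                      grid = tiny_grid(nr, nc), time = tiny_time(n_t)) {
  v <- array(0, dim = c(nr, nc, n_t))
  for (r in 1:nr) for (c in 1:nc) for (t in 1:n_t) v[r, c, t] <- f(r, c, t)
  precip_cube(v, grid, time)
}

simple_legend <- function(k = 4, forest_from = 3) {
  data.frame(code = seq_len(k),
             name = paste0("b", seq_len(k)),
             open_or_forest = ifelse(seq_len(k) >= forest_from,
                                     "forest", "open"))
}

tiny_biome <- function(codes, legend = NULL, grid = NULL, time = NULL) {
  d <- dim(codes)
  if (is.null(legend)) legend <- simple_legend(max(codes, na.rm = TRUE))
  if (is.null(grid)) grid <- tiny_grid(d[1], d[2])
  if (is.null(time)) time <- tiny_time(d[3])
  biome_cube(codes, grid, time, legend)
}

random_precip_cube <- function(nr, nc, n_t, lo = 0, hi = 2000) {
  v <- array(runif(nr * nc * n_t, lo, hi), dim = c(nr, nc, n_t))
  precip_cube(v, tiny_grid(nr, nc), tiny_time(n_t))
}

random_biome_codes <- function(nr, nc, n_t, k = 4) {
  array(sample.int(k, nr * nc * n_t, replace = TRUE), dim = c(nr, nc, n_t))
}

# ---- independent oracles -------------------------------------------------

# persistence by explicit triple loop over cells and slices
oracle_persistence <- function(cube, lower, upper) {
  d <- dim(cube$values)
  out <- matrix(FALSE, d[1], d[2])
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    ok <- TRUE
    for (t in seq_len(d[3])) {
      v <- cube$values[r, c, t]
      if (is.na(v) || v < lower || v > upper) { ok <- FALSE; break }
    }
    out[r, c] <- ok
  }
  out
}

# empirical quantile by sorting and linear interpolation between order stats
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# connected components by BFS flood fill
oracle_label_count <- function(mask, connectivity = 4) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  offs <- list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  if (connectivity == 8)
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  count <- 0
  sizes <- integer(0)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    count <- count + 1
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]; size <- size + 1
      for (o in offs) {
        r <- cur[1] + o[1]; c <- cur[2] + o[2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue <- c(queue, list(c(r, c)))
        }
      }
    }
    sizes <- c(sizes, size)
  }
  list(count = count, sizes = sort(sizes, decreasing = TRUE))
}

# ecotone detection by explicit 9-cell window loop
oracle_ecotone_slice <- function(of_slice) {
  nr <- nrow(of_slice); nc <- ncol(of_slice)
  out <- matrix(NA, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(of_slice[r, c])) next
    vals <- c()
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
          !is.na(of_slice[rr, cc]))
        vals <- c(vals, of_slice[rr, cc])
    }
    out[r, c] <- any(vals == 1) && any(vals == 2)
  }
  out
}

# zone lookup per record, scalar at a time
oracle_zone <- function(lat, lon, grid, narrow_mask, broad_mask) {
  half <- grid$resolution / 2
  lats <- grid_lats(grid); lons <- grid_lons(grid)
  for (r in seq_len(grid$n_rows)) for (c in seq_len(grid$n_cols)) {
    south <- lats[r] - half; north <- lats[r] + half
    west <- lons[c] - half; east <- lons[c] + half
    if (lat >= south && lat < north && lon >= west && lon < east) {
      if (narrow_mask[r, c]) return("narrow")
      if (broad_mask[r, c]) return("broad")
      return("beyond")
    }
  }
  NA_character_
}

# uncovered sub-intervals by a fine sweep over the window
oracle_gaps_total <- function(lo, hi, window, step = 0.001) {
  xs <- seq(window[1] + step / 2, window[2] - step / 2, by = step)
  covered <- rep(FALSE, length(xs))
  for (i in seq_along(lo)) covered <- covered | (xs >= lo[i] & xs <= hi[i])
  sum(!covered) * step
}
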