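#' Parameters for the synthetic study-system generator
#'
#' The generator emulates the statistical structure of the pipeline's
#' inputs: a spatial precipitation gradient with periodic orbital-scale
#' forcing (default ~21-kyr period, echoing precessional variability) plus
#' Gaussian noise, precipitation-linked biomes with stochastic jitter, a
#' sea border to exercise coastline handling, and a planted set of
#' ground-truth refugial cells. The forcing phase varies smoothly across
#' the grid so that wet and dry extremes are spatially asynchronous.
#'
#' @param n_rows,n_cols Grid dimensions (default 24 x 36).
#' @param resolution Cell size in degrees (default 0.5).
#' @param lat_origin,lon_origin Centre of the top-left cell.
#' @param ages Age axis in ka (default 130, 129, ..., 10).
#' @param baseline_range Endpoints (mm/yr) of the west-east baseline
#'   precipitation gradient.
#' @param forcing_amplitude Amplitude of the periodic forcing, mm.
#' @param forcing_period Forcing period, kyr.
#' @param noise_sd Gaussian noise s.d., mm.
#' @param envelope A [threshold_pair()]; the habitability envelope the
#'   planted refugia are guaranteed to satisfy (default 248-1403 mm, the
#'   narrow forager envelope).
#' @param planted_refugia Logical matrix of ground-truth refugial cells;
#'   `NULL` plants a central rectangular block.
#' @param sea_border Width (cells) of the all-missing border ring.
#' @param biome_edges Strictly increasing precipitation cut-points (mm)
#'   defining the synthetic biome classes.
#' @param forest_split_mm Edge at which the open/forest split falls:
#'   biomes whose precipitation band lies at or above it are forest.
#' @param jitter_prob Probability that a biome code is replaced by an
#'   adjacent code, per cell-slice.
#' @return Object of class `synth_params`.
#' @export
synth_params <- function(n_rows = 24, n_cols = 36, resolution = 0.5,
                         lat_origin = 14, lon_origin = -17,
                         ages = seq(130, 10, by = -1),
                         baseline_range = c(100, 1600),
                         forcing_amplitude = 80, forcing_period = 21,
                         noise_sd = 30,
                         envelope = threshold_pair(248, 1403, 0.68, "fixed"),
                         planted_refugia = NULL, sea_border = 1,
                         biome_edges = seq(200, 1600, by = 200),
                         forest_split_mm = 1000, jitter_prob = 0.05) {
  stopifnot(noise_sd >= 0, jitter_prob >= 0, jitter_prob < 1,
            forcing_period > 0, forcing_amplitude >= 0,
            length(baseline_range) == 2,
            all(diff(biome_edges) > 0),
            inherits(envelope, "threshold_pair"))
  if (envelope$lower >= max(baseline_range) ||
      envelope$upper <= min(baseline_range))
    stop("envelope incompatible with baseline_range: no overlap")
  if (!forest_split_mm %in% biome_edges)
    stop("forest_split_mm must be one of biome_edges")
  grid <- grid_spec(n_rows, n_cols, lat_origin, lon_origin, resolution)
  time <- time_axis(ages)
  if (is.null(planted_refugia)) {
    planted_refugia <- matrix(FALSE, n_rows, n_cols)
    r0 <- max(sea_border + 1, floor(n_rows * 0.3))
    r1 <- min(n_rows - sea_border, ceiling(n_rows * 0.7))
    c0 <- max(sea_border + 1, floor(n_cols * 0.35))
    c1 <- min(n_cols - sea_border, ceiling(n_cols * 0.65))
    planted_refugia[r0:r1, c0:c1] <- TRUE
  }
  stopifnot(is.logical(planted_refugia),
            nrow(planted_refugia) == n_rows,
            ncol(planted_refugia) == n_cols)
  structure(list(grid = grid, time = time,
                 baseline_range = baseline_range,
                 forcing_amplitude = forcing_amplitude,
                 forcing_period = forcing_period, noise_sd = noise_sd,
                 envelope = envelope, planted_refugia = planted_refugia,
                 sea_border = sea_border, biome_edges = biome_edges,
                 forest_split_mm = forest_split_mm,
                 jitter_prob = jitter_prob),
            class = "synth_params")
}

sea_border_mask <- function(params) {
  nr <- params$grid$n_rows; nc <- params$grid$n_cols
  b <- params$sea_border
  sea <- matrix(FALSE, nr, nc)
  if (b > 0) {
    sea[c(seq_len(b), nr - seq_len(b) + 1), ] <- TRUE
    sea[, c(seq_len(b), nc - seq_len(b) + 1)] <- TRUE
  }
  sea
}

#' Generate a synthetic precipitation cube with planted refugia
#'
#' Each cell's trajectory is `baseline + amplitude * sin(2*pi * age /
#' period + phase) + noise`, with the baseline a west-east gradient and
#' the phase varying smoothly across the grid. Cells in the planted set
#' are then clipped into the habitability envelope in every slice, so the
#' planted set is persistently habitable by construction; every other
#' land cell is guaranteed at least one excursion outside the envelope
#' (cells whose trajectory never leaves it on its own are forced out in
#' one seeded slice). The planted set is therefore exactly the set of
#' persistently habitable land cells.
#'
#' @param params A [synth_params()].
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return List with `cube` (a [precip_cube()]) and `truth` (list:
#'   `planted` logical matrix, `envelope`, `forced_out` logical matrix of
#'   cells given an artificial excursion).
#' @export
synth_precip_cube <- function(params, seed = 1) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  grid <- params$grid; time <- params$time
  nr <- grid$n_rows; nc <- grid$n_cols; n_t <- length(time$ages)
  baseline <- matrix(rep(seq(params$baseline_range[1],
                             params$baseline_range[2], length.out = nc),
                         each = nr), nr, nc)
  phase <- outer(seq_len(nr), seq_len(nc),
                 function(r, c) 2 * pi * (r + c) / (nr + nc))
  values <- array(NA_real_, dim = c(nr, nc, n_t))
  for (t in seq_len(n_t)) {
    forcing <- params$forcing_amplitude *
      sin(2 * pi * time$ages[t] / params$forcing_period + phase)
    eps <- if (params$noise_sd > 0)
      matrix(stats::rnorm(nr * nc, 0, params$noise_sd), nr, nc)
    else matrix(0, nr, nc)
    values[, , t] <- pmax(baseline + forcing + eps, 0)
  }
  sea <- sea_border_mask(params)
  values[array(sea, dim = dim(values))] <- NA_real_
  env <- params$envelope
  planted <- params$planted_refugia & !sea
  # planted cells: clip every slice into the (closed) envelope
  for (t in seq_len(n_t)) {
    sl <- values[, , t]
    sl[planted] <- pmin(pmax(sl[planted], env$lower), env$upper)
    values[, , t] <- sl
  }
  # non-planted land cells must exit the envelope in at least one slice
  land <- !sea
  inside_all <- apply(values >= env$lower & values <= env$upper,
                      c(1, 2), function(v) all(v[!is.na(v)]) && any(!is.na(v)))
  need_force <- land & !planted & inside_all
  forced <- matrix(FALSE, nr, nc)
  if (any(need_force)) {
    idx <- which(need_force)
    t_force <- sample.int(n_t, length(idx), replace = TRUE)
    out_val <- if (env$lower > 100) env$lower - 100 else env$upper + 100
    for (i in seq_along(idx)) {
      r <- ((idx[i] - 1) %% nr) + 1
      c <- ((idx[i] - 1) %/% nr) + 1
      values[r, c, t_force[i]] <- max(out_val, 0)
    }
    forced[idx] <- TRUE
  }
  cube <- precip_cube(values, grid, time)
  list(cube = cube,
       truth = list(planted = planted, envelope = env, forced_out = forced))
}

#' Derive a synthetic biome cube from precipitation
#'
#' Biome codes are the precipitation bin indices under
#' `params$biome_edges` (code 1 below the first edge, rising with
#' precipitation), optionally perturbed: with probability `jitter_prob` a
#' cell-slice code is replaced by an adjacent code. The auto-generated
#' legend marks bins at or above `forest_split_mm` as forest, drier bins
#' as open.
#'
#' @param precip A [precip_cube()] (typically from [synth_precip_cube()]).
#' @param params A [synth_params()].
#' @param seed Integer seed for the jitter.
#' @return A [biome_cube()].
#' @export
synth_biome_cube <- function(precip, params, seed = 1) {
  stopifnot(inherits(precip, "precip_cube"), inherits(params, "synth_params"))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  edges <- params$biome_edges
  k <- length(edges) + 1
  codes <- array(NA_integer_, dim = dim(precip$values))
  nz <- !is.na(precip$values)
  codes[nz] <- findInterval(precip$values[nz], edges) + 1L
  if (params$jitter_prob > 0) {
    n <- sum(nz)
    hit <- stats::runif(n) < params$jitter_prob
    dir <- ifelse(stats::runif(n) < 0.5, -1L, 1L)
    v <- codes[nz]
    nv <- v + ifelse(hit, dir, 0L)
    nv[nv < 1L] <- 2L       # bounce off the ends to an adjacent code
    nv[nv > k] <- k - 1L
    codes[nz] <- nv
  }
  legend <- synth_biome_legend(edges, params$forest_split_mm)
  biome_cube(codes, precip$grid, precip$time, legend)
}

synth_biome_legend <- function(edges, forest_split_mm) {
  k <- length(edges) + 1
  lowers <- c(-Inf, edges)
  uppers <- c(edges, Inf)
  data.frame(
    code = seq_len(k),
    name = sprintf("synthetic biome %02d (%s-%s mm)", seq_len(k),
                   ifelse(is.finite(lowers), lowers, "0"),
                   ifelse(is.finite(uppers), uppers, "inf")),
    open_or_forest = ifelse(lowers >= forest_split_mm, "forest", "open"),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic catalogue of dated occupations
#'
#' Draws `n_records` occupation records: with probability `p_inside` the
#' record is placed uniformly in a planted refugial cell, otherwise
#' uniformly in a non-refugial land cell; the point is then jittered
#' uniformly within the cell. Central ages are uniform over the analysis
#' window and age intervals extend a uniform half-width either side.
#' Region is `"north"` for records in the northern half of the grid,
#' `"south"` otherwise.
#'
#' @param truth Truth list from [synth_precip_cube()] (or any list with a
#'   `planted` logical matrix).
#' @param grid The [grid_spec()] the truth refers to.
#' @param land Logical land matrix (e.g. `land_mask(cube)`).
#' @param n_records Number of records (default 164).
#' @param p_inside Probability a record falls inside the planted refugia
#'   (default 0.77).
#' @param seed Integer seed.
#' @param age_window Window for central ages, ka.
#' @param halfwidth_range Range of interval half-widths, kyr.
#' @return Occupation data frame as produced by [load_site_table()], plus
#'   a logical `inside_truth` column.
#' @export
synth_site_catalog <- function(truth, grid, land, n_records = 164,
                               p_inside = 0.77, seed = 1,
                               age_window = c(10, 130),
                               halfwidth_range = c(1, 8)) {
  stopifnot(p_inside >= 0, p_inside <= 1, n_records >= 1)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  planted <- truth$planted
  inside_cells <- which(planted & land)
  outside_cells <- which(land & !planted)
  if (length(inside_cells) == 0 || length(outside_cells) == 0)
    stop("need both refugial and non-refugial land cells")
  inside <- stats::runif(n_records) < p_inside
  cell <- integer(n_records)
  cell[inside] <- inside_cells[sample.int(length(inside_cells),
                                          sum(inside), replace = TRUE)]
  cell[!inside] <- outside_cells[sample.int(length(outside_cells),
                                            sum(!inside), replace = TRUE)]
  nr <- grid$n_rows
  row <- ((cell - 1) %% nr) + 1
  col <- ((cell - 1) %/% nr) + 1
  lat <- grid_lats(grid)[row] + stats::runif(n_records, -0.49, 0.49) * grid$resolution
  lon <- grid_lons(grid)[col] + stats::runif(n_records, -0.49, 0.49) * grid$resolution
  central <- stats::runif(n_records, age_window[1], age_window[2])
  hw <- stats::runif(n_records, halfwidth_range[1], halfwidth_range[2])
  mid_lat <- mean(range(grid_lats(grid)))
  data.frame(
    site = sprintf("synth_site_%03d", seq_len(n_records)),
    horizon = sprintf("H%d", seq_len(n_records)),
    age_central = central,
    age_min = pmax(central - hw, 0),
    age_max = central + hw,
    lat = lat, lon = lon,
    region = ifelse(lat >= mid_lat, "north", "south"),
    inside_truth = inside,
    stringsAsFactors = FALSE
  )
}
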