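# Synthetic landscape generator: fine-resolution tree cover and loss-year
# rasters, lease polygons, gridded confounders and a clearing process with
# known parameters, so the whole causal pipeline can be exercised against
# ground truth.

#' Configuration for a synthetic landscape
#'
#' Collects every free parameter of the generator. Defaults describe a
#' mid-sized landscape with confounded mine placement, spatially
#' autocorrelated clearing hazards and block-level zero inflation.
#'
#' @param extent Width and height of the landscape in metres.
#' @param fine_cell_size Fine raster cell edge in metres. Must divide the
#'   pixel size together with `block_edge` only through the overlap-weighted
#'   aggregation, so any value dividing the extent is legal.
#' @param block_edge Aggregation block edge, in fine cells (blocks of
#'   `block_edge * fine_cell_size` metres play the role of the ~0.5 ha
#'   intermediate resolution).
#' @param pixel_size Analysis pixel edge in metres (default 1 km).
#' @param n_years Number of simulated years.
#' @param baseline_logit Baseline log-odds of a fine cell clearing in a year.
#' @param covariate_effects Named numeric vector of log-odds effects of the
#'   standardised covariates on the clearing hazard. Names from
#'   `c("treecover2000", "dist_road", "elevation", "slope", "popdens",
#'   "burned", "protected")`.
#' @param spatial_range,spatial_var Matern (nu = 1) range (metres) and
#'   marginal variance of the latent clearing-hazard field.
#' @param treatment_multiplier Ground-truth treatment effect theta: log-odds
#'   offset added to the clearing hazard inside active mining leases and
#'   their buffers from the activation year on.
#' @param zero_inflation Probability that a 1 km2 pixel-year is "suppressed"
#'   (no clearing anywhere in the pixel that year), generating excess zeros.
#' @param lease_counts Named counts of leases to place:
#'   `c(lml = , lel = , ssl = )` (mining, exploration, small-scale).
#' @param buffer_distance Treatment buffer around mining leases in metres.
#' @param confounding_strength Weight of road proximity in the probability
#'   that an exploration lease hosts a mine (0 = unconfounded placement).
#' @param n_regions Number of vertical administrative regions ("provinces").
#' @param road_intensity Expected number of road segments per 1000 km2.
#' @param seed Integer seed governing all randomness.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(extent = c(20000, 20000),
                             fine_cell_size = 25,
                             block_edge = 4,
                             pixel_size = 1000,
                             n_years = 12,
                             baseline_logit = -5,
                             covariate_effects = c(dist_road = -0.4,
                                                   popdens = 0.4,
                                                   slope = -0.2),
                             spatial_range = 6000,
                             spatial_var = 0.5,
                             treatment_multiplier = 0,
                             zero_inflation = 0.3,
                             lease_counts = c(lml = 2, lel = 6, ssl = 3),
                             buffer_distance = 25000,
                             confounding_strength = 1,
                             n_regions = 2,
                             road_intensity = 10,
                             seed = 1L) {
  stopifnot(length(extent) == 2, all(extent > 0),
            fine_cell_size > 0, n_years >= 1,
            zero_inflation >= 0, zero_inflation <= 1,
            spatial_var >= 0, spatial_range > 0, buffer_distance >= 0)
  if (any(abs(extent / fine_cell_size - round(extent / fine_cell_size)) > 1e-9))
    stop("extent must be divisible by fine_cell_size")
  if (any(abs(extent / pixel_size - round(extent / pixel_size)) > 1e-9))
    stop("extent must be divisible by pixel_size")
  lc <- c(lml = 0, lel = 0, ssl = 0)
  lc[names(lease_counts)] <- lease_counts
  structure(list(
    extent = as.numeric(extent), fine_cell_size = fine_cell_size,
    block_edge = as.integer(block_edge), pixel_size = pixel_size,
    n_years = as.integer(n_years), baseline_logit = baseline_logit,
    covariate_effects = covariate_effects,
    spatial_range = spatial_range, spatial_var = spatial_var,
    treatment_multiplier = treatment_multiplier,
    zero_inflation = zero_inflation, lease_counts = lc,
    buffer_distance = buffer_distance,
    confounding_strength = confounding_strength,
    n_regions = as.integer(n_regions), road_intensity = road_intensity,
    seed = as.integer(seed)), class = "landscape_config")
}

# ---- Gaussian random fields ------------------------------------------------

# Exact Matern (nu = 1) field on a lattice via Cholesky; returned as a matrix
# indexed [row (y, from bottom), col (x)]. Lattice kept coarse; callers
# interpolate. Uses the current RNG state.
.grf_lattice <- function(xs, ys, range, variance) {
  nx <- length(xs); ny <- length(ys)
  n <- nx * ny
  if (variance <= 0) return(matrix(0, ny, nx))
  g <- expand.grid(x = xs, y = ys)
  d <- as.matrix(stats::dist(g))
  C <- matern_cov(d, range = range, sigma = sqrt(variance)) +
    diag(1e-8 * variance, n)
  L <- chol(C)
  z <- drop(crossprod(L, stats::rnorm(n)))
  matrix(z, ny, nx, byrow = TRUE)
}

# bilinear interpolation of a lattice field at arbitrary points
.interp_bilinear <- function(field, xs, ys, px, py) {
  nx <- length(xs); ny <- length(ys)
  dx <- xs[2] - xs[1]; dy <- ys[2] - ys[1]
  ix <- pmin(pmax(floor((px - xs[1]) / dx) + 1, 1), nx - 1)
  iy <- pmin(pmax(floor((py - ys[1]) / dy) + 1, 1), ny - 1)
  tx <- pmin(pmax((px - xs[ix]) / dx, 0), 1)
  ty <- pmin(pmax((py - ys[iy]) / dy, 0), 1)
  f00 <- field[cbind(iy, ix)];     f10 <- field[cbind(iy, ix + 1)]
  f01 <- field[cbind(iy + 1, ix)]; f11 <- field[cbind(iy + 1, ix + 1)]
  (1 - tx) * (1 - ty) * f00 + tx * (1 - ty) * f10 +
    (1 - tx) * ty * f01 + tx * ty * f11
}

# simulate a Matern field at points, via coarse lattice + bilinear interp
.gaussian_field_at <- function(px, py, extent, range, variance,
                               lattice_spacing = NULL) {
  if (variance <= 0) return(rep(0, length(px)))
  if (is.null(lattice_spacing))
    lattice_spacing <- max(min(range / 3, max(extent) / 12), max(extent) / 40)
  xs <- seq(-lattice_spacing, extent[1] + lattice_spacing, by = lattice_spacing)
  ys <- seq(-lattice_spacing, extent[2] + lattice_spacing, by = lattice_spacing)
  f <- .grf_lattice(xs, ys, range, variance)
  .interp_bilinear(f, xs, ys, px, py)
}

# ---- grids -----------------------------------------------------------------

# 1 km pixel lattice as a tibble; pixel_id is row-major from the south-west
.pixel_lattice <- function(config) {
  npx <- as.integer(round(config$extent[1] / config$pixel_size))
  npy <- as.integer(round(config$extent[2] / config$pixel_size))
  g <- expand.grid(col = seq_len(npx), row = seq_len(npy))
  tibble::tibble(
    pixel_id = as.integer((g$row - 1) * npx + g$col),
    row = as.integer(g$row), col = as.integer(g$col),
    x = (g$col - 0.5) * config$pixel_size,
    y = (g$row - 0.5) * config$pixel_size)
}

# fine cell centres (vectors ordered to match matrix[row, col] filling by col)
.fine_centres <- function(config) {
  nfx <- as.integer(round(config$extent[1] / config$fine_cell_size))
  nfy <- as.integer(round(config$extent[2] / config$fine_cell_size))
  list(nfx = nfx, nfy = nfy,
       x = (seq_len(nfx) - 0.5) * config$fine_cell_size,
       y = (seq_len(nfy) - 0.5) * config$fine_cell_size)
}

.region_of <- function(x, extent_x, n_regions) {
  idx <- pmin(pmax(ceiling(x / (extent_x / n_regions)), 1), n_regions)
  paste0("P", idx)
}

# ---- covariates ------------------------------------------------------------

#' Generate landscape covariates
#'
#' Simulates the confounder set: fine-resolution tree cover in year 2000 and,
#' on the 1 km2 pixel lattice, distance to the nearest road (true Euclidean
#' distance to sampled road segments), elevation (smooth random field), slope
#' (gradient magnitude of elevation), population density (kernel mixture
#' around sampled towns), a recent-burning flag, an agro-ecological zone
#' category and a protected-area flag. Regions are vertical bands.
#'
#' @param config A [landscape_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `landscape_covariates` list with elements `treecover2000` (fine
#'   matrix, percent), `pixels` (tibble of per-pixel covariates), `roads`
#'   (segment matrix), `protected_polys`, and grid metadata.
#' @export
generate_covariates <- function(config, seed = config$seed) {
  set.seed(seed)
  fc <- .fine_centres(config)
  px <- .pixel_lattice(config)

  # tree cover: logistic transform of a smooth field plus cell-level speckle
  gx <- rep(fc$x, each = fc$nfy); gy <- rep(fc$y, times = fc$nfx)
  tc_field <- .gaussian_field_at(gx, gy, config$extent,
                                 range = max(config$spatial_range, 3000),
                                 variance = 1.2)
  tc <- 100 * stats::plogis(0.8 + tc_field + stats::rnorm(length(gx), 0, 0.3))
  treecover2000 <- matrix(tc, fc$nfy, fc$nfx)

  # roads: Poisson number of long straight segments
  n_road <- stats::rpois(1, config$road_intensity *
                            prod(config$extent) / 1e9) + 1L
  ang <- stats::runif(n_road, 0, pi)
  len <- stats::runif(n_road, 0.5, 1.2) * max(config$extent)
  sx <- stats::runif(n_road, 0, config$extent[1])
  sy <- stats::runif(n_road, 0, config$extent[2])
  roads <- cbind(x0 = sx - cos(ang) * len / 2, y0 = sy - sin(ang) * len / 2,
                 x1 = sx + cos(ang) * len / 2, y1 = sy + sin(ang) * len / 2)
  dist_road <- dist_points_segments(roads, px$x, px$y)

  # elevation and slope
  el_lat_sp <- max(config$extent) / 15
  exs <- seq(-el_lat_sp, config$extent[1] + el_lat_sp, by = el_lat_sp)
  eys <- seq(-el_lat_sp, config$extent[2] + el_lat_sp, by = el_lat_sp)
  el_lat <- .grf_lattice(exs, eys, range = max(config$extent) / 2, variance = 1)
  elev_of <- function(xx, yy)
    1100 + 150 * .interp_bilinear(el_lat, exs, eys, xx, yy)
  elevation <- elev_of(px$x, px$y)
  h <- config$pixel_size
  slope_x <- (elev_of(px$x + h, px$y) - elev_of(px$x - h, px$y)) / (2 * h)
  slope_y <- (elev_of(px$x, px$y + h) - elev_of(px$x, px$y - h)) / (2 * h)
  slope <- atan(sqrt(slope_x^2 + slope_y^2)) * 180 / pi  # degrees

  # population: kernel mixture around towns, denser near roads
  n_town <- max(1L, stats::rpois(1, 3))
  tx <- stats::runif(n_town, 0, config$extent[1])
  ty <- stats::runif(n_town, 0, config$extent[2])
  amp <- stats::rlnorm(n_town, log(50), 0.6)
  sig <- stats::runif(n_town, 2000, 5000)
  popdens <- rep(0.5, nrow(px))
  for (k in seq_len(n_town)) {
    d2 <- (px$x - tx[k])^2 + (px$y - ty[k])^2
    popdens <- popdens + amp[k] * exp(-d2 / (2 * sig[k]^2))
  }

  burned <- as.integer(stats::runif(nrow(px)) <
                         stats::plogis(-1 + 0.3 * scale(slope)[, 1]))

  # agro-ecological zones: latitudinal bands with a wavy boundary
  wob <- 0.08 * config$extent[2] * sin(2 * pi * px$x / config$extent[1])
  aez <- pmin(pmax(ceiling((px$y + wob) / (config$extent[2] / 3)), 1), 3)

  # protected areas: one or two convex polygons
  n_pa <- sample(1:2, 1)
  protected_polys <- lapply(seq_len(n_pa), function(i) {
    cx <- stats::runif(1, 0.15, 0.85) * config$extent[1]
    cy <- stats::runif(1, 0.15, 0.85) * config$extent[2]
    r <- stats::runif(1, 0.08, 0.18) * max(config$extent)
    a <- sort(stats::runif(9, 0, 2 * pi))
    convex_polygon(cx + r * stats::runif(9, 0.6, 1) * cos(a),
                   cy + r * stats::runif(9, 0.6, 1) * sin(a))
  })
  protected <- rep(FALSE, nrow(px))
  for (p in protected_polys)
    protected <- protected | points_in_polygon(p, px$x, px$y)

  pixels <- px
  pixels$region <- .region_of(px$x, config$extent[1], config$n_regions)
  pixels$dist_road <- dist_road
  pixels$elevation <- elevation
  pixels$slope <- slope
  pixels$popdens <- popdens
  pixels$burned <- burned
  pixels$aez <- as.integer(aez)
  pixels$protected <- as.integer(protected)

  structure(list(treecover2000 = treecover2000, pixels = pixels,
                 roads = roads, protected_polys = protected_polys,
                 config = config), class = "landscape_covariates")
}

# ---- leases ----------------------------------------------------------------

.polys_overlap <- function(a, b) {
  # SAT for two convex polygons
  axes <- NULL
  for (p in list(a, b)) {
    n <- nrow(p)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      e <- c(p[j, 1] - p[i, 1], p[j, 2] - p[i, 2])
      axes <- rbind(axes, c(-e[2], e[1]))
    }
  }
  for (k in seq_len(nrow(axes))) {
    pa <- a %*% axes[k, ]; pb <- b %*% axes[k, ]
    if (max(pa) <= min(pb) || max(pb) <= min(pa)) return(FALSE)
  }
  TRUE
}

.random_convex <- function(cx, cy, r, extent, n_pts = 9) {
  a <- sort(stats::runif(n_pts, 0, 2 * pi))
  x <- pmin(pmax(cx + r * stats::runif(n_pts, 0.55, 1) * cos(a), 0), extent[1])
  y <- pmin(pmax(cy + r * stats::runif(n_pts, 0.55, 1) * sin(a), 0), extent[2])
  convex_polygon(x, y)
}

#' Place exploration, mining and small-scale leases
#'
#' Exploration leases (LELs) are placed first as non-overlapping convex
#' polygons. Mining leases (LMLs) are then carved inside host LELs chosen
#' with probability increasing with road proximity, so mine placement is
#' confounded with a deforestation driver; `config$confounding_strength = 0`
#' makes the choice uniform. Small-scale leases (SSLs) are placed
#' independently. Activation years leave at least two pre-treatment and five
#' post-treatment years.
#'
#' @param config A [landscape_config()].
#' @param covariates Output of [generate_covariates()].
#' @param seed Integer seed; defaults to `config$seed + 1`.
#' @return A `lease_set` tibble with columns `id`, `lease_type`
#'   (`"LML"`, `"LEL"`, `"SSL"`), `active_from` (year, `NA` for never),
#'   `region` and a list-column `geometry` of CCW vertex matrices.
#' @export
place_leases <- function(config, covariates, seed = config$seed + 1L) {
  set.seed(seed)
  ext <- config$extent
  n_lel <- config$lease_counts[["lel"]]
  n_lml <- config$lease_counts[["lml"]]
  n_ssl <- config$lease_counts[["ssl"]]
  if (n_lml > n_lel) stop("need at least as many exploration as mining leases")

  lels <- list()
  tries <- 0
  while (length(lels) < n_lel) {
    tries <- tries + 1
    if (tries > 200 * max(n_lel, 1))
      stop("could not place exploration leases without overlap; ",
           "reduce lease_counts or enlarge the extent")
    r <- stats::runif(1, 0.08, 0.16) * max(ext)
    p <- .random_convex(stats::runif(1, r, ext[1] - r),
                        stats::runif(1, r, ext[2] - r), r, ext)
    if (!any(vapply(lels, .polys_overlap, logical(1), b = p))) {
      lels[[length(lels) + 1]] <- p
    }
  }

  # confounded host choice: nearer roads => more likely to become a mine
  host_idx <- integer(0)
  if (n_lml > 0 && n_lel > 0) {
    cent <- t(vapply(lels, polygon_centroid, numeric(2)))
    droad <- dist_points_segments(covariates$roads, cent[, 1], cent[, 2])
    sdd <- stats::sd(droad)
    w <- if (config$confounding_strength == 0 || !is.finite(sdd) || sdd == 0)
      rep(1, n_lel)
    else exp(-config$confounding_strength * droad / sdd)
    host_idx <- sample.int(n_lel, n_lml, prob = w)
  }

  year_lo <- min(3L, config$n_years)
  year_hi <- max(year_lo, config$n_years - 4L)
  geoms <- list(); type <- character(0); active <- integer(0)
  for (i in seq_along(lels)) {
    geoms[[length(geoms) + 1]] <- lels[[i]]
    type <- c(type, "LEL"); active <- c(active, NA_integer_)
  }
  for (i in seq_along(host_idx)) {
    geoms[[length(geoms) + 1]] <-
      .shrink_polygon(lels[[host_idx[i]]], stats::runif(1, 0.25, 0.45))
    type <- c(type, "LML")
    active <- c(active, sample(seq(year_lo, year_hi), 1))
  }
  for (i in seq_len(n_ssl)) {
    r <- stats::runif(1, 400, 900)
    geoms[[length(geoms) + 1]] <-
      .random_convex(stats::runif(1, r, ext[1] - r),
                     stats::runif(1, r, ext[2] - r), r, ext, n_pts = 7)
    type <- c(type, "SSL"); active <- c(active, NA_integer_)
  }

  cx <- vapply(geoms, function(g) polygon_centroid(g)[1], numeric(1))
  tibble::tibble(
    id = seq_along(geoms),
    lease_type = type,
    active_from = active,
    region = .region_of(cx, ext[1], config$n_regions),
    geometry = geoms) -> out
  class(out) <- c("lease_set", class(out))
  out
}

# ---- loss simulation -------------------------------------------------------

#' Simulate the clearing process
#'
#' Per fine cell and year, the first-clearing hazard is
#' `plogis(baseline_logit + covariate effects + spatial field + theta *
#' treated(t))`, where a cell is treated from the activation year of any
#' mining lease whose buffered footprint contains it. Independently, each
#' 1 km2 pixel-year is suppressed with probability `zero_inflation`, forcing
#' zero loss in that pixel-year (the excess-zero mechanism the outcome model
#' targets). `lossyear` records the first clearing year (0 = never cleared).
#'
#' @param config A [landscape_config()].
#' @param covariates Output of [generate_covariates()].
#' @param leases Output of [place_leases()].
#' @param seed Integer seed; defaults to `config$seed + 2`.
#' @return A list with `stack` (a `fine_raster_stack`: `treecover2000`,
#'   `lossyear`, origin, cell size, years) and `truth` (theta, coefficients,
#'   the hazard field, per-cell activation year and suppression draws).
#' @export
simulate_loss <- function(config, covariates, leases,
                          seed = config$seed + 2L) {
  set.seed(seed)
  fc <- .fine_centres(config)
  nfx <- fc$nfx; nfy <- fc$nfy
  gx <- rep(fc$x, each = nfy); gy <- rep(fc$y, times = nfx)
  npx <- as.integer(round(config$extent[1] / config$pixel_size))
  npy <- as.integer(round(config$extent[2] / config$pixel_size))
  # pixel index of each fine cell (row-major from SW, matches .pixel_lattice)
  pcol <- pmin(floor(gx / config$pixel_size) + 1, npx)
  prow <- pmin(floor(gy / config$pixel_size) + 1, npy)
  pix_of_cell <- as.integer((prow - 1) * npx + pcol)

  # linear predictor from standardised covariates
  eff <- config$covariate_effects
  lin <- rep(config$baseline_logit, nfy * nfx)
  pix <- covariates$pixels
  zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  for (nm in names(eff)) {
    cellval <- if (nm == "treecover2000") {
      zs(as.vector(covariates$treecover2000))
    } else if (nm %in% names(pix)) {
      zs(as.numeric(pix[[nm]]))[pix_of_cell]
    } else stop("unknown covariate effect: ", nm)
    lin <- lin + eff[[nm]] * cellval
  }
  field <- .gaussian_field_at(gx, gy, config$extent,
                              range = config$spatial_range,
                              variance = config$spatial_var)
  lin <- lin + field

  # earliest activation year of a covering buffered mining lease, per cell
  amin <- rep(Inf, nfy * nfx)
  act <- leases[leases$lease_type == "LML" & !is.na(leases$active_from), ]
  for (i in seq_len(nrow(act))) {
    d <- dist_points_polygon(act$geometry[[i]], gx, gy)
    hit <- d <= config$buffer_distance
    amin[hit] <- pmin(amin[hit], act$active_from[i])
  }

  lossyear <- integer(nfy * nfx)
  suppressed <- matrix(FALSE, npx * npy, config$n_years)
  alive <- rep(TRUE, nfy * nfx)
  for (t in seq_len(config$n_years)) {
    sup_t <- stats::runif(npx * npy) < config$zero_inflation
    suppressed[, t] <- sup_t
    idx <- which(alive)
    if (length(idx) == 0) next
    eta <- lin[idx] + config$treatment_multiplier * (t >= amin[idx])
    p <- stats::plogis(eta)
    lost <- stats::runif(length(idx)) < p & !sup_t[pix_of_cell[idx]]
    lossyear[idx[lost]] <- t
    alive[idx[lost]] <- FALSE
  }

  stack <- structure(list(
    treecover2000 = covariates$treecover2000,
    lossyear = matrix(as.integer(lossyear), nfy, nfx),
    origin = c(0, 0), cell_size = config$fine_cell_size,
    n_years = config$n_years), class = "fine_raster_stack")
  truth <- list(theta = config$treatment_multiplier,
                coefficients = eff,
                baseline_logit = config$baseline_logit,
                field = matrix(field, nfy, nfx),
                linpred = matrix(lin, nfy, nfx),
                activation_year = matrix(amin, nfy, nfx),
                suppressed = suppressed)
  list(stack = stack, truth = truth)
}

#' Generate a full landscape in one call
#'
#' Runs [generate_covariates()], [place_leases()] and [simulate_loss()] with
#' seeds derived from `config$seed`.
#'
#' @param config A [landscape_config()].
#' @return A `landscape` list: `config`, `covariates`, `leases`, `stack`,
#'   `truth`.
#' @export
simulate_landscape <- function(config) {
  covariates <- generate_covariates(config)
  leases <- place_leases(config, covariates)
  sim <- simulate_loss(config, covariates, leases)
  structure(list(config = config, covariates = covariates, leases = leases,
                 stack = sim$stack, truth = sim$truth), class = "landscape")
}

# ---- I/O -------------------------------------------------------------------

#' Write a raster matrix as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a six-line header then rows from north to
#' south. Values are written with full precision so integer rasters
#' round-trip exactly.
#'
#' @param mat Matrix, row 1 = southernmost row.
#' @param path Output file.
#' @param origin Coordinates of the south-west corner (metres).
#' @param cell_size Cell edge (metres).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(mat, path, origin = c(0, 0), cell_size = 1) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(mat)), paste("nrows", nrow(mat)),
    paste("xllcorner", format(origin[1], digits = 15)),
    paste("yllcorner", format(origin[2], digits = 15)),
    paste("cellsize", format(cell_size, digits = 15)),
    "NODATA_value -9999"), con)
  for (r in rev(seq_len(nrow(mat))))   # north first
    writeLines(paste(formatC(mat[r, ], format = "g", digits = 17),
                     collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_grid()] (or any .asc raster).
#' @return A list: `mat` (row 1 = south), `origin`, `cell_size`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- function(i) as.numeric(strsplit(trimws(hdr[i]), "\\s+")[[1]][2])
  ncols <- kv(1); nrows <- kv(2)
  vals <- scan(path, skip = 6, quiet = TRUE)
  mat <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  mat <- mat[rev(seq_len(nrows)), , drop = FALSE]
  list(mat = mat, origin = c(kv(3), kv(4)), cell_size = kv(5))
}

#' Write a landscape to disk as plain-text files
#'
#' Rasters go to ASCII grids, leases to GeoJSON (properties `id`,
#' `lease_type`, `active_from`, `region`) and the pixel covariate table to
#' CSV. [read_landscape()] round-trips integer rasters bit-identically.
#'
#' @param landscape A `landscape` from [simulate_landscape()].
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  st <- landscape$stack
  write_ascii_grid(st$treecover2000, file.path(path, "treecover2000.asc"),
                   st$origin, st$cell_size)
  write_ascii_grid(st$lossyear, file.path(path, "lossyear.asc"),
                   st$origin, st$cell_size)
  feats <- purrr::pmap(landscape$leases, function(id, lease_type, active_from,
                                                  region, geometry) {
    ring <- rbind(geometry, geometry[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(id = id, lease_type = lease_type,
                           active_from = if (is.na(active_from)) "never"
                                         else active_from,
                           region = region),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(split(ring, row(ring))) |>
                           lapply(as.numeric))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file.path(path, "leases.geojson"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(landscape$covariates$pixels,
                   file.path(path, "covariates.csv"))
  jsonlite::write_json(list(n_years = st$n_years,
                            pixel_size = landscape$config$pixel_size,
                            block_edge = landscape$config$block_edge),
                       file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a landscape written by [write_landscape()]
#'
#' @param path Directory produced by [write_landscape()].
#' @return A list with `stack`, `leases` and `pixels` mirroring the written
#'   objects (ground truth is not serialised).
#' @export
read_landscape <- function(path) {
  tc <- read_ascii_grid(file.path(path, "treecover2000.asc"))
  ly <- read_ascii_grid(file.path(path, "lossyear.asc"))
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  stack <- structure(list(
    treecover2000 = tc$mat,
    lossyear = matrix(as.integer(ly$mat), nrow(ly$mat), ncol(ly$mat)),
    origin = tc$origin, cell_size = tc$cell_size,
    n_years = as.integer(meta$n_years)), class = "fine_raster_stack")
  gj <- jsonlite::read_json(file.path(path, "leases.geojson"))
  leases <- purrr::map_dfr(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    ring <- ring[-nrow(ring), , drop = FALSE]
    colnames(ring) <- c("x", "y")
    af <- f$properties$active_from
    tibble::tibble(id = f$properties$id,
                   lease_type = f$properties$lease_type,
                   active_from = if (identical(af, "never")) NA_integer_
                                 else as.integer(af),
                   region = f$properties$region,
                   geometry = list(ring))
  })
  class(leases) <- c("lease_set", class(leases))
  pixels <- readr::read_csv(file.path(path, "covariates.csv"),
                            show_col_types = FALSE)
  list(stack = stack, leases = leases, pixels = pixels)
}
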