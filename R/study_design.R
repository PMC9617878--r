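# Study design: rasterised treatment masks around buffered mining leases,
# control pools carved from exploration leases, systematic subsampling,
# forest and region filters, and per-mine study frames.

#' Pixels treated by a buffered mining lease
#'
#' A pixel is treated when its 1 km2 square intersects the lease polygon
#' buffered by `buffer_distance` with positive area (boundary contact does
#' not count). Treatment is binary regardless of overlaps with other mines.
#'
#' @param pixels Tibble of pixel centres (`pixel_id`, `x`, `y`).
#' @param lease A CCW convex vertex matrix (one lease polygon).
#' @param buffer_distance Buffer radius in metres.
#' @param pixel_size Pixel edge in metres.
#' @return Integer vector of treated `pixel_id`s.
#' @export
treated_mask <- function(pixels, lease, buffer_distance = 25000,
                         pixel_size = 1000) {
  half <- pixel_size / 2
  hit <- squares_overlap_polygon(lease, pixels$x, pixels$y, half,
                                 strict = TRUE)
  if (buffer_distance > 0) {
    d <- dist_squares_polygon(lease, pixels$x, pixels$y, half)
    hit <- hit | d < buffer_distance
  }
  if (!any(hit))
    warning("treated mask is empty: lease does not intersect the grid")
  pixels$pixel_id[hit]
}

#' Candidate control pixels
#'
#' Controls are drawn from exploration leases: pixels touching any LEL
#' polygon, minus pixels touching any mining lease buffered by
#' `buffer_distance` (active or not) and minus small-scale leases buffered by
#' `ssl_buffer`. `pool = "anywhere"` relaxes the LEL restriction to the whole
#' grid (the sensitivity variant), keeping the same exclusions.
#'
#' @param pixels Tibble of pixel centres (`pixel_id`, `x`, `y`).
#' @param leases A `lease_set`.
#' @param buffer_distance Mining-lease exclusion buffer (metres).
#' @param ssl_buffer Small-scale-lease exclusion buffer (metres).
#' @param pool `"lel"` (default) or `"anywhere"`.
#' @param pixel_size Pixel edge in metres.
#' @return Integer vector of candidate control `pixel_id`s.
#' @export
control_pool <- function(pixels, leases, buffer_distance = 25000,
                         ssl_buffer = 5000, pool = c("lel", "anywhere"),
                         pixel_size = 1000) {
  pool <- match.arg(pool)
  half <- pixel_size / 2
  n <- nrow(pixels)
  inpool <- if (pool == "anywhere") rep(TRUE, n) else rep(FALSE, n)
  if (pool == "lel") {
    for (g in leases$geometry[leases$lease_type == "LEL"])
      inpool <- inpool | squares_overlap_polygon(g, pixels$x, pixels$y, half)
  }
  excl <- rep(FALSE, n)
  for (g in leases$geometry[leases$lease_type == "LML"]) {
    hit <- squares_overlap_polygon(g, pixels$x, pixels$y, half)
    if (buffer_distance > 0)
      hit <- hit | dist_squares_polygon(g, pixels$x, pixels$y, half) <
        buffer_distance
    excl <- excl | hit
  }
  for (g in leases$geometry[leases$lease_type == "SSL"]) {
    hit <- squares_overlap_polygon(g, pixels$x, pixels$y, half)
    if (ssl_buffer > 0)
      hit <- hit | dist_squares_polygon(g, pixels$x, pixels$y, half) <
        ssl_buffer
    excl <- excl | hit
  }
  ids <- pixels$pixel_id[inpool & !excl]
  if (length(ids) == 0)
    warning("control pool is empty")
  ids
}

#' Systematic lattice subsample
#'
#' Retains one fixed position per `factor x factor` tile of the pixel
#' lattice, anchored at the raster origin — the spacing device that removes
#' direct neighbours and thins spatial autocorrelation. The default
#' one-per-4x4 retains 1/16 of pixels; `scheme = "2x2"` retains one per 2x2
#' tile (25%), the alternative reading of a "25% systematic subsample".
#' Deterministic and idempotent.
#'
#' @param frame Tibble with integer `row` and `col` lattice coordinates.
#' @param factor Tile edge (pixels).
#' @param scheme `"4x4"` (one per `factor` tile) or `"2x2"`.
#' @return The retained rows of `frame`.
#' @export
systematic_subsample <- function(frame, factor = 4, scheme = c("4x4", "2x2")) {
  scheme <- match.arg(scheme)
  f <- if (scheme == "2x2") 2L else as.integer(factor)
  frame[frame$row %% f == 0L & frame$col %% f == 0L, , drop = FALSE]
}

# apply a region-merge map (named character: old -> new) to a region vector
.merge_regions <- function(region, region_merge) {
  if (is.null(region_merge) || length(region_merge) == 0) return(region)
  hit <- region %in% names(region_merge)
  region[hit] <- unname(region_merge[region[hit]])
  region
}

#' Assemble the per-mine study frame
#'
#' Combines the treated mask and control pool with the canopy-loss metric and
#' covariates: subsamples both sets systematically, removes pixels with mean
#' tree cover below the forest threshold, restricts rows to the region that
#' holds the majority of treated pixels (after any configured merges),
#' attaches the pre-treatment-outcome flag (any canopy loss in the two years
#' before activation) and the five post-activation outcome years (three when
#' the series ends earlier).
#'
#' @param mine One row of a `lease_set` (an active LML).
#' @param leases The full `lease_set`.
#' @param metric A `canopy_loss_grid`.
#' @param covariates A `landscape_covariates` (or its `pixels` tibble).
#' @param buffer_distance Treatment/exclusion buffer (metres).
#' @param ssl_buffer Small-scale-lease exclusion buffer (metres).
#' @param pool Control pool variant, see [control_pool()].
#' @param subsample_scheme See [systematic_subsample()].
#' @param region_merge Named character vector mapping regions to merge
#'   (e.g. `c(P1 = "P2")`).
#' @param min_treecover Forest filter threshold (% cover).
#' @param min_years Minimum outcome years required (default 3).
#' @param pixel_size Pixel edge (metres).
#' @return A `study_frame` tibble: identifiers, coordinates, `treated`,
#'   confounders, `pre_loss`, `region` and outcome columns `loss_y1..loss_yK`
#'   (m2 of canopy lost in post-activation years 1..K).
#' @export
assemble_study_frame <- function(mine, leases, metric, covariates,
                                 buffer_distance = 25000,
                                 ssl_buffer = 5000,
                                 pool = "lel",
                                 subsample_scheme = "4x4",
                                 region_merge = NULL,
                                 min_treecover = 10,
                                 min_years = 3,
                                 pixel_size = 1000) {
  if (!identical(mine$lease_type, "LML") || is.na(mine$active_from))
    stop("mine must be an active large-scale mining lease")
  pix <- if (inherits(covariates, "landscape_covariates")) covariates$pixels
         else covariates
  af <- mine$active_from
  n_years <- attr(metric, "n_years")
  k_years <- min(5L, n_years - af + 1L)
  if (k_years < min_years)
    stop("mine ", mine$id, ": only ", k_years,
         " outcome years available (need ", min_years, ")")

  tr_ids <- treated_mask(pix, mine$geometry[[1]], buffer_distance, pixel_size)
  ct_ids <- control_pool(pix, leases, buffer_distance = buffer_distance,
                         ssl_buffer = ssl_buffer, pool = pool,
                         pixel_size = pixel_size)
  ct_ids <- setdiff(ct_ids, tr_ids)

  frame <- pix |>
    dplyr::filter(.data$pixel_id %in% c(tr_ids, ct_ids)) |>
    dplyr::mutate(treated = as.integer(.data$pixel_id %in% tr_ids)) |>
    systematic_subsample(scheme = subsample_scheme) |>
    dplyr::inner_join(
      dplyr::select(metric, "pixel_id", "forest", "mean_treecover",
                    "sd_treecover", dplyr::starts_with("canopy_loss_Y")),
      by = "pixel_id") |>
    dplyr::filter(.data$forest, .data$mean_treecover >= min_treecover)

  frame$region <- .merge_regions(frame$region, region_merge)
  if (sum(frame$treated) == 0)
    stop("mine ", mine$id, ": no treated pixels remain after subsampling ",
         "and the ", min_treecover, "% tree-cover filter")
  reg_tab <- table(frame$region[frame$treated == 1])
  majority_region <- names(reg_tab)[which.max(reg_tab)]
  frame <- dplyr::filter(frame, .data$region == majority_region)
  if (sum(frame$treated) == 0 || sum(frame$treated == 0) == 0)
    stop("mine ", mine$id, ": no ",
         if (sum(frame$treated) == 0) "treated" else "control",
         " pixels remain after the region restriction")

  pre_years <- intersect(c(af - 1L, af - 2L), seq_len(n_years))
  pre_cols <- paste0("canopy_loss_Y", pre_years)
  frame$pre_loss <- if (length(pre_cols))
    as.integer(rowSums(as.matrix(frame[pre_cols])) > 0) else 0L

  out <- frame |>
    dplyr::transmute(
      pixel_id = .data$pixel_id, x = .data$x, y = .data$y,
      row = .data$row, col = .data$col,
      treated = .data$treated,
      mine_id = mine$id, active_from = af,
      mean_treecover = .data$mean_treecover,
      sd_treecover = .data$sd_treecover,
      dist_road = .data$dist_road, elevation = .data$elevation,
      slope = .data$slope, popdens = .data$popdens,
      burned = .data$burned, aez = .data$aez, protected = .data$protected,
      pre_loss = .data$pre_loss, region = .data$region)
  for (k in seq_len(k_years))
    out[[paste0("loss_y", k)]] <- frame[[paste0("canopy_loss_Y", af + k - 1L)]]
  attr(out, "n_outcome_years") <- k_years
  class(out) <- c("study_frame", class(out))
  out
}

#' Default confounder set of a study frame
#'
#' @param frame A `study_frame`.
#' @return Character vector of confounder column names present in `frame`,
#'   dropping any that are constant.
#' @export
study_confounders <- function(frame) {
  cand <- c("mean_treecover", "sd_treecover", "dist_road", "elevation",
            "slope", "popdens", "burned", "aez", "protected", "pre_loss")
  cand <- intersect(cand, names(frame))
  keep <- vapply(cand, function(v) length(unique(frame[[v]])) > 1, logical(1))
  cand[keep]
}
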