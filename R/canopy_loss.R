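# Canopy-weighted loss metric: fine cover/loss-year rasters -> yearly tree
# canopy area lost (m2) per 1 km2 pixel, plus forest-masked mean/SD of tree
# cover and the unweighted (forest-area-lost) variant.

# block means of a fine matrix for an integer block edge
.block_mean <- function(mat, edge) {
  ny <- nrow(mat); nx <- ncol(mat)
  if (ny %% edge != 0 || nx %% edge != 0)
    stop("block scheme incongruent with the fine grid: ", edge,
         " does not divide ", ny, "x", nx)
  nby <- ny %/% edge; nbx <- nx %/% edge
  a <- array(mat, c(edge, nby, edge, nbx))
  s <- colSums(a)                       # (nby, edge, nbx)
  colSums(aperm(s, c(2, 1, 3))) / (edge * edge)
}

#' Yearly canopy-cover bands
#'
#' Band `t` carries the year-2000 percent tree cover for cells not yet lost
#' by the end of year `t` and zero for cells already lost; band 0 is the
#' year-2000 cover itself. A cell lost in year `t` therefore still has its
#' full cover in band `t - 1`, which is the cover the loss weighting uses.
#'
#' @param stack A `fine_raster_stack`.
#' @return A 3-d array `[row, col, band]` with bands `0..n_years`.
#' @export
yearly_cover_bands <- function(stack) {
  T <- stack$n_years
  out <- array(0, c(nrow(stack$treecover2000), ncol(stack$treecover2000),
                    T + 1))
  for (t in 0:T) {
    keep <- stack$lossyear == 0L | stack$lossyear > t
    out[, , t + 1] <- stack$treecover2000 * keep
  }
  out
}

#' Aggregate a fine raster stack to analysis blocks
#'
#' Blocks of `block_edge x block_edge` fine cells (the ~0.5 ha intermediate
#' scale). Per block: the year-2000 cover mean, the forest mask (cover at or
#' above `mask_threshold` percent, the working definition of forest), the
#' yearly loss proportion, and the yearly canopy-weighted loss fraction.
#' With `weighting = "cell"` (default) the cover weight is applied per fine
#' cell before averaging, so downstream aggregation is exactly linear in the
#' fine cells; `"block"` multiplies the block loss proportion by the block
#' mean cover at the start of the year (a two-stage product of block means).
#'
#' @param stack A `fine_raster_stack`.
#' @param block_edge Block edge in fine cells.
#' @param mask_threshold Percent cover below which a block is non-forest.
#' @param weighting `"cell"` or `"block"` (see Details).
#' @return A `loss_blocks` list: matrices `cover2000` (%), `forest` (logical),
#'   lists `lossprop` and `covloss` indexed by year, block size and grid
#'   metadata.
#' @export
aggregate_blocks <- function(stack, block_edge, mask_threshold = 10,
                             weighting = c("cell", "block")) {
  weighting <- match.arg(weighting)
  T <- stack$n_years
  cover2000 <- .block_mean(stack$treecover2000, block_edge)
  forest <- cover2000 >= mask_threshold
  lossprop <- covloss <- vector("list", T)
  if (weighting == "block") {
    # canopy fraction at end of each year, per block
    coverfrac <- vector("list", T + 1)
    for (t in 0:T) {
      keep <- stack$lossyear == 0L | stack$lossyear > t
      coverfrac[[t + 1]] <- .block_mean(stack$treecover2000 * keep / 100,
                                        block_edge)
    }
  }
  for (t in seq_len(T)) {
    lost_t <- stack$lossyear == t
    lossprop[[t]] <- .block_mean(lost_t + 0, block_edge)
    covloss[[t]] <- if (weighting == "cell")
      .block_mean(stack$treecover2000 / 100 * lost_t, block_edge)
    else lossprop[[t]] * coverfrac[[t]]   # cover at start of year t
  }
  structure(list(cover2000 = cover2000, forest = forest,
                 lossprop = lossprop, covloss = covloss,
                 block_size = block_edge * stack$cell_size,
                 origin = stack$origin, n_years = T,
                 weighting = weighting), class = "loss_blocks")
}

# overlap lengths between two 1-d regular partitions: returns triplets
# (i = fine interval, j = coarse interval, len)
.overlap_1d <- function(n_a, size_a, n_b, size_b) {
  out_i <- integer(0); out_j <- integer(0); out_l <- numeric(0)
  for (i in seq_len(n_a)) {
    a0 <- (i - 1) * size_a; a1 <- i * size_a
    j0 <- max(1L, floor(a0 / size_b) + 1L)
    j1 <- min(n_b, ceiling(a1 / size_b))
    for (j in seq(j0, j1)) {
      l <- min(a1, j * size_b) - max(a0, (j - 1) * size_b)
      if (l > 1e-9) {
        out_i <- c(out_i, i); out_j <- c(out_j, j); out_l <- c(out_l, l)
      }
    }
  }
  list(i = out_i, j = out_j, len = out_l)
}

#' Aggregate blocks to the 1 km2 pixel table
#'
#' Overlap-area-weighted aggregation of the block-level loss quantities to
#' the analysis pixels (weights are uniform when the grids nest). Masked
#' (non-forest) blocks contribute zero loss; the overlap weights are areas,
#' so the reported value is exactly the canopy area (m2) lost within the
#' pixel's forested blocks. Mean and SD of year-2000 tree cover are computed
#' over unmasked blocks only; a pixel with no unmasked block is flagged
#' non-forest with `NA` cover and zero loss.
#'
#' @param blocks A `loss_blocks` from [aggregate_blocks()].
#' @param pixel_size Pixel edge in metres (default 1 km).
#' @return A `canopy_loss_grid` tibble: `pixel_id`, `row`, `col`, `x`, `y`,
#'   `forest`, `mean_treecover`, `sd_treecover`, yearly `canopy_loss_Y*` and
#'   `forest_loss_Y*` columns (m2 per pixel-year).
#' @export
canopy_loss_1km <- function(blocks, pixel_size = 1000) {
  nby <- nrow(blocks$cover2000); nbx <- ncol(blocks$cover2000)
  bs <- blocks$block_size
  npx <- as.integer(ceiling(nbx * bs / pixel_size - 1e-9))
  npy <- as.integer(ceiling(nby * bs / pixel_size - 1e-9))
  ox <- .overlap_1d(nbx, bs, npx, pixel_size)
  oy <- .overlap_1d(nby, bs, npy, pixel_size)
  # cross the two axes: every (block, pixel) pair with positive overlap
  nxp <- length(ox$i); nyp <- length(oy$i)
  bi <- rep(ox$i, each = nyp); pi_ <- rep(ox$j, each = nyp)
  bj <- rep(oy$i, times = nxp); pj <- rep(oy$j, times = nxp)
  w <- rep(ox$len, each = nyp) * rep(oy$len, times = nxp)
  bidx <- (bi - 1L) * nby + bj          # column-major index into block mats
  pidx <- (pj - 1L) * npx + pi_         # row-major pixel_id from SW
  T <- blocks$n_years
  forest_w <- w * as.vector(blocks$forest)[bidx]

  wsum_all <- rowsum(w, pidx)                 # ~ pixel area
  wsum_forest <- rowsum(forest_w, pidx)
  ids <- as.integer(rownames(wsum_all))
  ord <- order(ids)
  ids <- ids[ord]; wsum_all <- wsum_all[ord]; wsum_forest <- wsum_forest[ord]

  agg <- function(vals, weights) {
    s <- rowsum(weights * vals[bidx], pidx)
    s[ord]
  }
  cov_mean <- agg(as.vector(blocks$cover2000), forest_w) / wsum_forest
  cov_sq <- agg(as.vector(blocks$cover2000)^2, forest_w) / wsum_forest
  cov_var <- pmax(cov_sq - cov_mean^2, 0)
  no_forest <- wsum_forest <= 0
  cov_mean[no_forest] <- NA_real_
  sd_tc <- sqrt(cov_var); sd_tc[no_forest] <- NA_real_

  out <- tibble::tibble(
    pixel_id = ids,
    row = (ids - 1L) %/% npx + 1L,
    col = (ids - 1L) %% npx + 1L)
  out$x <- (out$col - 0.5) * pixel_size
  out$y <- (out$row - 0.5) * pixel_size
  out$forest <- !no_forest
  out$mean_treecover <- as.numeric(cov_mean)
  out$sd_treecover <- as.numeric(sd_tc)
  for (t in seq_len(T)) {
    # overlap weights are areas (m2) and the block quantities are area
    # fractions, so the weighted sum is the canopy/forest area lost (m2)
    # inside the pixel's unmasked blocks
    cl <- agg(as.vector(blocks$covloss[[t]]), forest_w)
    fl <- agg(as.vector(blocks$lossprop[[t]]), forest_w)
    out[[paste0("canopy_loss_Y", t)]] <- as.numeric(cl)
    out[[paste0("forest_loss_Y", t)]] <- as.numeric(fl)
  }
  attr(out, "pixel_size") <- pixel_size
  attr(out, "n_years") <- T
  class(out) <- c("canopy_loss_grid", class(out))
  out
}

#' Unweighted forest area lost per pixel-year
#'
#' The Global-Forest-Watch-comparable variant: the cover weight is replaced
#' by 1 for unmasked blocks, so a cleared sparse-woodland block counts the
#' same as a dense-forest block.
#'
#' @inheritParams canopy_loss_1km
#' @return A tibble `pixel_id`, `year`, `forest_loss` (m2).
#' @export
unweighted_forest_loss <- function(blocks, pixel_size = 1000) {
  grid <- canopy_loss_1km(blocks, pixel_size)
  grid |>
    dplyr::select("pixel_id", dplyr::starts_with("forest_loss_Y")) |>
    tidyr::pivot_longer(-"pixel_id", names_to = "year",
                        names_prefix = "forest_loss_Y",
                        names_transform = as.integer,
                        values_to = "forest_loss")
}

#' Compute the canopy-loss metric from a fine raster stack
#'
#' Convenience wrapper: [aggregate_blocks()] then [canopy_loss_1km()].
#'
#' @param stack A `fine_raster_stack`.
#' @param block_edge Block edge in fine cells.
#' @param pixel_size Analysis pixel edge (m).
#' @param mask_threshold Forest-definition threshold (% cover).
#' @param weighting See [aggregate_blocks()].
#' @return A `canopy_loss_grid` tibble.
#' @export
canopy_loss_metric <- function(stack, block_edge = 4, pixel_size = 1000,
                               mask_threshold = 10,
                               weighting = c("cell", "block")) {
  blocks <- aggregate_blocks(stack, block_edge, mask_threshold,
                             match.arg(weighting))
  canopy_loss_1km(blocks, pixel_size)
}

#' Pivot a canopy-loss grid to long pixel-year form
#'
#' @param grid A `canopy_loss_grid`.
#' @return A tibble `pixel_id, year, canopy_loss, forest_loss`.
#' @export
canopy_loss_long <- function(grid) {
  grid |>
    dplyr::select("pixel_id", dplyr::starts_with("canopy_loss_Y"),
                  dplyr::starts_with("forest_loss_Y")) |>
    tidyr::pivot_longer(-"pixel_id",
                        names_pattern = "(canopy_loss|forest_loss)_Y(\\d+)",
                        names_to = c(".value", "year"),
                        names_transform = list(year = as.integer))
}
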