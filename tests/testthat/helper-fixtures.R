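# Fixture builders and independent oracles, all generated in code.

# a fine raster stack from explicit matrices
make_stack <- function(treecover, lossyear, cell_size = 25, n_years = NULL) {
  if (is.null(n_years)) n_years <- max(lossyear, 1)
  structure(list(treecover2000 = treecover,
                 lossyear = matrix(as.integer(lossyear), nrow(lossyear),
                                   ncol(lossyear)),
                 origin = c(0, 0), cell_size = cell_size,
                 n_years = as.integer(n_years)),
            class = "fine_raster_stack")
}

# random stack on an ny x nx fine grid
random_stack <- function(ny = 60, nx = 60, n_years = 4, cell_size = 25,
                         p_loss = 0.25) {
  tc <- matrix(runif(ny * nx, 0, 100), ny, nx)
  ly <- matrix(ifelse(runif(ny * nx) < p_loss,
                      sample.int(n_years, ny * nx, replace = TRUE), 0L),
               ny, nx)
  make_stack(tc, ly, cell_size, n_years)
}

# brute-force canopy/forest loss per pixel-year: the fine-cell oracle.
# Sums cell_area * (cover fraction | 1) over cells lost in year t lying in
# unmasked blocks, assigning cells to pixels by their block's position
# (blocks assumed nested in pixels).
oracle_loss <- function(stack, block_edge, pixel_size, threshold = 10,
                        weighted = TRUE) {
  cs <- stack$cell_size
  ny <- nrow(stack$treecover2000); nx <- ncol(stack$treecover2000)
  bcov <- matrix(0, ny %/% block_edge, nx %/% block_edge)
  for (i in seq_len(nrow(bcov))) for (j in seq_len(ncol(bcov))) {
    rows <- ((i - 1) * block_edge + 1):(i * block_edge)
    cols <- ((j - 1) * block_edge + 1):(j * block_edge)
    bcov[i, j] <- mean(stack$treecover2000[rows, cols])
  }
  forest <- bcov >= threshold
  ri <- as.vector((row(stack$lossyear) - 1) %/% block_edge + 1)
  ci <- as.vector((col(stack$lossyear) - 1) %/% block_edge + 1)
  cellok <- forest[cbind(ri, ci)]
  cy <- (as.vector(row(stack$lossyear)) - 0.5) * cs
  cx <- (as.vector(col(stack$lossyear)) - 0.5) * cs
  prow <- floor(cy / pixel_size) + 1
  pcol <- floor(cx / pixel_size) + 1
  npx <- max(pcol)
  pid <- (prow - 1) * npx + pcol
  w <- if (weighted) as.vector(stack$treecover2000) / 100 else 1
  out <- list()
  for (t in seq_len(stack$n_years)) {
    lost <- as.vector(stack$lossyear == t)
    v <- tapply(cs^2 * w * lost * cellok, pid, sum)
    out[[t]] <- tibble::tibble(pixel_id = as.integer(names(v)), year = t,
                               loss = as.numeric(v))
  }
  dplyr::bind_rows(out)
}

# independent greedy PSM oracle: plain loops, descending score order
oracle_psm <- function(frame, caliper_sd = 0.25, exact = character(0)) {
  s <- frame$score
  caliper <- caliper_sd * sd(s)
  sig <- if (length(exact))
    do.call(paste, c(frame[exact], sep = "|")) else rep("", nrow(frame))
  tr <- which(frame$treated == 1)
  tr <- tr[order(-s[tr], frame$pixel_id[tr])]
  avail <- frame$treated == 0
  pairs <- NULL
  for (i in tr) {
    best <- NA; bestd <- Inf
    for (j in which(avail)) {
      if (sig[j] != sig[i]) next
      dd <- abs(s[j] - s[i])
      if (dd > caliper + 1e-12) next
      if (dd < bestd - 1e-15 ||
          (abs(dd - bestd) <= 1e-15 && !is.na(best) &&
           frame$pixel_id[j] < frame$pixel_id[best])) {
        best <- j; bestd <- dd
      }
    }
    if (!is.na(best)) {
      avail[best] <- FALSE
      pairs <- rbind(pairs, data.frame(treated_id = frame$pixel_id[i],
                                       control_id = frame$pixel_id[best]))
    }
  }
  pairs
}

# random matching frame with a score column
random_match_frame <- function(n_treated, n_control, n_exact_levels = 0) {
  n <- n_treated + n_control
  fr <- tibble::tibble(
    pixel_id = sample.int(10 * n, n),
    treated = rep(c(1L, 0L), c(n_treated, n_control)),
    score = runif(n, 0.05, 0.95))
  if (n_exact_levels > 0) {
    fr$aez <- sample.int(n_exact_levels, n, replace = TRUE)
    fr$protected <- sample(0:1, n, replace = TRUE)
  }
  fr
}

# tiny landscape configuration used across design/pipeline tests
tiny_config <- function(seed = 7, ...) {
  defaults <- list(extent = c(30000, 30000), n_years = 10, seed = seed,
                   lease_counts = c(lml = 1, lel = 8, ssl = 1),
                   buffer_distance = 3000, baseline_logit = -4.2,
                   n_regions = 1)
  do.call(landscape_config, utils::modifyList(defaults, list(...)))
}

# a well-specified small simulation + fit, reused by diagnostics tests
fit_small_sim <- function(seed, n_pixels = 120, n_years = 3, draws = 600,
                          warmup = 400, delta = 0) {
  sim <- simulate_mine_frame(n_pixels = n_pixels, n_years = n_years,
                             delta = delta, seed = seed)
  fit <- fit_outcome_model(sim$data,
                           covariates = c("mean_treecover", "sd_treecover",
                                          "slope"),
                           draws = draws, warmup = warmup, seed = seed + 1,
                           eta_store = 150)
  list(sim = sim, fit = fit)
}
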