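# Synthetic landscape generator: determinism, degenerate limits, the
# clearing-hazard distribution and lease placement.

test_that("configuration validation rejects inconsistent grids", {
  expect_error(landscape_config(extent = c(10010, 10000)), "divisible")
  expect_error(landscape_config(zero_inflation = 1.5))
  expect_s3_class(landscape_config(), "landscape_config")
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- landscape_config(extent = c(6000, 6000), n_years = 6, seed = 12,
                          lease_counts = c(lml = 1, lel = 2, ssl = 1),
                          buffer_distance = 1000)
  a <- simulate_landscape(cfg)
  b <- simulate_landscape(cfg)
  expect_identical(a$stack$lossyear, b$stack$lossyear)
  expect_identical(a$stack$treecover2000, b$stack$treecover2000)
  expect_identical(a$leases$geometry, b$leases$geometry)
})

test_that("zero field variance gives a flat hazard field", {
  cfg <- landscape_config(extent = c(4000, 4000), n_years = 3, seed = 2,
                          spatial_var = 0, covariate_effects = c(),
                          lease_counts = c(lml = 0, lel = 1, ssl = 0))
  L <- simulate_landscape(cfg)
  expect_true(all(L$truth$field == 0))
  expect_equal(max(L$truth$linpred) - min(L$truth$linpred), 0)
})

test_that("distance-to-road is exact for points on and off segments", {
  cfg <- landscape_config(extent = c(4000, 4000), seed = 3,
                          lease_counts = c(lml = 0, lel = 1, ssl = 0))
  cov <- generate_covariates(cfg)
  # a point on a road has distance 0; oracle via dense sampling of segments
  seg <- cov$roads[1, , drop = FALSE]
  mid <- c((seg[1] + seg[3]) / 2, (seg[2] + seg[4]) / 2)
  expect_equal(dist_points_segments(cov$roads, mid[1], mid[2]), 0,
               tolerance = 1e-9)
  len <- sqrt((seg[3] - seg[1])^2 + (seg[4] - seg[2])^2)
  tt <- seq(0, 1, length.out = ceiling(len))
  sx <- seg[1] + tt * (seg[3] - seg[1]); sy <- seg[2] + tt * (seg[4] - seg[2])
  p <- cov$pixels[1:10, ]
  bf <- sqrt(outer(p$x, sx, "-")^2 + outer(p$y, sy, "-")^2)
  d1 <- dist_points_segments(seg, p$x, p$y)
  expect_true(all(abs(d1 - apply(bf, 1, min)) < 1.5))  # 1 m sampling slack
})

test_that("lease placement respects counts, containment and confounding off", {
  cfg <- landscape_config(extent = c(20000, 20000), seed = 5,
                          lease_counts = c(lml = 2, lel = 5, ssl = 2))
  cov <- generate_covariates(cfg)
  ls <- place_leases(cfg, cov)
  expect_equal(sum(ls$lease_type == "LML"), 2)
  expect_equal(sum(ls$lease_type == "LEL"), 5)
  expect_equal(sum(ls$lease_type == "SSL"), 2)
  expect_true(all(!is.na(ls$active_from[ls$lease_type == "LML"])))
  # every mining lease lies inside some exploration lease
  for (g in ls$geometry[ls$lease_type == "LML"]) {
    contained <- vapply(ls$geometry[ls$lease_type == "LEL"], function(h)
      all(points_in_polygon(h, g[, 1], g[, 2])), logical(1))
    expect_true(any(contained))
  }
  # empty counts give an empty set
  cfg0 <- landscape_config(lease_counts = c(lml = 0, lel = 0, ssl = 0))
  expect_equal(nrow(place_leases(cfg0, cov)), 0)
})

test_that("with confounding off, mine hosts are chosen uniformly", {
  cfg <- landscape_config(extent = c(20000, 20000), seed = 31,
                          confounding_strength = 0,
                          lease_counts = c(lml = 1, lel = 4, ssl = 0))
  cov <- generate_covariates(cfg)
  counts <- integer(4)
  for (s in 1:400) {
    ls <- place_leases(cfg, cov, seed = s)
    lels <- ls$geometry[ls$lease_type == "LEL"]
    g <- ls$geometry[ls$lease_type == "LML"][[1]]
    ct <- polygon_centroid(g)
    host <- which(vapply(lels, function(h)
      points_in_polygon(h, ct[1], ct[2]), logical(1)))[1]
    counts[host] <- counts[host] + 1
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("degenerate hazards produce no loss", {
  cfg <- landscape_config(extent = c(4000, 4000), n_years = 3, seed = 8,
                          baseline_logit = -Inf, zero_inflation = 1,
                          covariate_effects = c(), spatial_var = 0,
                          lease_counts = c(lml = 0, lel = 1, ssl = 0))
  L <- simulate_landscape(cfg)
  expect_true(all(L$stack$lossyear == 0L))
})

test_that("constant hazard yields geometric first-loss years", {
  p <- 0.15
  cfg <- landscape_config(extent = c(4000, 4000), fine_cell_size = 25,
                          n_years = 6, seed = 9,
                          baseline_logit = stats::qlogis(p),
                          covariate_effects = c(), spatial_var = 0,
                          zero_inflation = 0,
                          lease_counts = c(lml = 0, lel = 1, ssl = 0))
  L <- simulate_landscape(cfg)   # 160 x 160 = 25,600 cells
  ly <- as.vector(L$stack$lossyear)
  obs <- c(tabulate(ly, nbins = 6), sum(ly == 0))
  probs <- c(p * (1 - p)^(0:5), (1 - p)^6)
  gof <- stats::chisq.test(obs, p = probs)
  expect_gt(gof$p.value, 0.01)
  # empirical first-year hazard within 3 Monte-Carlo SEs
  se <- sqrt(p * (1 - p) / length(ly))
  expect_lt(abs(mean(ly == 1) - p), 3 * se)
})

test_that("block-level suppression produces at least the configured zeros", {
  zi <- 0.4
  cfg <- landscape_config(extent = c(8000, 8000), n_years = 5, seed = 10,
                          baseline_logit = -2, covariate_effects = c(),
                          spatial_var = 0, zero_inflation = zi,
                          lease_counts = c(lml = 0, lel = 1, ssl = 0))
  L <- simulate_landscape(cfg)
  m <- canopy_loss_metric(L$stack, block_edge = cfg$block_edge)
  long <- canopy_loss_long(m)
  expect_gte(mean(long$canopy_loss == 0), zi - 0.05)
  expect_identical(dim(L$truth$suppressed), c(64L, 5L))
})

test_that("a null treatment leaves treated and untreated loss rates equal", {
  # theta = 0: cells inside mine buffers clear at the same rate as outside
  rates_t <- rates_u <- numeric(30)
  for (r in 1:30) {
    cfg <- landscape_config(extent = c(10000, 10000), n_years = 4,
                            seed = 100 + r, baseline_logit = -3,
                            covariate_effects = c(), spatial_var = 0,
                            zero_inflation = 0, treatment_multiplier = 0,
                            lease_counts = c(lml = 1, lel = 3, ssl = 0),
                            buffer_distance = 2000)
    L <- simulate_landscape(cfg)
    trt <- is.finite(L$truth$activation_year)
    rates_t[r] <- mean(L$stack$lossyear[trt] > 0)
    rates_u[r] <- mean(L$stack$lossyear[!trt] > 0)
  }
  expect_lt(abs(mean(rates_t) - mean(rates_u)), 3 * sd(rates_t - rates_u) /
              sqrt(30))
})

test_that("a positive treatment effect raises loss inside buffers", {
  cfg <- landscape_config(extent = c(10000, 10000), n_years = 6, seed = 44,
                          baseline_logit = -3.5, covariate_effects = c(),
                          spatial_var = 0, zero_inflation = 0,
                          treatment_multiplier = 1.5,
                          lease_counts = c(lml = 1, lel = 3, ssl = 0),
                          buffer_distance = 2000)
  L <- simulate_landscape(cfg)
  af <- min(L$truth$activation_year)
  trt <- is.finite(L$truth$activation_year)
  post_t <- mean(L$stack$lossyear[trt] >= af)
  post_u <- mean(L$stack$lossyear[!trt] >= af)
  expect_gt(post_t, post_u)
})

test_that("landscapes round-trip through plain-text files", {
  cfg <- landscape_config(extent = c(5000, 5000), n_years = 4, seed = 13,
                          lease_counts = c(lml = 1, lel = 2, ssl = 1),
                          buffer_distance = 1000)
  L <- simulate_landscape(cfg)
  dir <- withr::local_tempdir()
  write_landscape(L, dir)
  back <- read_landscape(dir)
  expect_identical(back$stack$lossyear, L$stack$lossyear)  # bit-identical ints
  expect_equal(back$stack$treecover2000, L$stack$treecover2000,
               tolerance = 1e-12)
  expect_equal(nrow(back$leases), nrow(L$leases))
  expect_equal(back$leases$lease_type, L$leases$lease_type)
  expect_equal(back$leases$geometry[[1]], L$leases$geometry[[1]],
               ignore_attr = TRUE)
  expect_equal(nrow(back$pixels), nrow(L$covariates$pixels))  # one per pixel
})
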