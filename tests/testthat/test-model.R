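# Likelihood, covariance, priors, HPD intervals and the Bayesian outcome
# model (collapsed-model oracle, determinism, DIC).

test_that("the ZINB log-pmf is a proper, stable distribution", {
  # normalises to 1
  lp <- zinb_logpmf(0:1e6, mu = 50, size = 0.7, pi = 0.3)
  expect_lt(abs(sum(exp(lp)) - 1), 1e-8)
  # pi = 0 reduces to the plain negative binomial
  expect_equal(zinb_logpmf(0:20, 5, 1.2, 0),
               dnbinom(0:20, size = 1.2, mu = 5, log = TRUE))
  # closed form at zero: log(pi + (1-pi) (k/(k+mu))^k)
  expect_equal(zinb_logpmf(0L, 5, 1.2, 0.3),
               log(0.3 + 0.7 * (1.2 / 6.2)^1.2))
  # degenerate mass: pi = 1 puts probability one on zero
  expect_equal(zinb_logpmf(0L, 5, 1, 1), 0)
  expect_equal(zinb_logpmf(3L, 5, 1, 1), -Inf)
  # large-dispersion limit approaches the Poisson pmf
  expect_equal(zinb_logpmf(0:30, 7, 1e6, 0),
               dpois(0:30, 7, log = TRUE), tolerance = 1e-4)
  expect_error(zinb_logpmf(0, -1, 1, 0.5))
})

test_that("Matern covariance has the right scale, range and shape", {
  expect_equal(matern_cov(0, range = 1000, sigma = 2), 4)
  # at d = range the correlation is ~0.1396 for nu = 1 (Bessel evaluation)
  kd <- sqrt(8)
  expect_equal(matern_cov(1000, range = 1000) / matern_cov(0, range = 1000),
               kd * besselK(kd, 1), tolerance = 1e-12)
  expect_equal(matern_cov(1000, range = 1000), 0.1396, tolerance = 1e-3)
  d <- seq(0, 5000, length.out = 100)
  expect_true(all(diff(matern_cov(d, range = 1500)) < 0))
  expect_error(matern_cov(1, range = -5))
})

test_that("penalised-complexity priors hit their quantile targets", {
  # P(rho < 50 km) = 0.05 by quadrature
  q <- integrate(function(r) pc_prior_range(r, 5e4, 0.05, log = FALSE),
                 0, 5e4, rel.tol = 1e-10)
  expect_lt(abs(q$value - 0.05), 1e-6)
  # total mass via the substitution u = 1/rho: the transformed density is
  # exponential with rate lambda = -rho0 log(alpha), so integrating to
  # 30/lambda captures all but exp(-30) of the mass
  lam <- -5e4 * log(0.05)
  tot <- integrate(function(u) pc_prior_range(1 / u, 5e4, 0.05,
                                              log = FALSE) / u^2,
                   0, 30 / lam, rel.tol = 1e-10)
  expect_lt(abs(tot$value - 1), 1e-6)
  # P(sigma > sigma0) = alpha for the SD prior; density integrates to 1
  q2 <- integrate(function(s) pc_prior_sigma(s, 1.5, 0.1, log = FALSE),
                  1.5, Inf, rel.tol = 1e-10)
  expect_lt(abs(q2$value - 0.1), 1e-6)
  tot2 <- integrate(function(s) pc_prior_sigma(s, 1.5, 0.1, log = FALSE),
                    0, Inf, rel.tol = 1e-10)
  expect_lt(abs(tot2$value - 1), 1e-6)
})

test_that("HPD intervals match exhaustive shortest-window search", {
  # uniform ladder: any width-80 window ties; smallest lower bound wins
  expect_equal(hpd_interval(1:100, 0.8), c(lo = 1, hi = 80))
  set.seed(2)
  for (r in 1:20) {
    x <- rgamma(500, shape = 2)
    for (lev in c(0.8, 0.95)) {
      got <- hpd_interval(x, lev)
      s <- sort(x); m <- ceiling(lev * 500)
      width <- s[m:500] - s[1:(500 - m + 1)]
      i <- which.min(width)
      expect_equal(got, c(lo = s[i], hi = s[i + m - 1]))
    }
    # nesting
    h80 <- hpd_interval(x, 0.8); h95 <- hpd_interval(x, 0.95)
    expect_gte(h80[["lo"]], h95[["lo"]])
    expect_lte(h80[["hi"]], h95[["hi"]])
  }
  # symmetric unimodal: HPD close to the equal-tail interval
  set.seed(3)
  z <- rnorm(5000)
  h <- hpd_interval(z, 0.9)
  et <- quantile(z, c(0.05, 0.95))
  expect_lt(abs(h[["lo"]] - et[[1]]), 0.15)
  expect_lt(abs(h[["hi"]] - et[[2]]), 0.15)
  expect_error(hpd_interval(1:50, 0.8), "at least 100")
})

test_that("response preparation rounds to whole square metres", {
  fr <- tibble::tibble(pixel_id = c(1L, 2L), x = c(500, 1500), y = 500,
                       treated = c(1L, 0L), mean_treecover = 50,
                       sd_treecover = 5, slope = 1,
                       loss_y1 = c(12.4, 0), loss_y2 = c(100.6, 3.2),
                       loss_y3 = c(0, 0))
  attr(fr, "n_outcome_years") <- 3L
  d <- prepare_response(fr)
  expect_equal(nrow(d), 6)                       # K years x P pixels
  expect_equal(d$y[d$pixel_id == 1 & d$year == 1], 12L)
  expect_equal(d$y[d$pixel_id == 2 & d$year == 2], 3L)
  expect_true(all(d$year == rep(1:3, each = 2)))  # year-major panel
  fr$loss_y1[1] <- -5
  expect_error(prepare_response(fr), "negative")
})

test_that("collapsed fixed-effect posteriors match a ZINB GLM MLE", {
  skip_if_not_installed("glmmTMB")
  set.seed(14)
  sim <- simulate_mine_frame(n_pixels = 150, n_years = 3, delta = log(2),
                             sigma = 0, tau = 0, seed = 14)
  fit <- fit_outcome_model(sim$data,
                           covariates = c("mean_treecover", "slope"),
                           draws = 800, warmup = 500, seed = 2,
                           fix = list(sigma = 0, tau = 0))
  d <- sim$data
  d$yearf <- factor(d$year)
  d$tc_z <- scale(d$mean_treecover)[, 1]
  d$sl_z <- scale(d$slope)[, 1]
  ref <- glmmTMB::glmmTMB(
    y ~ yearf + tc_z + sl_z + yearf:treated,
    ziformula = ~1, family = glmmTMB::nbinom2(), data = d)
  rc <- glmmTMB::fixef(ref)$cond
  post <- colMeans(fit$beta)
  sds <- apply(fit$beta, 2, sd)
  # same parameterisation up to term naming: compare intercept, year and
  # treatment terms within one posterior SD
  expect_lt(abs(post[["(Intercept)"]] - rc[["(Intercept)"]]),
            sds[["(Intercept)"]])
  for (t in 1:3)
    expect_lt(abs(post[[paste0("treated_year", t)]] -
                    rc[[paste0("yearf", t, ":treated")]]),
              sds[[paste0("treated_year", t)]])
  expect_lt(abs(post[["mean_treecover"]] - rc[["tc_z"]]),
            sds[["mean_treecover"]])
  # dispersion and zero inflation in the same neighbourhood
  expect_lt(abs(mean(fit$hyper[, "k"]) - glmmTMB::sigma(ref)),
            3 * sd(fit$hyper[, "k"]) + 0.05)
  expect_lt(abs(mean(fit$hyper[, "pi"]) -
                  plogis(glmmTMB::fixef(ref)$zi[[1]])), 0.05)
})

test_that("zero contrasts with identical covariates give a zero ATE", {
  # crafted degenerate posterior: all treatment contrasts zero, covariates
  # constant, so expected loss is identical across arms in every draw
  n_pix <- 40; K <- 2
  X <- cbind(`(Intercept)` = 1,
             year2 = rep(c(0, 1), each = n_pix),
             treated_year1 = c(rep(c(1, 0), n_pix / 2), rep(0, n_pix)),
             treated_year2 = c(rep(0, n_pix), rep(c(1, 0), n_pix / 2)))
  beta <- cbind(`(Intercept)` = rnorm(200, 2, 0.1),
                year2 = rnorm(200, 0.3, 0.1),
                treated_year1 = 0, treated_year2 = 0)
  data <- tibble::tibble(pixel_id = rep(1:n_pix, K),
                         year = rep(1:K, each = n_pix),
                         treated = rep(rep(c(1L, 0L), n_pix / 2), K))
  fit <- structure(list(beta = beta,
                        hyper = cbind(k = rep(1, 200), pi = rep(0.2, 200),
                                      rho = 1, sigma = 0, tau = 0, cor = 0),
                        X = X, data = data, n_years = K,
                        eta_draws = matrix(0, 0, 0)),
                   class = "mine_fit")
  ate <- estimate_ate(fit)
  expect_equal(ate$mean, rep(0, K + 1))
  expect_true(all(ate$hpd80_lo <= 0 & ate$hpd80_hi >= 0))
  # unit conversion to hectares
  expect_equal(estimate_ate(fit, unit = "ha")$mean, rep(0, K + 1))
})

test_that("the sampler is seed-deterministic and MC-stable", {
  sim <- simulate_mine_frame(n_pixels = 150, n_years = 3, delta = 0,
                             seed = 5)
  f1 <- fit_outcome_model(sim$data, covariates = "mean_treecover",
                          draws = 1500, warmup = 700, seed = 9)
  f2 <- fit_outcome_model(sim$data, covariates = "mean_treecover",
                          draws = 1500, warmup = 700, seed = 9)
  expect_identical(f1$beta, f2$beta)          # bit-identical given the seed
  expect_identical(estimate_ate(f1)$mean, estimate_ate(f2)$mean)
  # two seeds agree within Monte-Carlo error on the aggregated effect,
  # with the MC standard error taken from the autocorrelation-adjusted
  # effective sample size
  f3 <- fit_outcome_model(sim$data, covariates = "mean_treecover",
                          draws = 1500, warmup = 700, seed = 10)
  a1 <- attr(estimate_ate(f1), "draws")[, "all"]
  a3 <- attr(estimate_ate(f3), "draws")[, "all"]
  ess <- function(x) {
    rho <- stats::acf(x, lag.max = 100, plot = FALSE)$acf[-1]
    s <- 0
    for (r in rho) { if (r < 0.05) break; s <- s + r }
    length(x) / (1 + 2 * s)
  }
  mcse <- sqrt(var(a1) / ess(a1) + var(a3) / ess(a3))
  expect_lt(abs(mean(a1) - mean(a3)), 4 * mcse)
})

test_that("DIC is reproducible and distinguishes informative covariates", {
  sim <- simulate_mine_frame(n_pixels = 100, n_years = 3, delta = 0,
                             beta_cov = c(mean_treecover = 1.2,
                                          sd_treecover = 0, slope = 0),
                             sigma = 0, tau = 0, seed = 6)
  f_full <- fit_outcome_model(sim$data, covariates = "mean_treecover",
                              draws = 400, warmup = 300, seed = 3,
                              fix = list(sigma = 0, tau = 0))
  f_null <- fit_outcome_model(sim$data, covariates = character(0),
                              draws = 400, warmup = 300, seed = 3,
                              fix = list(sigma = 0, tau = 0))
  # identical refits give identical DIC
  f_rep <- fit_outcome_model(sim$data, covariates = "mean_treecover",
                             draws = 400, warmup = 300, seed = 3,
                             fix = list(sigma = 0, tau = 0))
  expect_identical(model_dic(f_full)$dic, model_dic(f_rep)$dic)
  # the generating covariate lowers the DIC decisively
  expect_lt(model_dic(f_full)$dic, model_dic(f_null)$dic - 10)
  expect_gte(model_dic(f_full)$p_d, 0)
  # the selection helper ranks the informative set first
  sel <- select_covariates(sim$data, c("mean_treecover", "slope"),
                           draws = 300, warmup = 200, seed = 4,
                           fix = list(sigma = 0, tau = 0))
  expect_equal(sel$set[1], "full")
})

test_that("tidy and glance summarise a fit", {
  sim <- simulate_mine_frame(n_pixels = 60, n_years = 3, seed = 8)
  fit <- fit_outcome_model(sim$data, covariates = "mean_treecover",
                           draws = 400, warmup = 300, seed = 2)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "hpd95_lo", "rhat") %in% names(td)))
  expect_true(any(grepl("^treated_year", td$term)))
  expect_true(all(td$hpd95_lo <= td$hpd95_hi))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_gt(gl$hmc_acceptance, 0.4)
  expect_equal(gl$n_pixels, 60)
})
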