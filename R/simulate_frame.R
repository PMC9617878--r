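# Model-based simulator: pixel-year data drawn exactly from the
# spatiotemporal ZINB model, with the treatment contrast, covariate effects
# and hyperparameters known. The companion of the landscape generator for
# calibration studies: when the fitted model is the generating model,
# interval coverage and residual diagnostics have known targets.

#' Simulate a matched-mine dataset from the outcome model
#'
#' Draws `n_pixels` pixel locations uniformly in a square study area,
#' assigns half to treatment (at random, as after successful matching),
#' simulates covariates, yearly Matern field replicates, an iid pixel
#' effect, and ZINB responses with a per-year treatment contrast `delta` on
#' the log-mean. The returned truth includes the plug-in average treatment
#' effect implied by the fixed effects, the estimand [estimate_ate()]
#' reports.
#'
#' @param n_pixels Number of 1 km2 pixels (half treated).
#' @param n_years Outcome years K.
#' @param delta Treatment contrast per year (scalar or length K) on the
#'   log-mean; `log(2)` doubles expected loss.
#' @param beta0 Intercept of the log-mean (m2 scale; `log(300)` gives a
#'   median-ish 300 m2 of canopy loss per pixel-year).
#' @param beta_cov Named effects of the standardised covariates
#'   (`mean_treecover`, `sd_treecover`, `slope`).
#' @param year_effects Additive year effects (length K, first must be 0).
#' @param k NB dispersion.
#' @param pi Zero-inflation probability.
#' @param sigma,rho Field marginal SD and Matern range (metres).
#' @param tau Pixel-effect SD.
#' @param extent Study-area edge (metres).
#' @param seed Integer seed.
#' @return A list: `data` (a `model_data` tibble) and `truth` (parameters
#'   plus `ate_year` and `ate_all`, the true plug-in treatment effects in
#'   m2).
#' @export
simulate_mine_frame <- function(n_pixels = 300, n_years = 5,
                                delta = 0, beta0 = log(300),
                                beta_cov = c(mean_treecover = 0.3,
                                             sd_treecover = -0.1,
                                             slope = -0.2),
                                year_effects = NULL,
                                k = 0.8, pi = 0.3,
                                sigma = 0.5, rho = 15000, tau = 0.3,
                                extent = 40000, seed = 1L) {
  set.seed(seed)
  K <- n_years
  if (length(delta) == 1) delta <- rep(delta, K)
  stopifnot(length(delta) == K)
  if (is.null(year_effects)) year_effects <- c(0, stats::rnorm(K - 1, 0, 0.2))
  stopifnot(length(year_effects) == K, year_effects[1] == 0)

  px <- stats::runif(n_pixels, 0, extent)
  py <- stats::runif(n_pixels, 0, extent)
  treated <- as.integer(seq_len(n_pixels) %in%
                          sample.int(n_pixels, floor(n_pixels / 2)))
  cov <- tibble::tibble(
    mean_treecover = pmin(pmax(stats::rnorm(n_pixels, 45, 15), 10), 100),
    sd_treecover = pmax(stats::rnorm(n_pixels, 12, 4), 0.5),
    slope = pmax(stats::rnorm(n_pixels, 2, 1.2), 0))
  Z <- scale(as.matrix(cov))
  xb <- drop(Z[, names(beta_cov), drop = FALSE] %*% beta_cov)

  u <- matrix(0, n_pixels, K)
  if (sigma > 0) {
    D <- as.matrix(stats::dist(cbind(px, py)))
    Cm <- matern_cov(D, range = rho, sigma = sigma) + diag(1e-8, n_pixels)
    L <- chol(Cm)
    for (t in seq_len(K)) u[, t] <- drop(crossprod(L, stats::rnorm(n_pixels)))
  }
  v <- stats::rnorm(n_pixels, 0, tau)

  rows <- purrr::map_dfr(seq_len(K), function(t) {
    eta <- beta0 + year_effects[t] + xb + delta[t] * treated + u[, t] + v
    mu <- exp(pmin(eta, 30))
    y <- stats::rnbinom(n_pixels, size = k, mu = mu)
    y[stats::runif(n_pixels) < pi] <- 0L
    tibble::tibble(pixel_id = seq_len(n_pixels), weight = 1,
                   px = px, py = py, treated = treated,
                   mean_treecover = cov$mean_treecover,
                   sd_treecover = cov$sd_treecover, slope = cov$slope,
                   year = t, y = as.integer(y))
  }) |>
    dplyr::arrange(.data$year, .data$pixel_id) |>
    dplyr::mutate(pixel = .data$pixel_id)
  attr(rows, "n_years") <- K
  attr(rows, "n_pixels") <- n_pixels
  class(rows) <- c("model_data", class(rows))

  # plug-in fixed-effects estimand, per year and aggregated (m2)
  ate_year <- vapply(seq_len(K), function(t) {
    evT <- (1 - pi) * exp(beta0 + year_effects[t] + xb[treated == 1] +
                            delta[t])
    evC <- (1 - pi) * exp(beta0 + year_effects[t] + xb[treated == 0])
    mean(evT) - mean(evC)
  }, numeric(1))
  list(data = rows,
       truth = list(delta = delta, beta0 = beta0, beta_cov = beta_cov,
                    year_effects = year_effects, k = k, pi = pi,
                    sigma = sigma, rho = rho, tau = tau,
                    ate_year = ate_year, ate_all = mean(ate_year)))
}
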