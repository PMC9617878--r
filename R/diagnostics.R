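# Model checking: posterior predictive simulation, simulated (randomised)
# quantile residuals, and empirical variograms of residuals with
# permutation envelopes to screen for leftover spatial autocorrelation.

#' Posterior predictive replicates
#'
#' Simulates replicate response vectors from the ZINB parameters of retained
#' posterior draws (latent fields included via the stored linear-predictor
#' draws) and compares summary discrepancies — proportion of zeros, maximum,
#' total — between observed data and replicates as tail probabilities
#' `P(T_rep >= T_obs)`.
#'
#' @param fit A `mine_fit`.
#' @param n_rep Number of replicate datasets (capped by the stored
#'   linear-predictor draws).
#' @param seed Integer seed.
#' @return A `posterior_predictive` list: `replicates` (n_rep x n matrix),
#'   `observed`, `summaries` tibble and the data reference.
#' @export
posterior_predictive <- function(fit, n_rep = 200, seed = 1L) {
  set.seed(seed)
  S <- nrow(fit$eta_draws)
  if (S == 0) stop("fit stores no linear-predictor draws")
  take <- if (n_rep <= S) sample.int(S, n_rep) else
    sample.int(S, n_rep, replace = TRUE)
  n <- ncol(fit$eta_draws)
  reps <- matrix(0L, length(take), n)
  for (r in seq_along(take)) {
    s <- take[r]
    mu <- exp(fit$eta_draws[s, ])
    yr <- stats::rnbinom(n, size = fit$eta_hyper[s, "k"], mu = mu)
    yr[stats::runif(n) < fit$eta_hyper[s, "pi"]] <- 0L
    reps[r, ] <- as.integer(yr)
  }
  obs <- fit$data$y
  stat_tbl <- purrr::map_dfr(
    list(prop_zero = function(v) mean(v == 0),
         max = function(v) max(v),
         total = function(v) sum(v)) |> purrr::imap(function(f, nm) {
      to <- f(obs)
      tr <- apply(reps, 1, f)
      tibble::tibble(statistic = nm, observed = to,
                     replicate_mean = mean(tr),
                     tail_prob = mean(tr >= to))
    }), identity)
  structure(list(replicates = reps, observed = obs, data = fit$data,
                 summaries = stat_tbl), class = "posterior_predictive")
}

#' Simulated (randomised) quantile residuals
#'
#' For each observation, `(#\{rep < obs\} + U * #\{rep = obs\} + U0) /
#' (n_rep + 1)` with independent uniforms `U`, `U0` — strictly inside (0,1)
#' and Uniform(0,1) under a correctly specified model, the discrete-response
#' analogue of PIT residuals.
#'
#' @param pp A `posterior_predictive` (needs at least 100 replicates).
#' @param seed Integer seed for the randomisation.
#' @return A `residual_set` tibble: `pixel_id`, `px`, `py`, `year`,
#'   `residual`.
#' @export
quantile_residuals <- function(pp, seed = 1L) {
  set.seed(seed)
  n_rep <- nrow(pp$replicates)
  if (n_rep < 100) stop("need at least 100 replicates per observation")
  obs <- matrix(pp$observed, n_rep, length(pp$observed), byrow = TRUE)
  below <- colSums(pp$replicates < obs)
  equal <- colSums(pp$replicates == obs)
  u <- stats::runif(length(pp$observed))
  u0 <- stats::runif(length(pp$observed))
  res <- (below + u * equal + u0) / (n_rep + 1)
  out <- tibble::tibble(pixel_id = pp$data$pixel_id,
                        px = pp$data$px, py = pp$data$py,
                        year = pp$data$year, residual = res)
  class(out) <- c("residual_set", class(out))
  out
}

# pooled-over-years binned semivariance of a residual vector arrangement
.vgram_gamma <- function(res_by_year, pair_idx, bin_idx, n_bins) {
  num <- numeric(n_bins); cnt <- numeric(n_bins)
  for (t in seq_along(pair_idx)) {
    r <- res_by_year[[t]]
    pr <- pair_idx[[t]]
    d2 <- 0.5 * (r[pr$i] - r[pr$j])^2
    s <- rowsum(d2, bin_idx[[t]])
    num[as.integer(rownames(s))] <- num[as.integer(rownames(s))] + s[, 1]
    cnt <- cnt + tabulate(bin_idx[[t]], n_bins)
  }
  ifelse(cnt > 0, num / cnt, NA_real_)
}

#' Empirical variogram of residuals with a permutation envelope
#'
#' Binned semivariance `gamma(h) = mean of 0.5 (r_i - r_j)^2` over same-year
#' pixel pairs, pooled across years, with a pointwise Monte-Carlo envelope
#' obtained by randomly relabelling residuals over locations (within year).
#' Bins default to 10 equal-width intervals from the minimum post-subsample
#' spacing (4 km) to half the study-frame diameter. Bins whose observed
#' semivariance leaves the envelope are flagged.
#'
#' @param residuals A `residual_set` (at least 30 locations).
#' @param bins Number of distance bins.
#' @param d_min,d_max Bin range (metres); defaults 4 km and half the maximum
#'   inter-pixel distance.
#' @param n_permutations Envelope permutations (default 199).
#' @param min_pairs Bins with fewer pairs are reported but flagged `NA`.
#' @param seed Integer seed.
#' @return A `variogram_result` tibble: `dist` (bin midpoint), `gamma`,
#'   `lo`, `hi`, `n_pairs`, `outside`.
#' @export
residual_variogram <- function(residuals, bins = 10, d_min = 4000,
                               d_max = NULL, n_permutations = 199,
                               min_pairs = 10, seed = 1L) {
  set.seed(seed)
  years <- sort(unique(residuals$year))
  loc <- dplyr::distinct(residuals[c("pixel_id", "px", "py")])
  if (nrow(loc) < 30) stop("need at least 30 locations for a variogram")
  if (is.null(d_max)) {
    dd <- stats::dist(as.matrix(loc[c("px", "py")]))
    d_max <- max(dd) / 2
  }
  breaks <- seq(d_min, d_max, length.out = bins + 1)
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2

  pair_idx <- list(); bin_idx <- list(); res_by_year <- list()
  for (t in seq_along(years)) {
    ry <- residuals[residuals$year == years[t], ]
    D <- as.matrix(stats::dist(as.matrix(ry[c("px", "py")])))
    ut <- which(upper.tri(D), arr.ind = TRUE)
    dv <- D[ut]
    bi <- findInterval(dv, breaks, rightmost.closed = TRUE)
    keep <- bi >= 1 & bi <= bins & dv >= d_min & dv <= d_max
    pair_idx[[t]] <- list(i = ut[keep, 1], j = ut[keep, 2])
    bin_idx[[t]] <- bi[keep]
    res_by_year[[t]] <- ry$residual
  }
  cnt <- Reduce(`+`, lapply(bin_idx, tabulate, nbins = bins))
  gamma_obs <- .vgram_gamma(res_by_year, pair_idx, bin_idx, bins)

  perm <- matrix(NA_real_, n_permutations, bins)
  for (b in seq_len(n_permutations)) {
    shuf <- lapply(res_by_year, function(r) r[sample.int(length(r))])
    perm[b, ] <- .vgram_gamma(shuf, pair_idx, bin_idx, bins)
  }
  lo <- apply(perm, 2, min); hi <- apply(perm, 2, max)
  enough <- cnt >= min_pairs
  out <- tibble::tibble(dist = mids, gamma = gamma_obs, lo = lo, hi = hi,
                        n_pairs = as.integer(cnt),
                        outside = ifelse(enough,
                                         gamma_obs < lo | gamma_obs > hi,
                                         NA))
  class(out) <- c("variogram_result", class(out))
  out
}

#' Per-mine run report
#'
#' Assembles the treatment-effect table with interval-excludes-zero flags at
#' 80% and 95%, balance quality, and residual diagnostics into one tidy
#' report. The headline decision rule — does the 80% highest-density
#' interval of the aggregated effect include zero — appears as the
#' `no_effect_80` column.
#'
#' @param ate An `ate_estimate`.
#' @param balance Optional `balance_report`.
#' @param residuals Optional `residual_set`.
#' @param variogram Optional `variogram_result`.
#' @param mine_id Identifier carried into the table.
#' @return A `mine_report` tibble, one row per year plus `"all"`.
#' @export
mine_report <- function(ate, balance = NULL, residuals = NULL,
                        variogram = NULL, mine_id = NA_integer_) {
  if (is.null(ate) || nrow(ate) == 0) stop("empty treatment-effect input")
  out <- ate |>
    dplyr::mutate(
      mine_id = mine_id,
      excludes_zero_80 = .data$hpd80_lo > 0 | .data$hpd80_hi < 0,
      excludes_zero_95 = .data$hpd95_lo > 0 | .data$hpd95_hi < 0,
      no_effect_80 = !.data$excludes_zero_80)
  if (!is.null(balance))
    out$mean_abs_smd_after <- mean(abs(balance$smd_after), na.rm = TRUE)
  if (!is.null(residuals)) {
    ks <- suppressWarnings(stats::ks.test(residuals$residual, "punif"))
    out$residual_ks_p <- ks$p.value
  }
  if (!is.null(variogram))
    out$variogram_bins_outside <- sum(variogram$outside, na.rm = TRUE)
  class(out) <- c("mine_report", class(out))
  out
}
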