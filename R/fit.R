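# Bayesian spatiotemporal zero-inflated negative binomial outcome model.
#
# y_it ~ ZINB(mu_it, k, pi);  log mu_it = x_i' beta + delta_t treated_i
#                                         + u_t(s_i) + v_i
# with one zero-mean Matern (nu = 1) spatial field replicate per year sharing
# (range rho, SD sigma), an iid Gaussian pixel effect v_i ~ N(0, tau^2), and
# penalised-complexity priors on (rho, sigma, tau). The field is represented
# at reduced rank through a coarse knot lattice (predictive-process weights),
# and inference is gradient-based MCMC: Hamiltonian updates of the
# non-centred latent block (beta, field weights, pixel effects) with
# adaptive random-walk Metropolis for the five hyperparameters.

#' Prepare the pixel-year response table
#'
#' Expands a matched study frame into long pixel-year rows with the integer
#' response (canopy loss rounded to the nearest square metre), the treatment
#' flag, covariates and coordinates. Years are indexed 1..K from mine
#' activation. Rows are ordered year-major with a complete pixel panel, the
#' layout the sampler relies on.
#'
#' @param frame A `study_frame`.
#' @param matched Optional `matched_set`; when supplied only matched pixels
#'   (with their weights) are kept.
#' @return A `model_data` tibble: `pixel_id`, `pixel` (1..n index), `px`,
#'   `py` (metres), `year`, `y`, `treated`, covariates, `weight`.
#' @export
prepare_response <- function(frame, matched = NULL) {
  f <- frame
  if (!is.null(matched)) {
    w <- dplyr::distinct(matched[matched$weight > 0,
                                 c("pixel_id", "weight")])
    f <- dplyr::inner_join(w, frame, by = "pixel_id")
  } else f$weight <- 1
  k_years <- attr(frame, "n_outcome_years")
  if (is.null(k_years))
    k_years <- sum(grepl("^loss_y\\d+$", names(f)))
  loss_cols <- paste0("loss_y", seq_len(k_years))
  if (any(as.matrix(f[loss_cols]) < 0)) stop("negative canopy loss in input")
  f <- dplyr::rename(f, px = "x", py = "y")
  keep <- intersect(c("pixel_id", "weight", "px", "py", "treated",
                      "mean_treecover", "sd_treecover", "dist_road",
                      "elevation", "slope", "popdens", "burned", "aez",
                      "protected", "pre_loss"), names(f))
  long <- f[c(keep, loss_cols)] |>
    tidyr::pivot_longer(dplyr::all_of(loss_cols), names_to = "year",
                        names_prefix = "loss_y",
                        names_transform = as.integer,
                        values_to = "loss") |>
    dplyr::mutate(y = as.integer(round(.data$loss))) |>
    dplyr::select(-"loss") |>
    dplyr::arrange(.data$year, .data$pixel_id) |>
    dplyr::mutate(pixel = match(.data$pixel_id, sort(unique(.data$pixel_id))))
  attr(long, "n_years") <- k_years
  attr(long, "n_pixels") <- length(unique(long$pixel_id))
  class(long) <- c("model_data", class(long))
  long
}

# design matrix: intercept, year dummies (2..K), standardised covariates,
# per-year treatment contrasts. Returns X plus the column index of contrasts.
.build_design <- function(data, covariates) {
  K <- attr(data, "n_years")
  n <- nrow(data)
  covariates <- intersect(covariates, names(data))
  covariates <- covariates[vapply(covariates, function(v)
    stats::sd(as.numeric(data[[v]])) > 0, logical(1))]
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (K > 1) for (t in 2:K) {
    X <- cbind(X, as.numeric(data$year == t))
    colnames(X)[ncol(X)] <- paste0("year", t)
  }
  for (v in covariates) {
    x <- as.numeric(data[[v]])
    X <- cbind(X, (x - mean(x)) / stats::sd(x))
    colnames(X)[ncol(X)] <- v
  }
  trt_idx <- integer(K)
  for (t in seq_len(K)) {
    X <- cbind(X, as.numeric(data$year == t) * data$treated)
    colnames(X)[ncol(X)] <- paste0("treated_year", t)
    trt_idx[t] <- ncol(X)
  }
  list(X = X, trt_idx = trt_idx, covariates = covariates)
}

# knot lattice over the pixel bounding box
.knot_lattice <- function(px, py, k = 5) {
  pad <- 0.05
  rx <- range(px); ry <- range(py)
  dx <- max(diff(rx), 1); dy <- max(diff(ry), 1)
  xs <- seq(rx[1] - pad * dx, rx[2] + pad * dx, length.out = k)
  ys <- seq(ry[1] - pad * dy, ry[2] + pad * dy, length.out = k)
  as.matrix(expand.grid(x = xs, y = ys))
}

# predictive-process weight matrix M(rho) = C_sk U^{-1}, chol C_kk = U'U,
# so that u(s) = sigma * M z, z ~ N(0, I), has covariance
# sigma^2 C_sk C_kk^{-1} C_ks
.field_basis <- function(coords, knots, rho) {
  dk <- as.matrix(stats::dist(knots))
  Ckk <- matern_cov(dk, range = rho) + diag(1e-6, nrow(knots))
  ds <- sqrt(outer(coords[, 1], knots[, 1], "-")^2 +
             outer(coords[, 2], knots[, 2], "-")^2)
  Csk <- matern_cov(ds, range = rho)
  U <- chol(Ckk)
  t(backsolve(U, t(Csk), transpose = TRUE))
}

# dlog zinb / d eta, vectorised (mu = exp(eta))
.zinb_score_eta <- function(y, mu, k, pi) {
  g <- k * (y - mu) / (k + mu)
  z <- y == 0
  if (pi > 0 && any(z)) {
    muz <- mu[z]
    logf0 <- k * (log(k) - log(k + muz))
    # d logf0 / d eta = -k * muz / (k + muz)
    num <- log1p(-pi) + logf0
    denom <- log(exp(num) + pi)
    g[z] <- exp(num - denom) * (-k * muz / (k + muz))
  }
  g
}

.split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  a <- x[seq_len(n)]; b <- x[seq_len(n) + n]
  W <- (stats::var(a) + stats::var(b)) / 2
  B <- n * (mean(a) - mean(b))^2 / 2
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the spatiotemporal ZINB outcome model
#'
#' Posterior sampling for the zero-inflated negative binomial model with
#' per-year treatment contrasts, year effects, standardised covariates,
#' exchangeable yearly Matern spatial fields (independent replicates sharing
#' range and SD; optionally with a common inter-year correlation), and an iid
#' pixel effect. The latent block is updated by Hamiltonian Monte Carlo in a
#' non-centred parameterisation; hyperparameters (NB dispersion,
#' zero-inflation probability, field range and SD, pixel-effect SD) by
#' adaptive random-walk Metropolis. The field range carries a
#' penalised-complexity prior with `P(range > rho0) = 1 - alpha` (default
#' 95% above 50 km); the SD priors are penalised-complexity with a reference
#' scale tuned to the response's empirical log-scale spread.
#'
#' @param data A `model_data` from [prepare_response()].
#' @param covariates Covariate columns to include (constant ones dropped).
#' @param draws Posterior draws to keep (default 4000).
#' @param warmup Adaptation iterations discarded (default 1000).
#' @param seed Integer seed.
#' @param knots Knot lattice edge (knots per axis, default 5).
#' @param leapfrog Leapfrog steps per Hamiltonian update.
#' @param temporal `"exchangeable"` (independent yearly replicates, default)
#'   or `"correlated"` (adds a shared component with estimated weight).
#' @param pc_range List `rho0` (metres), `alpha`: prior
#'   `P(range < rho0) = alpha`.
#' @param pc_sigma,pc_tau Lists `sigma0`, `alpha` for the field and pixel SD
#'   priors; `sigma0 = NULL` uses the empirical SD of `log1p(y)`.
#' @param fix Named list pinning hyperparameters (e.g.
#'   `list(sigma = 0, tau = 0)` collapses the model to a ZINB GLM).
#' @param eta_store Number of evenly spaced draws for which the full linear
#'   predictor is retained (posterior predictive work).
#' @return A `mine_fit` object: draw matrices, deviances, acceptance rates,
#'   split-R-hat per fixed effect, data and design references.
#' @export
fit_outcome_model <- function(data,
                              covariates = c("mean_treecover", "sd_treecover",
                                             "slope", "protected"),
                              draws = 4000, warmup = 1000, seed = 1L,
                              knots = 5, leapfrog = 8,
                              temporal = c("exchangeable", "correlated"),
                              pc_range = list(rho0 = 50000, alpha = 0.05),
                              pc_sigma = list(sigma0 = NULL, alpha = 0.05),
                              pc_tau = list(sigma0 = NULL, alpha = 0.05),
                              fix = list(), eta_store = 200) {
  temporal <- match.arg(temporal)
  set.seed(seed)
  if (attr(data, "n_pixels") < 2) stop("need at least 2 pixels")
  K <- attr(data, "n_years")
  n_pix <- attr(data, "n_pixels")
  n <- nrow(data)
  stopifnot(n == K * n_pix)   # complete year-major panel
  y <- data$y

  des <- .build_design(data, covariates)
  X <- des$X; p <- ncol(X)
  coords <- as.matrix(dplyr::distinct(data[data$year == data$year[1],
                                           c("px", "py")]))
  kn <- .knot_lattice(coords[, 1], coords[, 2], knots)
  m <- nrow(kn)

  use_field <- !(("sigma" %in% names(fix)) && fix$sigma == 0)
  use_pix <- !(("tau" %in% names(fix)) && fix$tau == 0)
  sig0 <- pc_sigma$sigma0
  if (is.null(sig0)) sig0 <- max(stats::sd(log1p(y)), 0.5)
  tau0 <- pc_tau$sigma0
  if (is.null(tau0)) tau0 <- sig0

  # ---- maximum-likelihood start for the collapsed GLM --------------------
  nll <- function(par) {
    eta <- pmin(pmax(X %*% par[1:p], -30), 30)
    -sum(zinb_logpmf(y, exp(eta), exp(par[p + 1]),
                     stats::plogis(par[p + 2])))
  }
  start <- c(log(mean(y) + 1), rep(0, p - 1), 0,
             stats::qlogis(min(max(mean(y == 0) / 2, 0.05), 0.9)))
  ml <- try(stats::optim(start, nll, method = "BFGS",
                         control = list(maxit = 300), hessian = TRUE),
            silent = TRUE)
  if (inherits(ml, "try-error") || !is.finite(ml$value)) {
    beta <- c(log(mean(y) + 1), rep(0, p - 1))
    log_k <- 0; logit_pi <- 0
    sd_beta <- rep(0.5, p)
  } else {
    beta <- ml$par[1:p]
    log_k <- ml$par[p + 1]; logit_pi <- ml$par[p + 2]
    sd_beta <- rep(0.5, p)
    h <- try(solve(ml$hessian[1:p, 1:p, drop = FALSE]), silent = TRUE)
    if (!inherits(h, "try-error")) {
      dg <- diag(h)
      ok <- is.finite(dg) & dg > 0
      sd_beta[ok] <- sqrt(dg[ok])
    }
  }
  sd_beta <- pmin(pmax(sd_beta, 0.02), 2)

  # ---- state --------------------------------------------------------------
  # the field range is sampled on a log-spaced grid so the reduced-rank
  # basis (which needs Bessel evaluations) can be precomputed once per value
  if (use_field) {
    if (!is.null(fix$rho)) {
      rho_grid <- fix$rho
    } else {
      rho_min <- max(min(stats::dist(kn)) / 2, 1)
      rho_max <- 8 * max(stats::dist(coords))
      rho_grid <- exp(seq(log(rho_min), log(rho_max), length.out = 41))
    }
    M_list <- lapply(rho_grid, function(r) .field_basis(coords, kn, r))
    rho_i <- which.min(abs(log(rho_grid) -
                             log(min(pc_range$rho0,
                                     max(stats::dist(coords)) / 2))))
    M <- M_list[[rho_i]]
    # log prior mass on the grid: PC density times rho (log-uniform spacing)
    lp_rho_grid <- pc_prior_range(rho_grid, pc_range$rho0, pc_range$alpha) +
      log(rho_grid)
  } else {
    rho_grid <- NA_real_; rho_i <- 1L; M <- NULL; lp_rho_grid <- 0
  }
  log_sigma <- log(if (!is.null(fix$sigma) && fix$sigma > 0) fix$sigma
                   else 0.3)
  log_tau <- log(if (!is.null(fix$tau) && fix$tau > 0) fix$tau else 0.3)
  if (!is.null(fix$k)) log_k <- log(fix$k)
  if (!is.null(fix$pi)) logit_pi <- stats::qlogis(fix$pi)
  n_z <- if (temporal == "correlated") K + 1L else K
  z <- matrix(0, m, n_z)        # last column = shared component if used
  vraw <- rep(0, n_pix)
  logit_cor <- 0                # shared-component weight (correlated only)

  # unit-scale field rows (sigma multiplies later)
  field1_of <- function(z, logit_cor, Muse = M) {
    if (!use_field) return(0)
    if (temporal == "correlated") {
      cw <- stats::plogis(logit_cor)
      zz <- sqrt(cw) * z[, n_z] + sqrt(1 - cw) * z[, seq_len(K),
                                                   drop = FALSE]
      as.vector(Muse %*% zz)
    } else as.vector(Muse %*% z)
  }
  assemble_eta <- function(etaX, fld1, vrep)
    pmin(pmax(etaX + exp(log_sigma) * fld1 + exp(log_tau) * vrep, -30), 30)
  loglik_eta <- function(eta, log_k, logit_pi)
    sum(zinb_logpmf(y, exp(eta), exp(log_k), stats::plogis(logit_pi)))

  beta_prior_var <- 1000   # N(0, 1000) on fixed effects (precision 0.001)

  latent_prior <- function(beta, z, vraw)
    -sum(beta^2) / (2 * beta_prior_var) - sum(z^2) / 2 - sum(vraw^2) / 2

  grad_latent <- function(beta, z, vraw, eta) {
    g <- .zinb_score_eta(y, exp(eta), exp(log_k), stats::plogis(logit_pi))
    gmat <- matrix(g, n_pix, K)
    gb <- crossprod(X, g) - beta / beta_prior_var
    gz <- NULL
    if (use_field) {
      s <- exp(log_sigma)
      gz <- matrix(0, m, n_z)
      base <- s * crossprod(M, gmat)     # m x K
      if (temporal == "correlated") {
        cw <- stats::plogis(logit_cor)
        gz[, seq_len(K)] <- sqrt(1 - cw) * base
        gz[, n_z] <- sqrt(cw) * rowSums(base)
      } else gz[] <- base
      gz <- gz - z
    }
    gv <- if (use_pix) exp(log_tau) * rowSums(gmat) - vraw else NULL
    list(beta = as.vector(gb), z = gz, v = gv)
  }

  # ---- HMC over (beta, z, v) ---------------------------------------------
  inv_mass_beta <- sd_beta^2   # q += eps * inv_mass * p
  eps <- 0.05; log_eps_bar <- log(eps); Hbar <- 0
  da_mu <- log(10 * eps); da_t0 <- 10; da_gamma <- 0.05; da_kappa <- 0.75
  accept_hmc <- 0

  hmc_step <- function(beta, z, vraw, eta, ll, iter, adapt) {
    pB <- stats::rnorm(p) / sd_beta
    pZ <- if (use_field) matrix(stats::rnorm(m * n_z), m, n_z) else NULL
    pV <- if (use_pix) stats::rnorm(n_pix) else NULL
    kin <- function(pB, pZ, pV)
      sum(pB^2 * inv_mass_beta) / 2 +
      (if (use_field) sum(pZ^2) / 2 else 0) +
      (if (use_pix) sum(pV^2) / 2 else 0)
    H0 <- -(ll + latent_prior(beta, z, vraw)) + kin(pB, pZ, pV)
    b <- beta; zz <- z; vv <- vraw; e <- eta
    gr <- grad_latent(b, zz, vv, e)
    L <- sample(max(2, leapfrog - 3):(leapfrog + 3), 1)
    for (l in seq_len(L)) {
      pB <- pB + eps / 2 * gr$beta
      if (use_field) pZ <- pZ + eps / 2 * gr$z
      if (use_pix) pV <- pV + eps / 2 * gr$v
      b <- b + eps * inv_mass_beta * pB
      if (use_field) zz <- zz + eps * pZ
      if (use_pix) vv <- vv + eps * pV
      e <- assemble_eta(as.vector(X %*% b), field1_of(zz, logit_cor),
                        if (use_pix) rep(vv, K) else 0)
      gr <- grad_latent(b, zz, vv, e)
      pB <- pB + eps / 2 * gr$beta
      if (use_field) pZ <- pZ + eps / 2 * gr$z
      if (use_pix) pV <- pV + eps / 2 * gr$v
    }
    ll_prop <- loglik_eta(e, log_k, logit_pi)
    H1 <- -(ll_prop + latent_prior(b, zz, vv)) + kin(pB, pZ, pV)
    a <- if (is.finite(H1)) min(1, exp(H0 - H1)) else 0
    if (stats::runif(1) < a) {
      beta <- b; z <- zz; vraw <- vv; eta <- e; ll <- ll_prop
    }
    if (adapt) {
      Hbar <<- (1 - 1 / (iter + da_t0)) * Hbar +
        (0.8 - a) / (iter + da_t0)
      leps <- da_mu - sqrt(iter) / da_gamma * Hbar
      eps <<- exp(leps)
      w <- iter^(-da_kappa)
      log_eps_bar <<- w * leps + (1 - w) * log_eps_bar
    }
    accept_hmc <<- accept_hmc + a
    list(beta = beta, z = z, vraw = vraw, eta = eta, ll = ll)
  }

  # ---- adaptive RW for hyperparameters -----------------------------------
  sc <- c(sig = 0.3, tau = 0.3, kp = 0.2, cor = 0.5)
  acc <- c(sig = 0, tau = 0, kp = 0, cor = 0)
  try_n <- c(sig = 0, tau = 0, kp = 0, cor = 0)
  rw_adapt <- function(name, a, iter) {
    acc[name] <<- acc[name] + a; try_n[name] <<- try_n[name] + 1
    sc[name] <<- sc[name] * exp((a - 0.35) / sqrt(iter / 2 + 1))
  }

  total <- warmup + draws
  beta_draws <- matrix(NA_real_, draws, p,
                       dimnames = list(NULL, colnames(X)))
  hyper_draws <- matrix(NA_real_, draws, 6,
                        dimnames = list(NULL, c("k", "pi", "rho", "sigma",
                                                "tau", "cor")))
  deviance <- numeric(draws)
  eta_sum <- numeric(n)
  store_at <- if (eta_store > 0)
    unique(round(seq(1, draws, length.out = min(eta_store, draws)))) else
    integer(0)
  eta_draws <- matrix(NA_real_, length(store_at), n)
  eta_hyper <- matrix(NA_real_, length(store_at), 2,
                      dimnames = list(NULL, c("k", "pi")))

  etaX <- as.vector(X %*% beta)
  fld1 <- field1_of(z, logit_cor)
  vrep <- if (use_pix) rep(vraw, K) else 0
  eta <- assemble_eta(etaX, fld1, vrep)
  ll <- loglik_eta(eta, log_k, logit_pi)
  for (iter in seq_len(total)) {
    adapt <- iter <= warmup
    if (!adapt && iter == warmup + 1) eps <- exp(log_eps_bar)
    st <- hmc_step(beta, z, vraw, eta, ll, iter, adapt)
    beta <- st$beta; z <- st$z; vraw <- st$vraw; eta <- st$eta; ll <- st$ll
    etaX <- as.vector(X %*% beta)
    fld1 <- field1_of(z, logit_cor)
    if (use_pix) vrep <- rep(vraw, K)

    # rho: random walk on the precomputed grid (symmetric proposal)
    if (use_field && is.null(fix$rho)) {
      j <- rho_i + sample(c(-3L, -2L, -1L, 1L, 2L, 3L), 1)
      if (j >= 1 && j <= length(rho_grid)) {
        fld1_p <- field1_of(z, logit_cor, M_list[[j]])
        eta_p <- assemble_eta(etaX, fld1_p, vrep)
        ll_p <- loglik_eta(eta_p, log_k, logit_pi)
        lr <- ll_p + lp_rho_grid[j] - ll - lp_rho_grid[rho_i]
        if (is.finite(lr) && stats::runif(1) < exp(lr)) {
          rho_i <- j; M <- M_list[[j]]; fld1 <- fld1_p
          eta <- eta_p; ll <- ll_p
        }
      }
    }

    # sigma
    if (use_field && is.null(fix$sigma)) {
      prop <- log_sigma + stats::rnorm(1, 0, sc["sig"])
      eta_p <- pmin(pmax(etaX + exp(prop) * fld1 +
                           exp(log_tau) * vrep, -30), 30)
      ll_p <- loglik_eta(eta_p, log_k, logit_pi)
      lr <- ll_p + pc_prior_sigma(exp(prop), sig0, pc_sigma$alpha) + prop -
        ll - pc_prior_sigma(exp(log_sigma), sig0, pc_sigma$alpha) - log_sigma
      a <- if (is.finite(lr)) min(1, exp(lr)) else 0
      if (stats::runif(1) < a) { log_sigma <- prop; eta <- eta_p; ll <- ll_p }
      if (adapt) rw_adapt("sig", a, iter)
    }

    # tau
    if (use_pix && is.null(fix$tau)) {
      prop <- log_tau + stats::rnorm(1, 0, sc["tau"])
      eta_p <- pmin(pmax(etaX + exp(log_sigma) * fld1 +
                           exp(prop) * vrep, -30), 30)
      ll_p <- loglik_eta(eta_p, log_k, logit_pi)
      lr <- ll_p + pc_prior_sigma(exp(prop), tau0, pc_tau$alpha) + prop -
        ll - pc_prior_sigma(exp(log_tau), tau0, pc_tau$alpha) - log_tau
      a <- if (is.finite(lr)) min(1, exp(lr)) else 0
      if (stats::runif(1) < a) { log_tau <- prop; eta <- eta_p; ll <- ll_p }
      if (adapt) rw_adapt("tau", a, iter)
    }

    # (k, pi)
    if (is.null(fix$k) && is.null(fix$pi)) {
      prop <- c(log_k, logit_pi) + stats::rnorm(2, 0, sc["kp"])
      ll_p <- loglik_eta(eta, prop[1], prop[2])
      pr <- function(lk, lp) stats::dnorm(lk, 0, 1.5, log = TRUE) +
        lp - 2 * log1p(exp(lp))   # uniform pi on logit scale
      lr <- ll_p + pr(prop[1], prop[2]) - ll - pr(log_k, logit_pi)
      a <- if (is.finite(lr)) min(1, exp(lr)) else 0
      if (stats::runif(1) < a) { log_k <- prop[1]; logit_pi <- prop[2]
        ll <- ll_p }
      if (adapt) rw_adapt("kp", a, iter)
    }

    # inter-year correlation weight (correlated structure only)
    if (use_field && temporal == "correlated") {
      prop <- logit_cor + stats::rnorm(1, 0, sc["cor"])
      fld1_p <- field1_of(z, prop)
      eta_p <- assemble_eta(etaX, fld1_p, vrep)
      ll_p <- loglik_eta(eta_p, log_k, logit_pi)
      jac <- function(l) l - 2 * log1p(exp(l))
      lr <- ll_p + jac(prop) - ll - jac(logit_cor)
      a <- if (is.finite(lr)) min(1, exp(lr)) else 0
      if (stats::runif(1) < a) { logit_cor <- prop; fld1 <- fld1_p
        eta <- eta_p; ll <- ll_p }
      if (adapt) rw_adapt("cor", a, iter)
    }

    if (!adapt) {
      s <- iter - warmup
      beta_draws[s, ] <- beta
      hyper_draws[s, ] <- c(exp(log_k), stats::plogis(logit_pi),
                            if (use_field) rho_grid[rho_i] else 0,
                            if (use_field) exp(log_sigma) else 0,
                            if (use_pix) exp(log_tau) else 0,
                            stats::plogis(logit_cor))
      deviance[s] <- -2 * ll
      eta_sum <- eta_sum + eta
      j <- match(s, store_at)
      if (!is.na(j)) {
        eta_draws[j, ] <- eta
        eta_hyper[j, ] <- c(exp(log_k), stats::plogis(logit_pi))
      }
    }
  }

  eta_mean <- eta_sum / draws
  rhat <- apply(beta_draws, 2, .split_rhat)
  if (any(!is.finite(beta_draws)))
    stop("sampler produced non-finite draws; check the data scale")
  structure(list(
    beta = beta_draws, hyper = hyper_draws, deviance = deviance,
    eta_mean = eta_mean, eta_draws = eta_draws, eta_hyper = eta_hyper,
    data = data, X = X, trt_idx = des$trt_idx,
    covariates = des$covariates, knots = kn, temporal = temporal,
    n_years = K, n_pixels = n_pix,
    accept = c(hmc = accept_hmc / total,
               if (sum(try_n) > 0) acc[try_n > 0] / try_n[try_n > 0]),
    step_size = eps, rhat = rhat, seed = seed,
    draws = draws, warmup = warmup), class = "mine_fit")
}

#' @export
print.mine_fit <- function(x, ...) {
  cat("Spatiotemporal ZINB fit:", x$draws, "draws (", x$warmup,
      "warmup),", x$n_pixels, "pixels x", x$n_years, "years\n")
  cat("max split-Rhat (fixed effects):", round(max(x$rhat), 3),
      "| HMC acceptance:", round(x$accept[["hmc"]], 2), "\n")
  invisible(x)
}

#' Average treatment effect from posterior draws
#'
#' For each posterior draw the expected canopy loss per pixel-year,
#' `(1 - pi) * mu`, is averaged over treated rows and over control rows; the
#' difference is the draw's treatment effect, per year and aggregated across
#' years. By default predictions use the fixed effects plus the expected
#' (zero-mean) latent contribution; `include_latent = TRUE` instead uses the
#' sampled latent fields for the retained linear-predictor draws. Summaries
#' are the posterior mean and 80%/95% highest-posterior-density intervals.
#'
#' @param fit A `mine_fit`.
#' @param include_latent Use sampled latent effects (on the thinned
#'   linear-predictor draws) instead of their zero mean.
#' @param unit `"m2"` (native) or `"ha"`.
#' @return An `ate_estimate` tibble: `year` (`"1"..K` and `"all"`), `mean`,
#'   `hpd80_lo/hi`, `hpd95_lo/hi`; draw matrix in attribute `"draws"`.
#' @export
estimate_ate <- function(fit, include_latent = FALSE,
                         unit = c("m2", "ha")) {
  unit <- match.arg(unit)
  K <- fit$n_years
  d <- fit$data
  scale <- if (unit == "ha") 1e-4 else 1
  if (include_latent) {
    S <- nrow(fit$eta_draws)
    mu <- exp(fit$eta_draws)
    pi_ <- fit$eta_hyper[, "pi"]
    ev <- (1 - pi_) * mu
  } else {
    S <- nrow(fit$beta)
    eta <- fit$X %*% t(fit$beta)          # n x S
    pi_ <- fit$hyper[, "pi"]
    ev <- t(exp(pmin(eta, 30))) * (1 - pi_)   # S x n
  }
  ate <- matrix(NA_real_, S, K + 1,
                dimnames = list(NULL, c(paste0("year", 1:K), "all")))
  for (t in seq_len(K)) {
    ti <- d$year == t & d$treated == 1
    ci <- d$year == t & d$treated == 0
    ate[, t] <- (rowMeans(ev[, ti, drop = FALSE]) -
                 rowMeans(ev[, ci, drop = FALSE])) * scale
  }
  ate[, K + 1] <- rowMeans(ate[, seq_len(K), drop = FALSE])
  summarise_one <- function(x, lab) {
    h80 <- hpd_interval(x, 0.80); h95 <- hpd_interval(x, 0.95)
    tibble::tibble(year = lab, mean = mean(x),
                   hpd80_lo = h80[["lo"]], hpd80_hi = h80[["hi"]],
                   hpd95_lo = h95[["lo"]], hpd95_hi = h95[["hi"]])
  }
  out <- dplyr::bind_rows(
    purrr::map2(asplit(ate, 2), c(as.character(1:K), "all"), summarise_one))
  out$unit <- unit
  attr(out, "draws") <- ate
  class(out) <- c("ate_estimate", class(out))
  out
}

#' Deviance information criterion
#'
#' `DIC = mean posterior deviance + pD`, with the effective number of
#' parameters `pD` the mean deviance minus the deviance at the posterior
#' mean (of the linear predictor, dispersion and zero-inflation). Computed
#' conditionally on the latent effects. A negative `pD` is reported with a
#' warning (a sign of a poorly behaved fit).
#'
#' @param fit A `mine_fit`.
#' @return A list `dic`, `p_d`, `mean_deviance`.
#' @export
model_dic <- function(fit) {
  dbar <- mean(fit$deviance)
  k <- mean(fit$hyper[, "k"]); pi_ <- mean(fit$hyper[, "pi"])
  dhat <- -2 * sum(zinb_logpmf(fit$data$y, exp(fit$eta_mean), k, pi_))
  pd <- dbar - dhat
  if (pd < 0) warning("negative effective parameter count (pD = ",
                      round(pd, 2), ")")
  list(dic = dbar + pd, p_d = pd, mean_deviance = dbar)
}

#' Covariate selection by DIC
#'
#' Drops one of each pair of candidate covariates whose absolute correlation
#' exceeds `cor_threshold`, then fits the model for each supplied candidate
#' set (reduced draws) and tabulates DIC.
#'
#' @param data A `model_data`.
#' @param candidates Character vector of candidate covariates.
#' @param candidate_sets Optional list of covariate sets to compare; default
#'   compares the full (decollineared) set against intercept-only.
#' @param cor_threshold Collinearity cutoff on |r|.
#' @param draws,warmup Sampler size for the comparison fits.
#' @param ... Passed to [fit_outcome_model()].
#' @return A tibble `set`, `covariates`, `dic`, sorted by DIC.
#' @export
select_covariates <- function(data, candidates, candidate_sets = NULL,
                              cor_threshold = 0.7, draws = 500,
                              warmup = 300, ...) {
  keep <- candidates[vapply(candidates, function(v)
    v %in% names(data) && stats::sd(as.numeric(data[[v]])) > 0, logical(1))]
  if (length(keep) > 1) {
    cm <- abs(stats::cor(sapply(data[keep], as.numeric)))
    drop <- character(0)
    for (i in seq_along(keep)) for (j in seq_len(i - 1)) {
      if (cm[i, j] > cor_threshold && !(keep[j] %in% drop))
        drop <- union(drop, keep[i])
    }
    keep <- setdiff(keep, drop)
  }
  if (is.null(candidate_sets))
    candidate_sets <- list(full = keep, intercept_only = character(0))
  res <- purrr::imap_dfr(candidate_sets, function(set, nm) {
    f <- fit_outcome_model(data, covariates = set, draws = draws,
                           warmup = warmup, ...)
    tibble::tibble(set = nm,
                   covariates = paste(set, collapse = "+"),
                   dic = model_dic(f)$dic)
  })
  dplyr::arrange(res, .data$dic)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a fitted outcome model
#'
#' @param x A `mine_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fixed effect and hyperparameter:
#'   posterior mean, SD, 95% HPD bounds and split-R-hat (fixed effects).
#' @export
tidy.mine_fit <- function(x, ...) {
  fx <- purrr::map_dfr(colnames(x$beta), function(nm) {
    s <- x$beta[, nm]
    h <- hpd_interval(s, 0.95)
    tibble::tibble(term = nm, type = "fixed", estimate = mean(s),
                   std.error = stats::sd(s),
                   hpd95_lo = h[["lo"]], hpd95_hi = h[["hi"]],
                   rhat = x$rhat[[nm]])
  })
  hy <- purrr::map_dfr(colnames(x$hyper), function(nm) {
    s <- x$hyper[, nm]
    if (stats::sd(s) == 0) return(tibble::tibble())
    h <- hpd_interval(s, 0.95)
    tibble::tibble(term = nm, type = "hyper", estimate = mean(s),
                   std.error = stats::sd(s),
                   hpd95_lo = h[["lo"]], hpd95_hi = h[["hi"]],
                   rhat = NA_real_)
  })
  dplyr::bind_rows(fx, hy)
}

#' One-row model summary
#'
#' @param x A `mine_fit`.
#' @param ... Unused.
#' @return A one-row tibble: draws, pixels, years, DIC, pD, max R-hat, HMC
#'   acceptance.
#' @export
glance.mine_fit <- function(x, ...) {
  ic <- suppressWarnings(model_dic(x))
  tibble::tibble(draws = x$draws, n_pixels = x$n_pixels, n_years = x$n_years,
                 dic = ic$dic, p_d = ic$p_d, max_rhat = max(x$rhat),
                 hmc_acceptance = x$accept[["hmc"]])
}
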