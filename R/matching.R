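# Statistical matching: propensity scores, common support, greedy 1-1
# nearest-neighbour matching with caliper and exact categorical constraints,
# coarsened exact matching, random-draw controls and balance diagnostics.

# model formula for the propensity logistic regression; aez is categorical
.propensity_formula <- function(confounders) {
  terms <- ifelse(confounders == "aez", "factor(aez)", confounders)
  stats::as.formula(paste("treated ~", paste(terms, collapse = " + ")))
}

#' Fit the propensity-score model
#'
#' Logistic regression of treatment on the matching confounders, fitted by
#' iteratively reweighted least squares. Errors explicitly on non-convergence
#' or (quasi-)separation, naming the most extreme variable.
#'
#' @param frame A `study_frame` (needs a 0/1 `treated` column).
#' @param confounders Character vector of confounder columns; defaults to
#'   [study_confounders()].
#' @return A `propensity_model`: the glm fit plus per-row `score` (in (0,1)),
#'   linear predictor and the frame's `pixel_id`s.
#' @export
fit_propensity <- function(frame, confounders = study_confounders(frame)) {
  if (sum(frame$treated == 1) < 1 || sum(frame$treated == 0) < 1)
    stop("need at least one treated and one control row")
  const <- confounders[vapply(confounders,
                              function(v) length(unique(frame[[v]])) <= 1,
                              logical(1))]
  if (length(const))
    stop("constant confounder(s): ", paste(const, collapse = ", "))
  fit <- stats::glm(.propensity_formula(confounders), data = frame,
                    family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  if (!fit$converged)
    stop("propensity model did not converge")
  p <- stats::fitted(fit)
  if (any(p < 1e-10) || any(p > 1 - 1e-10) ||
      any(abs(stats::coef(fit)[-1]) > 50, na.rm = TRUE)) {
    cf <- stats::coef(fit)[-1]
    culprit <- names(cf)[which.max(abs(cf))]
    stop("propensity model shows (quasi-)separation; culprit variable: ",
         culprit)
  }
  structure(list(fit = fit, coefficients = stats::coef(fit),
                 score = as.numeric(p),
                 linear_predictor = as.numeric(stats::predict(fit)),
                 pixel_id = frame$pixel_id, confounders = confounders),
            class = "propensity_model")
}

#' Restrict a frame to the region of common support
#'
#' Keeps rows whose propensity score lies in the overlap of the treated and
#' control score ranges; dropped units are recorded in the `"dropped"`
#' attribute.
#'
#' @param frame A `study_frame`.
#' @param model A `propensity_model` fitted on `frame`.
#' @return The filtered frame with a `score` column.
#' @export
common_support <- function(frame, model) {
  stopifnot(identical(model$pixel_id, frame$pixel_id))
  s <- model$score
  lo <- max(min(s[frame$treated == 1]), min(s[frame$treated == 0]))
  hi <- min(max(s[frame$treated == 1]), max(s[frame$treated == 0]))
  if (lo > hi)
    stop("no common support: treated and control score ranges are disjoint")
  keep <- s >= lo & s <= hi
  out <- frame[keep, , drop = FALSE]
  out$score <- s[keep]
  attr(out, "dropped") <- frame$pixel_id[!keep]
  attr(out, "support") <- c(lo = lo, hi = hi)
  out
}

#' Greedy 1-1 propensity-score matching
#'
#' Nearest-neighbour matching without replacement: treated units are
#' processed in descending score order (ties by `pixel_id`) and each is
#' paired with the unmatched control of smallest absolute score difference
#' among controls that agree exactly on the `exact` categorical variables and
#' lie within the caliper, `caliper_sd` standard deviations of the score
#' (probability scale by default). Treated units with no admissible control
#' are dropped and logged.
#'
#' @param frame A frame with `score` (from [common_support()], or supply a
#'   `model` to score an unfiltered frame).
#' @param model Optional `propensity_model` used when `frame` has no `score`.
#' @param caliper_sd Caliper width in score standard deviations.
#' @param exact Categorical variables requiring exact agreement.
#' @param caliper_scale `"score"` (probability scale, default) or `"linear"`
#'   (linear-predictor scale).
#' @return A `matched_set` tibble: `scheme`, `pair`, `pixel_id`, `treated`,
#'   `weight`, `distance`; dropped treated ids in attribute `"dropped"`.
#' @export
psm_match <- function(frame, model = NULL, caliper_sd = 0.25,
                      exact = c("protected", "aez"),
                      caliper_scale = c("score", "linear")) {
  caliper_scale <- match.arg(caliper_scale)
  if (!"score" %in% names(frame)) {
    stopifnot(!is.null(model))
    frame$score <- model$score[match(frame$pixel_id, model$pixel_id)]
  }
  s <- if (caliper_scale == "linear") stats::qlogis(frame$score)
       else frame$score
  caliper <- caliper_sd * stats::sd(s)
  exact <- intersect(exact, names(frame))
  sig <- if (length(exact))
    do.call(paste, c(frame[exact], sep = "\r")) else rep("", nrow(frame))

  tr <- which(frame$treated == 1)
  ct <- which(frame$treated == 0)
  tr <- tr[order(-frame$score[tr], frame$pixel_id[tr])]
  used <- rep(FALSE, nrow(frame))
  pairs_t <- integer(0); pairs_c <- integer(0); dist <- numeric(0)
  dropped <- integer(0)
  for (i in tr) {
    cand <- ct[!used[ct] & sig[ct] == sig[i]]
    if (length(cand)) {
      dd <- abs(s[cand] - s[i])
      ok <- dd <= caliper + 1e-12
      cand <- cand[ok]; dd <- dd[ok]
    }
    if (!length(cand)) {
      dropped <- c(dropped, frame$pixel_id[i])
      next
    }
    best <- cand[order(dd, frame$pixel_id[cand])][1]
    used[best] <- TRUE
    pairs_t <- c(pairs_t, i); pairs_c <- c(pairs_c, best)
    dist <- c(dist, abs(s[best] - s[i]))
  }
  if (!length(pairs_t)) {
    if (length(dropped) == sum(frame$treated == 1) && length(dropped))
      out <- tibble::tibble(scheme = character(0), pair = integer(0),
                            pixel_id = integer(0), treated = integer(0),
                            weight = numeric(0), distance = numeric(0))
    else stop("matching produced zero pairs")
  } else {
    k <- seq_along(pairs_t)
    out <- tibble::tibble(
      scheme = "psm",
      pair = rep(k, 2L),
      pixel_id = c(frame$pixel_id[pairs_t], frame$pixel_id[pairs_c]),
      treated = rep(c(1L, 0L), each = length(k)),
      weight = 1,
      distance = rep(dist, 2L))
  }
  attr(out, "dropped") <- dropped
  attr(out, "caliper") <- caliper
  class(out) <- c("matched_set", class(out))
  out
}

#' Coarsened exact matching
#'
#' Continuous confounders are coarsened into `bins` equal-frequency bins,
#' categoricals kept exact; units sharing a joint bin signature form a
#' stratum. Strata lacking either treated or control units are discarded.
#' Control weights are the standard CEM weights
#' `(m_T/m_C) * (M_C/M_T)` within each stratum (treated weight 1), so every
#' control matching one or more treated units is retained.
#'
#' @param frame A `study_frame`.
#' @param confounders Confounders to coarsen/match on.
#' @param bins Number of equal-frequency bins per continuous confounder.
#' @return A `matched_set` tibble with `stratum` and CEM `weight`s.
#' @export
cem_match <- function(frame, confounders = study_confounders(frame),
                      bins = 5) {
  categorical <- c("burned", "aez", "protected", "pre_loss")
  sig_cols <- lapply(confounders, function(v) {
    x <- frame[[v]]
    if (v %in% categorical || length(unique(x)) <= bins) as.character(x)
    else {
      br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
      if (length(br) < 2) as.character(x)
      else as.character(cut(x, breaks = br, include.lowest = TRUE))
    }
  })
  sig <- do.call(paste, c(sig_cols, sep = "\r"))
  keep_strata <- intersect(unique(sig[frame$treated == 1]),
                           unique(sig[frame$treated == 0]))
  if (!length(keep_strata))
    stop("coarsened exact matching found no stratum containing both ",
         "treated and control units")
  keep <- sig %in% keep_strata
  f <- frame[keep, , drop = FALSE]
  sigk <- sig[keep]
  M_T <- sum(f$treated == 1); M_C <- sum(f$treated == 0)
  mt <- tapply(f$treated == 1, sigk, sum)
  mc <- tapply(f$treated == 0, sigk, sum)
  w <- ifelse(f$treated == 1, 1,
              (mt[sigk] / mc[sigk]) * (M_C / M_T))
  out <- tibble::tibble(
    scheme = "cem",
    pair = NA_integer_,
    pixel_id = f$pixel_id,
    treated = as.integer(f$treated),
    weight = as.numeric(w),
    distance = NA_real_,
    stratum = match(sigk, keep_strata))
  class(out) <- c("matched_set", class(out))
  out
}

#' Random-draw control set
#'
#' The unmatched sensitivity variant: a uniform draw, without replacement, of
#' as many controls as there are treated units, from the eligible pool.
#'
#' @param frame A `study_frame` (typically built with the `"anywhere"` pool).
#' @param seed Integer seed; the draw is seed-deterministic.
#' @return A `matched_set` tibble (`scheme = "random"`).
#' @export
random_controls <- function(frame, seed = 1L) {
  n_t <- sum(frame$treated == 1)
  pool <- frame$pixel_id[frame$treated == 0]
  if (length(pool) < n_t)
    stop("control pool (", length(pool), ") smaller than treated count (",
         n_t, ")")
  set.seed(seed)
  draw <- if (length(pool) == n_t) pool else sample(pool, n_t)
  out <- tibble::tibble(
    scheme = "random",
    pair = NA_integer_,
    pixel_id = c(frame$pixel_id[frame$treated == 1], draw),
    treated = rep(c(1L, 0L), c(n_t, n_t)),
    weight = 1,
    distance = NA_real_)
  class(out) <- c("matched_set", class(out))
  out
}

.wmean <- function(x, w) sum(w * x) / sum(w)
.wvar <- function(x, w) {
  m <- .wmean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

# expand confounders to a numeric matrix (factors -> 0/1 dummies)
.balance_columns <- function(frame, confounders) {
  out <- list()
  for (v in confounders) {
    x <- frame[[v]]
    if (v == "aez" && length(unique(x)) > 2) {
      for (lv in sort(unique(x)))
        out[[paste0(v, "_", lv)]] <- as.numeric(x == lv)
    } else out[[v]] <- as.numeric(x)
  }
  out
}

#' Covariate balance before and after matching
#'
#' Standardised mean differences, `(mean_T - mean_C) / pooled SD`, computed
#' on the full frame (before) and on the matched rows with their weights
#' (after). Multi-level categoricals are expanded to indicator columns;
#' binary variables are treated as 0/1 numerics. When a pooled SD is zero the
#' SMD is 0 if the means agree and flagged otherwise.
#'
#' @param frame The full `study_frame`.
#' @param matched A `matched_set`.
#' @param confounders Confounders to report.
#' @return A `balance_report` tibble: `variable`, `smd_before`, `smd_after`,
#'   `flagged`; sample sizes in attributes.
#' @export
covariate_balance <- function(frame, matched,
                              confounders = study_confounders(frame)) {
  if (nrow(matched) == 0) stop("matched set is empty")
  post <- dplyr::inner_join(matched, frame,
                            by = "pixel_id", suffix = c("", ".frame"))
  smd_of <- function(dat, w) {
    cols <- .balance_columns(dat, confounders)
    purrr::map_dfr(names(cols), function(nm) {
      x <- cols[[nm]]
      ti <- dat$treated == 1
      mT <- .wmean(x[ti], w[ti]); mC <- .wmean(x[!ti], w[!ti])
      sp <- sqrt((.wvar(x[ti], w[ti]) + .wvar(x[!ti], w[!ti])) / 2)
      if (sp > 0) tibble::tibble(variable = nm, smd = (mT - mC) / sp,
                                 flagged = FALSE)
      else tibble::tibble(variable = nm,
                          smd = if (abs(mT - mC) < 1e-12) 0 else NA_real_,
                          flagged = abs(mT - mC) >= 1e-12)
    })
  }
  pre <- smd_of(frame, rep(1, nrow(frame)))
  pst <- smd_of(post, post$weight)
  out <- dplyr::left_join(
    dplyr::rename(pre, smd_before = "smd", flag_before = "flagged"),
    dplyr::rename(pst, smd_after = "smd", flag_after = "flagged"),
    by = "variable") |>
    dplyr::transmute(variable = .data$variable,
                     smd_before = .data$smd_before,
                     smd_after = .data$smd_after,
                     flagged = .data$flag_before | .data$flag_after)
  attr(out, "n_before") <- c(treated = sum(frame$treated == 1),
                             control = sum(frame$treated == 0))
  attr(out, "n_after") <- c(treated = sum(post$treated == 1),
                            control = sum(post$treated == 0))
  class(out) <- c("balance_report", class(out))
  out
}
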