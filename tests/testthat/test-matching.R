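# Matching: propensity model against closed forms and an independent
# optimizer, greedy PSM against an exhaustive oracle, CEM weights against
# hand arithmetic, and balance diagnostics.

test_that("exchangeable groups give a null propensity model", {
  set.seed(1)
  n <- 400
  fr <- tibble::tibble(pixel_id = 1:n,
                       treated = rep(c(1L, 0L), each = n / 2),
                       mean_treecover = rnorm(n, 50, 10),
                       slope = rnorm(n, 2, 1))
  pm <- fit_propensity(fr, c("mean_treecover", "slope"))
  z <- summary(pm$fit)$coefficients[-1, "z value"]
  expect_true(all(abs(z) < 3))
  expect_lt(abs(mean(pm$score) - 0.5), 0.02)
})

test_that("a single binary confounder recovers the log odds ratio", {
  # treated: 50 with x=1, 50 with x=0; controls: 20 with x=1, 80 with x=0
  fr <- tibble::tibble(
    pixel_id = 1:200,
    treated = rep(c(1L, 0L), each = 100),
    burned = c(rep(1L, 50), rep(0L, 50), rep(1L, 20), rep(0L, 80)))
  pm <- fit_propensity(fr, "burned")
  expect_equal(unname(pm$coefficients["burned"]), log(4), tolerance = 1e-6)
})

test_that("IRLS coefficients match an independent optimizer's MLE", {
  set.seed(7)
  n <- 300
  fr <- tibble::tibble(pixel_id = 1:n,
                       mean_treecover = rnorm(n),
                       dist_road = rnorm(n))
  eta <- -0.3 + 0.8 * fr$mean_treecover - 0.5 * fr$dist_road
  fr$treated <- as.integer(runif(n) < plogis(eta))
  pm <- fit_propensity(fr, c("mean_treecover", "dist_road"))
  X <- cbind(1, fr$mean_treecover, fr$dist_road)
  nll <- function(b) -sum(fr$treated * (X %*% b) - log1p(exp(X %*% b)))
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(pm$coefficients), opt$par, tolerance = 1e-5)
})

test_that("separation is reported with the culprit variable", {
  fr <- tibble::tibble(pixel_id = 1:40,
                       treated = rep(c(1L, 0L), each = 20),
                       slope = c(rnorm(20, 10), rnorm(20, -10)))
  expect_error(fit_propensity(fr, "slope"), "separation.*slope")
  expect_error(fit_propensity(fr[fr$treated == 1, ], "slope"),
               "at least one")
  fr$flat <- 1
  expect_error(fit_propensity(fr, c("slope", "flat")), "constant")
})

test_that("common support keeps exactly the overlap interval", {
  set.seed(3)
  fr <- random_match_frame(30, 60)
  fr$treated <- fr$treated[sample.int(90)]
  pm <- list(score = fr$score, pixel_id = fr$pixel_id)
  class(pm) <- "propensity_model"
  out <- common_support(fr, pm)
  lo <- max(min(fr$score[fr$treated == 1]), min(fr$score[fr$treated == 0]))
  hi <- min(max(fr$score[fr$treated == 1]), max(fr$score[fr$treated == 0]))
  expect_setequal(out$pixel_id,
                  fr$pixel_id[fr$score >= lo & fr$score <= hi])
  expect_setequal(c(out$pixel_id, attr(out, "dropped")), fr$pixel_id)
  # disjoint ranges error
  fr2 <- fr
  fr2$score <- ifelse(fr2$treated == 1, fr2$score / 10, 0.5 + fr2$score / 2)
  pm2 <- list(score = fr2$score, pixel_id = fr2$pixel_id)
  class(pm2) <- "propensity_model"
  expect_error(common_support(fr2, pm2), "common support")
})

test_that("greedy matching agrees with the exhaustive oracle", {
  set.seed(11)
  for (rep in 1:50) {
    fr <- random_match_frame(sample(2:15, 1), sample(5:40, 1),
                             n_exact_levels = if (rep %% 2) 2 else 0)
    exact <- if (rep %% 2) c("protected", "aez") else character(0)
    got <- psm_match(fr, caliper_sd = 0.25, exact = exact)
    want <- oracle_psm(fr, caliper_sd = 0.25, exact = exact)
    if (is.null(want)) {
      expect_equal(sum(got$treated == 1), 0)
    } else {
      pairs <- tidyr::pivot_wider(got[, c("pair", "treated", "pixel_id")],
                                  names_from = "treated",
                                  values_from = "pixel_id")
      expect_equal(sort(pairs$`1`), sort(want$treated_id))
      m <- merge(pairs, want, by.x = "1", by.y = "treated_id")
      expect_equal(m$`0`, m$control_id)
    }
    # every pair respects the caliper and the exact constraints (recheck)
    if (nrow(got)) {
      cal <- attr(got, "caliper")
      w <- tidyr::pivot_wider(got[, c("pair", "treated", "pixel_id")],
                              names_from = "treated",
                              values_from = "pixel_id")
      st <- fr$score[match(w$`1`, fr$pixel_id)]
      sc <- fr$score[match(w$`0`, fr$pixel_id)]
      expect_true(all(abs(st - sc) <= cal + 1e-9))
      expect_false(any(duplicated(w$`0`)))       # without replacement
      for (v in exact)
        expect_equal(fr[[v]][match(w$`1`, fr$pixel_id)],
                     fr[[v]][match(w$`0`, fr$pixel_id)])
    }
  }
})

test_that("caliper edge cases: identical units match, distant ones drop", {
  fr <- tibble::tibble(pixel_id = 1:2, treated = c(1L, 0L),
                       score = c(0.5, 0.5))
  got <- psm_match(fr, caliper_sd = 0.25)
  expect_equal(nrow(got), 2)
  expect_equal(got$distance, c(0, 0))
  # sole control beyond the caliper: treated unit dropped, empty set
  fr2 <- tibble::tibble(pixel_id = 1:4, treated = c(1L, 0L, 1L, 0L),
                        score = c(0.9, 0.1, 0.85, 0.15))
  got2 <- psm_match(fr2, caliper_sd = 0.25)   # caliper = 0.25 * sd << 0.7
  expect_equal(nrow(got2), 0)
  expect_setequal(attr(got2, "dropped"), c(1, 3))
})

test_that("CEM weights equal hand-worked stratum arithmetic", {
  # two strata by a binary confounder:
  #   stratum A: 2 treated, 4 controls; stratum B: 1 treated, 1 control;
  #   plus a stratum with controls only (discarded)
  fr <- tibble::tibble(
    pixel_id = 1:12,
    treated = c(1L, 1L, 0L, 0L, 0L, 0L,  1L, 0L,  0L, 0L, 1L, 1L),
    burned =  c(0L, 0L, 0L, 0L, 0L, 0L,  1L, 1L,  2L, 2L, 3L, 3L))
  got <- cem_match(fr, "burned")
  # strata with both groups: burned 0 and 1; M_T = 3, M_C = 5
  expect_setequal(got$pixel_id, c(1:8))
  wA <- (2 / 4) * (5 / 3)   # m_T/m_C * M_C/M_T
  wB <- (1 / 1) * (5 / 3)
  expect_equal(got$weight[got$treated == 1], rep(1, 3))
  expect_equal(got$weight[got$pixel_id %in% 3:6], rep(wA, 4))
  expect_equal(got$weight[got$pixel_id == 8], wB)
  # control weights within each stratum sum to its treated count, rescaled
  # by the overall control/treated ratio
  expect_equal(sum(got$weight[got$treated == 0]), 5)
  # all units in one signature: everyone retained with equal control weight
  fr1 <- tibble::tibble(pixel_id = 1:6, treated = rep(c(1L, 0L), 3),
                        burned = 1L)
  g1 <- cem_match(fr1, "burned")
  expect_equal(nrow(g1), 6)
  expect_equal(unique(g1$weight[g1$treated == 0]), 1)
  # no mixed stratum errors
  fr2 <- tibble::tibble(pixel_id = 1:4, treated = c(1L, 1L, 0L, 0L),
                        burned = c(0L, 0L, 1L, 1L))
  expect_error(cem_match(fr2, "burned"), "no stratum")
})

test_that("random controls draw uniformly and deterministically", {
  fr <- tibble::tibble(pixel_id = 1:28,
                       treated = rep(c(1L, 0L), c(4, 24)),
                       slope = rnorm(28))
  a <- random_controls(fr, seed = 5)
  b <- random_controls(fr, seed = 5)
  expect_identical(a, b)
  expect_equal(sum(a$treated == 0), 4)
  # pool exactly the treated count: returned in full
  fr_eq <- fr[c(1:4, 5:8), ]
  full <- random_controls(fr_eq, seed = 1)
  expect_setequal(full$pixel_id[full$treated == 0], fr_eq$pixel_id[5:8])
  # pool too small errors
  expect_error(random_controls(fr[1:6, ], seed = 1), "smaller")
  # uniformity over the pool across replicate draws
  counts <- integer(24)
  for (s in 1:5000) {
    d <- random_controls(fr, seed = s)
    ids <- d$pixel_id[d$treated == 0] - 4L
    counts[ids] <- counts[ids] + 1L
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("balance SMDs match hand arithmetic and exact-match zeros", {
  fr <- tibble::tibble(
    pixel_id = 1:8,
    treated = rep(c(1L, 0L), each = 4),
    slope = c(1, 2, 3, 4, 2, 3, 4, 5),
    protected = c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L))
  ms <- tibble::tibble(scheme = "psm", pair = rep(1:4, 2),
                       pixel_id = 1:8, treated = rep(c(1L, 0L), each = 4),
                       weight = 1, distance = 0)
  class(ms) <- c("matched_set", class(ms))
  bal <- covariate_balance(fr, ms, c("slope", "protected"))
  # hand: means 2.5 vs 3.5, population variances both 1.25
  expect_equal(bal$smd_before[bal$variable == "slope"], -1 / sqrt(1.25))
  expect_equal(bal$smd_after[bal$variable == "slope"], -1 / sqrt(1.25))
  expect_equal(bal$smd_before[bal$variable == "protected"], 0)
  # identical groups: all SMDs zero
  fr2 <- fr; fr2$slope <- rep(c(1, 2, 3, 4), 2)
  bal2 <- covariate_balance(fr2, ms, c("slope", "protected"))
  expect_equal(bal2$smd_before, c(0, 0))
  expect_false(any(bal2$flagged))
  # zero pooled SD with different means is flagged
  fr3 <- fr; fr3$slope <- rep(c(1, 2), each = 4)
  bal3 <- covariate_balance(fr3, ms, "slope")
  expect_true(bal3$flagged)
})

test_that("PSM improves balance on confounded frames", {
  set.seed(99)
  improved <- logical(100)
  for (r in 1:100) {
    n <- 150
    fr <- tibble::tibble(pixel_id = 1:n,
                         mean_treecover = rnorm(n, 50, 10),
                         dist_road = rnorm(n, 5, 2))
    eta <- -2.2 + 0.04 * (fr$mean_treecover - 50) - 0.35 * (fr$dist_road - 5)
    fr$treated <- as.integer(runif(n) < plogis(eta))
    if (sum(fr$treated) < 5 || sum(fr$treated) > n / 2) next
    pm <- try(fit_propensity(fr, c("mean_treecover", "dist_road")),
              silent = TRUE)
    if (inherits(pm, "try-error")) next
    cs <- common_support(fr, pm)
    ms <- psm_match(cs, exact = character(0))
    if (nrow(ms) == 0) next
    bal <- covariate_balance(fr, ms, c("mean_treecover", "dist_road"))
    improved[r] <- mean(abs(bal$smd_after)) <= mean(abs(bal$smd_before))
  }
  expect_gte(mean(improved), 0.95)
})
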