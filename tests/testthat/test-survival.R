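test_that("km_estimate matches the survival package on censored data", {
  set.seed(3)
  d <- round(rexp(200, 1 / 10), 2) + 0.01
  obs <- runif(200) < 0.7
  km <- km_estimate(d, obs)
  sf <- survival::survfit(survival::Surv(d, obs) ~ 1, conf.type = "log-log")
  sm <- summary(sf)
  ev <- km$curve$n_event > 0
  expect_equal(km$curve$survival[ev], sm$surv, tolerance = 1e-12)
  pos <- km$curve$survival[ev] > 0   # at S = 0 survfit reports NA bands
  expect_equal(km$curve$lower[ev][pos], sm$lower[pos], tolerance = 1e-9)
  q <- quantile(sf, 0.5)
  expect_equal(km$median, unname(q$quantile))
  expect_equal(unname(km$median_ci), unname(c(q$lower, q$upper)))
})

test_that("km_estimate without censoring reproduces the empirical survival", {
  set.seed(8)
  d <- sample(seq(0.25, 20, by = 0.25), 60, replace = TRUE)
  km <- km_estimate(d, rep(TRUE, 60))
  ecdf_surv <- vapply(km$curve$time, function(t) mean(d > t), numeric(1))
  expect_equal(km$curve$survival, ecdf_surv)
  expect_equal(km$median, min(d[vapply(d, function(t) mean(d <= t), numeric(1)) >= 0.5]))
})

test_that("censoring enters only through the risk set", {
  # a censored duration shorter than the first event is never at risk at an
  # event time, so the curve is unchanged
  km1 <- km_estimate(c(2, 4, 6), c(TRUE, TRUE, TRUE))
  km2 <- km_estimate(c(1, 2, 4, 6), c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(km2$curve$survival[km2$curve$n_event > 0], km1$curve$survival)
  # a censored duration beyond the last event adds no event step but joins
  # every earlier risk set (its effect on S is multiplicative, not zero)
  km3 <- km_estimate(c(2, 4, 6, 50), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(km3$curve$time[km3$curve$n_event > 0], c(2, 4, 6))
  expect_equal(km3$curve$survival[1], 3 / 4)
})

test_that("all-censored input yields a curve above 0.5 and no median", {
  km <- km_estimate(c(3, 5, 8), rep(FALSE, 3))
  expect_true(all(km$curve$survival > 0.5))
  expect_true(is.na(km$median))
  expect_error(km_estimate(numeric(0), logical(0)))
})

test_that("per-generation medians are flat when the generator does not shrink", {
  p <- sim_params(seed = 33, n_colonies = 40, per_generation_shrink = 1)
  rec <- truth_to_records(simulate_lineage(p, "DIFF", frames = FALSE))
  mt <- suppressWarnings(km_median_by_generation(rec, "CC_L", "DIFF",
                                                 min_n = 30))
  # restrict to strata with mostly observed events: in near-fully-censored
  # strata lineage-heritable speed makes censoring informative and biases
  # the KM median low (see the methods vignette)
  mt <- mt[mt$n_events / mt$n >= 0.5, ]
  expect_gte(nrow(mt), 2L)
  pooled <- km_estimate(km_input(rec, "CC_L")$duration,
                        km_input(rec, "CC_L")$observed)$median
  expect_true(all(mt$ci_low <= pooled & pooled <= ifelse(is.na(mt$ci_high),
                                                         Inf, mt$ci_high)))
})

test_that("small strata are omitted with a warning; single stratum passes through", {
  rec <- toy_records()
  rec$censored_duration_h <- NA_real_
  expect_warning(
    expect_warning(
      mt <- km_median_by_generation(rec, "CC_L", "GROUND_STATE", min_n = 3),
      "generation 1"),
    "generation 2")
  expect_equal(mt$generation, 3L)
  expect_equal(nrow(mt), 1L)
})

test_that("logrank_test is symmetric-null and matches survdiff", {
  a <- c(2, 4, 6, 8, 10)
  lr0 <- logrank_test(a, rep(TRUE, 5), a, rep(TRUE, 5))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p, 1)

  set.seed(5)
  g1 <- rexp(100, 1 / 10); g2 <- g1 + 5
  lr <- logrank_test(g1, rep(TRUE, 100), g2, rep(TRUE, 100))
  expect_lt(lr$p, 0.001)

  o1 <- runif(100) < 0.8; o2 <- runif(100) < 0.8
  lr2 <- logrank_test(g1, o1, g2, o2)
  sd2 <- survival::survdiff(
    survival::Surv(c(g1, g2), c(o1, o2)) ~ rep(1:2, each = 100))
  expect_equal(lr2$statistic, sd2$chisq, tolerance = 1e-12)
})

test_that("logrank p agrees with a permutation null on a small sample", {
  # 12 cells, some censored; compare chi-square p with the permutation
  # distribution of the statistic (Monte-Carlo tolerance)
  d <- c(2, 3, 3, 5, 7, 8, 4, 6, 9, 10, 12, 13)
  o <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
         TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  grp <- rep(c(TRUE, FALSE), each = 6)
  obs <- logrank_test(d[grp], o[grp], d[!grp], o[!grp])
  set.seed(99)
  B <- 20000L
  perm <- vapply(seq_len(B), function(i) {
    g <- sample(grp)
    logrank_test(d[g], o[g], d[!g], o[!g])$statistic
  }, numeric(1))
  p_perm <- mean(perm >= obs$statistic - 1e-12)
  expect_lt(abs(p_perm - obs$p), 0.05)
})

test_that("mann_whitney is exact on small samples and matches brute-force U", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$p, 1 / 3)
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  set.seed(2)
  a <- sample(seq(0.25, 5, by = 0.25), 40, replace = TRUE)
  b <- sample(seq(0.25, 5, by = 0.25), 35, replace = TRUE) + 0.5
  mw <- mann_whitney(a, b)
  expect_equal(mw$U, brute_U(a, b))
})

test_that("generation_fraction counts all tracked cells", {
  rec <- toy_records()
  expect_equal(generation_fraction(rec, 5L, "GROUND_STATE"), 0)
  rec$generation[1:2] <- 5L
  expect_equal(generation_fraction(rec, 5L, "GROUND_STATE"), 100 * 2 / 7)
})
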