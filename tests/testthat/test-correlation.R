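test_that("spearman_rho matches hand rank computations", {
  expect_equal(spearman_rho(1:5, 1:5 * 2), 1)
  expect_equal(spearman_rho(1:5, -(1:5)), -1)
  # 1 - 6 * 4 / (4 * 15) = 0.6
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_warning(r <- spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))
})

test_that("a single stratum leaves the Spearman coefficient unchanged", {
  set.seed(1)
  pv <- data.frame(relation = "MOTHER_DAUGHTER", colony_id = "c",
                   condition = "DIFF", generation = 2L,
                   value_a = rnorm(40), value_b = rnorm(40))
  pv$value_b <- pv$value_a * 0.5 + pv$value_b
  cen <- stratified_center(pv)
  expect_equal(cor(cen$centered_a, cen$centered_b, method = "spearman"),
               cor(pv$value_a, pv$value_b, method = "spearman"))
})

test_that("stratified centering removes a between-stratum confound", {
  # two generations with disjoint value ranges, zero association within each
  set.seed(42)
  n <- 60
  mk <- function(gen, base) {
    data.frame(relation = "SISTER", colony_id = rep(c("c1", "c2"), n / 2),
               condition = "DIFF", generation = gen,
               value_a = base + runif(n), value_b = base + runif(n))
  }
  pv <- rbind(mk(2L, 10), mk(3L, 0))
  pooled <- cor(c(pv$value_a, pv$value_b), c(pv$value_b, pv$value_a),
                method = "spearman")
  centered <- pair_spearman(pv)
  expect_gt(pooled, 0.5)
  expect_lt(abs(centered), 0.1)
})

test_that("centering preserves genuine within-stratum association", {
  set.seed(7)
  for (rho_sign in c(1, -1)) {
    x <- rnorm(80)
    pv <- data.frame(relation = "SISTER", colony_id = rep(c("c1", "c2"), 40),
                     condition = "DIFF",
                     generation = rep(2:3, each = 40),
                     value_a = x + rep(c(0, 5), each = 40))
    pv$value_b <- rho_sign * x + rnorm(80, 0, 0.4) + rep(c(0, 5), each = 40)
    expect_equal(sign(pair_spearman(pv)), rho_sign)
  }
})

test_that("strata with fewer than 2 pairs are dropped with a warning", {
  pv <- data.frame(relation = "SISTER", colony_id = "c", condition = "DIFF",
                   generation = c(2L, 2L, 2L, 9L),
                   value_a = c(1, 2, 3, 4), value_b = c(1, 2, 3, 4))
  expect_warning(cen <- stratified_center(pv), "dropped")
  expect_equal(nrow(cen), 3L)
})

test_that("bootstrap_corr is reproducible and pins perfect association", {
  set.seed(10)
  v <- rnorm(60)
  pv <- data.frame(relation = "MOTHER_DAUGHTER",
                   colony_id = rep(paste0("c", 1:6), each = 10),
                   condition = "DIFF", generation = rep(2:3, 30),
                   value_a = v, value_b = v)
  bc <- bootstrap_corr(pv, n_boot = 300, seed = 5)
  expect_equal(bc$rho_hat, 1)
  expect_equal(bc$ci_high, 1)
  expect_lt(bc$p_value, 0.01)
  bc2 <- bootstrap_corr(pv, n_boot = 300, seed = 5)
  expect_identical(bc$replicates, bc2$replicates)
  expect_error(bootstrap_corr(pv[pv$colony_id == "c1", ], 300, 1), "colonies")
})

test_that("centered sister correlation recovers the target where pooling overshoots", {
  p <- sim_params(seed = 55, n_colonies = 40, per_generation_shrink = 0.85)
  rec <- truth_to_records(simulate_lineage(p, "DIFF", frames = FALSE))
  pv <- pair_values(enumerate_pairs(build_forest(rec), rec, "SISTER"),
                    rec, "CC_L")
  expect_gt(nrow(pv), 400L)
  pooled <- cor(c(pv$value_a, pv$value_b), c(pv$value_b, pv$value_a),
                method = "spearman")
  centered <- pair_spearman(pv)
  expect_gt(pooled, centered)
  g1 <- pair_values(enumerate_pairs(build_forest(rec), rec, "SISTER"),
                    rec, "G1_L")
  expect_lt(abs(pair_spearman(g1) - 0.8), 0.1)
})

test_that("inheritance_inequality reports the exact replicate-wise contrast", {
  p <- sim_params(seed = 61, n_colonies = 12, window_h = 55,
                  apoptosis_prob = 0)
  rec <- truth_to_records(simulate_lineage(p, "GROUND_STATE", frames = FALSE))
  ii <- inheritance_inequality(rec, variable = "G1_L", n_boot = 200, seed = 2)
  expect_equal(ii$delta, ii$rho_cc - ii$rho_md^2 * ii$rho_ss)
  expect_equal(ii$replicates[, 4],
               ii$replicates[, 3] - ii$replicates[, 2]^2 * ii$replicates[, 1])
  expect_true(ii$ci_low <= ii$ci_high)
  ii2 <- inheritance_inequality(rec, variable = "G1_L", n_boot = 200, seed = 2)
  expect_identical(ii$replicates, ii2$replicates)
})
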