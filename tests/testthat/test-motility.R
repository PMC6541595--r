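test_that("path_length sums segments, splits long gaps, warns on points", {
  sq <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(path_length(1:4, sq[, 1], sq[, 2]), 3)
  expect_equal(path_length(1:5, rep(2, 5), rep(3, 5)), 0)
  expect_warning(expect_equal(path_length(1L, 0, 0), 0), "< 2 points")
  # a 6-frame gap contributes nothing; the two flanking legs remain
  expect_equal(path_length(c(1, 2, 8, 9), c(0, 1, 5, 6), rep(0, 4)), 2)
  # interpolation equivalence: a <= 4 frame gap is the straight segment
  expect_equal(path_length(c(1, 2, 5), c(0, 1, 4), rep(0, 3)), 4)
})

test_that("convex hull area matches an independent Jarvis-march oracle", {
  expect_equal(convex_hull_area(c(0, 1, 1, 0), c(0, 0, 1, 1)), 1)
  expect_equal(convex_hull_area(1:5, 2 * (1:5)), 0)
  expect_equal(convex_hull_area(3, 4), 0)
  set.seed(20)
  for (i in 1:3) {
    x <- rnorm(100); y <- rnorm(100)
    expect_equal(convex_hull_area(x, y), jarvis_hull_area(x, y))
  }
})

test_that("motility summary reproduces hand arithmetic on a square path", {
  dt <- 0.25
  fr <- 1:4
  tab <- data.frame(cell_id = "s1", colony_id = "c", condition = "DIFF",
                    frame = c(0L, fr, 5L), time_h = c(0L, fr, 5L) * dt,
                    x = c(0, 0, 1, 1, 0, 0), y = c(0, 0, 0, 1, 1, 1),
                    nuclear_area = pi, cherry = 1, venus = 1,
                    parent_id = NA_character_)
  rec <- toy_records()[1, ]
  rec$cell_id <- "s1"; rec$parent_id <- NA_character_
  rec$CC_L_h <- 4; rec$complete <- TRUE
  ms <- motility_summary(rec, validate_tracking_table(tab))
  expect_equal(ms$hull_area, 1)
  expect_equal(ms$exploration, 0.25)
  # doubling CC-L at fixed trajectory halves both normalized metrics
  rec2 <- rec; rec2$CC_L_h <- 8
  ms2 <- motility_summary(rec2, validate_tracking_table(tab))
  expect_equal(ms2$mean_speed, ms$mean_speed / 2)
  expect_equal(ms2$exploration, ms$exploration / 2)
})

test_that("speed and exploration are rigid-motion invariant", {
  p <- sim_params(seed = 26, n_colonies = 1, founders_per_colony = 2)
  tab <- simulate_lineage(p, "DIFF")
  rec <- extract_records(tab)
  ms <- motility_summary(rec, tab)
  th <- 1.1
  rot <- tab
  rot$x <- cos(th) * tab$x - sin(th) * tab$y + 500
  rot$y <- sin(th) * tab$x + cos(th) * tab$y - 200
  ms2 <- motility_summary(rec, rot)
  expect_equal(ms2$mean_speed, ms$mean_speed, tolerance = 1e-6)
  expect_equal(ms2$exploration, ms$exploration, tolerance = 1e-6)
})

test_that("colony metrics: area, density and degenerate colonies", {
  tab <- data.frame(cell_id = paste0("c", 1:4), colony_id = "A",
                    condition = "DIFF", frame = 0L, time_h = 0,
                    x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), nuclear_area = 1,
                    cherry = 1, venus = 1, parent_id = NA_character_)
  cm <- colony_metrics(tab)
  expect_equal(cm$colony_area, 1)
  expect_equal(cm$density, 4)
  solo <- tab[1, ]
  solo$colony_id <- "B"
  cm2 <- colony_metrics(rbind(tab, solo))
  expect_equal(cm2$colony_area[cm2$colony_id == "B"], 0)
  expect_true(is.na(cm2$density[cm2$colony_id == "B"]))
})

test_that("peripheral classification: corners are peripheral, the center is not", {
  mk <- function(n_center = 1) {
    xy <- rbind(c(0, 0), c(40, 0), c(40, 40), c(0, 40),
                matrix(20, n_center, 2))
    data.frame(cell_id = paste0("c", seq_len(nrow(xy))), colony_id = "A",
               condition = "DIFF", frame = rep(0:1, each = nrow(xy)),
               time_h = rep(0:1, each = nrow(xy)) * 0.25,
               x = rep(xy[, 1], 2), y = rep(xy[, 2], 2),
               nuclear_area = pi * 4, cherry = 1, venus = 1,   # radius 2 << 20
               parent_id = NA_character_)
  }
  per <- classify_peripheral(mk())
  expect_true(all(per[paste0("c", 1:4)]))
  expect_false(per[["c5"]])
  # colonies of <= 3 cells are all-peripheral by construction
  tiny <- mk()[c(1, 6, 2, 7, 3, 8), ]
  expect_true(all(classify_peripheral(tiny)))
})

test_that("a trajectory hull never exceeds its colony hull", {
  p <- sim_params(seed = 27, n_colonies = 1)
  tab <- simulate_lineage(p, "GROUND_STATE")
  rec <- extract_records(tab)
  ms <- motility_summary(rec, tab)
  colony_all <- convex_hull_area(tab$x, tab$y)
  expect_true(all(ms$hull_area <= colony_all + 1e-9))
})

test_that("nuclear area summary averages per cell and warns when absent", {
  tab <- toy_table()
  rec <- extract_records(tab)
  ns <- nuclear_area_summary(tab, rec)
  expect_equal(unique(ns$mean_area), 80)
  tab2 <- tab
  tab2$nuclear_area <- NA_real_
  expect_warning(empty <- nuclear_area_summary(tab2, rec), "skipping")
  expect_equal(nrow(empty), 0L)
})
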