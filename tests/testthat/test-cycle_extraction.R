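test_that("assign_generations walks parent links from founders", {
  par7 <- c(f = NA, d1 = "f", d2 = "f", g1 = "d1", g2 = "d1", g3 = "d2",
            g4 = "d2")
  expect_equal(unname(assign_generations(par7)),
               c(1L, 2L, 2L, 3L, 3L, 3L, 3L))
  expect_equal(unname(assign_generations(c(lone = NA))), 1L)
  # 5-generation balanced tree built programmatically
  par <- c(r = NA_character_)
  leaves <- "r"
  for (g in 2:5) {
    kids <- setNames(rep(leaves, each = 2),
                     paste0(rep(leaves, each = 2), c("a", "b")))
    par <- c(par, kids)
    leaves <- names(kids)
  }
  gen <- assign_generations(par)
  expect_equal(max(gen), 5L)
  expect_equal(sum(gen == 5L), 16L)
  expect_error(assign_generations(c(a = "b", b = "a")),
               class = "fucci_lineage_error")
})

test_that("detect_g1_boundary finds single peaks and refuses degenerate traces", {
  tt <- seq(0, 10, by = 0.25)
  tri <- ifelse(tt <= 3, tt / 3, (10 - tt) / 7)
  expect_equal(detect_g1_boundary(tt, tri, 0, 10), 3)
  dec <- rev(seq_along(tt))
  expect_true(is.na(detect_g1_boundary(tt, dec, 0, 10)))
  expect_equal(attr(detect_g1_boundary(tt, dec, 0, 10), "reason"), "monotone")
  short <- detect_g1_boundary(c(1, 2, 3), c(1, 5, 1), 0, 10)
  expect_equal(attr(short, "reason"), "too_short")
  flat <- detect_g1_boundary(tt, rep(2, length(tt)), 0, 10)
  expect_equal(attr(flat, "reason"), "flat")
})

test_that("toy extraction yields the hand-computed record", {
  # born at 10 h (frame 40/41 boundary), divides at 21 h, peak at 13 h
  tab <- toy_table(peak_frac = 0.3)
  rec <- extract_records(tab)
  d1 <- rec[rec$cell_id == "d1", ]
  expect_true(d1$complete)
  expect_equal(d1$birth_time_h, 10.125)
  expect_equal(d1$end_time_h, 20.125)
  expect_equal(d1$CC_L_h, 10)
  # peak at frame 41 + 0.3 * 39 = 53 -> 13.25 h
  expect_equal(d1$G1_L_h, 13.25 - 10.125)
  expect_equal(d1$SG2M_L_h, d1$CC_L_h - d1$G1_L_h)
  # founder has no observed birth
  expect_false(rec$complete[rec$cell_id == "f"])
  expect_equal(rec$generation[rec$cell_id == "g4"], 3L)
})

test_that("cells reaching the last frame are censored with their elapsed time", {
  dt <- 0.25
  fr <- 160:180   # born at ~40 h of a 45 h movie, never divides
  tab <- data.frame(cell_id = c(rep("m", 2), rep("s1", length(fr)),
                                rep("s2", length(fr))),
                    colony_id = "c", condition = "GROUND_STATE",
                    frame = c(158L, 159L, fr, fr),
                    time_h = c(158L, 159L, fr, fr) * dt,
                    x = 0, y = 0, nuclear_area = 80, cherry = 1, venus = 1,
                    parent_id = c(NA, NA, rep("m", length(fr)),
                                  rep("m", length(fr))))
  rec <- extract_records(validate_tracking_table(tab), dataset_metadata())
  s1 <- rec[rec$cell_id == "s1", ]
  expect_equal(s1$fate, "CENSORED_END")
  expect_false(s1$complete)
  expect_true(is.na(s1$CC_L_h))
  expect_equal(s1$censored_duration_h, 45 - 39.875)
})

test_that("extracted cycle lengths match simulator truth exactly", {
  p <- sim_params(seed = 6, n_colonies = 3)
  tab <- simulate_lineage(p, "DIFF")
  rec <- extract_records(tab)
  tr <- ground_truth(tab)
  m <- merge(rec[rec$complete, c("cell_id", "CC_L_h", "G1_L_h")],
             tr[, c("cell_id", "true_CC_L_h", "true_G1_L_h")], by = "cell_id")
  expect_gt(nrow(m), 100L)
  expect_equal(m$CC_L_h, m$true_CC_L_h)
  # default noise: peak calls within 2 frames in median
  err <- abs(m$G1_L_h - m$true_G1_L_h) / 0.25
  expect_lte(median(err, na.rm = TRUE), 2)
})

test_that("noise-free traces give exact boundary calls", {
  p <- sim_params(seed = 6, n_colonies = 2, fluor_noise_sd = 0,
                  peak_jitter_frames = 0)
  tab <- simulate_lineage(p, "GROUND_STATE")
  rec <- extract_records(tab)
  tr <- ground_truth(tab)
  m <- merge(rec[rec$complete & !is.na(rec$G1_L_h), c("cell_id", "G1_L_h")],
             tr[, c("cell_id", "true_G1_L_h")], by = "cell_id")
  expect_gt(nrow(m), 30L)
  expect_equal(m$G1_L_h, m$true_G1_L_h)
})

test_that("filter_complete keeps only fully observed cycles", {
  rec <- toy_records()
  rec$complete[c(1, 5, 7)] <- FALSE
  expect_equal(nrow(filter_complete(rec)), 4L)
  rec$complete <- FALSE
  expect_equal(nrow(filter_complete(rec)), 0L)
})

test_that("record invariants: birth + CC-L = end time, within the window", {
  p <- sim_params(seed = 14, n_colonies = 3)
  tab <- simulate_lineage(p, "DIFF")
  rec <- filter_complete(extract_records(tab))
  expect_equal(rec$birth_time_h + rec$CC_L_h, rec$end_time_h)
  expect_true(all(rec$birth_time_h + rec$CC_L_h <= 45 + 1e-9))
  expect_true(all(rec$G1_L_h > 0 & rec$G1_L_h < rec$CC_L_h, na.rm = TRUE))
})

test_that("apoptosis annotations override the fate", {
  p <- sim_params(seed = 25, n_colonies = 6)
  tab <- simulate_lineage(p, "GROUND_STATE")
  ann <- attr(tab, "annotations")
  expect_gt(nrow(ann), 0L)   # ~3% of ~400 cells at this seed
  rec <- extract_records(tab)
  expect_true(all(rec$fate[rec$cell_id %in% ann$cell_id] == "APOPTOSIS"))
  # apoptotic cells never contribute censored durations by default
  expect_true(all(is.na(rec$censored_duration_h[rec$fate == "APOPTOSIS"])))
})
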