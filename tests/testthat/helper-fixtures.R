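# Shared fixtures and independent oracles. Everything is built in code; no
# data files.

# A hand-built one-colony tracking table: founder f divides at frame 40 into
# d1/d2; d1 divides at frame 80 into g1/g2. Cherry traces are triangular with
# a known peak; venus rises after it. Frame interval 0.25 h, window 45 h.
toy_table <- function(peak_frac = 0.3) {
  dt <- 0.25
  mk_cell <- function(id, parent, first, last, peak_frame, colony = "colA") {
    fr <- first:last
    n <- length(fr)
    up <- fr <= peak_frame
    cherry <- numeric(n)
    cherry[up] <- 100 + 900 * (fr[up] - first) / max(1, peak_frame - first)
    cherry[!up] <- 1000 - 900 * (fr[!up] - peak_frame) / max(1, last - peak_frame)
    venus <- ifelse(up, 50, 50 + 900 * (fr - peak_frame) / max(1, last - peak_frame))
    data.frame(cell_id = id, colony_id = colony, condition = "GROUND_STATE",
               frame = fr, time_h = fr * dt, x = fr * 0.1, y = -fr * 0.05,
               nuclear_area = 80, cherry = cherry, venus = venus,
               parent_id = parent, stringsAsFactors = FALSE)
  }
  span <- function(first, last) first + round(peak_frac * (last - first))
  tab <- rbind(
    mk_cell("f", NA_character_, 0L, 40L, span(0L, 40L)),
    mk_cell("d1", "f", 41L, 80L, span(41L, 80L)),
    mk_cell("d2", "f", 41L, 80L, span(41L, 80L)),
    mk_cell("g1", "d1", 81L, 140L, span(81L, 140L)),
    mk_cell("g2", "d1", 81L, 140L, span(81L, 140L)),
    mk_cell("g3", "d2", 81L, 140L, span(81L, 140L)),
    mk_cell("g4", "d2", 81L, 140L, span(81L, 140L)))
  validate_tracking_table(tab, dataset_metadata())
}

# cycle_records for a complete 7-cell binary tree with the given values
toy_records <- function(values = c(f = 10, d1 = 11, d2 = 12, g1 = 9,
                                   g2 = 10, g3 = 13, g4 = 8)) {
  ids <- names(values)
  parent <- c(f = NA, d1 = "f", d2 = "f", g1 = "d1", g2 = "d1",
              g3 = "d2", g4 = "d2")
  gen <- c(f = 1L, d1 = 2L, d2 = 2L, g1 = 3L, g2 = 3L, g3 = 3L, g4 = 3L)
  rec <- data.frame(cell_id = ids, colony_id = "colA",
                    condition = "GROUND_STATE",
                    parent_id = unname(parent[ids]),
                    generation = unname(gen[ids]),
                    birth_time_h = 0, end_time_h = unname(values),
                    fate = "DIVIDED", CC_L_h = unname(values),
                    G1_L_h = unname(values) * 0.3,
                    SG2M_L_h = unname(values) * 0.7,
                    censored_duration_h = NA_real_, complete = TRUE,
                    track_gap = FALSE, stringsAsFactors = FALSE)
  class(rec) <- c("cycle_records", "data.frame")
  rec
}

# Observed-records view of simulator truth: applies the 45 h window censoring
# without trace extraction (fast path for statistics-level tests; extraction
# fidelity is tested separately in test-cycle_extraction.R).
truth_to_records <- function(table, W = attr(table, "metadata")$window_h) {
  tr <- ground_truth(table)
  complete <- tr$fate == "DIVIDED" & tr$generation >= 2L
  boundary_seen <- tr$generation >= 2L &
    (tr$birth_time_h + tr$true_G1_L_h) <= pmin(W, tr$division_time_h)
  rec <- data.frame(
    cell_id = tr$cell_id, colony_id = tr$colony_id, condition = tr$condition,
    parent_id = tr$parent_id, generation = tr$generation,
    birth_time_h = ifelse(tr$generation >= 2L, tr$birth_time_h, NA_real_),
    end_time_h = pmin(tr$division_time_h, W),
    fate = ifelse(tr$fate == "DIVIDED", "DIVIDED", tr$fate),
    CC_L_h = ifelse(complete, tr$true_CC_L_h, NA_real_),
    G1_L_h = ifelse(boundary_seen, tr$true_G1_L_h, NA_real_),
    SG2M_L_h = ifelse(complete, tr$true_SG2M_L_h, NA_real_),
    censored_duration_h = ifelse(!complete & tr$generation >= 2L &
                                   tr$fate != "APOPTOSIS",
                                 pmin(W, tr$division_time_h) - tr$birth_time_h,
                                 NA_real_),
    complete = complete, track_gap = FALSE, stringsAsFactors = FALSE)
  class(rec) <- c("cycle_records", "data.frame")
  rec
}

# Independent convex-hull oracle: Jarvis march (gift wrapping) + shoelace,
# a different algorithm from the implementation's chull-based path.
jarvis_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3L) return(0)
  crossp <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1L) 2L else 1L
    for (j in seq_len(n)) {
      if (j == cur) next
      cp <- crossp(pts[cur, ], pts[cand, ], pts[j, ])
      if (cand == cur || cp < 0 ||
          (cp == 0 && sum((pts[j, ] - pts[cur, ])^2) >
             sum((pts[cand, ] - pts[cur, ])^2))) {
        cand <- j
      }
    }
    cur <- cand
    if (cur == start || length(hull) > n) break
  }
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  if (length(hull) < 3L) return(0)
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# Brute-force Mann-Whitney U (pairs where a > b, half credit for ties)
brute_U <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}
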