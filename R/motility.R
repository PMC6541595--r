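#' Total trajectory length
#'
#' Sum of consecutive Euclidean segment lengths after ordering by frame.
#' Missing frames are bridged by the straight segment (equivalent to linear
#' interpolation) up to `max_gap_frames`; longer gaps split the path and
#' contribute no length.
#'
#' @param frame integer frame indices.
#' @param x,y coordinates.
#' @param max_gap_frames largest gap bridged by a straight segment.
#' @return path length (spatial units); 0 with a warning for a single point.
#' @export
path_length <- function(frame, x, y, max_gap_frames = 4L) {
  stopifnot(length(frame) == length(x), length(x) == length(y))
  if (length(frame) < 2L) {
    warning("trajectory with < 2 points: path length 0", call. = FALSE)
    return(0)
  }
  o <- order(frame)
  fx <- x[o]; fy <- y[o]; fr <- frame[o]
  seg <- sqrt(diff(fx)^2 + diff(fy)^2)
  seg[diff(fr) > max_gap_frames] <- 0
  sum(seg)
}

#' Area of the 2D convex hull of a point set
#'
#' Hull via [grDevices::chull()] (Graham-like scan), area via the shoelace
#' formula. Fewer than 3 distinct non-collinear points give area 0.
#'
#' @param x,y coordinates.
#' @return hull area (squared spatial units).
#' @export
convex_hull_area <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3L) return(0)
  h <- chull(pts[, 1], pts[, 2])
  if (length(h) < 3L) return(0)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Per-cell motility summary
#'
#' For complete cells with at least `min_points` trajectory points: total path
#' length, mean speed (`path / CC_L`, units/h), trajectory hull area and
#' exploration (`hull_area / CC_L`, units^2/h), plus the peripheral flag from
#' [classify_peripheral()]. Normalization by CC-L removes the bias that
#' longer-cycling cells accumulate more trajectory.
#'
#' @param records `cycle_records`.
#' @param table `tracking_table` with positions.
#' @param max_gap_frames forwarded to [path_length()].
#' @param min_points minimum trajectory points.
#' @param peripheral optional precomputed named logical from
#'   [classify_peripheral()] (computed here when `NULL`).
#' @return data.frame of class `motility_summary`.
#' @export
motility_summary <- function(records, table, max_gap_frames = 4L,
                             min_points = 3L, peripheral = NULL) {
  tab <- as.data.frame(table)
  rec <- filter_complete(records)
  peripheral <- peripheral %||% classify_peripheral(table)
  idx <- split(seq_len(nrow(tab)), tab$cell_id)
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    id <- rec$cell_id[i]
    rws <- idx[[id]]
    if (is.null(rws) || length(rws) < min_points) return(NULL)
    pl <- path_length(tab$frame[rws], tab$x[rws], tab$y[rws], max_gap_frames)
    ha <- convex_hull_area(tab$x[rws], tab$y[rws])
    cc <- rec$CC_L_h[i]
    data.frame(cell_id = id, colony_id = rec$colony_id[i],
               condition = rec$condition[i], generation = rec$generation[i],
               CC_L_h = cc, path_length = pl, mean_speed = pl / cc,
               hull_area = ha, exploration = ha / cc,
               peripheral = isTRUE(peripheral[[id]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cell_id = character(0), colony_id = character(0),
                      condition = character(0), generation = integer(0),
                      CC_L_h = numeric(0), path_length = numeric(0),
                      mean_speed = numeric(0), hull_area = numeric(0),
                      exploration = numeric(0), peripheral = logical(0))
  }
  rownames(out) <- NULL
  class(out) <- c("motility_summary", "data.frame")
  out
}

#' Colony area and density over time
#'
#' Per colony and frame: member count, convex-hull area of member centroids
#' and density `n / area`. With fewer than 3 cells (or zero area) the density
#' is undefined and flagged `NA`.
#'
#' @param table `tracking_table`.
#' @return data.frame `colony_id`, `condition`, `frame`, `time_h`, `n_cells`,
#'   `colony_area`, `density`.
#' @export
colony_metrics <- function(table) {
  tab <- as.data.frame(table)
  key <- paste(tab$colony_id, tab$frame, sep = "\r")
  idx <- split(seq_len(nrow(tab)), key)
  rows <- lapply(idx, function(rws) {
    n <- length(rws)
    area <- convex_hull_area(tab$x[rws], tab$y[rws])
    data.frame(colony_id = tab$colony_id[rws[1]],
               condition = tab$condition[rws[1]],
               frame = tab$frame[rws[1]], time_h = tab$time_h[rws[1]],
               n_cells = n, colony_area = area,
               density = if (n >= 3L && area > 0) n / area else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$colony_id, out$frame), ]
  rownames(out) <- NULL
  out
}

#' Classify peripheral cells
#'
#' A cell is peripheral when, in at least one frame of its life, its centroid
#' lies within `epsilon` of the boundary of its colony's convex hull (hull
#' vertices always qualify). In colonies of three or fewer cells every cell is
#' on the hull. The default tolerance is one nuclear radius estimated from
#' the median nuclear area.
#'
#' @param table `tracking_table`.
#' @param epsilon contact tolerance in spatial units (default: median nuclear
#'   radius, `sqrt(median(nuclear_area) / pi)`).
#' @return named logical vector, one entry per cell.
#' @export
classify_peripheral <- function(table, epsilon = NULL) {
  tab <- as.data.frame(table)
  cells <- unique(tab$cell_id)
  if (!length(cells)) return(setNames(logical(0), character(0)))
  epsilon <- epsilon %||% sqrt(median(tab$nuclear_area, na.rm = TRUE) / pi)
  res <- setNames(rep(FALSE, length(cells)), cells)
  key <- paste(tab$colony_id, tab$frame, sep = "\r")
  for (rws in split(seq_len(nrow(tab)), key)) {
    px <- tab$x[rws]; py <- tab$y[rws]
    ids <- tab$cell_id[rws]
    if (length(rws) <= 3L) {
      res[ids] <- TRUE
      next
    }
    h <- chull(px, py)
    res[ids[h]] <- TRUE
    inner <- setdiff(seq_along(rws), h)
    if (!length(inner)) next
    undecided <- inner[!res[ids[inner]]]
    if (!length(undecided)) next
    hx <- px[h]; hy <- py[h]
    dmin <- dist_to_polygon(px[undecided], py[undecided], hx, hy)
    res[ids[undecided[dmin <= epsilon]]] <- TRUE
  }
  res
}

#' @noRd
dist_to_polygon <- function(px, py, hx, hy) {
  # minimum distance from each point to the closed polygon boundary (hx, hy)
  nseg <- length(hx)
  x2 <- c(hx[-1], hx[1]); y2 <- c(hy[-1], hy[1])
  vapply(seq_along(px), function(i) {
    dx <- x2 - hx; dy <- y2 - hy
    len2 <- dx^2 + dy^2
    t <- ((px[i] - hx) * dx + (py[i] - hy) * dy) / pmax(len2, 1e-12)
    t <- pmin(1, pmax(0, t))
    qx <- hx + t * dx; qy <- hy + t * dy
    sqrt(min((px[i] - qx)^2 + (py[i] - qy)^2))
  }, numeric(1))
}

#' Per-cell nuclear area summaries by condition and generation
#'
#' @param table `tracking_table` with `nuclear_area`.
#' @param records `cycle_records` (for generation / condition labels).
#' @return data.frame `cell_id`, `condition`, `generation`, `mean_area`;
#'   empty strata simply do not appear. A missing/all-NA area column gives an
#'   empty result with a warning.
#' @export
nuclear_area_summary <- function(table, records) {
  tab <- as.data.frame(table)
  if (!"nuclear_area" %in% names(tab) || all(is.na(tab$nuclear_area))) {
    warning("nuclear_area absent; skipping area summary", call. = FALSE)
    return(data.frame(cell_id = character(0), condition = character(0),
                      generation = integer(0), mean_area = numeric(0)))
  }
  mu <- vapply(split(tab$nuclear_area, tab$cell_id), mean, numeric(1),
               na.rm = TRUE)
  m <- match(names(mu), records$cell_id)
  out <- data.frame(cell_id = names(mu),
                    condition = records$condition[m],
                    generation = records$generation[m],
                    mean_area = unname(mu), stringsAsFactors = FALSE)
  out <- out[!is.na(out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}
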