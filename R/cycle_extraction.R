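#' Assign generation numbers from parent links
#'
#' Founders (no parent, i.e. cells already present at video start or first
#' appearing without a recorded parent) are generation 1; every child is its
#' parent's generation + 1.
#'
#' @param parent named character vector `cell_id -> parent_id` (NA for founders),
#'   or a `tracking_table` / `cycle_records` data.frame carrying `cell_id` and
#'   `parent_id` columns.
#' @return named integer vector `cell_id -> generation`.
#' @export
assign_generations <- function(parent) {
  if (is.data.frame(parent)) {
    df <- parent[!duplicated(parent$cell_id), c("cell_id", "parent_id")]
    parent <- setNames(as.character(df$parent_id), df$cell_id)
  }
  check_acyclic_parents(parent)
  gen <- setNames(rep(NA_integer_, length(parent)), names(parent))
  depth <- function(id) {
    if (!is.na(gen[[id]])) return(gen[[id]])
    p <- parent[[id]]
    g <- if (is.na(p) || !p %in% names(parent)) 1L else depth(p) + 1L
    gen[[id]] <<- g
    g
  }
  for (id in names(parent)) depth(id)
  gen
}

#' Detect the G1/S boundary from a cherry trace
#'
#' The boundary is called at the global maximum of the moving-average-smoothed
#' hCdt1-mCherry trace restricted to the open interval (birth, end), provided
#' that maximum is a genuine interior local maximum whose prominence exceeds
#' `prominence` times the smoothed trace range. A monotone or flat trace
#' yields `NA` (boundary not callable: for cells born before the movie the
#' true maximum may predate the first frame). Traces with fewer than 5
#' observations inside the interval return `NA` with `attr(, "reason") ==
#' "too_short"`, distinct from a null call.
#'
#' @param time_h,intensity trace vectors (same length).
#' @param birth_time_h,end_time_h cell lifetime bounds (hours).
#' @param smooth_window moving-average width in frames (odd; default 3).
#' @param prominence minimum peak prominence as a fraction of trace range.
#' @return boundary time in hours, or `NA` with a `reason` attribute in
#'   `"too_short"`, `"flat"`, `"monotone"`, `"low_prominence"`.
#' @export
detect_g1_boundary <- function(time_h, intensity, birth_time_h, end_time_h,
                               smooth_window = 3L, prominence = 0.1) {
  stopifnot(length(time_h) == length(intensity), birth_time_h < end_time_h)
  not_callable <- function(reason) structure(NA_real_, reason = reason)
  sel <- time_h > birth_time_h & time_h < end_time_h & !is.na(intensity)
  tt <- time_h[sel]
  yy <- intensity[sel][order(tt)]
  tt <- sort(tt)
  if (length(tt) < 5L) return(not_callable("too_short"))
  sm <- moving_average(yy, smooth_window)
  rng <- max(sm) - min(sm)
  if (rng <= 0) return(not_callable("flat"))
  i <- which.max(sm)
  if (i == 1L || i == length(sm)) return(not_callable("monotone"))
  if (sm[i] - min(sm) < prominence * rng) return(not_callable("low_prominence"))
  # refine on the raw trace around the smoothed call: smoothing an
  # asymmetric peak (slow post-boundary decay) otherwise shifts the maximum
  # systematically toward the shallow side
  half <- max(1L, smooth_window %/% 2L)
  win <- max(1L, i - half):min(length(yy), i + half)
  cand <- win[yy[win] == max(yy[win])]
  i <- cand[which.min(abs(cand - i))]
  if (i == 1L || i == length(sm)) return(not_callable("monotone"))
  tt[i]
}

#' Extract per-cell cycle records from a tracking table
#'
#' One record per tracked cell. A cell is `complete` when both its birth
#' (appearance as a daughter of a parent with two recorded daughters) and its
#' division (two recorded daughters of its own) were observed; then
#' `CC_L_h = end - birth` and `G1_L_h` comes from [detect_g1_boundary()], with
#' `SG2M_L_h = CC_L_h - G1_L_h`. Division instants are placed at the midpoint
#' between the parent's last frame and the daughters' first frame, so sisters
#' share their birth time exactly and durations live on the frame grid.
#'
#' Cells reaching the last movie frame are `CENSORED_END`; cells disappearing
#' earlier without daughters are `TRACK_LOST`; both contribute
#' `censored_duration_h = end - birth` when their birth was observed. Parents
#' with exactly one recorded child are flagged `track_gap` (fate `TRACK_LOST`)
#' and their child's birth is treated as unobserved. Cells named in
#' `annotations` (the manual-curation channel) get fate `APOPTOSIS`.
#'
#' @param table validated `tracking_table`.
#' @param metadata [dataset_metadata()]; defaults to the table's own metadata.
#' @param annotations optional data.frame (`cell_id`, `fate`) of curated fates;
#'   defaults to the table's `annotations` attribute if present.
#' @param smooth_window,prominence forwarded to [detect_g1_boundary()].
#' @return `cycle_records` data.frame.
#' @export
extract_records <- function(table, metadata = NULL, annotations = NULL,
                            smooth_window = 3L, prominence = 0.1) {
  metadata <- metadata %||% attr(table, "metadata") %||% dataset_metadata()
  annotations <- annotations %||% attr(table, "annotations")
  dt <- metadata$frame_interval_h
  last_movie_frame <- floor(metadata$window_h / dt + 1e-9)
  tab <- as.data.frame(table)
  info <- cell_spans(tab)
  n_children <- table(info$parent_id[!is.na(info$parent_id)])
  nchild <- setNames(rep(0L, nrow(info)), info$cell_id)
  nchild[names(n_children)] <- as.integer(n_children)
  gen <- assign_generations(setNames(info$parent_id, info$cell_id))
  last_fr <- setNames(info$last_frame, info$cell_id)
  apopt_ids <- if (!is.null(annotations) && nrow(annotations)) {
    annotations$cell_id[annotations$fate == "APOPTOSIS"]
  } else character(0)

  idx <- split(seq_len(nrow(tab)), tab$cell_id)
  recs <- lapply(seq_len(nrow(info)), function(i) {
    id <- info$cell_id[i]
    par <- info$parent_id[i]
    divided <- nchild[[id]] == 2L
    track_gap <- nchild[[id]] == 1L
    # birth observed only through a clean (two-daughter) parental division
    birth <- if (!is.na(par) && nchild[[par]] == 2L) {
      (last_fr[[par]] + 0.5) * dt
    } else {
      NA_real_
    }
    end <- if (divided) {
      (info$last_frame[i] + 0.5) * dt
    } else {
      info$last_frame[i] * dt
    }
    fate <- if (divided) {
      "DIVIDED"
    } else if (id %in% apopt_ids) {
      "APOPTOSIS"
    } else if (info$last_frame[i] >= last_movie_frame) {
      "CENSORED_END"
    } else {
      "TRACK_LOST"
    }
    if (track_gap && fate == "CENSORED_END") fate <- "TRACK_LOST"
    complete <- divided && !is.na(birth)
    cc <- if (complete) end - birth else NA_real_
    cens <- if (!complete && !is.na(birth) && fate != "APOPTOSIS") {
      end - birth
    } else {
      NA_real_
    }
    g1 <- NA_real_
    if (!is.na(birth)) {
      rows <- idx[[id]]
      b <- detect_g1_boundary(tab$time_h[rows], tab$cherry[rows],
                              birth, end, smooth_window, prominence)
      if (!is.na(b)) g1 <- b - birth
    }
    sg2m <- if (complete && !is.na(g1)) cc - g1 else NA_real_
    data.frame(cell_id = id, colony_id = info$colony_id[i],
               condition = info$condition[i], parent_id = par,
               generation = gen[[id]], birth_time_h = birth, end_time_h = end,
               fate = fate, CC_L_h = cc, G1_L_h = g1, SG2M_L_h = sg2m,
               censored_duration_h = cens, complete = complete,
               track_gap = track_gap, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$colony_id, out$cell_id), ]
  rownames(out) <- NULL
  class(out) <- c("cycle_records", "data.frame")
  out
}

#' Keep only cells with a fully observed cycle
#'
#' Generation-1 cells are necessarily excluded (their birth precedes the
#' movie), as are end-of-movie and lost cells.
#'
#' @param records `cycle_records`.
#' @return filtered `cycle_records`.
#' @export
filter_complete <- function(records) {
  out <- records[which(records$complete), , drop = FALSE]
  rownames(out) <- NULL
  out
}
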