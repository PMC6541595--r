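#' Dataset metadata for a tracking experiment
#'
#' Frame interval and window defaults correspond to a 45 h movie imaged every
#' 15 minutes.
#'
#' @param frame_interval_h imaging interval in hours (> 0).
#' @param window_h total imaging duration in hours (> 0).
#' @param spatial_units unit label for x/y coordinates ("pixel" or "um").
#' @param conditions condition labels admitted in the `condition` column.
#' @return object of class `dataset_metadata`.
#' @export
dataset_metadata <- function(frame_interval_h = 0.25, window_h = 45,
                             spatial_units = c("pixel", "um"),
                             conditions = CONDITIONS) {
  stopifnot(frame_interval_h > 0, window_h > 0)
  spatial_units <- match.arg(spatial_units)
  structure(list(frame_interval_h = frame_interval_h, window_h = window_h,
                 spatial_units = spatial_units, conditions = conditions),
            class = "dataset_metadata")
}

#' Default column map for tracker exports
#'
#' Maps the internal schema to column names found in the delimited export.
#' The tracker's export layout is configurable (names differ between
#' LineageTracker-style exports); override entries or load a dialect file with
#' [read_column_map()].
#'
#' @return named character vector, names = internal fields, values = file columns.
#' @export
default_column_map <- function() {
  c(cell_id = "cell_id", colony_id = "colony_id", condition = "condition",
    frame = "frame", time_h = "time_h", x = "x", y = "y",
    nuclear_area = "nuclear_area", cherry = "cherry", venus = "venus",
    parent_id = "parent_id")
}

#' Read a column-map dialect file (JSON)
#'
#' An example dialect ships with the package:
#' `system.file("extdata", "columnmap-example.json", package = "fuccitrack")`.
#'
#' @param path JSON file holding a flat object `{internal_field: file_column}`.
#' @return named character vector merged over [default_column_map()].
#' @export
read_column_map <- function(path) {
  m <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  map <- default_column_map()
  unknown <- setdiff(names(m), names(map))
  if (length(unknown)) {
    stop("unknown fields in column map: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  map[names(m)] <- m
  map
}

REQUIRED_FIELDS <- c("cell_id", "colony_id", "condition", "frame", "time_h",
                     "x", "y", "nuclear_area", "cherry", "venus", "parent_id")

#' Read and validate a per-frame tracking table
#'
#' Adapter over tracker-style delimited exports (one row per cell per frame).
#' Row-level violations (negative fluorescence/area, duplicated cell-frame
#' rows, non-finite coordinates) are dropped and reported with their original
#' row numbers in `attr(x, "violations")`, so rows-in equals observations-out
#' plus reported violations. Structural problems (missing columns, a cell that
#' is its own ancestor, more than two daughters per parent) abort with classed
#' errors (`fucci_schema_error`, `fucci_lineage_error`, `fucci_integrity_error`).
#'
#' Parents with exactly one recorded child are retained but flagged in
#' `attr(x, "track_gaps")`; downstream pair analyses exclude them.
#'
#' @param path delimited text file.
#' @param metadata [dataset_metadata()].
#' @param column_map named character vector as from [default_column_map()].
#' @param sep field separator.
#' @return validated `tracking_table` (data.frame) in canonical column order.
#' @export
read_tracking_table <- function(path, metadata = dataset_metadata(),
                                column_map = default_column_map(), sep = ",") {
  stopifnot(file.exists(path))
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  missing <- setdiff(unname(column_map[REQUIRED_FIELDS]), names(raw))
  if (length(missing)) {
    stop(structure(class = c("fucci_schema_error", "error", "condition"),
                   list(message = paste0("missing required column(s): ",
                                         paste(missing, collapse = ", ")),
                        call = NULL)))
  }
  tab <- raw[, unname(column_map[REQUIRED_FIELDS])]
  names(tab) <- REQUIRED_FIELDS
  tab$cell_id <- as.character(tab$cell_id)
  tab$colony_id <- as.character(tab$colony_id)
  tab$condition <- as.character(tab$condition)
  tab$parent_id <- as.character(tab$parent_id)
  tab$parent_id[tab$parent_id %in% c("", "NA")] <- NA_character_
  tab$frame <- as.integer(tab$frame)
  for (f in c("time_h", "x", "y", "nuclear_area", "cherry", "venus")) {
    tab[[f]] <- as.numeric(tab[[f]])
  }
  validate_tracking_table(tab, metadata)
}

#' Validate an in-memory tracking table
#'
#' @param tab data.frame with the canonical fields.
#' @param metadata [dataset_metadata()].
#' @return `tracking_table` with `violations` and `track_gaps` attributes.
#' @export
validate_tracking_table <- function(tab, metadata = dataset_metadata()) {
  stopifnot(all(REQUIRED_FIELDS %in% names(tab)))
  tab <- tab[, REQUIRED_FIELDS]
  n_in <- nrow(tab)
  viol <- data.frame(row = integer(0), rule = character(0),
                     message = character(0), stringsAsFactors = FALSE)
  flag <- function(rows, rule, msg) {
    if (length(rows)) {
      viol <<- rbind(viol, data.frame(row = rows, rule = rule, message = msg,
                                      stringsAsFactors = FALSE))
    }
  }
  bad_cond <- which(!tab$condition %in% metadata$conditions)
  flag(bad_cond, "condition", "condition label not declared in metadata")
  bad_neg <- which(tab$cherry < 0 | tab$venus < 0 | tab$nuclear_area < 0)
  flag(bad_neg, "nonnegative", "negative fluorescence or area")
  bad_coord <- which(!is.finite(tab$x) | !is.finite(tab$y) |
                       !is.finite(tab$time_h) | is.na(tab$frame) |
                       tab$frame < 0L)
  flag(bad_coord, "finite", "non-finite coordinate/time or bad frame")
  dup <- which(duplicated(tab[, c("cell_id", "frame")]))
  flag(dup, "duplicate", "duplicated (cell_id, frame) row")
  bad_time <- which(abs(tab$time_h - tab$frame * metadata$frame_interval_h) >
                      metadata$frame_interval_h / 2 + 1e-9)
  flag(bad_time, "clock", "time_h inconsistent with frame * frame_interval_h")
  drop <- unique(viol$row)
  keep <- if (length(drop)) tab[-drop, , drop = FALSE] else tab
  keep <- keep[order(keep$cell_id, keep$frame), , drop = FALSE]
  rownames(keep) <- NULL

  # structural checks on the surviving rows
  info <- cell_spans(keep)
  par <- setNames(info$parent_id, info$cell_id)
  check_acyclic_parents(par)
  kids <- table(par[!is.na(par)])
  if (any(kids > 2L)) {
    bad <- names(kids)[kids > 2L]
    stop(structure(class = c("fucci_integrity_error", "error", "condition"),
                   list(message = paste0("parent(s) with more than 2 children: ",
                                         paste(bad, collapse = ", ")),
                        call = NULL)))
  }
  known <- is.na(info$parent_id) | info$parent_id %in% info$cell_id
  if (!all(known)) {
    stop(structure(class = c("fucci_lineage_error", "error", "condition"),
                   list(message = paste0("parent_id not present as a cell: ",
                                         paste(info$cell_id[!known], collapse = ", ")),
                        call = NULL)))
  }
  last_fr <- setNames(info$last_frame, info$cell_id)
  has_par <- !is.na(info$parent_id)
  overlap <- has_par & info$first_frame <= last_fr[info$parent_id]
  overlap[is.na(overlap)] <- FALSE
  if (any(overlap)) {
    stop(structure(class = c("fucci_lineage_error", "error", "condition"),
                   list(message = paste0(
                     "parent has frames at/after child's first frame: ",
                     paste(info$cell_id[overlap], collapse = ", ")), call = NULL)))
  }
  gaps <- names(kids)[kids == 1L]
  structure(keep, class = c("tracking_table", "data.frame"),
            violations = viol, track_gaps = gaps, metadata = metadata)
}

#' @noRd
cell_spans <- function(tab) {
  sp <- split(seq_len(nrow(tab)), tab$cell_id)
  out <- data.frame(
    cell_id = names(sp),
    first_frame = vapply(sp, function(i) min(tab$frame[i]), integer(1)),
    last_frame = vapply(sp, function(i) max(tab$frame[i]), integer(1)),
    parent_id = vapply(sp, function(i) tab$parent_id[i[1L]], character(1)),
    colony_id = vapply(sp, function(i) tab$colony_id[i[1L]], character(1)),
    condition = vapply(sp, function(i) tab$condition[i[1L]], character(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @noRd
check_acyclic_parents <- function(par) {
  # par: named vector cell -> parent (NA for founders)
  for (start in names(par)) {
    seen <- character(0)
    cur <- start
    while (!is.na(par[[cur]] %||% NA_character_)) {
      if (cur %in% seen) {
        stop(structure(class = c("fucci_lineage_error", "error", "condition"),
                       list(message = paste0("cycle in parent links at ", cur),
                            call = NULL)))
      }
      seen <- c(seen, cur)
      nxt <- par[[cur]]
      if (!nxt %in% names(par)) break
      cur <- nxt
    }
  }
  invisible(TRUE)
}

DB_COLUMNS <- c("cell_id", "colony_id", "condition", "parent_id", "generation",
                "birth_time_h", "end_time_h", "fate", "CC_L_h", "G1_L_h",
                "SG2M_L_h", "censored_duration_h", "complete", "track_gap")

#' Write the curated per-cell database
#'
#' One row per cell, stable column order, plain CSV; the write/read round trip
#' is lossless and a second write is byte-identical to the first.
#'
#' @param records `cycle_records` data.frame (see [extract_records()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_database <- function(records, path) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(DB_COLUMNS, names(records))
  for (m in miss) records[[m]] <- NA
  out <- records[, DB_COLUMNS]
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Read a curated per-cell database written by [write_database()]
#'
#' @param path CSV path.
#' @return `cycle_records` data.frame.
#' @export
read_database <- function(path) {
  stopifnot(file.exists(path))
  rec <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(cell_id = "character", colony_id = "character",
                                 condition = "character", parent_id = "character",
                                 fate = "character"))
  miss <- setdiff(DB_COLUMNS, names(rec))
  if (length(miss)) {
    stop(structure(class = c("fucci_schema_error", "error", "condition"),
                   list(message = paste0("database missing column(s): ",
                                         paste(miss, collapse = ", ")),
                        call = NULL)))
  }
  rec <- rec[, DB_COLUMNS]
  class(rec) <- c("cycle_records", "data.frame")
  rec
}

#' Write a tracking table to CSV
#'
#' @param tab `tracking_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracking_table <- function(tab, path) {
  write.csv(as.data.frame(tab)[, REQUIRED_FIELDS], path,
            row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}
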