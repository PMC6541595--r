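#' Build a lineage forest from cycle records
#'
#' @param records `cycle_records` (or any data.frame with `cell_id`,
#'   `parent_id`, `colony_id`).
#' @return object of class `lineage_forest`: parent map, children map, colony
#'   partition and root ids.
#' @export
build_forest <- function(records) {
  df <- records[!duplicated(records$cell_id),
                c("cell_id", "parent_id", "colony_id")]
  parent <- setNames(as.character(df$parent_id), df$cell_id)
  # parents referencing unknown cells are treated as founders of their colony
  parent[!is.na(parent) & !parent %in% names(parent)] <- NA_character_
  check_acyclic_parents(parent)
  colony <- setNames(as.character(df$colony_id), df$cell_id)
  has_par <- !is.na(parent)
  if (any(has_par)) {
    bad <- names(parent)[has_par][colony[parent[has_par]] !=
                                    colony[names(parent)[has_par]]]
    if (length(bad)) {
      stop(structure(class = c("fucci_lineage_error", "error", "condition"),
                     list(message = paste0("cross-colony parentage: ",
                                           paste(bad, collapse = ", ")),
                          call = NULL)))
    }
  }
  children <- split(names(parent)[has_par], parent[has_par])
  over <- names(children)[lengths(children) > 2L]
  if (length(over)) {
    stop(structure(class = c("fucci_integrity_error", "error", "condition"),
                   list(message = paste0("parent(s) with more than 2 children: ",
                                         paste(over, collapse = ", ")),
                        call = NULL)))
  }
  structure(list(cells = names(parent), parent = parent, children = children,
                 colony = colony, roots = names(parent)[!has_par]),
            class = "lineage_forest")
}

#' @export
print.lineage_forest <- function(x, ...) {
  cat("<lineage_forest> ", length(x$cells), " cells, ",
      length(x$roots), " roots, ", length(unique(x$colony)), " colonies\n",
      sep = "")
  invisible(x)
}

#' Enumerate relative pairs (sisters, mother-daughter, cousins)
#'
#' Sister pairs: one pair per division with both daughters eligible.
#' Mother-daughter: one pair per eligible mother, pairing her with one
#' eligible daughter chosen uniformly at random under a dedicated seeded
#' stream (reproducing the "one daughter chosen at random" analysis).
#' Cousins: granddaughter pairs through *different* daughters of the shared
#' grandmother; all cross combinations by default, or one sampled pair per
#' grandmother (`cousin_mode = "one"`).
#'
#' Cells flagged `track_gap` (or children of a gap) never enter pairs.
#'
#' @param forest `lineage_forest`.
#' @param records `cycle_records` used for completeness, generation and values.
#' @param relation `"SISTER"`, `"MOTHER_DAUGHTER"` or `"COUSIN"`.
#' @param require_complete restrict both members to complete cells.
#' @param seed integer seed for the random-daughter / cousin sampling stream.
#' @param cousin_mode `"all"` cross combinations or `"one"` per grandmother.
#' @return data.frame of class `relative_pairs` with columns `relation`,
#'   `cell_a`, `cell_b`, `colony_id`, `generation` (stratum = generation of
#'   the younger member) and `condition`.
#' @export
enumerate_pairs <- function(forest, records,
                            relation = c("SISTER", "MOTHER_DAUGHTER", "COUSIN"),
                            require_complete = TRUE, seed = 1L,
                            cousin_mode = c("all", "one")) {
  relation <- match.arg(relation)
  cousin_mode <- match.arg(cousin_mode)
  stopifnot(inherits(forest, "lineage_forest"))
  rec <- records[match(forest$cells, records$cell_id), ]
  ok <- setNames(!is.na(rec$cell_id) &
                   (!require_complete | rec$complete) &
                   !rec$track_gap, forest$cells)
  gen <- setNames(rec$generation, forest$cells)
  cond <- setNames(rec$condition, forest$cells)
  gap_parent <- setNames(vapply(forest$cells, function(id) {
    p <- forest$parent[[id]]
    !is.na(p) && length(forest$children[[p]]) == 1L
  }, logical(1)), forest$cells)
  ok <- ok & !gap_parent

  pair_row <- function(a, b) {
    data.frame(relation = relation, cell_a = a, cell_b = b,
               colony_id = unname(forest$colony[[a]]),
               generation = unname(max(gen[[a]], gen[[b]])),
               condition = unname(cond[[a]]), stringsAsFactors = FALSE)
  }
  out <- list()
  if (relation == "SISTER") {
    for (p in names(forest$children)) {
      ch <- forest$children[[p]]
      if (length(ch) == 2L && ok[[ch[1]]] && ok[[ch[2]]]) {
        out[[length(out) + 1L]] <- pair_row(ch[1], ch[2])
      }
    }
  } else if (relation == "MOTHER_DAUGHTER") {
    set.seed(derive_seed(seed, "md-daughter-choice"))
    mothers <- sort(names(forest$children))
    for (p in mothers) {
      if (!ok[[p]]) next
      ch <- forest$children[[p]]
      ch <- ch[vapply(ch, function(c) ok[[c]], logical(1))]
      if (!length(ch)) next
      pick <- if (length(ch) == 1L) ch else ch[sample.int(length(ch), 1L)]
      out[[length(out) + 1L]] <- pair_row(p, pick)
    }
  } else {
    set.seed(derive_seed(seed, "cousin-sampling"))
    grannies <- sort(names(forest$children))
    for (g in grannies) {
      ds <- forest$children[[g]]
      if (length(ds) != 2L) next
      a_kids <- forest$children[[ds[1]]] %||% character(0)
      b_kids <- forest$children[[ds[2]]] %||% character(0)
      a_kids <- a_kids[vapply(a_kids, function(c) ok[[c]], logical(1))]
      b_kids <- b_kids[vapply(b_kids, function(c) ok[[c]], logical(1))]
      if (!length(a_kids) || !length(b_kids)) next
      combos <- expand.grid(a = a_kids, b = b_kids, stringsAsFactors = FALSE)
      if (cousin_mode == "one") {
        combos <- combos[sample.int(nrow(combos), 1L), , drop = FALSE]
      }
      for (r in seq_len(nrow(combos))) {
        out[[length(out) + 1L]] <- pair_row(combos$a[r], combos$b[r])
      }
    }
  }
  res <- if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(relation = character(0), cell_a = character(0),
               cell_b = character(0), colony_id = character(0),
               generation = integer(0), condition = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  class(res) <- c("relative_pairs", "data.frame")
  res
}

#' Attach a cycle variable's values to a pair table
#'
#' @param pairs `relative_pairs`.
#' @param records `cycle_records`.
#' @param variable one of `"CC_L"`, `"G1_L"`, `"SG2M_L"` (hours columns).
#' @return pairs with `value_a`, `value_b` columns; pairs with a missing value
#'   on either side are dropped.
#' @export
pair_values <- function(pairs, records, variable = c("CC_L", "G1_L", "SG2M_L")) {
  variable <- match.arg(variable)
  col <- paste0(variable, "_h")
  v <- setNames(records[[col]], records$cell_id)
  pairs$value_a <- unname(v[pairs$cell_a])
  pairs$value_b <- unname(v[pairs$cell_b])
  out <- pairs[complete.cases(pairs[, c("value_a", "value_b")]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "variable") <- variable
  out
}
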