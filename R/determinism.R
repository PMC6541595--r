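#' Embed a cycle variable along ancestor chains
#'
#' Each point is the variable measured along a maternal chain of `m` complete
#' cells ending at one cell: `m = 1` the cell alone, `m = 2` (mother,
#' daughter), `m = 3` (grandmother, mother, daughter). Coordinates are
#' z-scored column-wise. Chains within a colony may share ancestors; the
#' overlap count is recorded.
#'
#' @param records `cycle_records`.
#' @param forest `lineage_forest`.
#' @param variable cycle variable.
#' @param m embedding dimension, 1-3.
#' @return object of class `lineage_embedding`: standardized `points` matrix
#'   (rows = chains, oldest ancestor first), `raw` matrix and chain metadata.
#' @export
embed_lineage <- function(records, forest, variable = c("G1_L", "SG2M_L", "CC_L"),
                          m = 2L) {
  variable <- match.arg(variable)
  if (!m %in% 1:3) stop("embedding dimension m must be 1, 2 or 3", call. = FALSE)
  col <- paste0(variable, "_h")
  val <- setNames(records[[col]], records$cell_id)
  comp <- setNames(records$complete & !is.na(records[[col]]), records$cell_id)
  rows <- list(); meta <- list(); chains <- list()
  for (id in forest$cells) {
    if (!isTRUE(comp[[id]])) next
    chain <- id
    cur <- id
    ok <- TRUE
    while (length(chain) < m) {
      par <- forest$parent[[cur]]
      if (is.na(par) || !isTRUE(comp[[par]])) { ok <- FALSE; break }
      chain <- c(par, chain)
      cur <- par
    }
    if (!ok) next
    rows[[length(rows) + 1L]] <- unname(val[chain])
    chains[[length(chains) + 1L]] <- chain
    meta[[length(meta) + 1L]] <- data.frame(
      cell_id = id, colony_id = unname(forest$colony[[id]]),
      stringsAsFactors = FALSE)
  }
  raw <- do.call(rbind, rows)
  if (is.null(raw)) raw <- matrix(numeric(0), ncol = m)
  pts <- scale(raw)
  pts[is.nan(pts)] <- 0
  md <- if (length(meta)) do.call(rbind, meta) else
    data.frame(cell_id = character(0), colony_id = character(0))
  chain_ids <- if (length(chains)) do.call(rbind, chains) else
    matrix(character(0), ncol = m)
  structure(list(points = pts, raw = raw, meta = md, m = m,
                 variable = variable, chain_ids = chain_ids,
                 n_overlap = sum(duplicated(as.vector(chain_ids)))),
            class = "lineage_embedding")
}

#' Grassberger-Procaccia correlation integral
#'
#' `C(r) = 2 / (N (N - 1)) * #\{pairs i < j with ||x_i - x_j|| < r\}`,
#' exact pairwise counts with the Euclidean norm.
#'
#' @param points numeric matrix (rows = points).
#' @param radii positive radii.
#' @param min_points floor on the number of points.
#' @return numeric vector `C(r)`, named by radius.
#' @export
correlation_integral <- function(points, radii, min_points = 30L) {
  points <- as.matrix(points)
  if (nrow(points) < min_points) {
    stop("need at least ", min_points, " points, got ", nrow(points),
         call. = FALSE)
  }
  stopifnot(all(radii > 0))
  d <- as.numeric(dist(points))
  setNames(vapply(radii, function(r) mean(d < r), numeric(1)),
           format(radii, digits = 6))
}

#' Log-spaced radii spanning a point cloud
#'
#' @param points matrix.
#' @param n number of radii.
#' @return radii from the 1% distance quantile to just past the diameter.
#' @export
default_radii <- function(points, n = 30L) {
  d <- as.numeric(dist(as.matrix(points)))
  lo <- max(quantile(d, 0.005), max(d) * 1e-4)
  exp(seq(log(lo), log(max(d) * 1.05), length.out = n))
}

#' Correlation-dimension estimate (scaling exponent)
#'
#' Least-squares slope of `log C` versus `log r`. By default the fit window
#' is the usual scaling range `0.05 <= C <= 0.5`; pass `fit_range = c(rmin,
#' rmax)` to fit over an explicit radius interval instead.
#'
#' @param C correlation integral values.
#' @param radii matching radii.
#' @param fit_range optional radius interval.
#' @param c_window C interval used when `fit_range` is `NULL`.
#' @return slope `nu`.
#' @export
gp_dimension <- function(C, radii, fit_range = NULL, c_window = c(0.05, 0.5)) {
  stopifnot(length(C) == length(radii))
  sel <- if (is.null(fit_range)) {
    C >= c_window[1] & C <= c_window[2] & C > 0
  } else {
    radii >= fit_range[1] & radii <= fit_range[2] & C > 0
  }
  if (sum(sel) < 4L) {
    stop("degenerate fit range: fewer than 4 usable radii", call. = FALSE)
  }
  lc <- log(C[sel]); lr <- log(radii[sel])
  if (sd(lc) == 0) return(0)
  unname(coef(lm(lc ~ lr))[2])
}

#' @noRd
gp_nu_points <- function(pts, n_radii = 30L, c_window = c(0.05, 0.5)) {
  # single-dist fast path used inside the surrogate loop
  d <- as.numeric(dist(pts))
  lo <- max(quantile(d, 0.005), max(d) * 1e-4)
  radii <- exp(seq(log(lo), log(max(d) * 1.05), length.out = n_radii))
  C <- vapply(radii, function(r) mean(d < r), numeric(1))
  gp_dimension(C, radii, c_window = c_window)
}

#' Shuffle-surrogate determinism test on lineage embeddings
#'
#' The observed scaling exponent is compared with exponents of surrogate
#' embeddings in which the variable is shuffled across cells within
#' (colony x generation) strata: lineage linkage is destroyed, marginals and
#' the generation/colony structure are preserved. Verdict is
#' `"deterministic"` iff the data exponent falls below the `q`-quantile
#' (default 5%) of the surrogate exponents.
#'
#' @param records `cycle_records`.
#' @param forest `lineage_forest`.
#' @param variable cycle variable.
#' @param m embedding dimension (2 or 3 are informative).
#' @param n_surrogates surrogate count.
#' @param seed integer seed (dedicated stream).
#' @param q verdict quantile.
#' @param radii optional explicit radii (default [default_radii()] of the data).
#' @param min_points floor forwarded to [correlation_integral()].
#' @return object of class `gp_result`.
#' @export
surrogate_test <- function(records, forest, variable = c("G1_L", "SG2M_L", "CC_L"),
                           m = 3L, n_surrogates = 100L, seed = 1L, q = 0.05,
                           radii = NULL, min_points = 30L) {
  variable <- match.arg(variable)
  emb <- embed_lineage(records, forest, variable, m)
  if (nrow(emb$points) < min_points) {
    stop("too few embedded chains (", nrow(emb$points), ") for m = ", m,
         call. = FALSE)
  }
  radii <- radii %||% default_radii(emb$points)
  C <- correlation_integral(emb$points, radii, min_points)
  nu <- gp_dimension(C, radii)

  # surrogates reuse the chain structure: only the value map is permuted
  col <- paste0(variable, "_h")
  ok <- records$complete & !is.na(records[[col]])
  ids <- records$cell_id[ok]
  vals <- records[[col]][ok]
  strata <- paste(records$colony_id[ok], records$generation[ok])
  strata_ix <- split(seq_along(vals), strata)
  set.seed(derive_seed(seed, "gp-surrogates"))
  nu_s <- vapply(seq_len(n_surrogates), function(i) {
    v2 <- vals
    for (ix in strata_ix) v2[ix] <- vals[ix][sample.int(length(ix))]
    vmap <- setNames(v2, ids)
    raw <- matrix(vmap[emb$chain_ids], ncol = m)
    pts <- scale(raw)
    pts[is.nan(pts)] <- 0
    gp_nu_points(pts)
  }, numeric(1))
  thr <- unname(quantile(nu_s, q, type = 7))
  structure(list(variable = variable, m = m, nu_data = nu,
                 nu_surrogates = nu_s, threshold = thr, q = q,
                 verdict = if (nu < thr) "deterministic" else "stochastic",
                 C = C, radii = radii, n_points = nrow(emb$points),
                 seed = seed),
            class = "gp_result")
}

#' @export
print.gp_result <- function(x, ...) {
  cat("<gp_result> ", x$variable, " m = ", x$m, ": nu = ",
      format(round(x$nu_data, 3)), " vs surrogate q", 100 * x$q, " = ",
      format(round(x$threshold, 3)), " -> ", x$verdict,
      " (", x$n_points, " chains)\n", sep = "")
  invisible(x)
}
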