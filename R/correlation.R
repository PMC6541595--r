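#' Spearman rank correlation
#'
#' Average-rank tie handling via [stats::cor()]. Constant input is undefined
#' and returns `NA` with a warning rather than a number.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`, or `NA` for degenerate input.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input: Spearman correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Stratified centering of pair values
#'
#' Removes the between-stratum drift (generation trends, colony/condition
#' offsets) that inflates pooled correlations: within each stratum the pooled
#' values of both pair members are replaced by normalized average ranks
#' (`rank / (n + 1)`, method `"rank"`, default) or by z-scores around the
#' stratum mean (method `"mean"`). With a single stratum the rank transform
#' leaves Spearman unchanged. Strata with fewer than 2 pairs are dropped with
#' a warning.
#'
#' @param pairs `relative_pairs` with `value_a`, `value_b` and `generation`.
#' @param method `"rank"` or `"mean"`.
#' @param stratum optional explicit stratum labels (default: generation).
#' @return pairs with `centered_a`, `centered_b` columns added.
#' @export
stratified_center <- function(pairs, method = c("rank", "mean"),
                              stratum = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("value_a", "value_b") %in% names(pairs)))
  st <- stratum %||% paste(pairs$condition, pairs$generation)
  keep <- st %in% names(which(table(st) >= 2L))
  if (!all(keep)) {
    warning(sum(!keep), " pair(s) in strata of size < 2 dropped", call. = FALSE)
    pairs <- pairs[keep, , drop = FALSE]
    st <- st[keep]
  }
  n <- nrow(pairs)
  pooled <- c(pairs$value_a, pairs$value_b)
  gs <- rep(st, 2L)
  cen <- if (method == "rank") {
    ave(pooled, gs, FUN = function(v) rank(v) / (length(v) + 1))
  } else {
    ave(pooled, gs, FUN = function(v) {
      s <- sd(v)
      if (is.na(s) || s == 0) s <- 1
      (v - mean(v)) / s
    })
  }
  pairs$centered_a <- cen[seq_len(n)]
  pairs$centered_b <- cen[n + seq_len(n)]
  rownames(pairs) <- NULL
  pairs
}

#' @noRd
pairs_symmetric <- function(pairs) {
  rel <- unique(pairs$relation)
  length(rel) == 1L && rel %in% c("SISTER", "COUSIN")
}

#' Centered Spearman coefficient of a pair set
#'
#' For unordered relations (sisters, cousins) each pair enters in both orders
#' so the estimate is invariant to (a, b) labelling; mother-daughter pairs are
#' ordered and enter once.
#'
#' @param pairs `relative_pairs` with values.
#' @param method centering method, see [stratified_center()].
#' @param symmetric override the relation-based symmetry choice.
#' @return Spearman rho, `NA` when degenerate.
#' @export
pair_spearman <- function(pairs, method = "rank", symmetric = NULL) {
  if (nrow(pairs) < 3L) return(NA_real_)
  symmetric <- symmetric %||% pairs_symmetric(pairs)
  cen <- suppressWarnings(stratified_center(pairs, method))
  if (nrow(cen) < 3L) return(NA_real_)
  a <- cen$centered_a; b <- cen$centered_b
  if (symmetric) { x <- c(a, b); y <- c(b, a) } else { x <- a; y <- b }
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Colony/generation-stratified bootstrap Spearman correlation
#'
#' Two-level resampling per replicate: colonies with replacement, then pairs
#' with replacement within each resampled colony; the coefficient per
#' replicate is the generation-stratified centered Spearman of the replicate
#' sample. The point estimate is the centered Spearman of the original pairs,
#' the CI is the 95% percentile interval, and the p-value tests rho = 0 as
#' `2 * min(P(rho* <= 0), P(rho* >= 0))` with a +1 continuity floor.
#'
#' @param pairs `relative_pairs` with `value_a`/`value_b` (see [pair_values()]).
#' @param n_boot bootstrap replicates (>= 1000 for reported results).
#' @param seed integer seed (dedicated stream).
#' @param method centering method.
#' @return object of class `bootstrap_corr`.
#' @export
bootstrap_corr <- function(pairs, n_boot = 2000L, seed = 1L,
                           method = c("rank", "mean")) {
  method <- match.arg(method)
  stopifnot(nrow(pairs) >= 10L)
  colonies <- unique(pairs$colony_id)
  if (length(colonies) < 2L) {
    stop("need at least 2 colonies to resample colonies", call. = FALSE)
  }
  rho_hat <- pair_spearman(pairs, method)
  by_col <- split(seq_len(nrow(pairs)), pairs$colony_id)
  set.seed(derive_seed(seed, "bootstrap-corr"))
  reps <- vapply(seq_len(n_boot), function(i) {
    cs <- sample(colonies, replace = TRUE)
    idx <- unlist(lapply(cs, function(cl) {
      ix <- by_col[[cl]]
      ix[sample.int(length(ix), replace = TRUE)]
    }), use.names = FALSE)
    pair_spearman(pairs[idx, , drop = FALSE], method)
  }, numeric(1))
  reps_ok <- reps[!is.na(reps)]
  ci <- unname(quantile(reps_ok, c(0.025, 0.975), type = 7))
  B <- length(reps_ok)
  p <- min(1, 2 * (min(sum(reps_ok <= 0), sum(reps_ok >= 0)) + 1) / (B + 1))
  structure(list(relation = unique(pairs$relation),
                 variable = attr(pairs, "variable") %||% NA_character_,
                 rho_hat = rho_hat, ci_low = ci[1], ci_high = ci[2],
                 p_value = p, n_pairs = nrow(pairs), n_boot = n_boot,
                 n_boot_ok = B, seed = seed, method = method,
                 replicates = reps),
            class = "bootstrap_corr")
}

#' @export
print.bootstrap_corr <- function(x, ...) {
  cat("<bootstrap_corr> ", paste(x$relation, collapse = "/"),
      if (!is.na(x$variable)) paste0(" ", x$variable), ": rho = ",
      format(round(x$rho_hat, 3)), " [", format(round(x$ci_low, 3)), ", ",
      format(round(x$ci_high, 3)), "], p = ", format(signif(x$p_value, 3)),
      " (", x$n_pairs, " pairs, ", x$n_boot, " reps)\n", sep = "")
  invisible(x)
}

#' Inheritance-inequality test: rho_cc versus rho_md^2 * rho_ss
#'
#' Under simple one-step inheritance the cousin correlation should equal
#' `rho_md^2 * rho_ss`; a positive excess `delta = rho_cc - rho_md^2 * rho_ss`
#' points to determinants inherited across more than one generation. The
#' three coefficients are estimated on sister, mother-daughter and cousin
#' pairs with *joint* bootstrap replicates (one shared colony resample per
#' replicate), and `delta` gets a percentile CI.
#'
#' @param records `cycle_records`.
#' @param forest `lineage_forest` (defaults to `build_forest(records)`).
#' @param variable cycle variable.
#' @param n_boot replicates.
#' @param seed integer seed (drives daughter choice and the bootstrap).
#' @param method centering method.
#' @return object of class `inheritance_test`: point estimates, `delta`, its
#'   CI and the verdict (`"exceeds simple inheritance"` iff the CI lower
#'   bound is > 0).
#' @export
inheritance_inequality <- function(records, forest = NULL,
                                   variable = c("CC_L", "G1_L", "SG2M_L"),
                                   n_boot = 1000L, seed = 1L,
                                   method = c("rank", "mean")) {
  variable <- match.arg(variable)
  method <- match.arg(method)
  forest <- forest %||% build_forest(records)
  ps <- pair_values(enumerate_pairs(forest, records, "SISTER"),
                    records, variable)
  pm <- pair_values(enumerate_pairs(forest, records, "MOTHER_DAUGHTER",
                                    seed = seed), records, variable)
  pc <- pair_values(enumerate_pairs(forest, records, "COUSIN"),
                    records, variable)
  stopifnot(nrow(ps) >= 10L, nrow(pm) >= 10L, nrow(pc) >= 10L)
  colonies <- unique(c(ps$colony_id, pm$colony_id, pc$colony_id))
  if (length(colonies) < 2L) {
    stop("need at least 2 colonies to resample colonies", call. = FALSE)
  }
  idx_s <- split(seq_len(nrow(ps)), ps$colony_id)
  idx_m <- split(seq_len(nrow(pm)), pm$colony_id)
  idx_c <- split(seq_len(nrow(pc)), pc$colony_id)
  draw <- function(pairs, by_col, cs) {
    idx <- unlist(lapply(cs, function(cl) {
      ix <- by_col[[cl]]
      if (is.null(ix)) return(integer(0))
      ix[sample.int(length(ix), replace = TRUE)]
    }), use.names = FALSE)
    pairs[idx, , drop = FALSE]
  }
  rho_ss <- pair_spearman(ps, method)
  rho_md <- pair_spearman(pm, method)
  rho_cc <- pair_spearman(pc, method)
  delta <- rho_cc - rho_md^2 * rho_ss
  set.seed(derive_seed(seed, "inheritance-inequality"))
  reps <- t(vapply(seq_len(n_boot), function(i) {
    cs <- sample(colonies, replace = TRUE)
    s <- pair_spearman(draw(ps, idx_s, cs), method)
    m <- pair_spearman(draw(pm, idx_m, cs), method)
    cc <- pair_spearman(draw(pc, idx_c, cs), method)
    c(s, m, cc, cc - m^2 * s)
  }, numeric(4)))
  d_ok <- reps[, 4][!is.na(reps[, 4])]
  ci <- unname(quantile(d_ok, c(0.025, 0.975), type = 7))
  structure(list(variable = variable, rho_ss = rho_ss, rho_md = rho_md,
                 rho_cc = rho_cc, delta = delta,
                 ci_low = ci[1], ci_high = ci[2],
                 verdict = if (ci[1] > 0) "exceeds simple inheritance" else
                   "consistent with simple inheritance",
                 n_boot = n_boot, seed = seed, replicates = reps),
            class = "inheritance_test")
}

#' @export
print.inheritance_test <- function(x, ...) {
  cat("<inheritance_test> ", x$variable, ": rho_ss = ",
      format(round(x$rho_ss, 3)), ", rho_md = ", format(round(x$rho_md, 3)),
      ", rho_cc = ", format(round(x$rho_cc, 3)), "\n  delta = ",
      format(round(x$delta, 3)), " [", format(round(x$ci_low, 3)), ", ",
      format(round(x$ci_high, 3)), "] -> ", x$verdict, "\n", sep = "")
  invisible(x)
}
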