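#' Kaplan-Meier (product-limit) estimate of a duration distribution
#'
#' "Survival" here means not yet having completed the cycle: events are
#' observed divisions, censored entries (end-of-movie or lost tracks) reduce
#' the risk set without contributing events. `S(t) = prod over event times
#' t_i <= t of (1 - d_i / n_i)`. The median uses the convention
#' `inf{t : S(t) <= 0.5}` (`NA` when S never reaches 0.5). Pointwise 95%
#' confidence bands use the Greenwood variance on the log(-log S) scale and
#' give a median CI by inversion.
#'
#' @param durations positive durations (hours).
#' @param observed logical, `TRUE` = event (division) at that duration.
#' @return object of class `km_curve`: data.frame of `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, `lower`, `upper` plus `median` and
#'   `median_ci` attributes.
#' @export
km_estimate <- function(durations, observed) {
  stopifnot(length(durations) == length(observed), length(durations) > 0,
            all(durations > 0), is.logical(observed))
  tt <- sort(unique(durations))
  n_risk <- vapply(tt, function(t) sum(durations >= t), numeric(1))
  n_event <- vapply(tt, function(t) sum(durations == t & observed), numeric(1))
  n_cens <- vapply(tt, function(t) sum(durations == t & !observed), numeric(1))
  S <- cumprod(1 - n_event / n_risk)
  # Greenwood on the complementary log-log scale
  gw <- cumsum(ifelse(n_risk > n_event,
                      n_event / (n_risk * (n_risk - n_event)), 0))
  z <- stats::qnorm(0.975)
  lower <- upper <- rep(NA_real_, length(S))
  pos <- S > 0 & S < 1
  theta <- exp(z * sqrt(gw[pos]) / log(S[pos]))
  lower[pos] <- S[pos]^(1 / theta)
  upper[pos] <- S[pos]^theta
  lower[S == 0] <- 0; upper[S == 0] <- 0
  curve <- data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                      n_censor = n_cens, survival = S,
                      lower = lower, upper = upper)
  med_at <- function(surv) {
    i <- which(surv <= 0.5 + 1e-12)
    if (length(i)) tt[min(i)] else NA_real_
  }
  med <- med_at(S)
  # median CI by band inversion: the lower band crosses 0.5 first
  med_ci <- c(lower = med_at(ifelse(is.na(lower), S, lower)),
              upper = med_at(ifelse(is.na(upper), 1, upper)))
  structure(list(curve = curve, median = med, median_ci = med_ci,
                 n = length(durations), n_events = sum(observed)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> n = ", x$n, " (", x$n_events, " events), median = ",
      ifelse(is.na(x$median), "not reached", format(x$median)),
      " [", format(x$median_ci[1]), ", ", format(x$median_ci[2]), "]\n",
      sep = "")
  invisible(x)
}

#' Durations and event indicators for a cycle variable
#'
#' Builds the (duration, observed) input of [km_estimate()] from records:
#' complete cells are events; censored cells contribute their observed
#' elapsed time. Generation-1 cells (unknown birth, left-truncated) never
#' enter; apoptotic cells are excluded by default, matching their treatment
#' as a quality note rather than events.
#'
#' For `G1_L` the "event" is reaching the cherry maximum, so censored cells
#' with a called boundary still count as G1 events; complete cells whose
#' boundary could not be called are excluded (their G1 ended at an unknown
#' earlier time, so right-censoring them at CC-L would be wrong).
#'
#' @param records `cycle_records`.
#' @param variable `"CC_L"`, `"G1_L"` or `"SG2M_L"`.
#' @param include_apoptosis treat apoptotic cells as censored instead of
#'   excluding them.
#' @return data.frame with `duration`, `observed`, `generation`, `condition`.
#' @export
km_input <- function(records, variable = c("CC_L", "G1_L", "SG2M_L"),
                     include_apoptosis = FALSE) {
  variable <- match.arg(variable)
  r <- records[!is.na(records$birth_time_h), , drop = FALSE]
  if (!include_apoptosis) r <- r[r$fate != "APOPTOSIS", , drop = FALSE]
  elapsed <- ifelse(r$complete, r$CC_L_h, r$censored_duration_h)
  if (variable == "CC_L") {
    dur <- elapsed
    obs <- r$complete
  } else if (variable == "G1_L") {
    has_b <- !is.na(r$G1_L_h)
    dur <- ifelse(has_b, r$G1_L_h, elapsed)
    obs <- has_b
    drop <- r$complete & !has_b   # interval-censored G1, see docs
    dur[drop] <- NA
  } else {
    has_b <- !is.na(r$G1_L_h)
    dur <- ifelse(r$complete & has_b, r$SG2M_L_h,
                  ifelse(has_b, elapsed - r$G1_L_h, NA))
    obs <- r$complete & has_b
  }
  out <- data.frame(duration = dur, observed = obs,
                    generation = r$generation, condition = r$condition,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$duration) & out$duration > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-generation Kaplan-Meier medians for one condition
#'
#' @param records `cycle_records` (complete and censored cells).
#' @param variable cycle variable.
#' @param condition condition label.
#' @param min_n strata with fewer cells are omitted with a warning.
#' @param include_apoptosis forwarded to [km_input()].
#' @return data.frame `generation`, `n`, `n_events`, `median`, `ci_low`,
#'   `ci_high`; the `curves` attribute holds the per-generation `km_curve`s.
#' @export
km_median_by_generation <- function(records, variable = c("CC_L", "G1_L", "SG2M_L"),
                                    condition = "GROUND_STATE", min_n = 10L,
                                    include_apoptosis = FALSE) {
  variable <- match.arg(variable)
  assert_condition(condition)
  inp <- km_input(records, variable, include_apoptosis)
  inp <- inp[inp$condition == condition, , drop = FALSE]
  gens <- sort(unique(inp$generation))
  rows <- list(); curves <- list()
  for (g in gens) {
    sub <- inp[inp$generation == g, ]
    if (nrow(sub) < min_n) {
      warning("generation ", g, " has ", nrow(sub), " < ", min_n,
              " cells; omitted", call. = FALSE)
      next
    }
    km <- km_estimate(sub$duration, sub$observed)
    curves[[as.character(g)]] <- km
    rows[[length(rows) + 1L]] <- data.frame(
      generation = g, n = km$n, n_events = km$n_events, median = km$median,
      ci_low = unname(km$median_ci[1]), ci_high = unname(km$median_ci[2]))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(generation = integer(0), n = integer(0), n_events = integer(0),
               median = numeric(0), ci_low = numeric(0), ci_high = numeric(0))
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  attr(out, "variable") <- variable
  attr(out, "condition") <- condition
  out
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank chi-square on the pooled event
#' grid, with the hypergeometric variance at each event time.
#'
#' @param time_a,observed_a durations and event indicators of group A.
#' @param time_b,observed_b same for group B.
#' @return list with `statistic` (chi-square), `p` and the observed/expected
#'   event counts per group.
#' @export
logrank_test <- function(time_a, observed_a, time_b, observed_b) {
  stopifnot(length(time_a) > 0, length(time_b) > 0,
            length(time_a) == length(observed_a),
            length(time_b) == length(observed_b))
  if (sum(observed_a) + sum(observed_b) == 0) {
    stop("no events in either group", call. = FALSE)
  }
  time <- c(time_a, time_b)
  obs <- c(observed_a, observed_b)
  grp <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  tt <- sort(unique(time[obs]))
  O <- E <- V <- 0
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == "A")
    d <- sum(time == t & obs)
    d1 <- sum(time == t & obs & grp == "A")
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed_a = O, expected_a = E, variance = V)
}

#' Mann-Whitney U test (two-sided)
#'
#' Thin wrapper over [stats::wilcox.test()]: exact for small untied samples,
#' normal approximation with the tie correction otherwise (durations live on
#' a 0.25 h grid, so ties are the norm). The returned `U` counts pairs where
#' `a > b` plus half-ties (so complete separation with all `b` larger gives
#' `U = 0`).
#'
#' @param a,b numeric samples.
#' @return list with `U` and `p`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Fraction of tracked cells reaching a generation
#'
#' Denominator is every tracked cell of the condition, complete or not,
#' reproducing the "12% of total data reached the 5th generation" bookkeeping.
#'
#' @param records `cycle_records` including incomplete cells.
#' @param generation generation threshold (cells with generation >= this count).
#' @param condition condition label.
#' @return percentage (0-100).
#' @export
generation_fraction <- function(records, generation, condition) {
  assert_condition(condition)
  r <- records[records$condition == condition, ]
  if (!nrow(r)) return(NA_real_)
  100 * mean(r$generation >= generation)
}
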