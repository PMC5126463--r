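#' Nominal time grid with half-open bins
#'
#' Maps raw draw times to nominal analysis time points through disjoint
#' half-open bins `[edge_i, edge_{i+1})`. The default grid carries the
#' three first-day draws at 4, 12 and 20 h (one per 8-h network window)
#' and daily draws through day 7; its bins partition `[0, 192)`.
#'
#' @param times Strictly increasing nominal times, hours.
#' @param edges Strictly increasing bin edges, `length(times) + 1`; bin
#'   `i` must contain nominal time `i`.
#' @return Object of class `time_grid`.
#' @export
time_grid <- function(times = c(4, 12, 20, 48, 72, 96, 120, 144, 168),
                      edges = c(0, 8, 16, 24, 60, 84, 108, 132, 156, 192)) {
  if (is.unsorted(times, strictly = TRUE))
    stop("time_grid: 'times' must be strictly increasing")
  if (is.unsorted(edges, strictly = TRUE))
    stop("time_grid: 'edges' must be strictly increasing")
  if (length(edges) != length(times) + 1L)
    stop("time_grid: need length(times) + 1 edges")
  if (any(times < edges[-length(edges)] | times >= edges[-1]))
    stop("time_grid: each nominal time must lie in its own bin")
  structure(list(times = times, edges = edges), class = "time_grid")
}

#' Assign samples to nominal time bins
#'
#' Labels every sample with the nominal time of the half-open bin
#' containing its draw time; samples at or beyond the last edge are
#' dropped (their count is reported via a message and the
#' `n_dropped` attribute). When a patient has several draws of one
#' mediator in one bin, their mean is used.
#'
#' @param samples Mediator sample data frame (`patient_id`, `time_h`,
#'   `mediator`, `value`).
#' @param grid A [time_grid()].
#' @return Data frame `patient_id`, `mediator`, `time_h` (nominal),
#'   `value` -- at most one row per (patient, mediator, bin); attribute
#'   `n_dropped` counts out-of-range samples.
#' @export
assign_time_bins <- function(samples, grid = time_grid()) {
  stopifnot(inherits(grid, "time_grid"))
  if (any(samples$time_h < 0)) stop("assign_time_bins: negative sample time")
  idx <- findInterval(samples$time_h, grid$edges)
  drop <- idx < 1L | idx > length(grid$times)
  if (any(drop))
    message("assign_time_bins: dropped ", sum(drop),
            " sample(s) beyond the last bin edge")
  kept <- samples[!drop, , drop = FALSE]
  nominal <- grid$times[idx[!drop]]
  agg <- stats::aggregate(
    kept$value,
    by = list(patient_id = kept$patient_id, mediator = kept$mediator,
              time_h = nominal),
    FUN = mean)
  names(agg)[names(agg) == "x"] <- "value"
  agg <- agg[order(agg$patient_id, agg$mediator, agg$time_h), ]
  rownames(agg) <- NULL
  attr(agg, "n_dropped") <- sum(drop)
  agg
}

#' Per-cell group means of binned mediator data
#'
#' For each (mediator, group, nominal time) cell: number of patients,
#' mean concentration on the raw pg/mL scale, and SEM. Cells with no
#' observation are absent from the output (callers treat them as
#' missing).
#'
#' @param binned Output of [assign_time_bins()].
#' @param groups Factor of group labels named by `patient_id`.
#' @return Data frame `mediator`, `group`, `time_h`, `n`, `mean`, `sem`.
#' @export
group_time_means <- function(binned, groups) {
  g <- groups[binned$patient_id]
  if (anyNA(g))
    stop("group_time_means: group label missing for some patients")
  agg <- stats::aggregate(
    binned$value,
    by = list(mediator = binned$mediator, group = as.character(g),
              time_h = binned$time_h),
    FUN = function(v) c(n = length(v), mean = mean(v),
                        sem = if (length(v) > 1)
                          stats::sd(v) / sqrt(length(v)) else NA_real_))
  out <- cbind(agg[c("mediator", "group", "time_h")],
               as.data.frame(agg$x))
  out$n <- as.integer(out$n)
  out <- out[order(out$mediator, out$group, out$time_h), ]
  rownames(out) <- NULL
  out
}

#' Two-way group-by-time ANOVA for one mediator
#'
#' Fixed-effects two-way ANOVA of (by default log10-transformed)
#' concentrations on group, time and their interaction, fitted as a
#' linear model with sum-to-zero contrasts and tested with Type III
#' sums of squares, so unbalanced cells are handled; on balanced
#' designs this equals the classical two-way decomposition. Time is
#' treated as a factor. All observations enter (no subject term).
#'
#' @param values Numeric response (concentrations, pg/mL).
#' @param group Factor (>= 2 levels used).
#' @param time Time labels, coerced to factor (>= 2 levels used).
#' @param transform `"log10"` (default; requires positive values) or
#'   `"raw"`.
#' @return Data frame of class `anova_table`: one row per effect
#'   (`group`, `time`, `group:time`, `Residuals`) with `ss`, `df`, `F`,
#'   `p`; attribute `transform`.
#' @export
two_way_anova <- function(values, group, time, transform = c("log10", "raw")) {
  transform <- match.arg(transform)
  group <- droplevels(as.factor(group))
  time <- droplevels(as.factor(time))
  if (nlevels(group) < 2 || nlevels(time) < 2)
    stop("two_way_anova: need >= 2 group and >= 2 time levels")
  cells <- table(group, time)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)
    stop("two_way_anova: empty cell(s): ",
         paste(rownames(cells)[bad[, 1]], colnames(cells)[bad[, 2]],
               sep = "/", collapse = ", "))
  }
  y <- if (transform == "log10") {
    if (any(values <= 0)) stop("two_way_anova: log10 needs positive values")
    log10(values)
  } else values
  if (length(y) <= nlevels(group) * nlevels(time))
    stop("two_way_anova: zero residual degrees of freedom")
  if (stats::var(y) == 0)
    stop("two_way_anova: degenerate data (zero variance)")
  dat <- data.frame(y = y, group = group, time = time)
  fit <- stats::lm(y ~ group * time, data = dat,
                   contrasts = list(group = "contr.sum", time = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  pick <- c("group", "time", "group:time", "Residuals")
  a3 <- a3[pick, ]
  out <- data.frame(effect = pick, ss = a3[["Sum Sq"]], df = a3[["Df"]],
                    F = a3[["F value"]], p = a3[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "transform") <- transform
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Trapezoidal area under a mean trajectory
#'
#' Integrates the group-mean mediator trajectory over a time interval by
#' the trapezoid rule on the nominal time points. Missing interior means
#' are skipped (the trapezoid spans the gap); there is no extrapolation
#' beyond the first or last available point, so the integral runs from
#' the first to the last observed time inside the interval.
#'
#' @param times Strictly increasing nominal times, hours.
#' @param means Mean concentrations at `times`; `NA` allowed.
#' @param interval `c(start_h, end_h)`.
#' @return The integral (reported in the conventional pg.h/L units of
#'   AUC tables for this assay).
#' @export
#' @examples
#' auc_trapezoid(c(0, 10), c(0, 10), c(0, 10))  # 50
auc_trapezoid <- function(times, means, interval = range(times)) {
  if (is.unsorted(times, strictly = TRUE))
    stop("auc_trapezoid: 'times' must be strictly increasing")
  keep <- !is.na(means) & times >= interval[1] & times <= interval[2]
  if (sum(keep) < 2)
    stop("auc_trapezoid: need >= 2 nonmissing points inside the interval")
  pracma::trapz(times[keep], means[keep])
}

#' Sum-of-means alternative to the trapezoidal AUC
#'
#' Adds up the per-time-point means inside the interval (no time
#' weighting); exposed for sensitivity checks against the default
#' trapezoid.
#'
#' @inheritParams auc_trapezoid
#' @return Sum of the nonmissing means inside the interval.
#' @export
auc_sum_means <- function(times, means, interval = range(times)) {
  keep <- !is.na(means) & times >= interval[1] & times <= interval[2]
  if (sum(keep) < 2)
    stop("auc_sum_means: need >= 2 nonmissing points inside the interval")
  sum(means[keep])
}

#' Per-mediator, per-group AUC over an interval
#'
#' @param means_tbl Output of [group_time_means()].
#' @param interval `c(start_h, end_h)` in hours.
#' @param method `"trapezoid"` (default) or `"sum"` (sum of means).
#' @return Data frame `mediator`, `group`, `auc`, `start_h`, `end_h`.
#' @export
auc_by_group <- function(means_tbl, interval = c(0, 24),
                         method = c("trapezoid", "sum")) {
  method <- match.arg(method)
  f <- if (method == "trapezoid") auc_trapezoid else auc_sum_means
  combos <- unique(means_tbl[c("mediator", "group")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- means_tbl[means_tbl$mediator == combos$mediator[i] &
                     means_tbl$group == combos$group[i], ]
    sub <- sub[order(sub$time_h), ]
    data.frame(mediator = combos$mediator[i], group = combos$group[i],
               auc = f(sub$time_h, sub$mean, interval),
               start_h = interval[1], end_h = interval[2],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Rank mediators by AUC fold change between strata
#'
#' Computes `fold = AUC(BD_GE) / AUC(BD_LT)` per mediator, keeps the
#' mediators whose two-way ANOVA group effect is significant at `alpha`,
#' and sorts descending by fold (ties broken alphabetically by mediator
#' name) -- the published-table ranking of differentially produced
#' mediators.
#'
#' @param auc_tbl Data frame with columns `mediator`, `auc_bd_ge`,
#'   `auc_bd_lt` (both > 0) and `p_group` (group-effect p-value carried
#'   over from the ANOVA).
#' @param alpha Significance threshold on `p_group` (default 0.05).
#' @return Data frame `mediator`, `auc_bd_ge`, `auc_bd_lt`,
#'   `fold_change`, `p_group`, sorted by decreasing fold.
#' @export
fold_change_ranking <- function(auc_tbl, alpha = 0.05) {
  need <- c("mediator", "auc_bd_ge", "auc_bd_lt", "p_group")
  if (!all(need %in% names(auc_tbl)))
    stop("fold_change_ranking: need columns ",
         paste(need, collapse = ", "))
  if (any(auc_tbl$auc_bd_lt <= 0))
    stop("fold_change_ranking: zero or negative denominator AUC")
  if (any(auc_tbl$auc_bd_ge <= 0))
    stop("fold_change_ranking: zero or negative numerator AUC")
  out <- auc_tbl[need]
  out$fold_change <- out$auc_bd_ge / out$auc_bd_lt
  out <- out[!is.na(out$p_group) & out$p_group < alpha, ]
  out <- out[order(-out$fold_change, out$mediator), ]
  out <- out[c("mediator", "auc_bd_ge", "auc_bd_lt", "fold_change", "p_group")]
  rownames(out) <- NULL
  out
}
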