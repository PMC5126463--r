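#' Analysis window
#'
#' One half-open time window `[start_h, end_h)` over which a per-group
#' correlation network is inferred. The default windowing elsewhere in
#' the package is the three adjacent 8-h periods covering the first day
#' after injury.
#'
#' @param start_h,end_h Hours post-injury, `end_h > start_h`.
#' @param label Optional window label; defaults to `"start-end h"`.
#' @return Object of class `analysis_window`.
#' @export
analysis_window <- function(start_h, end_h, label = NULL) {
  if (!is.numeric(start_h) || !is.numeric(end_h) || end_h <= start_h)
    stop("analysis_window: need end_h > start_h")
  if (is.null(label)) label <- sprintf("%g-%g h", start_h, end_h)
  structure(list(start_h = start_h, end_h = end_h, label = label),
            class = "analysis_window")
}

#' Default first-day windows
#'
#' @return List of three [analysis_window()]s: `[0,8)`, `[8,16)`,
#'   `[16,24)` hours.
#' @export
default_windows <- function() {
  list(analysis_window(0, 8), analysis_window(8, 16), analysis_window(16, 24))
}

#' Patient-by-mediator matrix for one window
#'
#' One value per (patient, mediator): the mean of that patient's samples
#' whose draw time falls in `[start_h, end_h)`, on the log10 scale by
#' default. Patients with no sample in the window are absent from the
#' matrix; mediator columns observed in fewer than `min_pairs` patients
#' are dropped (a correlation on fewer points is not trusted).
#'
#' @param samples Mediator sample data frame.
#' @param window An [analysis_window()].
#' @param patients Optional character vector restricting to a patient
#'   subset (e.g. one stratum); default all patients in `samples`.
#' @param log10_scale Average log10 values (default) rather than raw.
#' @param min_pairs Minimum patients per retained mediator column.
#' @return Numeric matrix, rownames patient ids, colnames mediators.
#' @export
window_patient_matrix <- function(samples, window, patients = NULL,
                                  log10_scale = TRUE, min_pairs = 8) {
  stopifnot(inherits(window, "analysis_window"))
  if (is.null(patients)) patients <- unique(samples$patient_id)
  if (!length(patients)) stop("window_patient_matrix: empty patient set")
  sub <- samples[samples$patient_id %in% patients &
                 samples$time_h >= window$start_h &
                 samples$time_h < window$end_h, , drop = FALSE]
  if (!nrow(sub))
    stop("window_patient_matrix: window '", window$label,
         "' has insufficient data")
  v <- if (log10_scale) log10(sub$value) else sub$value
  agg <- stats::aggregate(v, by = list(patient_id = sub$patient_id,
                                       mediator = sub$mediator), FUN = mean)
  pids <- sort(unique(agg$patient_id))
  meds <- sort(unique(agg$mediator))
  m <- matrix(NA_real_, length(pids), length(meds),
              dimnames = list(pids, meds))
  m[cbind(match(agg$patient_id, pids), match(agg$mediator, meds))] <- agg$x
  keep <- colSums(!is.na(m)) >= min_pairs
  if (!any(keep))
    stop("window_patient_matrix: window '", window$label,
         "' has insufficient data")
  m[, keep, drop = FALSE]
}

#' Pairwise correlation matrix among mediators
#'
#' Pearson (default) or Spearman correlations across patients, computed
#' on pairwise-complete observations. Pairs observed together in fewer
#' than `min_pairs` patients are set to `NA` and can never form network
#' edges; a zero-variance column gets `NA` correlations with a warning.
#'
#' @param mat Patient-by-mediator matrix from [window_patient_matrix()].
#' @param method `"pearson"` or `"spearman"`.
#' @param min_pairs Minimum complete pairs per entry.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(mat, method = c("pearson", "spearman"),
                               min_pairs = 8) {
  method <- match.arg(method)
  zv <- apply(mat, 2, function(x) stats::var(x, na.rm = TRUE)) == 0
  zv[is.na(zv)] <- TRUE
  if (any(zv))
    warning("correlation_matrix: zero-variance column(s): ",
            paste(colnames(mat)[zv], collapse = ", "))
  C <- suppressWarnings(
    stats::cor(mat, use = "pairwise.complete.obs", method = method))
  npair <- crossprod(!is.na(mat))
  C[npair < min_pairs] <- NA_real_
  C[zv, ] <- NA_real_
  C[, zv] <- NA_real_
  diag(C) <- 1
  C
}

#' Threshold a correlation matrix into a network
#'
#' Creates an undirected edge between mediators i and j when
#' `r_ij >= threshold` (`mode = "signed"`, the default, reading the
#' edge rule literally as positive co-variation) or `|r_ij| >=
#' threshold` (`mode = "absolute"`). Missing correlations never form
#' edges. Every mediator in the matrix is a node whether or not it is
#' connected.
#'
#' @param corr Symmetric correlation matrix with unit diagonal.
#' @param threshold Edge threshold in `(0, 1]`; default 0.7.
#' @param mode `"signed"` or `"absolute"`.
#' @param group,window Optional metadata stored on the network.
#' @return Object of class `dyna_network`: `nodes`, `edges` (data frame
#'   `from`, `to`, `r` with `from < to`), `threshold`, `mode`, `group`,
#'   `window`, `n_patients`.
#' @export
build_network <- function(corr, threshold = 0.7,
                          mode = c("signed", "absolute"),
                          group = NA_character_, window = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("build_network: 'threshold' must be in (0, 1]")
  if (!isTRUE(all.equal(unname(corr), unname(t(corr)))) ||
      any(abs(diag(corr) - 1) > 1e-12))
    stop("build_network: 'corr' must be symmetric with unit diagonal")
  nodes <- colnames(corr)
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  r <- corr[ut]
  keep <- !is.na(r) & (if (mode == "signed") r >= threshold
                       else abs(r) >= threshold)
  edges <- data.frame(from = nodes[ut[keep, 1]], to = nodes[ut[keep, 2]],
                      r = r[keep], stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 mode = mode, group = group, window = window,
                 n_patients = attr(corr, "n_patients")),
            class = "dyna_network")
}

#' Network density (edge-times-node metric)
#'
#' Density = (number of edges x number of nodes) / (maximum possible
#' edges among those nodes) = `E * N / (N (N - 1) / 2) = 2 E / (N - 1)`,
#' a size-aware connectivity measure: a complete graph on N nodes scores
#' N. `node_rule` selects which nodes enter the formula: `"connected"`
#' (default) counts only nodes with degree >= 1, accounting for the
#' number of responsive mediators; `"all"` counts every mediator in the
#' network. Density is 0 when there are no edges or fewer than 2 nodes.
#'
#' @param network A [build_network()] result.
#' @param node_rule `"connected"` or `"all"`.
#' @return List of class `density_value`: `E`, `N`, `density`, plus the
#'   network's `group` and `window` metadata.
#' @export
network_density <- function(network, node_rule = c("connected", "all")) {
  node_rule <- match.arg(node_rule)
  stopifnot(inherits(network, "dyna_network"))
  E <- nrow(network$edges)
  N <- if (node_rule == "connected")
    length(unique(c(network$edges$from, network$edges$to)))
  else length(network$nodes)
  dens <- if (E == 0 || N < 2) 0 else E * N / (N * (N - 1) / 2)
  structure(list(E = E, N = N, density = dens, node_rule = node_rule,
                 group = network$group,
                 window = if (!is.null(network$window)) network$window$label
                          else NA_character_),
            class = "density_value")
}

#' Dynamic Network Analysis over groups and windows
#'
#' The full windowed-correlation procedure: for every (group, window)
#' pair, build the patient-by-mediator matrix of window means, correlate
#' mediators across patients, threshold into a network, and evaluate the
#' edge-times-node density. Deterministic given its inputs.
#'
#' @param samples Mediator sample data frame.
#' @param groups Factor of group labels named by `patient_id`.
#' @param windows List of [analysis_window()]s; default the three 8-h
#'   first-day windows.
#' @param threshold Edge threshold (default 0.7).
#' @param method Correlation method, `"pearson"` or `"spearman"`.
#' @param mode Edge rule, `"signed"` or `"absolute"`.
#' @param node_rule Density node rule, `"connected"` or `"all"`.
#' @param min_pairs Minimum patients per mediator column / pair.
#' @param log10_scale Correlate log10 values (default).
#' @return List of class `dyna_result`: `networks` (list keyed
#'   `"group|window"`) and `density` (data frame `group`, `window`, `E`,
#'   `N`, `density`).
#' @export
dyna_run <- function(samples, groups, windows = default_windows(),
                     threshold = 0.7, method = "pearson", mode = "signed",
                     node_rule = "connected", min_pairs = 8,
                     log10_scale = TRUE) {
  groups <- as.factor(groups)
  nets <- list()
  dens <- list()
  for (g in levels(groups)) {
    pids <- names(groups)[groups == g]
    for (w in windows) {
      mat <- window_patient_matrix(samples, w, pids,
                                   log10_scale = log10_scale,
                                   min_pairs = min_pairs)
      C <- correlation_matrix(mat, method = method, min_pairs = min_pairs)
      attr(C, "n_patients") <- nrow(mat)
      net <- build_network(C, threshold = threshold, mode = mode,
                           group = g, window = w)
      key <- paste(g, w$label, sep = "|")
      nets[[key]] <- net
      d <- network_density(net, node_rule = node_rule)
      dens[[key]] <- data.frame(group = g, window = w$label,
                                start_h = w$start_h, end_h = w$end_h,
                                E = d$E, N = d$N, density = d$density,
                                stringsAsFactors = FALSE)
    }
  }
  density <- do.call(rbind, dens)
  rownames(density) <- NULL
  structure(list(networks = nets, density = density), class = "dyna_result")
}

.edge_keys <- function(net) {
  if (!nrow(net$edges)) return(character(0))
  paste(pmin(net$edges$from, net$edges$to),
        pmax(net$edges$from, net$edges$to), sep = "|")
}

#' Compare two correlation networks
#'
#' Shared and unique edges and the Jaccard index of the two edge sets
#' (1 when identical, 0 when disjoint; 0 by convention when both are
#' empty). The networks must share a node universe.
#'
#' @param net_a,net_b [build_network()] results over the same nodes.
#' @return List: `shared`, `only_a`, `only_b` (character edge keys
#'   `"from|to"`), `jaccard`.
#' @export
compare_networks <- function(net_a, net_b) {
  if (!setequal(net_a$nodes, net_b$nodes))
    stop("compare_networks: node universes differ")
  ea <- .edge_keys(net_a)
  eb <- .edge_keys(net_b)
  un <- union(ea, eb)
  list(shared = intersect(ea, eb), only_a = setdiff(ea, eb),
       only_b = setdiff(eb, ea),
       jaccard = if (!length(un)) 0 else length(intersect(ea, eb)) / length(un))
}
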