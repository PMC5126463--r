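#' Planted correlation block
#'
#' Describes a block of mediators whose log-scale noise is drawn with a
#' common pairwise correlation `rho` for one stratum within one time
#' window. Planting such blocks gives the windowed network analysis a
#' known ground truth to recover.
#'
#' @param group Stratum label, `"BD_LT"` or `"BD_GE"`.
#' @param window Numeric `c(start_h, end_h)`, half-open `[start, end)`;
#'   draws whose nominal time falls in the window are correlated.
#' @param mediators Character vector (>= 2) of mediator names in the block.
#' @param rho Target pairwise correlation, in `[0, 1)`.
#' @return Object of class `planted_block`.
#' @export
planted_block <- function(group, window, mediators, rho) {
  stopifnot(is.character(group), length(group) == 1L)
  if (!group %in% c("BD_LT", "BD_GE"))
    stop("planted_block: 'group' must be \"BD_LT\" or \"BD_GE\"")
  if (length(window) != 2L || !is.numeric(window) || window[2] <= window[1])
    stop("planted_block: 'window' must be numeric c(start, end) with end > start")
  if (!is.character(mediators) || length(mediators) < 2L ||
      anyDuplicated(mediators))
    stop("planted_block: 'mediators' must be >= 2 unique names")
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1)
    stop("planted_block: 'rho' must be in [0, 1)")
  structure(list(group = group, window = as.numeric(window),
                 mediators = mediators, rho = as.numeric(rho)),
            class = "planted_block")
}

#' Default planted blocks for the two-strata cohort
#'
#' One rho = 0.85 block of 10 mediators planted in the high-BD stratum
#' for the first two 8-hour windows only, emulating the dense early
#' innate/lymphoid co-activation that stratum shows and its dissolution
#' by 16-24 h.
#'
#' @param rho Common pairwise correlation of the block.
#' @return List of [planted_block()] objects.
#' @export
default_planted_blocks <- function(rho = 0.85) {
  members <- c("sIL-2Ra", "MIP-1a", "IL-17A", "IL-4", "GM-CSF",
               "IL-7", "IL-2", "IFN-g", "IL-13", "IL-15")
  list(planted_block("BD_GE", c(0, 8), members, rho),
       planted_block("BD_GE", c(8, 16), members, rho))
}

#' Configuration for the synthetic two-strata cohort generator
#'
#' Captures every knob of the simulated study: group sizes, mediator
#' panel, nominal draw grid, per-cell mean log10 concentrations, residual
#' log-scale noise, planted correlation blocks, detection limits,
#' draw-level missingness, and the RNG seed. Defaults reproduce the
#' study conditions this package targets: 70 low-BD and 84 high-BD blunt
#' trauma patients, 22 mediators, three draws inside the first 24 h
#' (4, 12, 20 h -- one per 8-h analysis window) plus daily draws to day 7.
#'
#' @param n_per_group Integer vector of length 2, patients in
#'   `BD_LT` and `BD_GE` strata (each >= 3).
#' @param mediators Unique mediator names.
#' @param sampling_times_h Nominal draw grid, hours post-injury.
#' @param group_log_means Array `mediator x group x time` of mean log10
#'   pg/mL; see [default_log_means()].
#' @param log_sd Residual SD of log10 concentration, scalar or one per
#'   mediator; all > 0.
#' @param planted_blocks List of [planted_block()] objects.
#' @param lod Lower limit of detection in pg/mL, scalar or one per
#'   mediator; values below it are censored to LOD/2.
#' @param missing_prob Probability that a scheduled blood draw (all
#'   mediators at one time point) is absent; in `[0, 1)`.
#' @param seed Integer RNG seed.
#' @return Object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_per_group = c(BD_LT = 70, BD_GE = 84),
                              mediators = mediator_panel(),
                              sampling_times_h = c(4, 12, 20, 48, 72, 96,
                                                   120, 144, 168),
                              group_log_means = NULL,
                              log_sd = 0.4,
                              planted_blocks = default_planted_blocks(),
                              lod = 0.5,
                              missing_prob = 0.05,
                              seed = 1L) {
  if (length(n_per_group) != 2L || any(n_per_group < 3) ||
      any(n_per_group != round(n_per_group)))
    stop("simulation_config: 'n_per_group' must be 2 integers >= 3")
  n_per_group <- as.integer(n_per_group)
  names(n_per_group) <- c("BD_LT", "BD_GE")
  if (!is.character(mediators) || anyDuplicated(mediators))
    stop("simulation_config: 'mediators' must be unique names")
  if (is.unsorted(sampling_times_h, strictly = TRUE) ||
      any(sampling_times_h < 0))
    stop("simulation_config: 'sampling_times_h' must be increasing and >= 0")
  if (is.null(group_log_means))
    group_log_means <- default_log_means(mediators, sampling_times_h)
  dn <- dimnames(group_log_means)
  if (!identical(dn[[1]], mediators) ||
      !identical(dn[[2]], c("BD_LT", "BD_GE")) ||
      !identical(dn[[3]], as.character(sampling_times_h)))
    stop("simulation_config: 'group_log_means' dimnames must be ",
         "(mediators, c(BD_LT, BD_GE), sampling_times_h)")
  log_sd <- rep_len(as.numeric(log_sd), length(mediators))
  if (any(!is.finite(log_sd)) || any(log_sd < 0))
    stop("simulation_config: 'log_sd' must be finite and >= 0")
  if (!is.list(planted_blocks) ||
      !all(vapply(planted_blocks, inherits, logical(1), "planted_block")))
    stop("simulation_config: 'planted_blocks' must be a list of planted_block")
  for (b in planted_blocks)
    if (!all(b$mediators %in% mediators))
      stop("simulation_config: planted block names mediators outside the panel")
  lod <- rep_len(as.numeric(lod), length(mediators))
  if (any(!is.finite(lod)) || any(lod < 0))
    stop("simulation_config: 'lod' must be finite and >= 0")
  if (!is.numeric(missing_prob) || missing_prob < 0 || missing_prob >= 1)
    stop("simulation_config: 'missing_prob' must be in [0, 1)")
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("simulation_config: 'seed' must be a single integer")
  names(log_sd) <- names(lod) <- mediators
  cfg <- structure(list(n_per_group = n_per_group, mediators = mediators,
                        sampling_times_h = as.numeric(sampling_times_h),
                        group_log_means = group_log_means, log_sd = log_sd,
                        planted_blocks = planted_blocks, lod = lod,
                        missing_prob = as.numeric(missing_prob),
                        seed = as.integer(seed)),
                   class = "simulation_config")
  # every (group, time) noise correlation matrix must be positive definite
  for (g in c("BD_LT", "BD_GE"))
    for (t in cfg$sampling_times_h)
      .noise_chol(cfg, g, t)
  cfg
}

# Upper-triangular Cholesky factor of the noise correlation matrix for
# one (group, time) cell: identity plus equicorrelated planted blocks.
.noise_chol <- function(config, group, time_h) {
  p <- length(config$mediators)
  C <- diag(p)
  dimnames(C) <- list(config$mediators, config$mediators)
  for (b in config$planted_blocks) {
    if (b$group != group) next
    if (time_h < b$window[1] || time_h >= b$window[2]) next
    idx <- match(b$mediators, config$mediators)
    C[idx, idx] <- b$rho
    diag(C)[idx] <- 1
  }
  out <- tryCatch(chol(C), error = function(e)
    stop("simulation_config: planted blocks give a non-positive-definite ",
         "noise correlation at group ", group, ", time ", time_h))
  out
}

# Truncated normal draw by inverse-CDF (lower, upper may be +/-Inf).
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Clinical covariate generator for one stratum; means/SDs calibrated to
# the published cohort description (mean +/- SEM at n = 70 / 84).
.draw_clinical <- function(n, group) {
  ge <- group == "BD_GE"
  rn <- function(m, s, lo = -Inf, hi = Inf) .rtruncnorm(n, m, s, lo, hi)
  data.frame(
    group_truth = group,
    age = round(rn(if (ge) 45.8 else 49.3, if (ge) 18 else 20, 18, 95), 1),
    sex = ifelse(stats::runif(n) < (if (ge) 0.655 else 0.786), "M", "F"),
    iss = as.integer(round(rn(if (ge) 23 else 21, 11, 1, 75))),
    gcs = as.integer(round(rn(if (ge) 12.6 else 12.7, 4.5, 3, 15))),
    bd_admission = round(if (ge) .rtruncnorm(n, 6.7, 3.6, lower = 4)
                         else .rtruncnorm(n, 1.7, 0.85, upper = 3.99), 2),
    ethanol = round(ifelse(stats::runif(n) < 0.35,
                           stats::runif(n, 0, 10), 0), 2),
    prehospital_fluids = round(stats::runif(n, 0, 2), 2),
    sbp_admission = round(rn(if (ge) 114 else 130, 26, 60, 220)),
    hr_admission = round(rn(if (ge) 104 else 89, 22, 40, 190)),
    transfused_24h = stats::runif(n) < (if (ge) 43 / 84 else 22 / 70),
    surgery_24h = stats::runif(n) < (if (ge) 51 / 84 else 29 / 70),
    ais_head = as.integer(round(rn(1.5, 1.5, 0, 5))),
    ais_face = as.integer(round(rn(0.5, 0.8, 0, 5))),
    ais_chest = as.integer(round(rn(1.8, 1.5, 0, 5))),
    ais_abdomen = as.integer(round(rn(1.2, 1.3, 0, 5))),
    ais_extremity = as.integer(round(rn(if (ge) 2.2 else 1.5, 1.4, 0, 5))),
    ais_external = as.integer(round(rn(0.4, 0.7, 0, 5))),
    icu_los = round(rn(if (ge) 9.9 else 6.6, if (ge) 8.8 else 6.6, 0, 90), 1),
    hosp_los = round(rn(if (ge) 17.4 else 11.9, if (ge) 11 else 8, 0, 150), 1),
    vent_days = round(rn(if (ge) 5.5 else 3, if (ge) 8 else 4.7, 0, 60), 1),
    disposition = sample(
      c("home", "home_with_service", "inpatient_rehab",
        "outpatient_rehab", "skilled_nursing", "other"),
      n, replace = TRUE,
      prob = if (ge) c(0.274, 0.012, 0.012, 0.202, 0.464, 0.036)
             else c(0.486, 0.029, 0.086, 0.157, 0.229, 0.014)),
    stringsAsFactors = FALSE
  )
}

# MODScore trajectory days 1-7: elevated and persistent in the high-BD
# stratum, resolving in the low-BD stratum.
.draw_modscore <- function(n, group) {
  ge <- group == "BD_GE"
  base <- if (ge) c(4.0, 4.4, 4.4, 4.2, 3.8, 3.4, 3.0)
          else c(3.8, 3.2, 2.8, 2.4, 2.0, 1.8, 1.6)
  out <- sapply(base, function(m) pmax(0, pmin(24, round(stats::rnorm(n, m, 2), 1))))
  colnames(out) <- paste0("mod_d", 1:7)
  as.data.frame(out)
}

#' Draw the full mediator panel for one patient
#'
#' Generates one `MediatorSample` row per (mediator, scheduled time) for
#' a single patient: `value = 10^(group_log_mean + noise)`, where the
#' log10-scale noise has SD `log_sd` per mediator and, inside a planted
#' block whose window covers the draw time and whose stratum matches the
#' patient, common pairwise correlation `rho`; outside blocks the noise
#' is independent. Draws from the current RNG state; no censoring or
#' missingness is applied here.
#'
#' @param patient One-row patient data frame with `patient_id` and
#'   `group_truth` (as produced by [generate_cohort()]).
#' @param config A [simulation_config()].
#' @param times_h Draw times; must be a subset of the config grid.
#' @return Data frame with columns `patient_id`, `time_h`, `mediator`,
#'   `value` (pg/mL, > 0), `censored` (all `FALSE`).
#' @export
sample_mediator_panel <- function(patient, config,
                                  times_h = config$sampling_times_h) {
  stopifnot(inherits(config, "simulation_config"))
  if (!all(times_h %in% config$sampling_times_h))
    stop("sample_mediator_panel: time not in the configured sampling grid")
  g <- patient$group_truth
  if (!g %in% c("BD_LT", "BD_GE"))
    stop("sample_mediator_panel: patient stratum not in config")
  p <- length(config$mediators)
  rows <- lapply(times_h, function(t) {
    L <- .noise_chol(config, g, t)
    z <- drop(stats::rnorm(p) %*% L)              # cor(z) = C
    lg <- config$group_log_means[, g, as.character(t)] + config$log_sd * z
    data.frame(patient_id = patient$patient_id, time_h = t,
               mediator = config$mediators, value = 10^lg,
               censored = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Apply lower-limit-of-detection censoring
#'
#' Multiplex immunoassays cannot quantify below a per-analyte detection
#' limit; the conventional substitution replaces such values by LOD/2.
#' Records at or above the LOD are untouched.
#'
#' @param samples Mediator sample data frame (`patient_id`, `time_h`,
#'   `mediator`, `value`, `censored`).
#' @param lod Detection limit in pg/mL: scalar, or vector named by
#'   mediator.
#' @return `samples` with below-LOD values replaced by `lod/2` and
#'   `censored = TRUE`.
#' @export
apply_censoring <- function(samples, lod) {
  if (any(lod < 0)) stop("apply_censoring: 'lod' must be >= 0")
  if (is.null(names(lod))) {
    lim <- rep_len(as.numeric(lod), nrow(samples))
  } else {
    lim <- as.numeric(lod[samples$mediator])
    if (anyNA(lim)) stop("apply_censoring: 'lod' missing for some mediators")
  }
  below <- samples$value < lim
  samples$value[below] <- lim[below] / 2
  samples$censored <- samples$censored | below
  samples
}

#' Generate a synthetic two-strata trauma cohort
#'
#' Draws a seed-reproducible cohort with the structure the downstream
#' analysis assumes: two base-deficit strata with stratum-conditional
#' admission BD (truncated normals below/above the 4 mEq/L cutoff),
#' clinical covariates calibrated to the published cohort tables,
#' log10-normal mediator concentrations with group- and time-dependent
#' means, plantable within-window correlation blocks, draw-level
#' missingness, and LOD/2 censoring. Identical configs (including seed)
#' give identical tables.
#'
#' @param config A [simulation_config()].
#' @return List with `patients` (one row per patient) and `samples`
#'   (long mediator table: `patient_id`, `time_h`, `mediator`, `value`,
#'   `censored`).
#' @export
#' @examples
#' cfg <- simulation_config(n_per_group = c(5, 5), missing_prob = 0, seed = 7)
#' cohort <- generate_cohort(cfg)
#' table(cohort$patients$group_truth)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  groups <- c("BD_LT", "BD_GE")
  pats <- do.call(rbind, lapply(groups, function(g) {
    n <- config$n_per_group[[g]]
    cbind(data.frame(patient_id = character(n)), .draw_clinical(n, g),
          .draw_modscore(n, g))
  }))
  pats$patient_id <- sprintf("P%03d", seq_len(nrow(pats)))
  rownames(pats) <- NULL

  samples <- do.call(rbind, lapply(seq_len(nrow(pats)), function(i) {
    s <- sample_mediator_panel(pats[i, ], config)
    if (config$missing_prob > 0) {
      keep_t <- config$sampling_times_h[
        stats::runif(length(config$sampling_times_h)) >= config$missing_prob]
      s <- s[s$time_h %in% keep_t, , drop = FALSE]
    }
    s
  }))
  rownames(samples) <- NULL
  samples <- apply_censoring(samples, config$lod)
  list(patients = pats, samples = samples)
}
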