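#' Read a long-format mediator measurement table
#'
#' Expects an RFC-4180 CSV with header
#' `patient_id,time_h,mediator,value_pg_ml,censored`. Rows with
#' nonpositive values, missing fields or unparseable numbers are
#' rejected with their line number; duplicate (patient, mediator, time)
#' rows are an error. Mediators outside `known_mediators` (when given)
#' are reported via a message but kept.
#'
#' @param path CSV file path.
#' @param known_mediators Optional character vector of expected names.
#' @return Data frame `patient_id`, `time_h`, `mediator`, `value`,
#'   `censored`.
#' @export
read_measurements <- function(path, known_mediators = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character",
                                        mediator = "character"))
  need <- c("patient_id", "time_h", "mediator", "value_pg_ml", "censored")
  if (!all(need %in% names(raw)))
    stop("read_measurements: header must contain ",
         paste(need, collapse = ","))
  if (!nrow(raw))
    return(data.frame(patient_id = character(0), time_h = numeric(0),
                      mediator = character(0), value = numeric(0),
                      censored = logical(0)))
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  bad <- which(is.na(raw$time_h) | is.na(raw$value_pg_ml) |
               raw$value_pg_ml <= 0 | raw$time_h < 0 | is.na(raw$censored))
  if (length(bad))
    stop("read_measurements: invalid row at line ", line[bad[1]],
         " (value must be > 0, time >= 0, censored true/false)")
  key <- paste(raw$patient_id, raw$mediator, raw$time_h, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("read_measurements: duplicate (patient, mediator, time) at line ",
         line[dup[1]])
  if (!is.null(known_mediators)) {
    unk <- setdiff(unique(raw$mediator), known_mediators)
    if (length(unk))
      message("read_measurements: unknown mediator(s): ",
              paste(unk, collapse = ", "))
  }
  data.frame(patient_id = raw$patient_id, time_h = as.numeric(raw$time_h),
             mediator = raw$mediator, value = as.numeric(raw$value_pg_ml),
             censored = as.logical(raw$censored), stringsAsFactors = FALSE)
}

#' Write a mediator measurement table
#'
#' Inverse of [read_measurements()]; values are serialised with full
#' double precision so a write/read round trip is lossless.
#'
#' @param samples Data frame `patient_id`, `time_h`, `mediator`,
#'   `value`, `censored`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(samples, path) {
  out <- data.frame(patient_id = samples$patient_id,
                    time_h = samples$time_h, mediator = samples$mediator,
                    value_pg_ml = format(samples$value, digits = 17,
                                         scientific = FALSE, trim = TRUE),
                    censored = tolower(as.character(samples$censored)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the per-patient clinical table
#'
#' Plain CSV with one row per patient; column types are inferred except
#' `patient_id`, which is always character.
#'
#' @param patients Patient data frame (for writing).
#' @param path CSV path.
#' @return The patient data frame (reading) or `path` invisibly
#'   (writing).
#' @export
read_patients <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(patient_id = "character"))
}

#' @rdname read_patients
#' @export
write_patients <- function(patients, path) {
  utils::write.csv(patients, path, row.names = FALSE)
  invisible(path)
}

#' Export a correlation network as GraphML
#'
#' Nodes are mediators; edges carry the correlation coefficient in the
#' `r` attribute.
#'
#' @param network A [build_network()] result.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "dyna_network"))
  g <- igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = data.frame(name = network$nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export network edge lists as TSV
#'
#' One row per edge over all networks in a [dyna_run()] result:
#' `mediator_a`, `mediator_b`, `r`, `group`, `window`.
#'
#' @param result A `dyna_result` from [dyna_run()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(result, path) {
  rows <- lapply(result$networks, function(net) {
    if (!nrow(net$edges)) return(NULL)
    data.frame(mediator_a = net$edges$from, mediator_b = net$edges$to,
               r = net$edges$r, group = net$group,
               window = net$window$label, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(mediator_a = character(0), mediator_b = character(0),
                      r = numeric(0), group = character(0),
                      window = character(0))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every setting of [run_pipeline()]: either a simulation block
#' (simulate mode) or paths to patient and measurement CSVs, plus the
#' exclusion rules, time grid, trajectory and network settings.
#'
#' @param simulation A [simulation_config()] for simulate mode, or
#'   `NULL` to read `patient_path` / `measurement_path`.
#' @param patient_path,measurement_path Input CSVs (non-simulate mode).
#' @param rules An [exclusion_rules()].
#' @param grid A [time_grid()].
#' @param windows List of [analysis_window()]s.
#' @param threshold,mode,node_rule,min_pairs Network settings, see
#'   [dyna_run()].
#' @param transform ANOVA transform, `"log10"` or `"raw"`.
#' @param alpha Significance level for the fold-change ranking.
#' @param auc_method `"trapezoid"` or `"sum"`.
#' @param seed Seed recorded in the manifest (simulation uses the seed
#'   inside its own block).
#' @return Object of class `run_config`.
#' @export
run_config <- function(simulation = NULL, patient_path = NULL,
                       measurement_path = NULL, rules = exclusion_rules(),
                       grid = time_grid(), windows = default_windows(),
                       threshold = 0.7, mode = "signed",
                       node_rule = "connected", min_pairs = 8,
                       transform = "log10", alpha = 0.05,
                       auc_method = "trapezoid", seed = 1L) {
  if (is.null(simulation)) {
    for (p in c(patient_path, measurement_path))
      if (is.null(p) || !file.exists(p))
        stop("run_config: input path missing or nonexistent: ",
             if (is.null(p)) "(NULL)" else p)
  } else stopifnot(inherits(simulation, "simulation_config"))
  stopifnot(inherits(rules, "exclusion_rules"), inherits(grid, "time_grid"))
  structure(list(simulation = simulation, patient_path = patient_path,
                 measurement_path = measurement_path, rules = rules,
                 grid = grid, windows = windows, threshold = threshold,
                 mode = mode, node_rule = node_rule, min_pairs = min_pairs,
                 transform = transform, alpha = alpha,
                 auc_method = auc_method, seed = as.integer(seed)),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full stratified-inflammation pipeline
#'
#' Sequences the analysis end to end: simulate or load the cohort,
#' apply exclusions, stratify at the BD cutoff, build the clinical
#' comparison report, compute binned trajectories with per-mediator
#' two-way ANOVA and AUC fold-change ranking over the first 24 h and
#' over the full week, and run the windowed network analysis. All
#' outputs are written under `out_dir` together with a manifest holding
#' the settings, seed and MD5 content hashes; identical config and seed
#' give identical hashes.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with `patients`, `groups`, `clinical`
#'   (Table-1-style report), `fold_24h`, `fold_7d`, `trajectories`,
#'   `dyna` (a `dyna_result`), `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- .stage("input", {
    if (!is.null(config$simulation)) generate_cohort(config$simulation)
    else list(patients = read_patients(config$patient_path),
              samples = read_measurements(config$measurement_path))
  })

  excl <- .stage("exclusions", apply_exclusions(cohort$patients, config$rules))
  patients <- excl$retained
  groups <- .stage("stratification",
                   stratify_by_bd(patients, config$rules$bd_cutoff))
  samples <- cohort$samples[cohort$samples$patient_id %in%
                              patients$patient_id, , drop = FALSE]

  clinical <- .stage("clinical_report", {
    numvars <- intersect(c("age", "iss", "gcs", "bd_admission",
                           "sbp_admission", "hr_admission", "icu_los",
                           "hosp_los", "vent_days"), names(patients))
    summ <- summarize_groups(patients, numvars, groups)
    summ$test <- "mann_whitney"
    summ$p <- NA_real_
    for (v in numvars) {
      x <- patients[[v]][groups == "BD_GE"]
      y <- patients[[v]][groups == "BD_LT"]
      if (length(x) && length(y))
        summ$p[summ$variable == v] <- mann_whitney_u(x, y)$p
    }
    summ
  })

  traj <- .stage("trajectories", {
    binned <- suppressMessages(assign_time_bins(samples, config$grid))
    means <- group_time_means(binned, groups)
    fold_tbl <- function(interval) {
      anova_p <- vapply(unique(binned$mediator), function(m) {
        sub <- binned[binned$mediator == m &
                      binned$time_h >= interval[1] &
                      binned$time_h <= interval[2], ]
        tryCatch(
          two_way_anova(sub$value, groups[sub$patient_id], sub$time_h,
                        transform = config$transform)$p[1],
          error = function(e) NA_real_)
      }, numeric(1))
      auc <- auc_by_group(means[means$time_h >= interval[1] &
                                means$time_h <= interval[2], ],
                          interval, method = config$auc_method)
      wide <- merge(
        stats::setNames(auc[auc$group == "BD_GE", c("mediator", "auc")],
                        c("mediator", "auc_bd_ge")),
        stats::setNames(auc[auc$group == "BD_LT", c("mediator", "auc")],
                        c("mediator", "auc_bd_lt")))
      wide$p_group <- anova_p[wide$mediator]
      fold_change_ranking(wide, alpha = config$alpha)
    }
    list(means = means,
         fold_24h = fold_tbl(c(0, 24)),
         fold_7d = fold_tbl(c(0, 192)))
  })

  dyna <- .stage("dyna",
    dyna_run(samples, groups, windows = config$windows,
             threshold = config$threshold, mode = config$mode,
             node_rule = config$node_rule, min_pairs = config$min_pairs))

  # outputs
  .stage("write", {
    write_patients(patients, file.path(out_dir, "patients.csv"))
    write_measurements(samples, file.path(out_dir, "measurements.csv"))
    utils::write.csv(clinical, file.path(out_dir, "clinical_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(clinical, file.path(out_dir, "clinical_report.json"),
                         dataframe = "rows", digits = NA)
    utils::write.csv(excl$audit, file.path(out_dir, "exclusion_audit.csv"),
                     row.names = FALSE)
    utils::write.csv(traj$means, file.path(out_dir, "trajectories.csv"),
                     row.names = FALSE)
    utils::write.csv(traj$fold_24h, file.path(out_dir, "auc_fold_24h.csv"),
                     row.names = FALSE)
    utils::write.csv(traj$fold_7d, file.path(out_dir, "auc_fold_7d.csv"),
                     row.names = FALSE)
    utils::write.csv(dyna$density, file.path(out_dir, "network_density.csv"),
                     row.names = FALSE)
    write_edge_list(dyna, file.path(out_dir, "network_edges.tsv"))
    for (key in names(dyna$networks)) {
      fn <- paste0("network_", gsub("[^A-Za-z0-9]+", "_", key), ".graphml")
      write_graphml(dyna$networks[[key]], file.path(out_dir, fn))
    }
  })

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    seed = config$seed,
    settings = list(threshold = config$threshold, mode = config$mode,
                    node_rule = config$node_rule,
                    min_pairs = config$min_pairs,
                    transform = config$transform, alpha = config$alpha,
                    auc_method = config$auc_method,
                    simulate = !is.null(config$simulation)),
    n_excluded = nrow(excl$audit),
    n_patients = nrow(patients),
    hashes = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$hashes) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(patients = patients, groups = groups, clinical = clinical,
                 fold_24h = traj$fold_24h, fold_7d = traj$fold_7d,
                 trajectories = traj$means, dyna = dyna,
                 manifest = manifest))
}
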