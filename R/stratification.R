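#' Cohort exclusion rules
#'
#' Thresholds used to remove patients whose admission base deficit may be
#' confounded: documented alcohol intoxication (serum ethanol above
#' threshold) and large prehospital fluid/blood volumes. Both rules use
#' strict `>` comparisons, so boundary values are retained.
#'
#' @param max_prehospital_fluids Liters; patients above this are excluded.
#' @param max_ethanol ng/dL; patients above this are excluded.
#' @param bd_cutoff mEq/L; the stratification cutoff (must be > 0).
#' @return Object of class `exclusion_rules`.
#' @export
exclusion_rules <- function(max_prehospital_fluids = 2, max_ethanol = 10,
                            bd_cutoff = 4) {
  if (!all(is.finite(c(max_prehospital_fluids, max_ethanol, bd_cutoff))))
    stop("exclusion_rules: all thresholds must be finite")
  if (bd_cutoff <= 0) stop("exclusion_rules: 'bd_cutoff' must be > 0")
  structure(list(max_prehospital_fluids = max_prehospital_fluids,
                 max_ethanol = max_ethanol, bd_cutoff = bd_cutoff),
            class = "exclusion_rules")
}

#' Apply cohort exclusion rules
#'
#' Removes patients with serum ethanol above `max_ethanol` (alcohol can
#' elevate base deficit independently of shock) or prehospital fluids
#' above `max_prehospital_fluids` (dilution lowers it). Missing values in
#' either field are an error, never silently retained.
#'
#' @param patients Patient data frame with `patient_id`, `ethanol`,
#'   `prehospital_fluids`.
#' @param rules An [exclusion_rules()] object.
#' @return List with `retained` (patient rows passing both rules) and
#'   `audit` (data frame `patient_id`, `rule`, `value`, one row per rule
#'   violated).
#' @export
apply_exclusions <- function(patients, rules = exclusion_rules()) {
  stopifnot(inherits(rules, "exclusion_rules"))
  for (f in c("ethanol", "prehospital_fluids")) {
    if (is.null(patients[[f]]))
      stop("apply_exclusions: column '", f, "' is missing")
    bad <- which(is.na(patients[[f]]))
    if (length(bad))
      stop("apply_exclusions: missing '", f, "' for patient ",
           patients$patient_id[bad[1]])
  }
  alc <- patients$ethanol > rules$max_ethanol
  flu <- patients$prehospital_fluids > rules$max_prehospital_fluids
  audit <- rbind(
    data.frame(patient_id = patients$patient_id[alc],
               rule = rep("alcohol_intoxication", sum(alc)),
               value = patients$ethanol[alc], stringsAsFactors = FALSE),
    data.frame(patient_id = patients$patient_id[flu],
               rule = rep("prehospital_fluids", sum(flu)),
               value = patients$prehospital_fluids[flu],
               stringsAsFactors = FALSE))
  list(retained = patients[!(alc | flu), , drop = FALSE], audit = audit)
}

#' Stratify patients at the base-deficit cutoff
#'
#' Labels each patient `BD_GE` when admission base deficit is greater
#' than or equal to the cutoff and `BD_LT` otherwise; the partition is
#' exhaustive and disjoint and the cutoff itself falls in `BD_GE`.
#'
#' @param patients Patient data frame with `bd_admission`.
#' @param cutoff mEq/L, default 4.
#' @return Factor with levels `c("BD_LT", "BD_GE")`, named by
#'   `patient_id`, one element per patient.
#' @export
stratify_by_bd <- function(patients, cutoff = 4) {
  bd <- patients$bd_admission
  if (is.null(bd)) stop("stratify_by_bd: column 'bd_admission' is missing")
  if (anyNA(bd))
    stop("stratify_by_bd: missing bd_admission for patient ",
         patients$patient_id[which(is.na(bd))[1]])
  out <- factor(ifelse(bd >= cutoff, "BD_GE", "BD_LT"),
                levels = c("BD_LT", "BD_GE"))
  names(out) <- patients$patient_id
  out
}

#' Shock Index
#'
#' Heart rate divided by systolic blood pressure; an index strictly
#' greater than 1 signifies hypovolemic shock. Vectorised.
#'
#' @param hr Heart rate, beats per minute (> 0 when present).
#' @param sbp Systolic blood pressure, mmHg (must be > 0).
#' @return Data frame with `shock_index` and logical `shock`.
#' @export
#' @examples
#' shock_index(120, 100)  # 1.2, flagged
shock_index <- function(hr, sbp) {
  if (any(sbp <= 0, na.rm = TRUE))
    stop("shock_index: 'sbp' must be > 0")
  si <- hr / sbp
  data.frame(shock_index = si, shock = si > 1)
}

#' Mean and standard error by group
#'
#' Per-group n, mean and SEM (sd with the n-1 denominator divided by
#' sqrt(n)) for a set of numeric patient variables, the form in which
#' cohort comparison tables report continuous measures. A group with a
#' single observation gets `NA` SEM, not zero.
#'
#' @param patients Patient data frame.
#' @param variables Character vector of numeric column names.
#' @param groups Factor of group labels aligned with `patients` rows
#'   (e.g. from [stratify_by_bd()]).
#' @return Data frame `variable`, `group`, `n`, `mean`, `sem`.
#' @export
summarize_groups <- function(patients, variables, groups) {
  stopifnot(length(groups) == nrow(patients))
  groups <- as.factor(groups)
  out <- lapply(variables, function(v) {
    x <- patients[[v]]
    if (is.null(x)) stop("summarize_groups: no column '", v, "'")
    if (!is.numeric(x)) stop("summarize_groups: '", v, "' is not numeric")
    do.call(rbind, lapply(levels(groups), function(g) {
      xi <- x[groups == g & !is.na(x)]
      n <- length(xi)
      data.frame(variable = v, group = g, n = n,
                 mean = if (n) mean(xi) else NA_real_,
                 sem = if (n > 1) stats::sd(xi) / sqrt(n) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
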