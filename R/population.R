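# Population-level aggregation: cohort medians and ranges, population-based
# RBE-weighted doses, and (alpha/beta)x confidence-interval sweeps.

#' Median and range of a cohort metric
#'
#' Median with the mean-of-central-pair convention for even n (the cohort
#' size is typically 10), plus the (min, max) range.
#'
#' @param values non-empty numeric vector.
#' @return Named numeric \code{c(median, min, max)}.
#' @examples
#' medianRange(c(1, 2, 3, 4))  # 2.5, 1, 4
#' @export
medianRange <- function(values) {
  if (!length(values)) stop("'values' must be non-empty")
  c(median = stats::median(values), min = min(values), max = max(values))
}

#' Population-based RBE-weighted dose
#'
#' The organ-mean physical dose of a patient multiplied by the cohort-median
#' dose-weighted organ-mean RBE for that organ and model:
#' \eqn{\bar D_{RBE} = \bar D_{phys} \times \overline{RBE}_{d,median}}.
#' By linearity the same product applied to an RBE difference yields the
#' corresponding RBE-weighted dose difference.
#'
#' @param meanPhysDose organ-mean physical dose, Gy, > 0.
#' @param rbeDMedian cohort-median organ RBE (dimensionless, > 0), or an
#'   RBE difference when computing a dose difference.
#' @return Dose in Gy(RBE).
#' @examples
#' populationWeightedDose(54 / 1.1, 1.18)
#' @export
populationWeightedDose <- function(meanPhysDose, rbeDMedian) {
  if (any(meanPhysDose <= 0)) stop("'meanPhysDose' must be > 0 (Gy)")
  if (any(rbeDMedian <= 0)) stop("'rbeDMedian' must be > 0")
  meanPhysDose * rbeDMedian
}

#' Per-organ metrics for a whole cohort
#'
#' Runs \code{\link{accumulateDose}} and \code{\link{organMetrics}} for each
#' patient and stacks the rows.
#'
#' @param cohort list of \linkS4class{PatientCase} objects.
#' @param model an \linkS4class{RBEModel}.
#' @param ... passed to \code{\link{accumulateDose}}.
#' @return data.frame of per-patient, per-organ metrics.
#' @export
cohortMetrics <- function(cohort, model, ...) {
  do.call(rbind, lapply(cohort, function(pt)
    organMetrics(pt, accumulateDose(pt, model, ...))))
}

#' Cohort summary: median and range per organ, model and metric
#'
#' @param metrics a metrics data.frame from \code{\link{cohortMetrics}}.
#' @param metricCols metric columns to summarize.
#' @return data.frame with columns organ, model, metric, median, min, max, n.
#' @export
populationSummary <- function(metrics,
                              metricCols = c("mean_dose", "mean_phys_dose",
                                             "d50", "d2", "mean_letd",
                                             "rbe_d", "rbe_d2pct")) {
  groups <- unique(metrics[, c("organ", "model")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- metrics[metrics$organ == groups$organ[i] &
                     metrics$model == groups$model[i], ]
    do.call(rbind, lapply(metricCols, function(mc) {
      mr <- medianRange(sub[[mc]])
      data.frame(organ = groups$organ[i], model = groups$model[i],
                 metric = mc, median = mr[["median"]], min = mr[["min"]],
                 max = mr[["max"]], n = nrow(sub), stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Compare individual, population and constant-1.1 dose estimates
#'
#' For one organ and model, computes per patient the RBE-weighted mean dose
#' from (i) the patient's own organ RBE, (ii) the cohort-median organ RBE,
#' and (iii) the constant clinical RBE of 1.1, plus the absolute deviations
#' of the population and constant estimates from the individual one.
#'
#' @param metrics a metrics data.frame from \code{\link{cohortMetrics}}.
#' @param organ organ name.
#' @param model model id.
#' @param patients optional patient ids that must all be present.
#' @return data.frame with columns patient_id, organ, model,
#'   mean_phys_dose, individual, population, constant_1p1,
#'   dev_population, dev_constant (all doses in Gy(RBE)).
#' @export
compareDoseEstimates <- function(metrics, organ, model,
                                 patients = NULL) {
  sub <- metrics[metrics$organ == organ & metrics$model == model, ]
  if (!nrow(sub))
    stop(sprintf("no metric rows for organ '%s', model '%s'", organ, model))
  if (!is.null(patients)) {
    missing <- setdiff(patients, sub$patient_id)
    if (length(missing))
      stop("missing patient rows: ", paste(missing, collapse = ", "))
  }
  med <- stats::median(sub$rbe_d)
  individual <- sub$mean_phys_dose * sub$rbe_d
  population <- sub$mean_phys_dose * med
  constant <- sub$mean_phys_dose * 1.1
  data.frame(patient_id = sub$patient_id, organ = organ, model = model,
             mean_phys_dose = sub$mean_phys_dose,
             individual = individual, population = population,
             constant_1p1 = constant,
             dev_population = abs(individual - population),
             dev_constant = abs(individual - constant),
             stringsAsFactors = FALSE)
}

#' Sweep a metric over the (alpha/beta)x confidence interval
#'
#' Re-evaluates the full voxel pipeline for one organ of one patient at
#' \code{nGrid} evenly spaced (alpha/beta)x values spanning the tissue's
#' 95\% CI (endpoints included; no interpolation shortcuts), and reports
#' the metric envelope. Because the variable RBE models change
#' monotonically with (alpha/beta)x, the extremes should occur at the CI
#' endpoints — this is asserted against the grid, not assumed, and reported
#' in \code{extremesAtEndpoints}.
#'
#' @param patient a \linkS4class{PatientCase}.
#' @param model an \linkS4class{RBEModel}.
#' @param tissue \linkS4class{TissueParams} with the CI to sweep.
#' @param organ organ name (must have a mask).
#' @param metric \code{"rbe_d"} or \code{"rbe_d2pct"}.
#' @param nGrid number of grid points, >= 2.
#' @param ... passed to \code{\link{accumulateDose}}.
#' @return List with \code{grid} (data.frame alpha_beta, value),
#'   \code{envelope} = c(min, max), \code{nominal} (metric at the nominal
#'   (alpha/beta)x) and \code{extremesAtEndpoints} (logical).
#' @export
alphaBetaSweep <- function(patient, model, tissue, organ,
                           metric = c("rbe_d", "rbe_d2pct"), nGrid = 7L,
                           ...) {
  metric <- match.arg(metric)
  if (nGrid < 2L) stop("'nGrid' must be >= 2")
  if (is.null(patient@masks[[organ]]))
    stop(sprintf("patient has no mask for '%s'", organ))
  ci <- tissue@ci
  grid <- unique(c(seq(ci[1], ci[2], length.out = nGrid), tissue@alphaBeta))
  grid <- sort(grid)
  evalAt <- function(ab) {
    tm <- list(TissueParams(tissue@organ, ab))
    names(tm) <- organ
    res <- accumulateDose(patient, model, tissueMap = tm, ...)
    m <- patient@masks[[organ]]
    if (metric == "rbe_d") rbeD(res, m, organ) else rbeD2pct(res, m, organ = organ)
  }
  values <- vapply(grid, evalAt, 0)
  env <- range(values)
  atEnds <- isTRUE(all.equal(env,
                             sort(c(values[1], values[length(values)]))))
  list(grid = data.frame(alpha_beta = grid, value = values),
       envelope = env,
       nominal = values[which.min(abs(grid - tissue@alphaBeta))],
       extremesAtEndpoints = atEnds)
}
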