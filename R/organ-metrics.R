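# Organ-level DVH/LVH curves and scalar metrics.
#
# Conventions, fixed here once: D_x% is the minimum dose among the hottest
# ceiling(x% * N) voxels (descending-sort counting, no interpolation);
# organ-mean LETd is the plain arithmetic mean over all organ voxels with an
# optional total-dose threshold; voxel volume is uniform (masks are
# voxel-aligned), so volumes are voxel counts.

#' Cumulative dose- or LET-volume histogram
#'
#' Exact voxel-counting cumulative curve: \code{volumeFraction[i]} is the
#' fraction of organ voxels with value >= \code{axis[i]}. The same machinery
#' serves DVHs (dose field) and LVHs (LET field).
#'
#' @param field a \linkS4class{VoxelField}.
#' @param mask logical array on the same grid, non-empty.
#' @param nBins number of axis points (from 0 to the organ maximum).
#' @param organ organ name used in error messages.
#' @return A data.frame with columns \code{axis} (field units, strictly
#'   increasing) and \code{volume_fraction} (non-increasing, starts at 1).
#' @examples
#' f <- VoxelField(array(runif(64), c(4, 4, 4)), c(2, 2, 2))
#' dvh <- cumulativeDVH(f, array(TRUE, c(4, 4, 4)), nBins = 50)
#' @export
cumulativeDVH <- function(field, mask, nBins = 200L, organ = "organ") {
  stopifnot(is(field, "VoxelField"))
  if (!identical(dim(mask), dim(field@data)))
    stop("mask shape does not match the field grid")
  if (!any(mask)) stop(sprintf("empty mask for '%s'", organ))
  if (nBins < 2L) stop("'nBins' must be >= 2")
  v <- field@data[mask]
  axis <- seq(0, max(v), length.out = nBins)
  vf <- vapply(axis, function(t) mean(v >= t), 0)
  data.frame(axis = axis, volume_fraction = vf)
}

#' Dose at volume (D_x\%)
#'
#' The minimum dose among the hottest \code{ceiling(x\% * N)} voxels, i.e.
#' the near-maximum dose received by at least x\% of the organ volume.
#' D50\% is the same statistic at 50\%.
#'
#' @param field a \linkS4class{VoxelField} or a numeric vector of voxel
#'   values.
#' @param mask logical array (required for a VoxelField).
#' @param volumePct volume percentage in (0, 100).
#' @param organ organ name used in error messages.
#' @return Dose (or LET) in the field's units.
#' @examples
#' doseAtVolume(as.numeric(1:100), volumePct = 2)  # 99
#' @export
doseAtVolume <- function(field, mask = NULL, volumePct, organ = "organ") {
  if (volumePct <= 0 || volumePct >= 100)
    stop("'volumePct' must lie strictly between 0 and 100")
  v <- if (is(field, "VoxelField")) {
    if (is.null(mask)) stop("a mask is required with a VoxelField")
    if (!any(mask)) stop(sprintf("empty mask for '%s'", organ))
    field@data[mask]
  } else as.numeric(field)
  if (!length(v)) stop(sprintf("empty mask for '%s'", organ))
  k <- ceiling(volumePct / 100 * length(v))
  sort(v, decreasing = TRUE)[k]
}

#' Organ-mean dose-averaged LET
#'
#' Plain arithmetic mean of voxel LETd over all organ voxels. Optionally,
#' voxels whose total RBE1.1-weighted dose falls below \code{doseThreshold}
#' Gy(RBE) are excluded (mirroring the display threshold used for dose/LET
#' maps); this variant is off by default.
#'
#' @param letField \linkS4class{VoxelField} of dose-averaged LET (keV/um).
#' @param mask logical array, non-empty.
#' @param doseField total physical dose \linkS4class{VoxelField} (Gy);
#'   required when \code{doseThreshold} is given.
#' @param doseThreshold threshold in Gy(RBE) under the constant RBE of 1.1,
#'   or NULL (no thresholding).
#' @param organ organ name used in error messages.
#' @return Mean LETd in keV/um.
#' @export
organMeanLET <- function(letField, mask, doseField = NULL,
                         doseThreshold = NULL, organ = "organ") {
  stopifnot(is(letField, "VoxelField"))
  if (!any(mask)) stop(sprintf("empty mask for '%s'", organ))
  if (!is.null(doseThreshold)) {
    if (is.null(doseField))
      stop("'doseField' is required when 'doseThreshold' is set")
    checkGridCompatible(letField, doseField, "LET and dose grids")
    mask <- mask & (doseField@data * 1.1 >= doseThreshold)
    if (!any(mask))
      stop(sprintf("no voxels of '%s' above the dose threshold", organ))
  }
  mean(letField@data[mask])
}

#' Dose-weighted organ-mean RBE
#'
#' \deqn{\overline{RBE}_d = \frac{\sum_i RBE_i D_{phys,i}}{\sum_i D_{phys,i}}
#'  = \frac{\bar D_{RBE}}{\bar D_{phys}},}
#' the ratio of organ-mean RBE-weighted dose over organ-mean physical dose,
#' computed from the phase-summed totals. Dose weighting keeps high-RBE
#' voxels with negligible dose from inflating the organ RBE.
#'
#' @param result an \linkS4class{RBEWeightedResult}.
#' @param mask logical organ mask, non-empty.
#' @param organ organ name used in error messages.
#' @return Dimensionless organ RBE.
#' @export
rbeD <- function(result, mask, organ = "organ") {
  stopifnot(is(result, "RBEWeightedResult"))
  if (!any(mask)) stop(sprintf("empty mask for '%s'", organ))
  mp <- mean(result@totalPhysicalDose@data[mask])
  if (mp <= 0)
    stop(sprintf("undefined RBE: zero organ physical dose for '%s'", organ))
  mean(result@totalRBEWeightedDose@data[mask]) / mp
}

#' Effective near-maximum-dose RBE (RBE_D2\%)
#'
#' The ratio of the D2\% of the RBE-weighted dose to the D2\% of the physical
#' dose, each computed independently from its own distribution over the
#' organ — no spatial correspondence between the two near-maximum voxel sets
#' is required.
#'
#' @inheritParams rbeD
#' @param volumePct the near-maximum volume percentage (default 2).
#' @return Dimensionless effective RBE of the near-maximum dose.
#' @export
rbeD2pct <- function(result, mask, volumePct = 2, organ = "organ") {
  stopifnot(is(result, "RBEWeightedResult"))
  if (!any(mask)) stop(sprintf("empty mask for '%s'", organ))
  d2phys <- doseAtVolume(result@totalPhysicalDose, mask, volumePct, organ)
  if (d2phys <= 0)
    stop(sprintf("undefined RBE: zero physical D%g%% for '%s'",
                 volumePct, organ))
  doseAtVolume(result@totalRBEWeightedDose, mask, volumePct, organ) / d2phys
}

# internal: per-voxel LETd combined over phases, weighted by phase dose
.combinedLET <- function(patient) {
  doses <- lapply(patient@phases, function(p) p@physicalDose@data)
  lets <- lapply(patient@phases, function(p) p@letd@data)
  tot <- Reduce(`+`, doses)
  num <- Reduce(`+`, mapply(`*`, doses, lets, SIMPLIFY = FALSE))
  out <- ifelse(tot > 0, num / pmax(tot, .Machine$double.xmin),
                Reduce(`+`, lets) / length(lets))
  VoxelField(array(out, dim(tot)), patient@spacing)
}

#' Per-organ scalar metrics for one patient and model
#'
#' One row per organ: RBE-weighted mean dose, D50\%, D2\% (all Gy(RBE)),
#' the physical mean dose (Gy), the organ-mean LETd (keV/um, phase-dose-
#' weighted voxel LET, plain mean over organ voxels), the dose-weighted
#' organ-mean RBE and the effective near-maximum-dose RBE.
#'
#' @param patient a \linkS4class{PatientCase}.
#' @param result the \linkS4class{RBEWeightedResult} for this patient.
#' @param organs organ names to report (default: organ masks that have
#'   tissue parameters attached to the result).
#' @param doseThreshold optional Gy(RBE) threshold for the organ-mean LETd
#'   (see \code{\link{organMeanLET}}).
#' @return data.frame with columns patient_id, organ, model, alpha_beta,
#'   mean_dose, mean_phys_dose, d50, d2, mean_letd, rbe_d, rbe_d2pct.
#' @examples
#' cfg <- phantomConfig(gridShape = c(32L, 32L, 80L), voxelSpacing = c(5, 5, 5))
#' pt <- generatePatient(cfg, 0L)
#' res <- accumulateDose(pt, rbeModel("mcn"))
#' organMetrics(pt, res)
#' @export
organMetrics <- function(patient, result,
                         organs = intersect(names(result@tissueMap),
                                            names(organMasks(patient))),
                         doseThreshold = NULL) {
  stopifnot(is(patient, "PatientCase"), is(result, "RBEWeightedResult"))
  letTot <- .combinedLET(patient)
  rows <- lapply(organs, function(o) {
    m <- patient@masks[[o]]
    if (is.null(m)) stop(sprintf("patient has no mask for '%s'", o))
    ab <- if (!is.null(result@tissueMap[[o]]))
      result@tissueMap[[o]]@alphaBeta else NA_real_
    rw <- result@totalRBEWeightedDose
    data.frame(
      patient_id = patient@patientId, organ = o, model = result@modelId,
      alpha_beta = ab,
      mean_dose = mean(rw@data[m]),
      mean_phys_dose = mean(result@totalPhysicalDose@data[m]),
      d50 = doseAtVolume(rw, m, 50, o),
      d2 = doseAtVolume(rw, m, 2, o),
      mean_letd = organMeanLET(letTot, m, result@totalPhysicalDose,
                               doseThreshold, o),
      rbe_d = rbeD(result, m, o),
      rbe_d2pct = rbeD2pct(result, m, organ = o),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
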