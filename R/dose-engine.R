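# Voxel-wise RBE evaluation and phase accumulation.
#
# RBE models are evaluated on per-fraction physical dose: the plans were
# optimized under the clinical constant RBE of 1.1, so each voxel's fraction
# dose is its total phase dose divided by the phase's fraction count. The
# RBE-weighted dose of a phase is (voxel RBE) x (voxel phase physical dose),
# and phases are summed voxel-wise to the treatment total.

#' Voxel RBE field of one treatment phase
#'
#' Evaluates the model at each voxel's per-fraction physical dose
#' (phase dose / fraction count) and LET quantity. \code{tissue} may be a
#' single \linkS4class{TissueParams} (uniform (alpha/beta)x) or a numeric
#' array on the phase grid with a per-voxel (alpha/beta)x (used for
#' organ-specific tissue maps). Zero-dose voxels take the analytic
#' zero-dose limit (RBEmax); they carry no weight in any dose-weighted
#' statistic downstream.
#'
#' @param phase a \linkS4class{TreatmentPhase}.
#' @param model an \linkS4class{RBEModel}.
#' @param tissue \linkS4class{TissueParams} or numeric (alpha/beta)x array.
#' @param rorFallback allow the spectrum model to fall back to the
#'   dose-averaged LET when the phase has no spectrum (approximation,
#'   off by default).
#' @return A \linkS4class{VoxelField} of dimensionless voxel RBE.
#' @export
computePhaseRBE <- function(phase, model, tissue, rorFallback = FALSE) {
  stopifnot(is(phase, "TreatmentPhase"), is(model, "RBEModel"))
  dose <- phase@physicalDose@data
  if (any(dose < 0)) stop("corrupt input: negative physical dose voxels")
  dims <- dim(dose)
  ab <- if (is(tissue, "TissueParams")) tissue@alphaBeta else {
    if (!identical(dim(tissue), dims) && length(tissue) != 1L)
      stop("per-voxel (alpha/beta)x array must match the phase grid")
    as.vector(tissue)
  }
  dFx <- as.vector(dose) / phase@nFractions
  spectrum <- NULL
  if (model@modelId == "ror" && !is.null(phase@spectrum)) {
    spectrum <- list(
      binCenters = phase@spectrum@binCenters,
      masses = matrix(phase@spectrum@masses,
                      nrow = prod(dims),
                      ncol = length(phase@spectrum@binCenters)))
  }
  rbe <- voxelRBE(model, dFx, as.vector(phase@letd@data), ab,
                  spectrum = spectrum, rorFallback = rorFallback)
  if (!all(is.finite(rbe))) stop("non-finite RBE values produced")
  VoxelField(array(rbe, dims), phase@physicalDose@spacing)
}

#' Accumulate RBE-weighted dose over treatment phases
#'
#' Builds a per-voxel (alpha/beta)x map from the organ masks (voxels in no
#' named organ take \code{defaultTissue}, a generic late-effects value of
#' 3 Gy by default), evaluates the per-phase RBE fields, and sums
#' RBE x physical dose over phases. Overlapping organ masks are resolved by
#' \code{precedence} (first named wins); with \code{precedence = NULL} any
#' overlap is an error.
#'
#' @param patient a \linkS4class{PatientCase}.
#' @param model an \linkS4class{RBEModel}.
#' @param tissueMap named list of \linkS4class{TissueParams}; every name
#'   must have a mask on the patient.
#' @param defaultTissue \linkS4class{TissueParams} for unassigned voxels.
#' @param precedence character vector ordering organs for overlap
#'   resolution, or NULL to forbid overlaps.
#' @param rorFallback passed to \code{\link{computePhaseRBE}}.
#' @return An \linkS4class{RBEWeightedResult}.
#' @examples
#' cfg <- phantomConfig(gridShape = c(32L, 32L, 80L), voxelSpacing = c(5, 5, 5))
#' pt <- generatePatient(cfg, 0L)
#' res <- accumulateDose(pt, rbeModel("constant_1p1"))
#' @export
accumulateDose <- function(patient, model,
                           tissueMap = defaultTissueParams()[
                             intersect(c("brainstem", "thyroid", "heart",
                                         "lungs"), names(organMasks(patient)))],
                           defaultTissue = defaultTissueParams()[["default"]],
                           precedence = c("brainstem", "thyroid", "heart",
                                          "lungs"),
                           rorFallback = FALSE) {
  stopifnot(is(patient, "PatientCase"), is(model, "RBEModel"))
  missing <- setdiff(names(tissueMap), names(patient@masks))
  if (length(missing))
    stop("no mask for tissue(s): ", paste(missing, collapse = ", "))

  dims <- dim(patient@phases[[1]]@physicalDose@data)
  organs <- names(tissueMap)
  if (length(organs) > 1L) {
    overlap <- Reduce(`+`, lapply(organs, function(o)
      as.integer(patient@masks[[o]])))
    if (any(overlap > 1L)) {
      if (is.null(precedence))
        stop("overlapping organ masks and no precedence order given")
      unknown <- setdiff(organs, precedence)
      if (length(unknown))
        stop("organs missing from precedence order: ",
             paste(unknown, collapse = ", "))
    }
  }
  abMap <- array(defaultTissue@alphaBeta, dims)
  # assign lowest-precedence organs first so higher precedence overwrites
  ordered <- if (is.null(precedence)) organs else
    intersect(rev(precedence), organs)
  for (o in ordered) abMap[patient@masks[[o]]] <- tissueMap[[o]]@alphaBeta

  rbeFields <- lapply(patient@phases, computePhaseRBE, model = model,
                      tissue = abMap, rorFallback = rorFallback)
  sp <- patient@spacing
  totPhys <- Reduce(`+`, lapply(patient@phases,
                                function(p) p@physicalDose@data))
  totRW <- Reduce(`+`, mapply(function(p, r) p@physicalDose@data * r@data,
                              patient@phases, rbeFields, SIMPLIFY = FALSE))
  new("RBEWeightedResult",
      rbeFieldPerPhase = rbeFields,
      totalPhysicalDose = VoxelField(totPhys, sp),
      totalRBEWeightedDose = VoxelField(totRW, sp),
      modelId = model@modelId,
      tissueMap = c(tissueMap, list(default = defaultTissue)))
}
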