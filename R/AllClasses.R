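#' @import methods
NULL

#' VoxelField: a 3D scalar grid with spacing metadata
#'
#' The universal currency between pipeline stages: a dense 3D array of voxel
#' values (physical dose in Gy, dose-averaged LET in keV/um, or a
#' dimensionless RBE field) together with the voxel spacing in mm per axis.
#' Voxel centres sit at \code{(index - 0.5) * spacing} mm with 1-based array
#' indices; masks are voxel-aligned (no partial volumes).
#'
#' @slot data numeric 3D array of voxel values.
#' @slot spacing numeric(3), mm per axis, strictly positive.
#' @exportClass VoxelField
setClass("VoxelField",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "'data' must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "'spacing' must be 3 strictly positive finite numbers (mm)")
    if (length(msg)) msg else TRUE
  }
)

#' LETSpectrum: per-voxel binned dose-weighted LET histogram
#'
#' Stores, for every voxel, the distribution of that voxel's physical dose
#' over LET bins. The bin masses of a voxel sum to the voxel's physical dose
#' (Gy), and the dose-weighted average LET of the spectrum reproduces the
#' voxel's stored dose-averaged LET.
#'
#' @slot binCenters numeric, strictly increasing LET bin centres (keV/um).
#' @slot masses numeric 4D array, \code{dim = c(grid, nbins)}; non-negative
#'   dose mass (Gy) per voxel and bin.
#' @exportClass LETSpectrum
setClass("LETSpectrum",
  representation(binCenters = "numeric", masses = "array"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@masses)) != 4L)
      msg <- c(msg, "'masses' must be a 4D array (grid x bins)")
    if (is.unsorted(object@binCenters, strictly = TRUE))
      msg <- c(msg, "'binCenters' must be strictly increasing")
    if (length(object@binCenters) != dim(object@masses)[4L])
      msg <- c(msg, "number of bins must match the 4th dimension of 'masses'")
    if (any(object@masses < 0)) msg <- c(msg, "bin masses must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

setClassUnion("LETSpectrumOrNULL", c("LETSpectrum", "NULL"))

#' TreatmentPhase: one phase of a fractionated proton plan
#'
#' A CSI treatment consists of an initial cranio-spinal phase and a
#' posterior-fossa boost phase. Each phase carries its total physical dose
#' grid, its dose-averaged LET grid, an optional per-voxel LET spectrum, the
#' fraction count and the prescribed fraction dose in Gy(RBE1.1). RBE models
#' are evaluated on the per-fraction physical dose
#' (voxel phase dose / fraction count).
#'
#' @slot name character, one of \code{"csi"} or \code{"boost"}.
#' @slot physicalDose \linkS4class{VoxelField}, Gy over the whole phase.
#' @slot letd \linkS4class{VoxelField}, dose-averaged LET in keV/um.
#' @slot spectrum optional \linkS4class{LETSpectrum} (or NULL).
#' @slot nFractions positive integer.
#' @slot fractionDoseRBE11 prescribed fraction dose in Gy(RBE), under the
#'   clinical constant RBE of 1.1.
#' @exportClass TreatmentPhase
setClass("TreatmentPhase",
  representation(
    name = "character", physicalDose = "VoxelField", letd = "VoxelField",
    spectrum = "LETSpectrumOrNULL", nFractions = "integer",
    fractionDoseRBE11 = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (!object@name %in% c("csi", "boost"))
      msg <- c(msg, "phase name must be 'csi' or 'boost'")
    if (!identical(dim(object@physicalDose@data), dim(object@letd@data)))
      msg <- c(msg, "dose and LET grids must share shape")
    if (!isTRUE(all.equal(object@physicalDose@spacing, object@letd@spacing)))
      msg <- c(msg, "dose and LET grids must share spacing")
    if (any(object@physicalDose@data < 0))
      msg <- c(msg, "physical dose must be >= 0 everywhere")
    if (any(object@letd@data < 0))
      msg <- c(msg, "LET must be >= 0 everywhere")
    if (length(object@nFractions) != 1L || object@nFractions < 1L)
      msg <- c(msg, "'nFractions' must be a single positive integer")
    if (length(object@fractionDoseRBE11) != 1L || object@fractionDoseRBE11 <= 0)
      msg <- c(msg, "'fractionDoseRBE11' must be a single positive number")
    if (!is.null(object@spectrum) &&
        !identical(dim(object@spectrum@masses)[1:3], dim(object@physicalDose@data)))
      msg <- c(msg, "spectrum grid must match the dose grid")
    if (length(msg)) msg else TRUE
  }
)

#' PatientCase: per-patient dose/LET grids and organ masks
#'
#' Bundles the treatment phases of one patient with the organ label masks on
#' the same grid. All grids across all phases share shape and spacing with
#' all masks, and every named mask is non-empty.
#'
#' @slot patientId character scalar.
#' @slot phases named list of \linkS4class{TreatmentPhase} objects, in
#'   treatment order.
#' @slot masks named list of logical 3D arrays (organ and target masks).
#' @slot spacing numeric(3) mm, shared by grids and masks.
#' @exportClass PatientCase
setClass("PatientCase",
  representation(patientId = "character", phases = "list",
                 masks = "list", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@phases) < 1L)
      msg <- c(msg, "at least one phase is required")
    if (!all(vapply(object@phases, is, logical(1), "TreatmentPhase")))
      msg <- c(msg, "all phases must be TreatmentPhase objects")
    dims <- lapply(object@phases, function(p) dim(p@physicalDose@data))
    if (length(unique(dims)) > 1L)
      msg <- c(msg, "all phases must share grid shape")
    ref <- dims[[1L]]
    for (nm in names(object@masks)) {
      m <- object@masks[[nm]]
      if (!is.logical(m) || !identical(dim(m), ref))
        msg <- c(msg, sprintf("mask '%s' must be a logical array on the phase grid", nm))
      else if (!any(m))
        msg <- c(msg, sprintf("mask '%s' is empty", nm))
    }
    if (is.null(names(object@masks)) && length(object@masks))
      msg <- c(msg, "masks must be named")
    if (length(msg)) msg else TRUE
  }
)

#' TissueParams: photon fractionation sensitivity of a tissue
#'
#' Carries the (alpha/beta)x ratio of a tissue in Gy with its 95\% confidence
#' interval. Low values correspond to late-responding tissue; the variable
#' RBE models predict higher RBE for lower (alpha/beta)x.
#'
#' @slot organ character, tissue/organ name.
#' @slot alphaBeta numeric, nominal (alpha/beta)x in Gy.
#' @slot ci numeric(2), 95\% CI (low, high) with 0 < low <= nominal <= high.
#' @exportClass TissueParams
setClass("TissueParams",
  representation(organ = "character", alphaBeta = "numeric", ci = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@alphaBeta) != 1L || object@alphaBeta <= 0)
      msg <- c(msg, "'alphaBeta' must be a single positive number (Gy)")
    if (length(object@ci) != 2L || object@ci[1] <= 0 ||
        object@ci[1] > object@alphaBeta || object@ci[2] < object@alphaBeta)
      msg <- c(msg, "'ci' must satisfy 0 < low <= nominal <= high")
    if (length(msg)) msg else TRUE
  }
)

#' RBEModel: a pluggable proton RBE model
#'
#' Maps (physical fraction dose, LET quantity, (alpha/beta)x) to a voxel RBE.
#' Three models are provided: the clinical constant RBE of 1.1
#' (\code{"constant_1p1"}), the McNamara linear-LET phenomenological model
#' (\code{"mcn"}), and a spectrum-based nonlinear-LET model (\code{"ror"})
#' with RBE_min fixed at exactly 1.
#'
#' @slot modelId one of \code{"constant_1p1"}, \code{"mcn"}, \code{"ror"}.
#' @slot coefficients named numeric vector of model coefficients.
#' @slot requiresSpectrum logical; TRUE for the spectrum-based model.
#' @slot version character, coefficient-file version string.
#' @exportClass RBEModel
setClass("RBEModel",
  representation(modelId = "character", coefficients = "numeric",
                 requiresSpectrum = "logical", version = "character"),
  validity = function(object) {
    if (!object@modelId %in% c("constant_1p1", "mcn", "ror"))
      return("modelId must be one of 'constant_1p1', 'mcn', 'ror'")
    TRUE
  }
)

#' RBEWeightedResult: voxel RBE fields and accumulated RBE-weighted dose
#'
#' Result of evaluating one RBE model on one patient: per-phase voxel RBE
#' fields, the phase-summed physical dose, and the phase-summed RBE-weighted
#' dose (phase RBE field x phase physical dose, summed voxel-wise).
#'
#' @slot rbeFieldPerPhase named list of \linkS4class{VoxelField}
#'   (dimensionless), one per phase.
#' @slot totalPhysicalDose \linkS4class{VoxelField}, Gy.
#' @slot totalRBEWeightedDose \linkS4class{VoxelField}, Gy(RBE).
#' @slot modelId character.
#' @slot tissueMap named list of \linkS4class{TissueParams} used per organ.
#' @exportClass RBEWeightedResult
setClass("RBEWeightedResult",
  representation(
    rbeFieldPerPhase = "list", totalPhysicalDose = "VoxelField",
    totalRBEWeightedDose = "VoxelField", modelId = "character",
    tissueMap = "list"
  )
)

#' PhantomConfig: parameters of the synthetic CSI phantom generator
#'
#' See \code{\link{phantomConfig}} for field meanings and defaults.
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  representation(
    gridShape = "integer", voxelSpacing = "numeric",
    spineRangeMm = "numeric", boostRegion = "numeric",
    organGeometry = "list", plateauLet = "numeric", distalLetMax = "numeric",
    falloffWidthMm = "numeric", nSpectrumBins = "integer", seed = "integer",
    boostLet = "numeric", craniumZMm = "numeric", noiseSd = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
      msg <- c(msg, "'gridShape' must be three positive integers")
    if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0))
      msg <- c(msg, "'voxelSpacing' must be three positive numbers (mm)")
    if (object@spineRangeMm <= 0) msg <- c(msg, "'spineRangeMm' must be > 0")
    if (object@falloffWidthMm <= 0) msg <- c(msg, "'falloffWidthMm' must be > 0")
    if (object@plateauLet <= 0) msg <- c(msg, "'plateauLet' must be > 0")
    if (object@distalLetMax <= object@plateauLet)
      msg <- c(msg, "'distalLetMax' must exceed 'plateauLet'")
    extent <- object@gridShape * object@voxelSpacing
    if (length(object@boostRegion) != 6L)
      msg <- c(msg, "'boostRegion' must be c(xmin, xmax, ymin, ymax, zmin, zmax) in mm")
    else {
      lo <- object@boostRegion[c(1, 3, 5)]; hi <- object@boostRegion[c(2, 4, 6)]
      if (any(lo < 0) || any(hi > extent) || any(lo >= hi))
        msg <- c(msg, "'boostRegion' must be a non-degenerate box inside the grid")
    }
    for (nm in names(object@organGeometry)) {
      g <- object@organGeometry[[nm]]
      if (!all(c("center", "size", "jitter") %in% names(g)))
        msg <- c(msg, sprintf("organ '%s' needs center, size and jitter", nm))
      else {
        if (any(g$size <= 0))
          msg <- c(msg, sprintf("organ '%s' size must be positive", nm))
        if (any(g$center - g$size / 2 < 0) || any(g$center + g$size / 2 > extent))
          msg <- c(msg, sprintf("organ '%s' nominal box must lie inside the grid", nm))
      }
    }
    if (object@nSpectrumBins < 0L)
      msg <- c(msg, "'nSpectrumBins' must be >= 0 (0 disables spectra)")
    if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' RunConfig: full pipeline run configuration
#'
#' See \code{\link{runConfig}}.
#' @exportClass RunConfig
setClass("RunConfig",
  representation(phantom = "PhantomConfig", models = "character",
                 tissues = "list", outputDir = "character",
                 format = "character", nPatients = "integer",
                 flags = "list"),
  validity = function(object) {
    msg <- character()
    known <- c("constant_1p1", "mcn", "ror")
    bad <- setdiff(object@models, known)
    if (length(bad))
      msg <- c(msg, sprintf("unknown model id(s): %s",
                            paste(bad, collapse = ", ")))
    organs <- setdiff(names(object@tissues), "default")
    noGeom <- setdiff(organs, names(object@phantom@organGeometry))
    if (length(noGeom))
      msg <- c(msg, sprintf("tissue(s) without phantom geometry: %s",
                            paste(noGeom, collapse = ", ")))
    if (object@nPatients < 1L) msg <- c(msg, "'nPatients' must be >= 1")
    if (length(msg)) msg else TRUE
  }
)
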