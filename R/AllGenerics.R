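#' @rdname VoxelField-class
#' @param object,x an object.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname VoxelField-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname VoxelField-class
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname PatientCase-class
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname PatientCase-class
#' @export
setGeneric("phases", function(x) standardGeneric("phases"))

#' @rdname PatientCase-class
#' @export
setGeneric("organMasks", function(x) standardGeneric("organMasks"))

#' @rdname TissueParams-class
#' @export
setGeneric("alphaBeta", function(x) standardGeneric("alphaBeta"))

#' @rdname TissueParams-class
#' @export
setGeneric("alphaBetaCI", function(x) standardGeneric("alphaBetaCI"))

#' @rdname RBEModel-class
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))

#' @rdname RBEModel-class
#' @export
setGeneric("modelCoefficients", function(x) standardGeneric("modelCoefficients"))

#' @rdname RBEModel-class
#' @export
setGeneric("requiresSpectrum", function(x) standardGeneric("requiresSpectrum"))

#' @rdname RBEWeightedResult-class
#' @export
setGeneric("totalPhysicalDose", function(x) standardGeneric("totalPhysicalDose"))

#' @rdname RBEWeightedResult-class
#' @export
setGeneric("totalRBEWeightedDose", function(x) standardGeneric("totalRBEWeightedDose"))

#' @rdname RBEWeightedResult-class
#' @export
setGeneric("rbeFields", function(x) standardGeneric("rbeFields"))
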