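#' Construct a VoxelField
#'
#' @param data numeric 3D array of voxel values.
#' @param spacing numeric(3), voxel spacing in mm per axis.
#' @return A \linkS4class{VoxelField}.
#' @examples
#' f <- VoxelField(array(1, dim = c(4, 4, 4)), spacing = c(2.5, 2.5, 2.5))
#' gridShape(f)
#' @export
VoxelField <- function(data, spacing) {
  storage.mode(data) <- "double"
  new("VoxelField", data = data, spacing = as.numeric(spacing))
}

#' @rdname VoxelField-class
#' @export
setMethod("voxelData", "VoxelField", function(x) x@data)

#' @rdname VoxelField-class
#' @export
setMethod("voxelSpacing", "VoxelField", function(x) x@spacing)

#' @rdname VoxelField-class
#' @export
setMethod("gridShape", "VoxelField", function(x) dim(x@data))

setMethod("show", "VoxelField", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelField: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  cat(sprintf("  range [%g, %g], mean %g\n",
              min(object@data), max(object@data), mean(object@data)))
})

#' @rdname PatientCase-class
#' @export
setMethod("patientId", "PatientCase", function(x) x@patientId)

#' @rdname PatientCase-class
#' @export
setMethod("phases", "PatientCase", function(x) x@phases)

#' @rdname PatientCase-class
#' @export
setMethod("organMasks", "PatientCase", function(x) x@masks)

setMethod("show", "PatientCase", function(object) {
  cat(sprintf("PatientCase '%s': %d phase(s) [%s]\n", object@patientId,
              length(object@phases),
              paste(vapply(object@phases, function(p) p@name, ""), collapse = ", ")))
  d <- dim(object@phases[[1]]@physicalDose@data)
  cat(sprintf("  grid %d x %d x %d @ %s mm\n", d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  nv <- vapply(object@masks, sum, 0L)
  cat(sprintf("  masks: %s\n",
              paste(sprintf("%s (%d vox)", names(nv), nv), collapse = ", ")))
})

#' @rdname TissueParams-class
#' @param organ organ name.
#' @param alphaBeta nominal (alpha/beta)x in Gy.
#' @param ci numeric(2), 95\% confidence interval (low, high) in Gy.
#' @export
TissueParams <- function(organ, alphaBeta, ci = c(alphaBeta, alphaBeta)) {
  new("TissueParams", organ = organ, alphaBeta = alphaBeta, ci = as.numeric(ci))
}

#' @rdname TissueParams-class
#' @export
setMethod("alphaBeta", "TissueParams", function(x) x@alphaBeta)

#' @rdname TissueParams-class
#' @export
setMethod("alphaBetaCI", "TissueParams", function(x) x@ci)

setMethod("show", "TissueParams", function(object) {
  cat(sprintf("TissueParams '%s': (alpha/beta)x = %g Gy (95%% CI %g-%g)\n",
              object@organ, object@alphaBeta, object@ci[1], object@ci[2]))
})

#' @rdname RBEModel-class
#' @export
setMethod("modelId", "RBEModel", function(x) x@modelId)

#' @rdname RBEModel-class
#' @export
setMethod("modelCoefficients", "RBEModel", function(x) x@coefficients)

#' @rdname RBEModel-class
#' @export
setMethod("requiresSpectrum", "RBEModel", function(x) x@requiresSpectrum)

setMethod("show", "RBEModel", function(object) {
  cat(sprintf("RBEModel '%s' (coefficients v%s)%s\n", object@modelId,
              object@version,
              if (object@requiresSpectrum) ", requires LET spectrum" else ""))
  if (length(object@coefficients))
    cat("  ", paste(sprintf("%s = %g", names(object@coefficients),
                            object@coefficients), collapse = ", "), "\n")
})

#' @rdname RBEWeightedResult-class
#' @export
setMethod("totalPhysicalDose", "RBEWeightedResult", function(x) x@totalPhysicalDose)

#' @rdname RBEWeightedResult-class
#' @export
setMethod("totalRBEWeightedDose", "RBEWeightedResult", function(x) x@totalRBEWeightedDose)

#' @rdname RBEWeightedResult-class
#' @export
setMethod("rbeFields", "RBEWeightedResult", function(x) x@rbeFieldPerPhase)

setMethod("show", "RBEWeightedResult", function(object) {
  cat(sprintf("RBEWeightedResult (model '%s'): phases [%s]\n", object@modelId,
              paste(names(object@rbeFieldPerPhase), collapse = ", ")))
  cat(sprintf("  max physical dose %.2f Gy, max RBE-weighted dose %.2f Gy(RBE)\n",
              max(object@totalPhysicalDose@data),
              max(object@totalRBEWeightedDose@data)))
})

# internal: stop unless two fields share grid shape and spacing
checkGridCompatible <- function(a, b, what = "grids") {
  if (!identical(dim(a@data), dim(b@data)))
    stop(sprintf("%s have mismatched shapes (%s vs %s)", what,
                 paste(dim(a@data), collapse = "x"),
                 paste(dim(b@data), collapse = "x")), call. = FALSE)
  if (!isTRUE(all.equal(a@spacing, b@spacing)))
    stop(sprintf("%s have mismatched spacing (%s vs %s mm)", what,
                 paste(format(a@spacing), collapse = "x"),
                 paste(format(b@spacing), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}
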