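# Volumetric grid and patient-case I/O (NIfTI) and run configuration.

#' Read and write voxel grids as NIfTI
#'
#' Grids are stored as double-precision NIfTI (.nii / .nii.gz) so the
#' write-then-read round trip preserves shape, spacing and values
#' bit-exactly. An optional reference grid enforces shape/spacing
#' consistency with a descriptive error.
#'
#' @param path file path ending in .nii or .nii.gz.
#' @param reference optional \linkS4class{VoxelField} the grid must match.
#' @return \code{readGrid}: a \linkS4class{VoxelField};
#'   \code{writeGrid}: the path, invisibly.
#' @examples
#' f <- VoxelField(array(rnorm(64), c(4, 4, 4)), c(2.5, 2.5, 2.5))
#' p <- tempfile(fileext = ".nii.gz")
#' writeGrid(f, p)
#' g <- readGrid(p)
#' stopifnot(identical(voxelData(f), voxelData(g)))
#' @export
readGrid <- function(path, reference = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (grepl("\\.nrrd$", path))
    stop("NRRD is not supported; use NIfTI (.nii / .nii.gz)")
  img <- RNifti::readNifti(path)
  field <- VoxelField(array(as.numeric(img), dim = dim(img)),
                      RNifti::pixdim(img))
  if (!is.null(reference))
    checkGridCompatible(field, reference,
                        sprintf("grid '%s' and reference", basename(path)))
  field
}

#' @rdname readGrid
#' @param field a \linkS4class{VoxelField} to write.
#' @export
writeGrid <- function(field, path) {
  stopifnot(is(field, "VoxelField"))
  if (grepl("\\.nrrd$", path))
    stop("NRRD is not supported; use NIfTI (.nii / .nii.gz)")
  img <- RNifti::asNifti(field@data)
  RNifti::pixdim(img) <- field@spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write and read a patient case on disk
#'
#' Writes per patient: \code{<id>_csi_dose}, \code{<id>_csi_letd},
#' \code{<id>_boost_dose}, \code{<id>_boost_letd} (double NIfTI),
#' \code{<id>_labels} (integer organ label volume, overlaps resolved by
#' \code{precedence}, first named wins) and a JSON sidecar
#' \code{<id>_meta.json} mapping label integers to organ names and phases
#' to fraction counts. LET spectra are not persisted.
#'
#' @param patient a \linkS4class{PatientCase}.
#' @param dir output directory (created if needed).
#' @param precedence organ precedence for the label volume.
#' @return The sidecar path, invisibly.
#' @export
writePatientCase <- function(patient, dir,
                             precedence = c("brainstem", "thyroid", "heart",
                                            "lungs", "ptv_boost",
                                            "ptv_csi")) {
  stopifnot(is(patient, "PatientCase"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- patient@patientId
  for (ph in patient@phases) {
    writeGrid(ph@physicalDose,
              file.path(dir, sprintf("%s_%s_dose.nii.gz", id, ph@name)))
    writeGrid(ph@letd,
              file.path(dir, sprintf("%s_%s_letd.nii.gz", id, ph@name)))
  }
  organs <- c(intersect(precedence, names(patient@masks)),
              setdiff(names(patient@masks), precedence))
  labels <- array(0, dim(patient@phases[[1]]@physicalDose@data))
  labelMap <- stats::setNames(seq_along(organs), organs)
  for (o in rev(organs)) labels[patient@masks[[o]]] <- labelMap[[o]]
  writeGrid(VoxelField(labels, patient@spacing),
            file.path(dir, sprintf("%s_labels.nii.gz", id)))
  meta <- list(
    patient_id = id,
    labels = as.list(labelMap),
    phases = lapply(patient@phases, function(p)
      list(n_fractions = p@nFractions,
           fraction_dose_rbe11 = p@fractionDoseRBE11)),
    spacing_mm = patient@spacing)
  metaPath <- file.path(dir, sprintf("%s_meta.json", id))
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(metaPath)
}

#' @rdname writePatientCase
#' @param id patient id of the case to read back.
#' @export
readPatientCase <- function(dir, id) {
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_meta.json", id)),
                              simplifyVector = TRUE)
  labels <- readGrid(file.path(dir, sprintf("%s_labels.nii.gz", id)))
  masks <- lapply(meta$labels, function(k) labels@data == k)
  phs <- lapply(names(meta$phases), function(nm) {
    dose <- readGrid(file.path(dir, sprintf("%s_%s_dose.nii.gz", id, nm)))
    letd <- readGrid(file.path(dir, sprintf("%s_%s_letd.nii.gz", id, nm)),
                     reference = dose)
    new("TreatmentPhase", name = nm, physicalDose = dose, letd = letd,
        spectrum = NULL,
        nFractions = as.integer(meta$phases[[nm]]$n_fractions),
        fractionDoseRBE11 = meta$phases[[nm]]$fraction_dose_rbe11)
  })
  names(phs) <- names(meta$phases)
  new("PatientCase", patientId = id, phases = phs, masks = masks,
      spacing = as.numeric(meta$spacing_mm))
}

#' Assemble or load a pipeline run configuration
#'
#' A run configuration bundles the phantom parameters, the RBE models to
#' evaluate, the tissue parameters, the output directory and processing
#' flags. \code{readRunConfig} loads the same structure from a YAML file
#' whose keys mirror the \code{\link{phantomConfig}} field names.
#'
#' @param phantom a \linkS4class{PhantomConfig}.
#' @param models model ids to evaluate.
#' @param tissues named list of \linkS4class{TissueParams}.
#' @param outputDir output directory.
#' @param format volumetric container format; only \code{"nifti"} is
#'   supported.
#' @param nPatients cohort size.
#' @param flags list of processing flags: \code{let_dose_threshold}
#'   (Gy(RBE) or NULL), \code{ror_fallback} (logical), \code{n_grid}
#'   (sweep grid size), \code{alpha_beta} (one of nominal, ci-low,
#'   ci-high, sweep).
#' @return A \linkS4class{RunConfig}.
#' @export
runConfig <- function(phantom = phantomConfig(),
                      models = c("constant_1p1", "mcn"),
                      tissues = defaultTissueParams(),
                      outputDir = "protonRBE_out",
                      format = "nifti",
                      nPatients = 10L,
                      flags = list()) {
  defaults <- list(let_dose_threshold = NULL, ror_fallback = FALSE,
                   n_grid = 7L, alpha_beta = "nominal")
  flags <- utils::modifyList(defaults, flags)
  if (!identical(format, "nifti"))
    stop("only the 'nifti' container format is supported")
  new("RunConfig", phantom = phantom, models = models, tissues = tissues,
      outputDir = outputDir, format = format,
      nPatients = as.integer(nPatients), flags = flags)
}

#' @rdname runConfig
#' @param path path to a YAML configuration file.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- y$phantom
  phantomArgs <- list()
  fieldMap <- c(grid_shape = "gridShape", voxel_spacing = "voxelSpacing",
                spine_range_mm = "spineRangeMm", boost_region = "boostRegion",
                plateau_let = "plateauLet", distal_let_max = "distalLetMax",
                falloff_width_mm = "falloffWidthMm",
                n_spectrum_bins = "nSpectrumBins", seed = "seed",
                boost_let = "boostLet", cranium_z_mm = "craniumZMm",
                noise_sd = "noiseSd")
  for (k in names(fieldMap))
    if (!is.null(ph[[k]])) phantomArgs[[fieldMap[[k]]]] <- unlist(ph[[k]])
  if (!is.null(ph$organ_geometry))
    phantomArgs$organGeometry <- lapply(ph$organ_geometry, function(g)
      lapply(g, unlist))
  tissues <- if (is.null(y$tissues)) defaultTissueParams() else {
    out <- lapply(names(y$tissues), function(nm)
      TissueParams(nm, y$tissues[[nm]]$alpha_beta,
                   unlist(y$tissues[[nm]]$ci %||% y$tissues[[nm]]$alpha_beta)))
    stats::setNames(out, names(y$tissues))
  }
  runConfig(phantom = do.call(phantomConfig, phantomArgs),
            models = unlist(y$models %||% c("constant_1p1", "mcn")),
            tissues = tissues,
            outputDir = y$output_dir %||% "protonRBE_out",
            format = y$format %||% "nifti",
            nPatients = y$n_patients %||% 10L,
            flags = y$flags %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
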